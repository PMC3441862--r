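## Synthetic paired tumor/normal cohort generator. The generator writes down
## its own ground truth (which segments were injected into which samples and
## which genes carry a dosage effect), so every downstream stage can be
## benchmarked for parameter recovery. Defaults emulate the study design:
## 27 sample pairs, uniformly spaced probes on 4 chromosomes, injected
## gain/loss segments with carrier fractions spanning 0.15-0.70 (so both
## recurrent and non-recurrent aberrations exist), one histology-linked
## segment, and gene expression that tracks gene dosage with Gaussian log2
## noise. All randomness flows from the single seed argument through one
## set.seed call; draws happen in a fixed documented order (metadata,
## carriers, probe noise, baselines, expression noise).

#' Noise model for the synthetic cohort
#'
#' @param probeSigma Gaussian s.d. of probe log2 ratios (default 0.2).
#' @param exprSigma Gaussian s.d. of log2 expression noise (default 0.3).
#' @param centeringOffset Global shift added to all raw ratios so the
#'   centralization step has work to do (default 0.1).
#' @return A list with the three components.
#' @export
noiseModel <- function(probeSigma = 0.2, exprSigma = 0.3,
                       centeringOffset = 0.1) {
    if (probeSigma < 0 || exprSigma < 0)
        stop("noise sigmas must be non-negative")
    list(probeSigma = probeSigma, exprSigma = exprSigma,
         centeringOffset = centeringOffset)
}

#' Default injected-segment specification
#'
#' Eight segments over four 20-Mb chromosomes, mirroring the aberration
#' structure of a gastric-cancer cohort: a large high-frequency gain
#' (70\% carriers, the 8q analogue), a second frequent gain (63\%, the 20q
#' analogue), mid-frequency gains and losses (26--44\%), one non-recurrent
#' gain (15\%), and one gain linked to the MD histology class (80\% of MD
#' samples, absent elsewhere) to exercise the subtype scan. Shifts are
#' +/-0.8 log2 units.
#'
#' @param chromLengthBp Simulated chromosome length in bp (default 2e7).
#' @return A \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end}, \code{direction}, \code{shift}, \code{carrierFraction},
#'   \code{linkedClass} (NA for unlinked segments).
#' @export
defaultTruthSpec <- function(chromLengthBp = 2e7) {
    u <- chromLengthBp / 20  # segment coordinates laid out on a 20-unit grid
    data.frame(
        chrom = c("1", "1", "2", "2", "3", "3", "4", "4"),
        start = u * c(4, 13, 2, 12, 3, 11, 5, 12) + 1,
        end = u * c(9, 14.5, 7, 13.5, 6, 14, 7, 16),
        direction = c("gain", "gain", "gain", "gain", "loss", "gain",
                      "loss", "gain"),
        shift = c(0.8, 0.8, 0.8, 0.8, -0.8, 0.8, -0.8, 0.8),
        carrierFraction = c(19/27, 7/27, 17/27, 0.15, 9/27, NA, 7/27, 12/27),
        linkedClass = c(NA, NA, NA, NA, NA, "MD", NA, NA),
        linkedFraction = c(NA, NA, NA, NA, NA, 0.8, NA, NA),
        stringsAsFactors = FALSE)
}

## deterministic clinical labels: histology 12 PD (2 SRCC) / 11 MD / 4 M-PD
## at n = 27, scaled proportionally otherwise; stages follow the study's
## marginal counts (T1-2 vs T3-4 about 11:16, N0 about half, M1 in ~6/27).
.simulateMetadata <- function(sampleIdsVec) {
    n <- length(sampleIdsVec)
    nPD <- max(1L, round(n * 12 / 27))
    nMD <- max(1L, round(n * 11 / 27))
    nMPD <- n - nPD - nMD
    hist <- c(rep("PD", nPD), rep("MD", nMD), rep("M-PD", max(0L, nMPD)))
    srcc <- rep(FALSE, n)
    srcc[seq_len(min(2L, nPD))] <- TRUE
    tpool <- rep(c("T1", "T2", "T3", "T4"), times = c(5, 6, 8, 8))
    npool <- rep(c("N0", "N1", "N2", "N3"), times = c(14, 5, 4, 4))
    mpool <- rep(c("M0", "M1"), times = c(21, 6))
    idx <- (seq_len(n) - 1L) %% 27L + 1L
    data.frame(sample_id = sampleIdsVec,
               t_stage = tpool[idx], n_stage = npool[idx],
               m_stage = mpool[idx], histology = hist[seq_len(n)],
               srcc_flag = srcc, stringsAsFactors = FALSE)
}

#' Simulate a paired tumor/normal cohort with known truth
#'
#' Generates a probe-level log2-ratio table, a paired expression matrix,
#' sample metadata, a gene annotation and the injected ground truth.
#' Carrier samples receive probe ratios Normal(shift, probeSigma) inside
#' each injected segment; all other probes are Normal(0, probeSigma); the
#' centering offset is then added everywhere. Expression of a dosage gene
#' is baseline + coefficient x (the sample's true gene-level log2 copy
#' ratio) + Normal(0, exprSigma) in the tumor column and baseline + noise
#' in the normal column; null genes carry no dosage term. Within each
#' injected segment, alternating genes are dosage genes and the rest are
#' copy-altered bystanders with no expression response.
#'
#' @param nSamples Number of sample pairs (>= 4; default 27).
#' @param nProbesPerChrom Uniformly spaced probes per chromosome
#'   (default 2000).
#' @param nChrom Number of simulated chromosomes (default 4).
#' @param probeSpacing Probe spacing in bp (default 10000).
#' @param nGenes Number of annotated genes (default 500).
#' @param truthSpec Segment specification as from
#'   \code{\link{defaultTruthSpec}}.
#' @param noise A \code{\link{noiseModel}}.
#' @param dosageCoefficient Dosage coefficient given to dosage genes
#'   (default 1.0).
#' @param seed Integer seed; fixed seed gives identical cohorts.
#' @return A list with elements \code{probes} (\code{\link{ProbeSet}}),
#'   \code{expression} (\code{\link{PairedExpression}}), \code{metadata}
#'   (\code{data.frame}), \code{annotation} (\code{GRanges}) and
#'   \code{truth} (\code{SyntheticTruth}).
#' @export
#' @examples
#' sim <- simulateCohort(nSamples = 8, nProbesPerChrom = 200, nGenes = 60,
#'                       seed = 1)
#' sim$probes
#' truthSegments(sim$truth)
simulateCohort <- function(nSamples = 27L, nProbesPerChrom = 2000L,
                           nChrom = 4L, probeSpacing = 10000L,
                           nGenes = 500L,
                           truthSpec = defaultTruthSpec(
                               nProbesPerChrom * probeSpacing),
                           noise = noiseModel(),
                           dosageCoefficient = 1.0, seed = 1L) {
    if (nSamples < 4) stop("nSamples must be >= 4")
    chromLen <- nProbesPerChrom * probeSpacing
    chroms <- as.character(seq_len(nChrom))
    bad <- !(truthSpec$chrom %in% chroms) | truthSpec$end > chromLen |
        truthSpec$start < 1
    if (any(bad))
        stop("injected segment outside the simulated chromosome span")
    set.seed(as.integer(seed))

    sampleIdsVec <- sprintf("S%02d", seq_len(nSamples))
    meta <- .simulateMetadata(sampleIdsVec)

    ## carrier sets per segment (draw order fixed: one draw per segment row)
    carriers <- vector("list", nrow(truthSpec))
    for (i in seq_len(nrow(truthSpec))) {
        if (!is.na(truthSpec$linkedClass[i])) {
            pool <- meta$sample_id[meta$histology == truthSpec$linkedClass[i]]
            k <- round(truthSpec$linkedFraction[i] * length(pool))
        } else {
            pool <- sampleIdsVec
            k <- round(truthSpec$carrierFraction[i] * nSamples)
        }
        carriers[[i]] <- sort(sample(pool, k))
    }

    ## probe scaffold
    starts <- rep(seq(1L, by = probeSpacing, length.out = nProbesPerChrom),
                  times = nChrom)
    probeGr <- GRanges(rep(chroms, each = nProbesPerChrom),
                       IRanges(starts, width = 60L))
    names(probeGr) <- sprintf("P%06d", seq_along(probeGr))

    ratios <- matrix(rnorm(length(probeGr) * nSamples, 0,
                           noise$probeSigma),
                     nrow = length(probeGr), ncol = nSamples,
                     dimnames = list(names(probeGr), sampleIdsVec))
    segGr <- GRanges(truthSpec$chrom,
                     IRanges(as.integer(truthSpec$start),
                             as.integer(truthSpec$end)))
    hits <- findOverlaps(probeGr, segGr)
    for (i in seq_len(nrow(truthSpec))) {
        pr <- S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == i]
        cs <- match(carriers[[i]], sampleIdsVec)
        ratios[pr, cs] <- ratios[pr, cs] + truthSpec$shift[i]
    }
    ratios <- ratios + noise$centeringOffset
    probes <- ProbeSet(probeGr, ratios)

    ## gene annotation: evenly spaced 20-kb genes
    genesPerChrom <- ceiling(nGenes / nChrom)
    geneStarts <- round(seq(probeSpacing, chromLen - 3 * probeSpacing,
                            length.out = genesPerChrom))
    annGr <- GRanges(rep(chroms, each = genesPerChrom),
                     IRanges(rep(geneStarts, times = nChrom),
                             width = 20000L),
                     strand = rep(c("+", "-"),
                                  length.out = genesPerChrom * nChrom))
    annGr <- annGr[seq_len(min(nGenes, length(annGr)))]
    sym <- sprintf("G%04d", seq_along(annGr))
    names(annGr) <- sym
    annGr$gene_symbol <- sym
    annGr <- annGr[.karyotypeOrder(as.character(seqnames(annGr)),
                                   start(annGr))]

    ## true gene-level copy state: shift of the segment containing the gene
    ## midpoint (genes straddling a boundary take the midpoint's state)
    mid <- GRanges(seqnames(annGr),
                   IRanges(start(annGr) + width(annGr) %/% 2L, width = 1L))
    geneSeg <- rep(NA_integer_, length(annGr))
    gh <- findOverlaps(mid, segGr)
    geneSeg[S4Vectors::queryHits(gh)] <- S4Vectors::subjectHits(gh)

    geneCN <- matrix(0, length(annGr), nSamples,
                     dimnames = list(names(annGr), sampleIdsVec))
    inSeg <- which(!is.na(geneSeg))
    for (g in inSeg) {
        i <- geneSeg[g]
        geneCN[g, match(carriers[[i]], sampleIdsVec)] <- truthSpec$shift[i]
    }

    ## dosage genes: alternating genes within segments respond to dosage
    dosage <- inSeg[seq_along(inSeg) %% 2L == 1L]
    coef <- rep(0, length(annGr))
    coef[dosage] <- dosageCoefficient

    baseline <- rnorm(length(annGr), 7, 1)
    ## a handful of never-expressed genes to exercise the signal filter
    low <- setdiff(which(seq_along(annGr) %% 20L == 0L), inSeg)
    baseline[low] <- 3.0
    baseline[dosage] <- pmax(baseline[dosage], 5.5)

    nmat <- baseline + matrix(rnorm(length(annGr) * nSamples, 0,
                                    noise$exprSigma),
                              length(annGr), nSamples)
    tmat <- baseline + coef * geneCN +
        matrix(rnorm(length(annGr) * nSamples, 0, noise$exprSigma),
               length(annGr), nSamples)
    signals <- cbind(tmat, nmat)
    colnames(signals) <- c(paste0(sampleIdsVec, "T"),
                           paste0(sampleIdsVec, "N"))
    rownames(signals) <- names(annGr)
    expr <- PairedExpression(signals)

    segOut <- segGr
    segOut$direction <- truthSpec$direction
    segOut$shift <- truthSpec$shift
    segOut$carriers <- IRanges::CharacterList(carriers)
    segOut$carrier_count <- lengths(carriers)
    segOut$carrier_fraction <- lengths(carriers) / nSamples
    segOut$linked_class <- truthSpec$linkedClass
    truth <- new("SyntheticTruth", segments = segOut,
                 dosageGenes = data.frame(
                     gene_symbol = names(annGr)[dosage],
                     coefficient = rep(dosageCoefficient, length(dosage)),
                     segment = geneSeg[dosage],
                     stringsAsFactors = FALSE),
                 nullGenes = names(annGr)[coef == 0],
                 noise = noise, seed = as.integer(seed))

    list(probes = probes, expression = expr, metadata = meta,
         annotation = annGr, truth = truth)
}

#' Simulate a pure-noise cohort
#'
#' A probe table with no injected segments (one chromosome, uniform
#' spacing): Normal(0, probeSigma) ratios plus the centering offset. Used
#' to estimate false-call rates of the segmentation under the null.
#'
#' @param nSamples Number of sample columns.
#' @param nProbes Number of probes.
#' @param probeSpacing Probe spacing in bp.
#' @param noise A \code{\link{noiseModel}}.
#' @param seed Integer seed.
#' @return A \code{\link{ProbeSet}}.
#' @export
simulateNullCohort <- function(nSamples = 27L, nProbes = 500L,
                               probeSpacing = 10000L, noise = noiseModel(),
                               seed = 1L) {
    set.seed(as.integer(seed))
    gr <- GRanges("1", IRanges(seq(1L, by = probeSpacing,
                                   length.out = nProbes), width = 60L))
    names(gr) <- sprintf("P%06d", seq_along(gr))
    ratios <- matrix(rnorm(nProbes * nSamples, 0, noise$probeSigma) +
                         noise$centeringOffset,
                     nrow = nProbes,
                     dimnames = list(names(gr),
                                     sprintf("S%02d", seq_len(nSamples))))
    ProbeSet(gr, ratios)
}
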