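## Cohort-level recurrence: per-probe gain/loss frequency profiles, maximal
## runs of probes altered in at least a fraction of the samples (recurrent
## regions), and the minimal common regions (MCRs) inside them: the loci
## where the carrier count attains its local maximum, i.e. the smallest
## intervals shared by the most samples. Gains and losses are treated
## fully independently throughout.

#' Genome-wide aberration frequency profile
#'
#' @param callMat Probe x sample call matrix from \code{\link{callMatrix}}.
#' @param probeSet The matching \code{\link{ProbeSet}}.
#' @return A \code{GRanges} (one range per probe) with metadata columns
#'   \code{gain_count} and \code{loss_count}; the number of samples is in
#'   \code{metadata()$n_samples}.
#' @export
frequencyProfile <- function(callMat, probeSet) {
    gr <- probeRanges(probeSet)
    if (nrow(callMat) != length(gr))
        stop("call matrix and probe set sizes differ")
    gr$gain_count <- as.integer(rowSums(callMat == 1L))
    gr$loss_count <- as.integer(rowSums(callMat == -1L))
    metadata(gr)$n_samples <- ncol(callMat)
    gr
}

## maximal runs of TRUE within each chromosome of a probe-level GRanges;
## returns data.frame(chrom, fromIdx, toIdx) in genome order
.probeRuns <- function(keep, chrom) {
    out <- list()
    for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        r <- rle(keep[idx])
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        w <- which(r$values)
        if (length(w))
            out[[ch]] <- data.frame(chrom = ch, fromIdx = idx[starts[w]],
                                    toIdx = idx[ends[w]])
    }
    if (!length(out))
        return(data.frame(chrom = character(0), fromIdx = integer(0),
                          toIdx = integer(0)))
    do.call(rbind, out)
}

.regionSummary <- function(profile, runs, direction, counts, nSamples) {
    if (!nrow(runs)) {
        gr <- GRanges()
        gr$direction <- character(0); gr$size_mb <- numeric(0)
        gr$count <- integer(0); gr$percent <- numeric(0)
        return(gr)
    }
    cnt <- vapply(seq_len(nrow(runs)), function(i)
        max(counts[runs$fromIdx[i]:runs$toIdx[i]]), integer(1))
    gr <- GRanges(runs$chrom,
                  IRanges(start(profile)[runs$fromIdx],
                          end(profile)[runs$toIdx]))
    gr$direction <- direction
    gr$size_mb <- sizeMb(start(gr), end(gr))
    gr$count <- cnt
    gr$percent <- percentLabel(cnt, nSamples)
    gr
}

#' Recurrent aberration regions
#'
#' Maximal runs of consecutive probes whose direction-specific carrier
#' count reaches at least \code{ceiling(recurrenceFraction * nSamples)}
#' samples (7 of 27 under the default 25\% rule). Region bounds are taken
#' from the first and last probe of the run; the reported count is the
#' maximum carrier count inside the run, with its percent label.
#'
#' @param profile Frequency profile from \code{\link{frequencyProfile}}.
#' @param recurrenceFraction Recurrence fraction (default 0.25).
#' @param nSamples Number of samples (taken from the profile's metadata if
#'   missing).
#' @return A \code{GRanges} of region summaries with \code{direction},
#'   \code{size_mb}, \code{count}, \code{percent}.
#' @export
recurrentRegions <- function(profile, recurrenceFraction = 0.25,
                             nSamples = metadata(profile)$n_samples) {
    k <- recurrenceCount(recurrenceFraction, nSamples)
    chrom <- as.character(seqnames(profile))
    out <- lapply(c("gain", "loss"), function(dir) {
        counts <- if (dir == "gain") profile$gain_count else
            profile$loss_count
        runs <- .probeRuns(counts >= k, chrom)
        .regionSummary(profile, runs, dir, counts, nSamples)
    })
    res <- suppressWarnings(c(out[[1]], out[[2]]))
    res[.karyotypeOrder(as.character(seqnames(res)), start(res))]
}

#' Minimal common regions of recurrent aberrations
#'
#' Within every recurrent region, the sub-run(s) where the carrier count
#' attains a local maximum: the minimal intervals shared by the most
#' samples. A count plateau is reported as an MCR when it is at least as
#' high as both neighbouring plateaus inside the run (run edges count as
#' lower neighbours), so a broad recurrent region can split into several
#' MCRs with their own frequencies.
#'
#' @inheritParams recurrentRegions
#' @return A \code{GRanges} of MCR summaries with \code{direction},
#'   \code{size_mb}, \code{count}, \code{percent} and the index of the
#'   containing recurrent region in \code{region_id}.
#' @export
minimalCommonRegions <- function(profile, recurrenceFraction = 0.25,
                                 nSamples = metadata(profile)$n_samples) {
    k <- recurrenceCount(recurrenceFraction, nSamples)
    chrom <- as.character(seqnames(profile))
    regions <- recurrentRegions(profile, recurrenceFraction, nSamples)
    res <- list()
    for (dir in c("gain", "loss")) {
        counts <- if (dir == "gain") profile$gain_count else
            profile$loss_count
        runs <- .probeRuns(counts >= k, chrom)
        if (!nrow(runs)) next
        for (i in seq_len(nrow(runs))) {
            idx <- runs$fromIdx[i]:runs$toIdx[i]
            r <- rle(counts[idx])
            nl <- length(r$values)
            leftLower <- c(TRUE, r$values[-nl] < r$values[-1])
            rightLower <- c(r$values[-1] < r$values[-nl], TRUE)
            locmax <- which(leftLower & rightLower)
            ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
            for (p in locmax) {
                sub <- idx[starts[p]:ends[p]]
                gr <- GRanges(chrom[sub[1]],
                              IRanges(start(profile)[sub[1]],
                                      end(profile)[sub[length(sub)]]))
                gr$direction <- dir
                gr$size_mb <- sizeMb(start(gr), end(gr))
                gr$count <- r$values[p]
                gr$percent <- percentLabel(r$values[p], nSamples)
                res[[length(res) + 1L]] <- gr
            }
        }
    }
    if (!length(res)) {
        gr <- GRanges()
        gr$direction <- character(0); gr$size_mb <- numeric(0)
        gr$count <- integer(0); gr$percent <- numeric(0)
        gr$region_id <- integer(0)
        return(gr)
    }
    mcr <- suppressWarnings(do.call(c, res))
    mcr <- mcr[.karyotypeOrder(as.character(seqnames(mcr)), start(mcr))]
    ## each MCR lies in exactly one same-direction recurrent region
    hits <- findOverlaps(mcr, regions)
    rid <- rep(NA_integer_, length(mcr))
    ok <- mcr$direction[S4Vectors::queryHits(hits)] ==
        regions$direction[S4Vectors::subjectHits(hits)]
    rid[S4Vectors::queryHits(hits)[ok]] <- S4Vectors::subjectHits(hits)[ok]
    mcr$region_id <- rid
    mcr
}

#' Attach target genes to regions
#'
#' Target genes of a region are the genes inside it whose dosage fold
#' change passes the target cutoff: \code{fc >= targetFcCutoff} for gain
#' regions, \code{fc <= 1/targetFcCutoff} for loss regions (2-fold by
#' default).
#'
#' @param regions Region summaries (\code{GRanges}).
#' @param dosage Gene dosage results from \code{\link{integrateDosage}}
#'   (needs \code{gene_symbol}, \code{chrom}, \code{start}, \code{end},
#'   \code{fc}).
#' @param targetFcCutoff Fold-change cutoff (default 2).
#' @return \code{regions} with a \code{target_genes} \code{CharacterList}
#'   column.
#' @export
annotateTargetGenes <- function(regions, dosage, targetFcCutoff = 2.0) {
    if (is.null(dosage) || !nrow(dosage))
        stop("integration results are required to annotate target genes")
    geneGr <- GRanges(dosage$chrom, IRanges(dosage$start, dosage$end))
    ## regions on chromosomes without any annotated gene are legitimate
    hits <- suppressWarnings(findOverlaps(regions, geneGr))
    tg <- vector("list", length(regions))
    for (i in seq_along(regions)) {
        g <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
        fc <- dosage$fc[g]
        pass <- if (regions$direction[i] == "gain")
            !is.na(fc) & fc >= targetFcCutoff
        else !is.na(fc) & fc <= 1 / targetFcCutoff
        tg[[i]] <- dosage$gene_symbol[g][pass]
    }
    regions$target_genes <- IRanges::CharacterList(tg)
    regions
}
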