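#' Run the full integrative analysis on a cohort
#'
#' Orchestrates the pipeline end to end: per-sample segmentation with the
#' aberration filters, call rasterization, genome-wide frequency profile,
#' recurrent regions and minimal common regions, the Fisher region scans
#' for the three clinical contrasts, gene-level dosage integration over
#' the recurrent regions, target-gene annotation of the MCRs, and two-way
#' clustering of the dosage-selected genes.
#'
#' @param probeSet A \code{\link{ProbeSet}}.
#' @param expr A \code{\link{PairedExpression}}.
#' @param meta Sample metadata (see \code{\link{readSampleMetadata}}).
#' @param annotation Gene annotation \code{GRanges}.
#' @param config A \code{\link{cnvConfig}}.
#' @return A list with elements \code{calls}, \code{callMatrix},
#'   \code{profile}, \code{regions}, \code{mcrs}, \code{contrasts},
#'   \code{scans} (one data.frame per contrast), \code{dosage},
#'   \code{cluster} (NULL when fewer than 2 genes are selected) and
#'   \code{config}.
#' @export
#' @examples
#' sim <- simulateCohort(nSamples = 8, nProbesPerChrom = 300, nGenes = 80,
#'                       seed = 2)
#' res <- runCohortAnalysis(sim$probes, sim$expression, sim$metadata,
#'                          sim$annotation, cnvConfig(seed = 2))
#' res$regions
runCohortAnalysis <- function(probeSet, expr, meta, annotation,
                              config = cnvConfig()) {
    validateSampleMetadata(meta, probeSet, expr)
    calls <- segmentCohort(probeSet, config)
    cm <- callMatrix(probeSet, calls)
    profile <- frequencyProfile(cm, probeSet)
    regions <- recurrentRegions(profile, config@recurrenceFraction)
    mcrs <- minimalCommonRegions(profile, config@recurrenceFraction)
    contrasts <- buildContrasts(meta)
    scans <- lapply(contrasts, function(ct)
        scanRegions(regions, calls, ct, config))
    dosage <- integrateDosage(probeSet, expr, annotation, regions, config)
    if (nrow(dosage))
        mcrs <- annotateTargetGenes(mcrs, dosage, config@targetFcCutoff)
    cluster <- NULL
    sel <- dosage$gene_symbol[dosage$selected_1p3]
    if (length(sel) >= 2) {
        ## cluster on the log2-ratio scale: each gene centered at its
        ## cohort mean, the scale heatmap displays
        m <- exprSignals(expr)[sel, , drop = FALSE]
        m <- m - rowMeans(m)
        tissue <- colData(expr)$tissue
        cluster <- twoWayCluster(m, tissue = tissue)
    }
    list(calls = calls, callMatrix = cm, profile = profile,
         regions = regions, mcrs = mcrs, contrasts = contrasts,
         scans = scans, dosage = dosage, cluster = cluster,
         config = config)
}

#' Recovery of injected segments by the recurrence analysis
#'
#' Benchmarks parameter recovery on a synthetic cohort: for every injected
#' segment at or above a carrier-fraction threshold, checks that a
#' same-direction recurrent region covers it with both boundary errors at
#' most \code{maxProbeError} probes.
#'
#' @param truth A \code{SyntheticTruth}.
#' @param regions Recurrent regions from \code{\link{recurrentRegions}}.
#' @param probeSpacing Probe spacing of the simulated array in bp.
#' @param minCarrierFraction Only segments at or above this carrier
#'   fraction are scored (default 0.30).
#' @param maxProbeError Allowed boundary error in probes (default 2).
#' @return A list with \code{nSegments}, \code{nRecovered},
#'   \code{recoveryRate} and the per-segment logical \code{recovered}.
#' @export
segmentRecovery <- function(truth, regions, probeSpacing = 10000L,
                            minCarrierFraction = 0.30, maxProbeError = 2L) {
    seg <- truthSegments(truth)
    seg <- seg[seg$carrier_fraction >= minCarrierFraction]
    tol <- maxProbeError * probeSpacing
    rec <- vapply(seq_along(seg), function(i) {
        cand <- regions[as.character(seqnames(regions)) ==
                            as.character(seqnames(seg[i])) &
                        regions$direction == seg$direction[i]]
        any(abs(start(cand) - start(seg[i])) <= tol &
            abs(end(cand) - end(seg[i])) <= tol)
    }, logical(1))
    list(nSegments = length(seg), nRecovered = sum(rec),
         recoveryRate = if (length(seg)) mean(rec) else NA_real_,
         recovered = rec)
}

#' Expected false calls per sample on a null cohort
#'
#' Segments pure-noise cohorts (no injected aberrations) and reports the
#' mean number of surviving calls per sample, the Monte-Carlo estimate of
#' the segmentation's false-call rate at the configured filters.
#'
#' @param nReplicates Number of null replicates (default 200).
#' @param nSamples Samples per replicate (each replicate segments
#'   \code{nSamples} independent noise tracks; default 1).
#' @param nProbes Probes per replicate (default 500).
#' @param noise A \code{\link{noiseModel}}.
#' @param config A \code{\link{cnvConfig}}.
#' @param seed Integer seed.
#' @return A list with \code{callsPerSample}, \code{se} (standard error),
#'   \code{nTracks}.
#' @export
nullCallRate <- function(nReplicates = 200L, nSamples = 1L, nProbes = 500L,
                         noise = noiseModel(), config = cnvConfig(),
                         seed = 1L) {
    counts <- integer(0)
    for (r in seq_len(nReplicates)) {
        ps <- simulateNullCohort(nSamples, nProbes, noise = noise,
                                 seed = seed + r - 1L)
        calls <- segmentCohort(ps, config)
        tab <- table(factor(calls$sample_id, levels = colnames(ps)))
        counts <- c(counts, as.integer(tab))
    }
    list(callsPerSample = mean(counts),
         se = sd(counts) / sqrt(length(counts)),
         nTracks = length(counts))
}
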