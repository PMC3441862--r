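## Per-sample aberration calling: centralization of the log2-ratio
## distribution, robust derivative-based noise estimation, and recursive
## maximal-scoring-interval segmentation with the aberration filters
## (minimum probes, minimum |mean log2|, maximum call count, chrY excluded).
##
## The interval score is S(I) = |mean(r over I)| * sqrt(|I|) / sigma_hat:
## the interval mean in noise-s.d. units scaled by the square root of the
## probe count, the published form of the aberration-detection statistic.
## The proprietary long-aberration GC ("fuzzy zero") correction is
## approximated by the |mean| >= minAbsMean amplitude floor applied after
## scoring. Probe-quality weights are omitted (equal weights): the probes
## here are homoscedastic and no weight source exists for plain log2 tables.

#' Centralize one sample's log2 ratios
#'
#' Subtracts the mode of the ratio distribution so the dominant
#' copy-neutral state sits at zero. The mode is located on a fixed-width
#' histogram (bin width 0.01) and refined by parabolic interpolation over
#' the modal bin and its neighbours. Idempotent up to the bin resolution.
#'
#' @param ratios Numeric vector of log2 ratios for one sample.
#' @param binWidth Histogram bin width (default 0.01).
#' @return The centered ratios, with the applied offset in
#'   \code{attr(, "offset")}.
#' @export
#' @examples
#' x <- centralizeRatios(rnorm(1000, 0.1, 0.05))
#' attr(x, "offset")  # close to 0.1
centralizeRatios <- function(ratios, binWidth = 0.01) {
    if (!length(ratios)) stop("no ratios to centralize")
    if (length(ratios) < 100)
        warning("fewer than 100 probes: mode estimate may be unstable")
    rng <- range(ratios)
    if (diff(rng) < binWidth) {  # all-constant input
        offset <- ratios[1]
        out <- ratios - offset
        attr(out, "offset") <- offset
        return(out)
    }
    breaks <- seq(rng[1] - binWidth, rng[2] + binWidth, by = binWidth)
    h <- graphics::hist(ratios, breaks = breaks, plot = FALSE)
    i <- which.max(h$counts)
    offset <- h$mids[i]
    if (i > 1 && i < length(h$counts)) {
        l <- h$counts[i - 1]; m <- h$counts[i]; r <- h$counts[i + 1]
        denom <- l - 2 * m + r
        if (denom < 0)  # proper peak; parabolic vertex refinement
            offset <- offset + 0.5 * binWidth * (l - r) / denom
    }
    out <- ratios - offset
    attr(out, "offset") <- offset
    out
}

#' Estimate probe-level noise from adjacent-probe differences
#'
#' A robust spread estimate in the spirit of derivative-based array-noise
#' measures: \code{sigma_hat = median(|r[i+1] - r[i]|) / (0.6745 * sqrt(2))}
#' over adjacent probes on the same chromosome. For i.i.d. Gaussian probes
#' this is consistent for the probe s.d. and is insensitive to the
#' occasional true copy-number step. Shift-invariant by construction.
#'
#' @param ratios Numeric vector of (centered) log2 ratios in genome order.
#' @param chrom Chromosome of each probe (differences are only taken within
#'   a chromosome); a single value is recycled.
#' @return \code{sigma_hat} (positive; floored at 1e-8 for degenerate
#'   constant input).
#' @export
estimateNoise <- function(ratios, chrom = "1") {
    if (length(ratios) < 2) stop("need at least 2 probes")
    chrom <- rep_len(as.character(chrom), length(ratios))
    d <- unlist(lapply(split(ratios, factor(chrom, unique(chrom))),
                       function(x) if (length(x) >= 2) abs(diff(x))),
                use.names = FALSE)
    if (!length(d))
        stop("no chromosome has 2 or more probes")
    max(median(d) / (0.6745 * sqrt(2)), 1e-8)
}

## recursive maximal-scoring-interval search over one chromosome's centered
## ratios; returns data.frame(startIdx, endIdx, nProbes, meanLog2, score)
.admSegments <- function(x, sigma, threshold) {
    out <- list()
    stack <- list(c(1L, length(x)))
    while (length(stack)) {
        b <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        lo <- b[1]; hi <- b[2]
        if (hi < lo) next
        res <- .bestIntervalCpp(x[lo:hi], sigma)
        if (is.na(res[1]) || res[3] < threshold) next
        s <- lo + as.integer(res[1]) - 1L
        e <- lo + as.integer(res[2]) - 1L
        out[[length(out) + 1L]] <-
            c(s, e, e - s + 1L, mean(x[s:e]), res[3])
        stack[[length(stack) + 1L]] <- c(lo, s - 1L)
        stack[[length(stack) + 1L]] <- c(e + 1L, hi)
    }
    if (!length(out))
        return(data.frame(startIdx = integer(0), endIdx = integer(0),
                          nProbes = integer(0), meanLog2 = numeric(0),
                          score = numeric(0)))
    m <- do.call(rbind, out)
    data.frame(startIdx = as.integer(m[, 1]), endIdx = as.integer(m[, 2]),
               nProbes = as.integer(m[, 3]), meanLog2 = m[, 4],
               score = m[, 5])
}

#' Segment one sample's centered log2 ratios into aberration calls
#'
#' Recursive maximal-scoring-interval search per chromosome: the
#' best-scoring interval with \code{S >= admThreshold} is called, then the
#' flanks are searched recursively; ties are broken leftmost-then-shortest.
#' The aberration filters are then applied in order: calls with fewer than
#' \code{minProbes} probes are dropped, calls with
#' \code{|mean log2| < minAbsMean} are dropped (shallow-call suppression),
#' and if more than \code{maxRegions} calls survive only the top-scoring
#' \code{maxRegions} are kept. Chromosome Y is excluded before calling.
#'
#' @param ratios Numeric vector of centered log2 ratios, one per probe, in
#'   genome order (see \code{\link{centralizeRatios}}).
#' @param probes \code{GRanges} of the probe positions (same order).
#' @param sigma Noise estimate from \code{\link{estimateNoise}}.
#' @param config A \code{\link{cnvConfig}}.
#' @param sampleId Sample label attached to the calls.
#' @return A \code{GRanges} of aberration calls with metadata columns
#'   \code{sample_id}, \code{n_probes}, \code{mean_log2}, \code{score},
#'   \code{direction}; calls within a sample/chromosome do not overlap.
#' @export
segmentSample <- function(ratios, probes, sigma, config = cnvConfig(),
                          sampleId = "S") {
    if (length(ratios) != length(probes))
        stop("ratios and probes lengths differ")
    chrom <- as.character(seqnames(probes))
    if (is.unsorted(.chromRank(chrom)) ||
        any(unlist(lapply(split(start(probes), factor(chrom, unique(chrom))),
                          is.unsorted))))
        stop("probes must be sorted in karyotype order")
    keep <- chrom != "Y"
    ratios <- ratios[keep]; probes <- probes[keep]; chrom <- chrom[keep]
    res <- list()
    for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        seg <- .admSegments(ratios[idx], sigma, config@admThreshold)
        if (!nrow(seg)) next
        seg$chrom <- ch
        seg$startBp <- start(probes)[idx[seg$startIdx]]
        seg$endBp <- end(probes)[idx[seg$endIdx]]
        res[[ch]] <- seg
    }
    if (!length(res)) return(.emptyCalls())
    seg <- do.call(rbind, res)
    seg <- seg[seg$nProbes >= config@minProbes, , drop = FALSE]
    seg <- seg[abs(seg$meanLog2) >= config@minAbsMean, , drop = FALSE]
    if (nrow(seg) > config@maxRegions)
        seg <- seg[order(seg$score, decreasing = TRUE)[
            seq_len(config@maxRegions)], , drop = FALSE]
    if (!nrow(seg)) return(.emptyCalls())
    gr <- GRanges(seg$chrom, IRanges(seg$startBp, seg$endBp))
    gr$sample_id <- sampleId
    gr$n_probes <- seg$nProbes
    gr$mean_log2 <- seg$meanLog2
    gr$score <- seg$score
    gr$direction <- ifelse(seg$meanLog2 > 0, "gain", "loss")
    sort(gr)
}

.emptyCalls <- function() {
    gr <- GRanges()
    gr$sample_id <- character(0)
    gr$n_probes <- integer(0)
    gr$mean_log2 <- numeric(0)
    gr$score <- numeric(0)
    gr$direction <- character(0)
    gr
}

#' Segment every sample of a cohort
#'
#' Runs, per sample: centralization over all probes, noise estimation on
#' the centered ratios, and \code{\link{segmentSample}}.
#'
#' @param probeSet A \code{\link{ProbeSet}}.
#' @param config A \code{\link{cnvConfig}}.
#' @return A \code{GRanges} of all samples' aberration calls, with the
#'   per-sample centralization offsets and noise estimates in
#'   \code{metadata()}.
#' @export
segmentCohort <- function(probeSet, config = cnvConfig()) {
    gr <- probeRanges(probeSet)
    m <- log2Ratios(probeSet)
    chrom <- as.character(seqnames(gr))
    offsets <- numeric(ncol(m)); sigmas <- numeric(ncol(m))
    names(offsets) <- names(sigmas) <- colnames(m)
    calls <- vector("list", ncol(m))
    for (j in seq_len(ncol(m))) {
        cen <- centralizeRatios(m[, j])
        offsets[j] <- attr(cen, "offset")
        sigmas[j] <- estimateNoise(as.numeric(cen), chrom)
        calls[[j]] <- segmentSample(as.numeric(cen), gr, sigmas[j], config,
                                    sampleId = colnames(m)[j])
    }
    out <- suppressWarnings(do.call(c, calls))
    metadata(out)$offsets <- offsets
    metadata(out)$sigmas <- sigmas
    metadata(out)$n_samples <- ncol(m)
    out
}

#' Rasterize aberration calls onto the probe grid
#'
#' @param probeSet A \code{\link{ProbeSet}}.
#' @param calls Calls from \code{\link{segmentCohort}}.
#' @return An integer matrix (probes x samples) with entries +1 (gain),
#'   0 (neutral), -1 (loss): a probe is marked iff it is covered by a
#'   surviving call of that direction in that sample.
#' @export
callMatrix <- function(probeSet, calls) {
    gr <- probeRanges(probeSet)
    m <- matrix(0L, length(gr), ncol(probeSet),
                dimnames = list(names(gr), colnames(probeSet)))
    if (!length(calls)) return(m)
    hits <- findOverlaps(gr, calls)
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    val <- ifelse(calls$direction[s] == "gain", 1L, -1L)
    m[cbind(q, match(calls$sample_id[s], colnames(m)))] <- val
    m
}
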