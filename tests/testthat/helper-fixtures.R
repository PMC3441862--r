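## Shared fixture builders: tiny probe sets and cohorts constructed in code.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(SummarizedExperiment)
})

## evenly spaced probes on one or more chromosomes
makeProbes <- function(nPerChrom, chroms = "1", spacing = 10000L,
                       width = 60L) {
    gr <- GRanges(rep(chroms, each = nPerChrom),
                  IRanges(rep(seq(1L, by = spacing, length.out = nPerChrom),
                              times = length(chroms)), width = width))
    names(gr) <- sprintf("P%05d", seq_along(gr))
    gr
}

## probe set with given ratio matrix (vector accepted for one sample)
makeProbeSet <- function(ratios, chroms = "1", spacing = 10000L) {
    if (is.null(dim(ratios))) ratios <- matrix(ratios, ncol = 1,
                                               dimnames = list(NULL, "S01"))
    nPerChrom <- nrow(ratios) / length(chroms)
    ProbeSet(makeProbes(nPerChrom, chroms, spacing), ratios)
}

## metadata mirroring the study's composition at arbitrary n
makeMeta <- function(n = 27) {
    sim <- simulateCohort(nSamples = n, nProbesPerChrom = 50, nGenes = 8,
                          truthSpec = defaultTruthSpec(50 * 10000)[0, ],
                          seed = 1)
    sim$metadata
}

## exhaustive O(n^2) maximal-scoring-interval oracle in plain R
oracleBestInterval <- function(x, sigma) {
    n <- length(x)
    best <- c(NA, NA, -1)
    for (i in seq_len(n)) {
        for (j in i:n) {
            m <- j - i + 1
            sc <- abs(mean(x[i:j])) * sqrt(m) / sigma
            if (sc > best[3] + 1e-12) best <- c(i, j, sc)
        }
    }
    best
}

## brute-force average-linkage agglomerator; returns sorted merge heights
oracleAverageLinkHeights <- function(d) {
    d <- as.matrix(d)
    n <- nrow(d)
    sizes <- rep(1, n)
    active <- seq_len(n)
    heights <- numeric(0)
    while (length(active) > 1) {
        best <- c(NA, NA, Inf)
        for (a in seq_along(active)) {
            for (b in seq_len(a - 1)) {
                i <- active[a]; j <- active[b]
                if (d[i, j] < best[3]) best <- c(i, j, d[i, j])
            }
        }
        i <- best[1]; j <- best[2]
        heights <- c(heights, best[3])
        ## average linkage: weighted by cluster sizes
        newd <- (sizes[i] * d[i, ] + sizes[j] * d[j, ]) /
            (sizes[i] + sizes[j])
        d[i, ] <- newd; d[, i] <- newd
        sizes[i] <- sizes[i] + sizes[j]
        active <- setdiff(active, j)
        d[j, ] <- Inf; d[, j] <- Inf
    }
    sort(heights)
}

## enumeration-free 2x2 Fisher closed form (hypergeometric tail sum)
oracleFisher2x2 <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    support <- max(0, k - n):min(k, m)
    pr <- dhyper(support, m, n, k)
    pobs <- dhyper(tab[1, 1], m, n, k)
    sum(pr[pr <= pobs * (1 + 1e-7)])
}
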