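## small helper: build a call matrix directly and wrap it in a profile
profileFrom <- function(cm, chroms = "1") {
    ps <- makeProbeSet(matrix(0, nrow(cm), ncol(cm),
                              dimnames = dimnames(cm)), chroms = chroms)
    frequencyProfile(cm, ps)
}

test_that("frequency profile counts gains and losses and conserves call totals", {
    set.seed(31)
    cm <- matrix(sample(c(-1L, 0L, 1L), 40 * 27, replace = TRUE,
                        prob = c(0.1, 0.6, 0.3)), 40, 27,
                 dimnames = list(sprintf("P%05d", 1:40),
                                 sprintf("S%02d", 1:27)))
    pf <- profileFrom(cm)
    expect_equal(sum(pf$gain_count), sum(cm == 1L))
    expect_equal(sum(pf$loss_count), sum(cm == -1L))
    expect_true(all(pf$gain_count + pf$loss_count <= 27))

    ## all-neutral matrix gives an all-zero profile
    pf0 <- profileFrom(matrix(0L, 10, 4))
    expect_true(all(pf0$gain_count == 0L & pf0$loss_count == 0L))

    ## 19 of 27 samples gained at a probe: count 19, percent label 70
    cm19 <- matrix(0L, 5, 27)
    cm19[3, 1:19] <- 1L
    pf19 <- profileFrom(cm19)
    expect_equal(pf19$gain_count[3], 19L)
    expect_equal(percentLabel(pf19$gain_count[3], 27), 70)
})

test_that("recurrent regions are maximal runs at the ceiling-threshold count", {
    ## k = ceil(0.25 * 27) = 7; a run at exactly 7 reports percent 26
    cm <- matrix(0L, 30, 27)
    cm[5:9, 1:7] <- 1L                   # run of 5 probes at count 7
    cm[15:19, 1:6] <- 1L                 # count 6: below threshold
    cm[22:24, 1:10] <- 1L                # second run at count 10
    cm[23, 1:10] <- 0L                   # split by one sub-threshold probe
    pf <- profileFrom(cm)
    rr <- recurrentRegions(pf, 0.25, 27)
    expect_equal(length(rr), 3L)
    expect_equal(rr$count, c(7L, 10L, 10L))
    expect_equal(rr$percent[1], 26)
    ## maximal-run contract: the sub-threshold probe splits the second run
    expect_equal(start(rr)[2:3], start(probeRanges(
        makeProbeSet(matrix(0, 30, 1))))[c(22, 24)])

    ## nothing above threshold: empty output
    cm6 <- matrix(0L, 10, 27); cm6[, 1:6] <- 1L
    expect_length(recurrentRegions(profileFrom(cm6), 0.25, 27), 0L)
})

test_that("MCRs are the locally maximal plateaus inside recurrent runs", {
    ## nested calls: one sample spans probes 1-100, nine others 40-60;
    ## k = 7 of 10 samples -> the MCR is probes 40-60 at count 10
    cm <- matrix(0L, 100, 10)
    cm[1:100, 1] <- 1L
    cm[40:60, 2:10] <- 1L
    pf <- profileFrom(cm)
    mcr <- minimalCommonRegions(pf, 0.25, 10)
    expect_equal(length(mcr), 1L)
    gr <- probeRanges(makeProbeSet(matrix(0, 100, 1)))
    expect_equal(start(mcr), start(gr)[40])
    expect_equal(end(mcr), end(gr)[60])
    expect_equal(mcr$count, 10L)
    ## brute-force maximal-overlap oracle: the deepest column count
    expect_equal(mcr$count, max(rowSums(cm)))

    ## a double-peaked run yields two MCRs inside one recurrent region
    cm2 <- matrix(0L, 40, 27)
    cm2[5:30, 1:8] <- 1L
    cm2[8:12, 9:14] <- 1L    # peak 1: count 14
    cm2[20:24, 9:12] <- 1L   # peak 2: count 12
    pf2 <- profileFrom(cm2)
    rr2 <- recurrentRegions(pf2, 0.25, 27)
    mcr2 <- minimalCommonRegions(pf2, 0.25, 27)
    expect_equal(length(rr2), 1L)
    expect_equal(length(mcr2), 2L)
    expect_equal(mcr2$count, c(14L, 12L))
    expect_true(all(mcr2$region_id == 1L))
    expect_true(all(start(mcr2) >= start(rr2) & end(mcr2) <= end(rr2)))
})

test_that("region output is invariant to sample column order", {
    set.seed(32)
    cm <- matrix(sample(c(-1L, 0L, 1L), 60 * 20, replace = TRUE,
                        prob = c(0.2, 0.4, 0.4)), 60, 20,
                 dimnames = list(NULL, sprintf("S%02d", 1:20)))
    perm <- sample(20)
    r1 <- recurrentRegions(profileFrom(cm), 0.25, 20)
    r2 <- recurrentRegions(profileFrom(cm[, perm]), 0.25, 20)
    expect_equal(start(r1), start(r2))
    expect_equal(r1$count, r2$count)
    m1 <- minimalCommonRegions(profileFrom(cm), 0.25, 20)
    m2 <- minimalCommonRegions(profileFrom(cm[, perm]), 0.25, 20)
    expect_equal(start(m1), start(m2))
})

test_that("target genes are selected by the two-fold rule with the reciprocal for losses", {
    regions <- GRanges(c("1", "2"), IRanges(c(1, 1), c(1e6, 1e6)))
    regions$direction <- c("gain", "loss")
    regions$count <- c(10L, 8L); regions$percent <- c(37, 30)
    regions$size_mb <- sizeMb(start(regions), end(regions))
    dosage <- data.frame(
        gene_symbol = c("A", "B", "C", "D", "E"),
        chrom = c("1", "1", "2", "2", "3"),
        start = c(100, 2000, 100, 2000, 100),
        end = c(1100, 3000, 1100, 3000, 1100),
        fc = c(2.1, 1.9, 0.45, 0.55, 5.0))
    ann <- annotateTargetGenes(regions, dosage, 2.0)
    expect_equal(as.character(ann$target_genes[[1]]), "A")  # 2.1 in, 1.9 out
    expect_equal(as.character(ann$target_genes[[2]]), "C")  # 0.45 <= 0.5
    ## region with no overlapping genes gives an empty list
    r3 <- GRanges("4", IRanges(1, 100))
    r3$direction <- "gain"
    r3$count <- 7L; r3$percent <- 26; r3$size_mb <- 0
    expect_length(annotateTargetGenes(r3, dosage)$target_genes[[1]], 0L)
    expect_error(annotateTargetGenes(regions, NULL), "integration")
})

test_that("recurrence analysis recovers injected segments on a synthetic cohort", {
    sim <- simulateCohort(nSamples = 12, nProbesPerChrom = 500,
                          nGenes = 60, truthSpec = defaultTruthSpec(5e6),
                          seed = 33)
    calls <- segmentCohort(sim$probes, cnvConfig())
    cm <- callMatrix(sim$probes, calls)
    pf <- frequencyProfile(cm, sim$probes)
    rr <- recurrentRegions(pf)
    rec <- segmentRecovery(sim$truth, rr, probeSpacing = 10000L,
                           minCarrierFraction = 0.30, maxProbeError = 2L)
    expect_gte(rec$recoveryRate, 0.95)
})
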