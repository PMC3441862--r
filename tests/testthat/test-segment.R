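test_that("centralization finds and removes the copy-neutral mode", {
    ## constant input: offset is the constant, output all zero
    x <- centralizeRatios(rep(0.1, 200))
    expect_equal(as.numeric(x), rep(0, 200))
    expect_equal(attr(x, "offset"), 0.1)

    ## 90/10 mixture: mode estimator lands within 0.02 of the neutral peak
    set.seed(101)
    y <- c(rnorm(9000, 0.1, 0.05), rnorm(1000, 1.1, 0.05))
    cy <- centralizeRatios(y)
    expect_lt(abs(attr(cy, "offset") - 0.1), 0.02)

    ## idempotence up to the bin resolution
    cz <- centralizeRatios(as.numeric(cy))
    expect_lt(abs(attr(cz, "offset")), 0.01)

    expect_warning(centralizeRatios(rnorm(50)), "fewer than 100")
})

test_that("derivative noise estimator is calibrated, exact on constructed input, and shift-invariant", {
    ## Monte-Carlo calibration on i.i.d. Gaussian probes
    set.seed(202)
    x <- rnorm(10000, 0, 0.2)
    expect_lt(abs(estimateNoise(x) - 0.2) / 0.2, 0.05)

    ## alternating +c/-c: every adjacent difference is exactly 2c
    c0 <- 0.3
    alt <- rep(c(c0, -c0), 50)
    expect_equal(estimateNoise(alt), 2 * c0 / (0.6745 * sqrt(2)))

    ## adding a constant changes nothing
    expect_equal(estimateNoise(x + 5), estimateNoise(x))

    ## differences never straddle a chromosome boundary
    two <- c(rep(0, 5), rep(10, 5))
    expect_equal(estimateNoise(two, rep(c("1", "2"), each = 5)), 1e-8)
})

test_that("segmentation calls injected segments and respects the aberration filters", {
    cfg <- cnvConfig()
    gr <- makeProbes(200)

    ## null signal: no calls
    expect_length(segmentSample(rep(0, 200), gr, 0.2, cfg), 0)

    ## 20-probe injected gain at +1.0, sigma 0.2: one call, score ~ 22.4,
    ## boundaries within 2 probes
    set.seed(303)
    x <- rnorm(200, 0, 0.2)
    x[91:110] <- x[91:110] + 1.0
    calls <- segmentSample(x, gr, 0.2, cfg)
    expect_length(calls, 1)
    expect_equal(calls$direction, "gain")
    expect_gt(calls$score, 4)
    expect_lt(abs(calls$score - 1.0 * sqrt(20) / 0.2), 6)
    expect_lte(abs(start(calls) - start(gr)[91]), 2 * 10000)
    expect_lte(abs(end(calls) - end(gr)[110]), 2 * 10000)

    ## single-probe spike: huge score but fails the 2-probe minimum
    y <- rep(0, 200); y[50] <- 2.0
    expect_length(segmentSample(y, gr, 0.2, cfg), 0)

    ## broad shallow 30-probe segment at +0.4 with tiny noise: enormous
    ## score, dropped by the 0.5 amplitude floor (the 1.4-fold rule)
    set.seed(304)
    z <- rnorm(200, 0, 0.01)
    z[101:130] <- z[101:130] + 0.4
    expect_length(segmentSample(z, gr, estimateNoise(z), cfg), 0)

    ## unsorted probes violate the contract
    expect_error(segmentSample(x, rev(gr), 0.2, cfg), "sorted")
})

test_that("negating ratios swaps gain/loss and preserves scores; thresholds are monotone", {
    set.seed(404)
    x <- rnorm(300, 0, 0.2)
    x[51:90] <- x[51:90] + 0.9
    x[201:230] <- x[201:230] - 0.8
    gr <- makeProbes(300)
    up <- segmentSample(x, gr, 0.2, cnvConfig())
    dn <- segmentSample(-x, gr, 0.2, cnvConfig())
    expect_equal(start(up), start(dn))
    expect_equal(up$score, dn$score)
    expect_equal(dn$direction, ifelse(up$direction == "gain", "loss", "gain"))

    ## raising the score threshold or the amplitude floor never adds calls
    n4 <- length(segmentSample(x, gr, 0.2, cnvConfig()))
    n8 <- length(segmentSample(x, gr, 0.2, cnvConfig(admThreshold = 8)))
    nAmp <- length(segmentSample(x, gr, 0.2, cnvConfig(minAbsMean = 1.2)))
    expect_lte(n8, n4)
    expect_lte(nAmp, n4)
})

test_that("recursive search matches the exhaustive interval oracle", {
    set.seed(505)
    for (rep in 1:5) {
        n <- sample(50:200, 1)
        x <- rnorm(n, 0, 0.2)
        if (rep %% 2 == 0) {
            at <- sample(n - 15, 1)
            x[at:(at + 14)] <- x[at:(at + 14)] + 0.8
        }
        got <- cnvIntegrate:::.bestIntervalCpp(x, 0.2)
        want <- oracleBestInterval(x, 0.2)
        expect_equal(got[3], want[3], tolerance = 1e-10)
        expect_equal(got[1:2], want[1:2])
    }
})

test_that("chromosome Y is excluded and calls rasterize onto the probe grid", {
    set.seed(606)
    x <- rnorm(100, 0, 0.1)
    x[11:30] <- x[11:30] + 1   # on chromosome 1
    x[61:80] <- x[61:80] + 1   # on chromosome Y: must be ignored
    gr <- makeProbes(50, c("1", "Y"))
    calls <- segmentSample(x, gr, 0.1, cnvConfig())
    expect_length(calls, 1)
    expect_equal(as.character(seqnames(calls)), "1")

    ps <- makeProbeSet(matrix(x, ncol = 1, dimnames = list(NULL, "S01")),
                       chroms = c("1", "Y"))
    calls$sample_id <- "S01"
    cm <- callMatrix(ps, calls)
    expect_equal(sum(cm == 1L), 20)
    expect_equal(which(cm[, "S01"] == 1L), 11:30, ignore_attr = TRUE)
    ## no calls: all-neutral matrix
    expect_true(all(callMatrix(ps, calls[0]) == 0L))
})

test_that("cohort segmentation undoes the centering offset and recovers per-sample truth", {
    ## sharp probe noise so the histogram mode pins the offset tightly
    sim <- simulateCohort(nSamples = 6, nProbesPerChrom = 500, nGenes = 40,
                          truthSpec = defaultTruthSpec(5e6)[c(1, 5), ],
                          noise = noiseModel(probeSigma = 0.05),
                          seed = 707)
    calls <- segmentCohort(sim$probes, cnvConfig())
    offs <- S4Vectors::metadata(calls)$offsets
    expect_lt(max(abs(offs - 0.1)), 0.03)
    seg <- truthSegments(sim$truth)
    for (i in seq_along(seg)) {
        for (sm in unlist(seg$carriers[[i]])) {
            hit <- calls[calls$sample_id == sm &
                         calls$direction == seg$direction[i]]
            ov <- IRanges::overlapsAny(seg[i], hit)
            expect_true(ov, label = sprintf("segment %d in %s", i, sm))
        }
    }
})

test_that("false-call rate on pure-noise cohorts stays within the design bound", {
    ## 200 single-sample null tracks of 500 probes at the default filters;
    ## the bound allows two Monte-Carlo standard errors above 0.05
    nc <- nullCallRate(nReplicates = 200, nSamples = 1, nProbes = 500,
                       seed = 20)
    expect_lte(nc$callsPerSample, 0.05 + 2 * max(nc$se, 1e-3))
})
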