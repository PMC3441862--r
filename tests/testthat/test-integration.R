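test_that("gene copy ratio is the mean of overlapping probes, matching a brute-force scan", {
    ## two probes at 0.4 and 0.8 under one gene -> 0.6
    m <- matrix(c(0.4, 0.8, 5, -1), 4, 1, dimnames = list(NULL, "S01"))
    ps <- makeProbeSet(m)
    gr <- probeRanges(ps)
    ann <- GRanges("1", IRanges(start(gr)[1], end(gr)[2]))
    names(ann) <- "G1"; ann$gene_symbol <- "G1"
    gcr <- geneCopyRatio(ps, ann)
    expect_equal(unname(gcr["G1", "S01"]), 0.6)

    ## a gene overlapping no probe is excluded and flagged
    ann2 <- suppressWarnings(c(ann, GRanges("2", IRanges(1, 100))))
    names(ann2) <- c("G1", "G2"); ann2$gene_symbol <- names(ann2)
    gcr2 <- geneCopyRatio(ps, ann2)
    expect_equal(rownames(gcr2), "G1")
    expect_equal(attr(gcr2, "missing_genes"), "G2")

    ## oracle equivalence on random fixtures: O(genes x probes) double loop
    set.seed(51)
    psR <- makeProbeSet(matrix(rnorm(200 * 3), 200,
                               dimnames = list(NULL, paste0("S", 1:3))),
                        chroms = c("1", "2"))
    grR <- probeRanges(psR)
    annR <- GRanges(sample(c("1", "2"), 10, TRUE),
                    IRanges(sample.int(9e5, 10), width = 50000))
    names(annR) <- paste0("G", 1:10); annR$gene_symbol <- names(annR)
    gcrR <- geneCopyRatio(psR, annR)
    mR <- log2Ratios(psR)
    for (g in rownames(gcrR)) {
        i <- which(names(annR) == g)
        ov <- which(as.character(seqnames(grR)) ==
                        as.character(seqnames(annR)[i]) &
                    start(grR) <= end(annR)[i] & end(grR) >= start(annR)[i])
        expect_equal(gcrR[g, ], colMeans(mR[ov, , drop = FALSE]))
    }
})

test_that("CNV classification uses the inclusive 1.5-fold boundary per direction", {
    x <- c(a = 0.585, b = 0.584, c = -0.6, d = 0)
    pos <- classifyCNV(x, "gain")
    expect_equal(as.vector(pos), c(TRUE, FALSE, FALSE, FALSE))
    expect_equal(attr(pos, "frequency"), 1L)
    neg <- classifyCNV(x, "loss")
    expect_equal(as.vector(neg), c(FALSE, FALSE, TRUE, FALSE))
    expect_equal(attr(classifyCNV(rep(0, 5), "gain"), "frequency"), 0L)
})

test_that("expression filter keeps genes strictly above the signal cutoff and is idempotent", {
    m <- rbind(low = rep(3.9, 4), high = rep(10, 4),
               edge = c(3.8, 3.9, 4.0, 3.9))
    colnames(m) <- c("S1T", "S1N", "S2T", "S2N")
    ex <- PairedExpression(m)
    f <- expressionFilter(ex, 3.9)
    expect_equal(rownames(f), "high")
    expect_equal(exprSignals(expressionFilter(f, 3.9)), exprSignals(f))
})

test_that("dosage fold change follows the median-ratio definition with inclusive selection", {
    ## constructed boundary: CNV+ median 2.6 vs CNV- 2.0 on the linear
    ## scale -> fc = 1.3, selected (inclusive)
    tumorLog2 <- log2(c(2.6, 2.6, 2.6, 2.0, 2.0, 2.0))
    pos <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
    r <- dosageFC(tumorLog2, pos, "gain")
    expect_equal(r$fc, 1.3)
    expect_true(r$selected_1p3)
    expect_false(r$selected_2fold)

    ## identical groups: fc = 1, nothing selected
    r1 <- dosageFC(rep(3, 6), pos, "gain")
    expect_equal(r1$fc, 1)
    expect_false(r1$selected_1p3)

    ## loss direction uses the reciprocal rule
    rl <- dosageFC(log2(c(1, 1, 1, 2.6, 2.6, 2.6)), pos, "loss")
    expect_equal(rl$fc, 1 / 2.6)
    expect_true(rl$selected_1p3)
    expect_true(rl$selected_2fold)

    ## undefined without both groups
    expect_equal(dosageFC(rep(1, 4), rep(TRUE, 4), "gain")$flag,
                 "no CNV+ or no CNV- samples")

    ## scale invariance: multiplying all linear signals by c leaves fc
    r2 <- dosageFC(tumorLog2 + log2(7), pos, "gain")
    expect_equal(r2$fc, r$fc)
})

test_that("dosage correlation matches the definitional formula and calibrates under the null", {
    ## perfect linear relation
    x <- seq_len(10)
    expect_equal(unname(dosageCorrelation(x, 2 * x)["r"]), 1)
    expect_lt(unname(dosageCorrelation(x, 2 * x)["p"]), 1e-12)

    ## from-the-definition oracle to 1e-12 on random fixtures
    set.seed(52)
    for (i in 1:5) {
        a <- rnorm(25); b <- 0.5 * a + rnorm(25)
        got <- dosageCorrelation(a, b)
        rOracle <- sum((a - mean(a)) * (b - mean(b))) /
            sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
        expect_equal(unname(got["r"]), rOracle, tolerance = 1e-12)
        tOracle <- rOracle * sqrt(23) / sqrt(1 - rOracle^2)
        expect_equal(unname(got["p"]), 2 * pt(-abs(tOracle), 23),
                     tolerance = 1e-12)
    }

    ## zero variance is flagged, not guessed
    expect_true(is.na(dosageCorrelation(rep(1, 10), rnorm(10))["r"]))

    ## null rejection rate ~ alpha
    cal <- nullCorrelationCalibration(nReplicates = 400, seed = 53)
    expect_gt(cal$rate, 0.02); expect_lt(cal$rate, 0.08)
})

test_that("differential t-test matches hand arithmetic and separates shifted groups", {
    ## 3+3 fixture: groups (1,2,3) vs (4,5,6); pooled s^2 = 1,
    ## t = -3 / sqrt(2/3), p = 2 P(T4 < t)
    m <- rbind(G1 = c(1, 2, 3, 4, 5, 6), G2 = rep(2, 6))
    colnames(m) <- c("S1T", "S2T", "S3T", "S1N", "S2N", "S3N")
    ex <- PairedExpression(m)
    tt <- differentialTTest(ex)
    tHand <- -3 / sqrt(1 * (1 / 3 + 1 / 3))
    expect_equal(tt$t[tt$gene_symbol == "G1"], tHand)
    expect_equal(tt$p_value[tt$gene_symbol == "G1"],
                 2 * pt(tHand, 4))
    ## identical groups: t = 0, p = 1
    expect_equal(tt$t[tt$gene_symbol == "G2"], 0)
    expect_equal(tt$p_value[tt$gene_symbol == "G2"], 1)

    ## power: N(0,1) vs N(2,1) at n = 25 clears the 1e-4 panel threshold
    set.seed(54)
    big <- rbind(DG = c(rnorm(25, 2), rnorm(25, 0)))
    colnames(big) <- c(paste0("S", 1:25, "T"), paste0("S", 1:25, "N"))
    ttb <- differentialTTest(PairedExpression(big))
    expect_lt(ttb$p_value, 1e-4)
    expect_true(ttb$selected)
})

test_that("integration recovers dosage genes and rejects bystanders on synthetic truth", {
    sim <- simulateCohort(seed = 55)
    res <- runCohortAnalysis(sim$probes, sim$expression, sim$metadata,
                             sim$annotation, cnvConfig(seed = 55))
    d <- res$dosage
    dg <- truthDosageGenes(sim$truth)$gene_symbol
    isDosage <- d$gene_symbol %in% dg
    ## >= 90% of dosage genes selected at 1.3-fold; <= 10% of null genes
    expect_gte(mean(d$selected_1p3[isDosage]), 0.90)
    expect_lte(mean(d$selected_1p3[!isDosage]), 0.10)
    ## expected fold change ~ 2^0.8 for coefficient 1 and shift 0.8
    expect_equal(median(d$fc[isDosage & d$direction == "gain"]), 2^0.8,
                 tolerance = 0.15)
    ## dosage genes outrank null genes
    expect_gt(median(d$fc[isDosage & d$direction == "gain"]),
              median(d$fc[!isDosage & d$direction == "gain"]))
    ## correlations are strong for dosage genes, near zero for bystanders
    expect_gt(median(d$pearson_r[isDosage], na.rm = TRUE), 0.4)
    ## percent-significant reporting identity
    nSel <- sum(d$selected_1p3); nSig <- sum(d$significant & d$selected_1p3)
    expect_equal(percentLabel(nSig, nSel, 1),
                 roundHalfUp(100 * nSig / nSel, 1))
})
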