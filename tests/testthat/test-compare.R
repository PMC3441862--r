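test_that("contrasts implement the exclusion rules", {
    meta <- makeMeta(27)
    ct <- buildContrasts(meta)
    ## 12 PD minus 2 SRCC -> 10; 11 MD; M-PD excluded from histology only
    expect_length(ct$PD.MD$groupA, 10)
    expect_length(ct$PD.MD$groupB, 11)
    expect_true(all(c("partial signet-ring histology", "mixed histology")
                    %in% ct$PD.MD$excluded$reason))
    ## stage contrasts keep M-PD samples but drop SRCC
    expect_equal(length(ct$T12.T34$groupA) + length(ct$T12.T34$groupB), 25)
    expect_equal(length(ct$N0.N13$groupA) + length(ct$N0.N13$groupB), 25)
    expect_true(!any(meta$sample_id[meta$srcc_flag] %in%
                     unlist(ct$N0.N13[c("groupA", "groupB")])))

    ## a degenerate contrast is rejected
    allT1 <- meta; allT1$t_stage <- "T1"
    expect_error(buildContrasts(allT1), "empty group")
})

test_that("region state calls need half-region overlap and build correct tables", {
    region <- GRanges("1", IRanges(100001, 200000))
    calls <- GRanges(
        rep("1", 3), IRanges(c(100001, 150001, 190001),
                             c(200000, 260000, 195000)))
    calls$sample_id <- c("S1", "S2", "S3")
    calls$direction <- c("gain", "loss", "gain")
    st <- regionCallStates(calls, region, c("S1", "S2", "S3", "S4"))
    expect_equal(unname(st), c("gain", "loss", "neutral", "neutral"))

    ct <- list(name = "demo", groupA = c("S1", "S2"), groupB = c("S3", "S4"))
    tab <- regionTable(st, ct)
    expect_equal(unname(tab), rbind(c(1L, 0L, 1L), c(0L, 2L, 0L)))
    expect_equal(rowSums(tab), c(groupA = 2, groupB = 2))

    ## all neutral
    tab0 <- regionTable(setNames(rep("neutral", 6), paste0("S", 1:6)),
                        list(name = "x", groupA = paste0("S", 1:3),
                             groupB = paste0("S", 4:6)))
    expect_equal(unname(tab0), rbind(c(0L, 3L, 0L), c(0L, 3L, 0L)))

    ## counts are invariant to sample order
    st2 <- st[sample(length(st))]
    expect_equal(regionTable(st2, ct), tab)
})

test_that("exact 2xc Fisher enumeration matches closed forms and fisher.test", {
    ## no association: identical rows give p = 1
    expect_equal(fisherExactRxC(rbind(c(2, 2, 2), c(2, 2, 2))), 1)

    ## degenerate margins give p = 1
    expect_equal(fisherExactRxC(rbind(c(0, 0, 0), c(1, 2, 3))), 1)
    expect_equal(fisherExactRxC(rbind(c(0, 3, 0), c(0, 5, 0))), 1)

    ## embedded 2x2: [[3,0],[0,3]] has p = 2 / C(6,3) = 0.1
    expect_equal(fisherExactRxC(rbind(c(3, 0, 0), c(0, 3, 0))),
                 oracleFisher2x2(rbind(c(3, 0), c(0, 3))))
    expect_equal(fisherExactRxC(rbind(c(3, 0, 0), c(0, 3, 0))), 0.1)

    ## perfect 5/5 separation, cross-checked against stats::fisher.test
    tab <- rbind(c(5, 0, 0), c(0, 5, 0))
    expect_equal(fisherExactRxC(tab),
                 stats::fisher.test(t(tab))$p.value, tolerance = 1e-10)

    ## random tables with totals <= 20 agree with fisher.test
    set.seed(41)
    for (i in 1:25) {
        tot <- sample(4:20, 1)
        cells <- as.vector(stats::rmultinom(1, tot, runif(6, 0.2, 1)))
        tab <- matrix(cells, 2, 3)
        if (any(rowSums(tab) == 0) || sum(colSums(tab) > 0) < 2) next
        expect_equal(fisherExactRxC(tab),
                     stats::fisher.test(tab)$p.value, tolerance = 1e-8,
                     label = paste(cells, collapse = ","))
    }
})

test_that("Fisher p is invariant under row swap and column permutation", {
    set.seed(42)
    for (i in 1:10) {
        tab <- matrix(sample(0:6, 6, replace = TRUE), 2, 3)
        if (any(rowSums(tab) == 0)) next
        p <- fisherExactRxC(tab)
        expect_equal(fisherExactRxC(tab[2:1, ]), p, tolerance = 1e-12)
        perm <- sample(3)
        expect_equal(fisherExactRxC(tab[, perm]), p, tolerance = 1e-12)
    }
})

test_that("region scan applies the X/Y and classifying-fraction gates, then tests", {
    meta <- makeMeta(27)
    ct <- buildContrasts(meta)$PD.MD
    samp <- c(ct$groupA, ct$groupB)
    ## region 1: strong group difference; region 2: 10% in both classes
    ## (skipped); region 3: on X (skipped)
    regions <- GRanges(c("1", "2", "X"),
                       IRanges(c(1, 1, 1), c(1e5, 1e5, 1e5)))
    regions$direction <- "gain"
    mkCalls <- function(samples, chrom) {
        if (!length(samples)) return(NULL)
        g <- GRanges(rep(chrom, length(samples)),
                     IRanges(rep(1, length(samples)),
                             rep(1e5, length(samples))))
        g$sample_id <- samples
        g$direction <- "gain"
        g
    }
    calls <- suppressWarnings(c(
        mkCalls(ct$groupB[1:9], "1"),           # 9/11 MD carry the gain
        mkCalls(c(ct$groupA[1], ct$groupB[1]), "2"),  # ~10% each
        mkCalls(samp, "X")))
    res <- scanRegions(regions, calls, ct, cnvConfig())
    expect_equal(res$tested, c(TRUE, FALSE, FALSE))
    expect_true(res$significant[1])
    expect_lt(res$p_value[1], 0.001)
    expect_true(is.na(res$p_value[2]) && is.na(res$p_value[3]))
})

test_that("an injected subtype-linked gain is flagged by the scan on synthetic data", {
    sim <- simulateCohort(seed = 43, nProbesPerChrom = 500,
                          truthSpec = defaultTruthSpec(5e6), nGenes = 60)
    calls <- segmentCohort(sim$probes, cnvConfig())
    cm <- callMatrix(sim$probes, calls)
    rr <- recurrentRegions(frequencyProfile(cm, sim$probes))
    ct <- buildContrasts(sim$metadata)$PD.MD
    res <- scanRegions(rr, calls, ct, cnvConfig())
    seg <- truthSegments(sim$truth)
    linked <- seg[!is.na(seg$linked_class)]
    hit <- which(res$chrom == as.character(seqnames(linked)) &
                 res$start <= start(linked) & res$end >= start(linked))
    expect_true(length(hit) >= 1 && any(res$significant[hit]))
})

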