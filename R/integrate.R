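## Gene-level copy-number / expression integration. For genes inside
## recurrent regions: a gene-level copy ratio (mean of overlapping probes'
## log2 ratios per sample), CNV+/CNV- classification at |log2| >= 0.585
## (1.5-fold), dosage fold change (median linear tumor expression of CNV+
## over CNV- samples) with 1.3-fold and 2-fold selection, and the Pearson
## correlation between gene copy ratio and tumor-minus-normal expression
## log2 ratio with its t-based significance and BH FDR.

#' Gene-level copy ratio
#'
#' Mean log2 ratio of all probes overlapping each gene (any bp
#' intersection, 1-based inclusive), per sample. Genes overlapping no
#' probe are excluded and flagged as lacking aCGH data.
#'
#' @param probeSet A \code{\link{ProbeSet}}.
#' @param annotation Gene annotation \code{GRanges} (named by symbol).
#' @return Numeric matrix (covered genes x samples); symbols of uncovered
#'   genes are in \code{attr(, "missing_genes")}.
#' @export
geneCopyRatio <- function(probeSet, annotation) {
    gr <- probeRanges(probeSet)
    m <- log2Ratios(probeSet)
    hits <- findOverlaps(annotation, gr)
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    covered <- sort(unique(q))
    out <- matrix(NA_real_, length(covered), ncol(m),
                  dimnames = list(names(annotation)[covered], colnames(m)))
    for (i in seq_along(covered)) {
        pr <- s[q == covered[i]]
        out[i, ] <- if (length(pr) == 1L) m[pr, ] else colMeans(m[pr, ,
                                                                  drop = FALSE])
    }
    attr(out, "missing_genes") <- names(annotation)[setdiff(
        seq_along(annotation), covered)]
    out
}

#' Classify samples as CNV-positive for a gene
#'
#' A sample is CNV+ when its gene-level copy ratio passes the 1.5-fold
#' classification threshold in the direction of the containing region:
#' \code{>= cutoff} for gains, \code{<= -cutoff} for losses (cutoff 0.585
#' log2 units by default; the boundary is inclusive).
#'
#' @param geneLog2 Numeric vector of one gene's per-sample copy ratios.
#' @param direction \code{"gain"} or \code{"loss"}.
#' @param cnvCallLog2 Classification threshold (default 0.585).
#' @return Logical vector with the CNV+ count in \code{attr(,
#'   "frequency")}.
#' @export
classifyCNV <- function(geneLog2, direction = c("gain", "loss"),
                        cnvCallLog2 = 0.585) {
    direction <- match.arg(direction)
    pos <- if (direction == "gain") geneLog2 >= cnvCallLog2
    else geneLog2 <= -cnvCallLog2
    attr(pos, "frequency") <- sum(pos)
    pos
}

#' Filter expressed genes
#'
#' Keeps genes whose mean log2 signal across all tumor and normal columns
#' strictly exceeds the expression signal cutoff (3.9 by default).
#' Idempotent.
#'
#' @param expr A \code{\link{PairedExpression}}.
#' @param exprSignalCutoff Signal cutoff (default 3.9).
#' @return The filtered \code{PairedExpression}.
#' @export
expressionFilter <- function(expr, exprSignalCutoff = 3.9) {
    keep <- rowMeans(exprSignals(expr)) > exprSignalCutoff
    expr[keep, ]
}

#' Dosage fold change of one gene
#'
#' Fold change = median linear-scale tumor expression (2^log2 signal) of
#' the CNV+ samples divided by that of the CNV- samples. Selection flags:
#' \code{selected_1p3} at the 1.3-fold cutoff and \code{selected_2fold} at
#' 2-fold, both inclusive, with the reciprocal rule for loss regions
#' (\code{fc <= 1/cutoff}). Undefined (NA, flagged) when either group is
#' empty.
#'
#' @param tumorLog2 Numeric vector of the gene's tumor log2 signals.
#' @param cnvPositive Logical vector from \code{\link{classifyCNV}}.
#' @param direction \code{"gain"} or \code{"loss"}.
#' @param fcCutoff Selection cutoff (default 1.3).
#' @param targetFcCutoff Target-gene cutoff (default 2).
#' @return List with \code{fc}, \code{selected_1p3}, \code{selected_2fold},
#'   \code{flag} (NA or the reason the FC is undefined).
#' @export
dosageFC <- function(tumorLog2, cnvPositive, direction = c("gain", "loss"),
                     fcCutoff = 1.3, targetFcCutoff = 2.0) {
    direction <- match.arg(direction)
    if (!any(cnvPositive) || all(cnvPositive))
        return(list(fc = NA_real_, selected_1p3 = FALSE,
                    selected_2fold = FALSE,
                    flag = "no CNV+ or no CNV- samples"))
    fc <- median(2^tumorLog2[cnvPositive]) / median(2^tumorLog2[!cnvPositive])
    sel <- function(cut) if (direction == "gain") fc >= cut else fc <= 1 / cut
    list(fc = fc, selected_1p3 = sel(fcCutoff),
         selected_2fold = sel(targetFcCutoff), flag = NA_character_)
}

## Pearson r with t-based two-sided p; NA (flagged) on zero variance
.pearsonTest <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 3 || sd(x) == 0 || sd(y) == 0)
        return(c(r = NA_real_, p = NA_real_, n = n))
    r <- cor(x, y)
    if (abs(r) >= 1) return(c(r = r, p = 0, n = n))
    t <- r * sqrt(n - 2) / sqrt(1 - r^2)
    c(r = r, p = 2 * pt(-abs(t), n - 2), n = n)
}

#' Copy-number / expression correlation of one gene
#'
#' Standard Pearson correlation between the gene's per-sample copy ratio
#' and its tumor-minus-normal log2 expression ratio, with significance
#' from \code{t = r sqrt(n-2) / sqrt(1-r^2)} (two-sided). Undefined and
#' flagged when either vector has zero variance or fewer than 3 pairs.
#'
#' @param geneLog2 Per-sample gene copy ratios.
#' @param exprLog2Ratio Per-sample tumor-minus-normal expression log2
#'   ratios (same sample order).
#' @return Named vector \code{c(r, p, n)}.
#' @export
dosageCorrelation <- function(geneLog2, exprLog2Ratio) {
    .pearsonTest(geneLog2, exprLog2Ratio)
}

#' Tumor-vs-normal differential t-test per gene
#'
#' Two-sample Student t-test (equal variance, two-sided) of tumor against
#' normal log2 signals for each gene of a \code{\link{PairedExpression}},
#' with selection at a configurable p threshold (default 1e-4, the
#' stringency used for the 8q candidate-gene panel). Degenerate zero
#' pooled variance gives p = 1 for equal means and p = 0 otherwise.
#'
#' @param expr A \code{\link{PairedExpression}}.
#' @param genes Optional character vector restricting the genes tested.
#' @param pCutoff Selection threshold on p (default 1e-4).
#' @return \code{data.frame} with \code{gene_symbol}, \code{t},
#'   \code{p_value}, \code{selected}.
#' @export
differentialTTest <- function(expr, genes = rownames(expr),
                              pCutoff = 1e-4) {
    genes <- intersect(genes, rownames(expr))
    tm <- tumorSignals(expr)[genes, , drop = FALSE]
    nm <- normalSignals(expr)[genes, , drop = FALSE]
    res <- t(vapply(genes, function(g) {
        x <- tm[g, ]; y <- nm[g, ]
        if (sd(x) == 0 && sd(y) == 0)
            return(c(t = 0, p = as.numeric(mean(x) == mean(y))))
        tt <- t.test(x, y, var.equal = TRUE)
        c(t = unname(tt$statistic), p = tt$p.value)
    }, numeric(2)))
    data.frame(gene_symbol = genes, t = res[, 1], p_value = res[, 2],
               selected = res[, 2] < pCutoff, row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Integrate copy number and expression over recurrent regions
#'
#' The full gene-level dosage analysis: filters expressed genes, restricts
#' to genes inside recurrent aberration regions (gains and losses handled
#' separately by each region's direction), computes gene copy ratios,
#' CNV+/- classification, dosage fold change with 1.3-/2-fold selection,
#' and the copy-number/expression Pearson correlation with BH FDR across
#' the tested genes.
#'
#' @param probeSet A \code{\link{ProbeSet}}.
#' @param expr A \code{\link{PairedExpression}}.
#' @param annotation Gene annotation \code{GRanges}.
#' @param regions Recurrent regions from \code{\link{recurrentRegions}}.
#' @param config A \code{\link{cnvConfig}}.
#' @return \code{data.frame}, one row per analyzed gene: symbol,
#'   coordinates, region id and direction, mean normal/tumor log2
#'   expression, CNV+ frequency, mean CNV+ copy ratio, \code{fc},
#'   selection flags, \code{pearson_r}, \code{p_value}, \code{fdr},
#'   \code{significant}, \code{flag}. Genes lacking aCGH data are listed
#'   in \code{attr(, "missing_genes")}.
#' @export
integrateDosage <- function(probeSet, expr, annotation, regions,
                            config = cnvConfig()) {
    exprF <- expressionFilter(expr, config@exprSignalCutoff)
    samples <- intersect(colnames(probeSet), sampleIds(exprF))
    if (length(samples) < 3)
        stop("need at least 3 samples shared between aCGH and expression")
    ## genes inside recurrent regions, region of maximal overlap
    hits <- findOverlaps(annotation, regions)
    if (length(hits)) {
        ov <- width(pintersect(annotation[S4Vectors::queryHits(hits)],
                               regions[S4Vectors::subjectHits(hits)]))
        o <- order(S4Vectors::queryHits(hits), -ov)
        hits <- hits[o][!duplicated(S4Vectors::queryHits(hits)[o])]
    }
    gidx <- S4Vectors::queryHits(hits)
    keep <- names(annotation)[gidx] %in% rownames(exprF)
    gidx <- gidx[keep]
    rid <- S4Vectors::subjectHits(hits)[keep]
    if (!length(gidx)) {
        out <- data.frame()
        attr(out, "missing_genes") <- character(0)
        return(out)
    }
    ann <- annotation[gidx]
    gcr <- geneCopyRatio(probeSet, ann)
    missing <- attr(gcr, "missing_genes")
    present <- match(rownames(gcr), names(ann))
    ann <- ann[present]; rid <- rid[present]
    gcr <- gcr[, samples, drop = FALSE]

    tum <- tumorSignals(exprF)[names(ann), samples, drop = FALSE]
    nor <- normalSignals(exprF)[names(ann), samples, drop = FALSE]
    eratio <- tum - nor

    n <- length(ann)
    out <- data.frame(
        gene_symbol = names(ann), chrom = as.character(seqnames(ann)),
        start = start(ann), end = end(ann), region_id = rid,
        direction = regions$direction[rid],
        mean_normal = rowMeans(nor), mean_tumor = rowMeans(tum),
        n_cnv_pos = NA_integer_, acgh_mean_pos = NA_real_, fc = NA_real_,
        selected_1p3 = FALSE, selected_2fold = FALSE,
        pearson_r = NA_real_, p_value = NA_real_, fdr = NA_real_,
        significant = FALSE, flag = NA_character_,
        row.names = NULL, stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
        dir <- out$direction[i]
        pos <- classifyCNV(gcr[i, ], dir, config@cnvCallLog2)
        out$n_cnv_pos[i] <- attr(pos, "frequency")
        if (any(pos)) out$acgh_mean_pos[i] <- mean(gcr[i, pos])
        fc <- dosageFC(tum[i, ], pos, dir, config@fcCutoff,
                       config@targetFcCutoff)
        out$fc[i] <- fc$fc
        out$selected_1p3[i] <- fc$selected_1p3
        out$selected_2fold[i] <- fc$selected_2fold
        ct <- dosageCorrelation(gcr[i, ], eratio[i, ])
        out$pearson_r[i] <- ct["r"]
        out$p_value[i] <- ct["p"]
        out$flag[i] <- fc$flag
    }
    tested <- !is.na(out$p_value)
    out$fdr[tested] <- p.adjust(out$p_value[tested], method = "BH")
    out$significant <- tested & out$p_value < config@alpha
    attr(out, "missing_genes") <- missing
    out
}

#' Null calibration of the dosage correlation test
#'
#' Rejection rate of the Pearson significance test at level alpha on
#' independently drawn copy-ratio and expression-ratio vectors (no true
#' association), over many replicates.
#'
#' @param nReplicates Number of replicates (default 1000).
#' @param n Pairs per replicate (default 25).
#' @param alpha Level (default 0.05).
#' @param seed Integer seed.
#' @return List with \code{rate} and \code{nReplicates}.
#' @export
nullCorrelationCalibration <- function(nReplicates = 1000L, n = 25L,
                                       alpha = 0.05, seed = 1L) {
    set.seed(as.integer(seed))
    p <- vapply(seq_len(nReplicates), function(i)
        .pearsonTest(rnorm(n), rnorm(n))["p"], numeric(1))
    list(rate = mean(p < alpha), nReplicates = nReplicates)
}
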