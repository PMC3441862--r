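#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib cnvIntegrate, .registration = TRUE
#' @importClassesFrom SummarizedExperiment SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand findOverlaps pintersect
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlevels seqlevelsInUse keepSeqlevels
#' @importFrom stats cor cutree dist hclust median p.adjust pt qnorm rnorm runif sd setNames t.test as.dist quantile
#' @importFrom graphics hist
#' @importFrom utils read.delim write.table head
NULL

## ---------------------------------------------------------------------------
## ProbeSet: genome-ordered aCGH probes with per-sample tumor/normal log2
## ratios, stored as a RangedSummarizedExperiment with a single "log2ratio"
## assay. Rows are probes (named by probe id), columns are sample pairs.
## ---------------------------------------------------------------------------

#' @rdname ProbeSet
#' @export
setClass("ProbeSet", contains = "RangedSummarizedExperiment")

.validProbeSet <- function(object) {
    msg <- character(0)
    if (!"log2ratio" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'log2ratio' is required")
    else {
        m <- SummarizedExperiment::assay(object, "log2ratio")
        if (!all(is.finite(m)))
            msg <- c(msg, "all log2 ratios must be finite")
    }
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample column names must be unique")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "probe ids must be unique")
    gr <- SummarizedExperiment::rowRanges(object)
    if (length(gr) > 1) {
        o <- .karyotypeOrder(as.character(seqnames(gr)), start(gr))
        if (!identical(o, seq_along(gr)))
            msg <- c(msg, "probes must be sorted in karyotype order by start")
    }
    if (length(msg)) msg else TRUE
}
setValidity("ProbeSet", .validProbeSet)

#' ProbeSet: aCGH probe log2-ratio container
#'
#' A \code{RangedSummarizedExperiment} holding genome-ordered aCGH probes
#' (1-based inclusive coordinates, bare chromosome names) and one column of
#' log2(tumor/normal) ratios per sample pair in the \code{"log2ratio"} assay.
#' Rows are sorted in karyotype order (1--22, X, Y; start ascending) on
#' construction.
#'
#' @param probes A \code{GRanges} of probe positions, with names used as
#'   probe ids (generated if absent).
#' @param ratios Numeric matrix, one row per probe, one column per sample.
#' @return A \code{ProbeSet} object.
#' @export
#' @examples
#' gr <- GenomicRanges::GRanges(c("1", "1", "2"),
#'                              IRanges::IRanges(c(1, 101, 1), width = 60))
#' ps <- ProbeSet(gr, matrix(0, 3, 2, dimnames = list(NULL, c("S1", "S2"))))
#' probeRanges(ps)
ProbeSet <- function(probes, ratios) {
    ratios <- as.matrix(ratios)
    if (length(probes) != nrow(ratios))
        stop("number of probes and ratio rows differ")
    GenomeInfoDb::seqlevels(probes) <- normalizeChrom(seqlevels(probes))
    if (is.null(names(probes)))
        names(probes) <- sprintf("P%06d", seq_along(probes))
    o <- .karyotypeOrder(as.character(seqnames(probes)), start(probes))
    probes <- probes[o]
    ratios <- ratios[o, , drop = FALSE]
    rownames(ratios) <- names(probes)
    new("ProbeSet", SummarizedExperiment(
        assays = list(log2ratio = ratios), rowRanges = probes))
}

#' @describeIn ProbeSet the log2(tumor/normal) ratio matrix (probes x samples).
#' @param x,object A \code{ProbeSet}.
#' @export
log2Ratios <- function(x) SummarizedExperiment::assay(x, "log2ratio")

#' @describeIn ProbeSet the probe positions as a \code{GRanges}.
#' @export
probeRanges <- function(x) SummarizedExperiment::rowRanges(x)

setMethod("show", "ProbeSet", function(object) {
    cat(sprintf("ProbeSet: %d probes x %d samples on chromosome(s) %s\n",
                nrow(object), ncol(object),
                paste(seqlevelsInUse(rowRanges(object)), collapse = ", ")))
})

## ---------------------------------------------------------------------------
## PairedExpression: gene-level log2 expression with matched tumor ("T") and
## normal ("N") columns per sample.
## ---------------------------------------------------------------------------

#' @rdname PairedExpression
#' @export
setClass("PairedExpression", contains = "SummarizedExperiment")

.validPairedExpression <- function(object) {
    msg <- character(0)
    cd <- colData(object)
    if (!all(c("sample_id", "tissue") %in% colnames(cd)))
        return("colData must contain 'sample_id' and 'tissue'")
    if (!all(cd$tissue %in% c("T", "N")))
        msg <- c(msg, "tissue must be 'T' or 'N'")
    tab <- table(cd$sample_id, cd$tissue)
    if (!(all(tab == 1) && ncol(tab) == 2))
        msg <- c(msg, "every sample needs exactly one T and one N column")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene symbols must be unique")
    m <- SummarizedExperiment::assay(object)
    if (!all(is.finite(m)))
        msg <- c(msg, "all expression signals must be finite")
    if (length(msg)) msg else TRUE
}
setValidity("PairedExpression", .validPairedExpression)

#' PairedExpression: matched tumor/normal expression container
#'
#' A \code{SummarizedExperiment} of gene-level log2 expression signals with
#' one tumor (column suffix \code{"T"}) and one normal (suffix \code{"N"})
#' column per sample; rows are unique gene symbols. The \code{"log2signal"}
#' assay holds the signals; \code{exprRatio} derives the per-sample
#' tumor-minus-normal log2 ratio matrix the integration consumes.
#'
#' @param signals Numeric matrix of log2 signals, rows named by gene symbol,
#'   columns named \code{"<sample>T"} / \code{"<sample>N"}.
#' @return A \code{PairedExpression} object.
#' @export
PairedExpression <- function(signals) {
    signals <- as.matrix(signals)
    cn <- colnames(signals)
    if (is.null(cn) || !all(grepl("[TN]$", cn)))
        stop("column names must end in 'T' (tumor) or 'N' (normal)")
    cd <- DataFrame(sample_id = sub("[TN]$", "", cn),
                    tissue = sub("^.*([TN])$", "\\1", cn),
                    row.names = cn)
    new("PairedExpression", SummarizedExperiment(
        assays = list(log2signal = signals), colData = cd))
}

#' @describeIn PairedExpression the log2 signal matrix.
#' @param x,object A \code{PairedExpression}.
#' @export
exprSignals <- function(x) SummarizedExperiment::assay(x, "log2signal")

#' @describeIn PairedExpression sample ids (one per tumor/normal pair).
#' @export
sampleIds <- function(x) unique(colData(x)$sample_id)

#' @describeIn PairedExpression log2 tumor signals (genes x samples).
#' @export
tumorSignals <- function(x) {
    cd <- colData(x)
    m <- exprSignals(x)[, cd$tissue == "T", drop = FALSE]
    colnames(m) <- cd$sample_id[cd$tissue == "T"]
    m
}

#' @describeIn PairedExpression log2 normal signals (genes x samples).
#' @export
normalSignals <- function(x) {
    cd <- colData(x)
    m <- exprSignals(x)[, cd$tissue == "N", drop = FALSE]
    colnames(m) <- cd$sample_id[cd$tissue == "N"]
    m
}

#' @describeIn PairedExpression tumor-minus-normal log2 expression ratios
#'   (genes x samples).
#' @export
exprRatio <- function(x) {
    t_ <- tumorSignals(x)
    n_ <- normalSignals(x)
    t_[, colnames(t_), drop = FALSE] - n_[, colnames(t_), drop = FALSE]
}

setMethod("show", "PairedExpression", function(object) {
    cat(sprintf("PairedExpression: %d genes x %d samples (T/N paired)\n",
                nrow(object), length(sampleIds(object))))
})

## ---------------------------------------------------------------------------
## CNVConfig: the analysis thresholds, all from the study's settings.
## ---------------------------------------------------------------------------

#' @rdname cnvConfig
#' @export
setClass("CNVConfig", representation(
    admThreshold = "numeric", minProbes = "integer", minAbsMean = "numeric",
    maxRegions = "integer", recurrenceFraction = "numeric",
    fcCutoff = "numeric", targetFcCutoff = "numeric", cnvCallLog2 = "numeric",
    exprSignalCutoff = "numeric", alpha = "numeric",
    classifyingFraction = "numeric", seed = "integer"))

setValidity("CNVConfig", function(object) {
    pos <- c(adm_threshold = object@admThreshold,
             min_probes = object@minProbes,
             min_abs_mean = object@minAbsMean,
             max_regions = object@maxRegions,
             recurrence_fraction = object@recurrenceFraction,
             fc_cutoff = object@fcCutoff,
             target_fc_cutoff = object@targetFcCutoff,
             cnv_call_log2 = object@cnvCallLog2,
             alpha = object@alpha,
             classifying_fraction = object@classifyingFraction)
    if (any(pos <= 0))
        return(paste("thresholds must be strictly positive:",
                     paste(names(pos)[pos <= 0], collapse = ", ")))
    if (object@recurrenceFraction > 1)
        return("recurrence_fraction must lie in (0, 1]")
    TRUE
})

#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline. Defaults reproduce the
#' study settings: aberration score threshold 4, at least 2 probes per
#' region, minimum absolute mean log2 ratio 0.5 (a 1.4-fold floor), at most
#' 10,000 regions per sample, 25\% recurrence rule, 1.3-fold dosage
#' selection, 2-fold target-gene rule, |log2| >= 0.585 (1.5-fold) CNV+
#' classification, expression signal cutoff 3.9, and alpha 0.05.
#'
#' @param admThreshold Segment score threshold (noise-s.d. units).
#' @param minProbes Minimum probes per aberration call.
#' @param minAbsMean Minimum |mean log2 ratio| of a call (shallow-call
#'   suppression).
#' @param maxRegions Maximum surviving calls per sample (top by score).
#' @param recurrenceFraction Fraction of samples defining a recurrent
#'   aberration.
#' @param fcCutoff Dosage fold-change selection cutoff.
#' @param targetFcCutoff Fold-change cutoff for region target genes.
#' @param cnvCallLog2 Gene-level |log2| ratio classifying a sample as CNV+.
#' @param exprSignalCutoff Mean log2 expression signal a gene must exceed.
#' @param alpha Significance level for the Fisher scan and correlations.
#' @param classifyingFraction Minimum per-class aberration fraction a region
#'   needs before it is tested in the subtype scan.
#' @param seed Integer seed recorded in every output header.
#' @return A \code{CNVConfig} object.
#' @export
#' @examples
#' cnvConfig(seed = 17)
cnvConfig <- function(admThreshold = 4, minProbes = 2L, minAbsMean = 0.5,
                      maxRegions = 10000L, recurrenceFraction = 0.25,
                      fcCutoff = 1.3, targetFcCutoff = 2.0,
                      cnvCallLog2 = 0.585, exprSignalCutoff = 3.9,
                      alpha = 0.05, classifyingFraction = 0.25, seed = 1L) {
    new("CNVConfig", admThreshold = admThreshold,
        minProbes = as.integer(minProbes), minAbsMean = minAbsMean,
        maxRegions = as.integer(maxRegions),
        recurrenceFraction = recurrenceFraction, fcCutoff = fcCutoff,
        targetFcCutoff = targetFcCutoff, cnvCallLog2 = cnvCallLog2,
        exprSignalCutoff = exprSignalCutoff, alpha = alpha,
        classifyingFraction = classifyingFraction, seed = as.integer(seed))
}

setMethod("show", "CNVConfig", function(object) {
    cat("CNVConfig\n")
    cat(sub("^# cnvIntegrate config: ", "  ", .configHeader(object)[1]), "\n")
    cat("  seed:", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## ClusterResult: two-way clustering output.
## ---------------------------------------------------------------------------

#' @rdname twoWayCluster
#' @export
setClass("ClusterResult", representation(
    sampleTree = "ANY", geneTree = "ANY", sampleOrder = "integer",
    geneOrder = "integer", twoClusterLabels = "character",
    separationPurity = "numeric"))

setMethod("show", "ClusterResult", function(object) {
    cat(sprintf(
        "ClusterResult: %d samples x %d genes; two-cluster purity %s\n",
        length(object@sampleOrder), length(object@geneOrder),
        ifelse(is.na(object@separationPurity), "NA",
               sprintf("%.3f", object@separationPurity))))
})

## ---------------------------------------------------------------------------
## SyntheticTruth: what the generator injected, for recovery benchmarks.
## ---------------------------------------------------------------------------

#' @rdname simulateCohort
#' @export
setClass("SyntheticTruth", representation(
    segments = "GRanges", dosageGenes = "data.frame",
    nullGenes = "character", noise = "list", seed = "integer"))

setMethod("show", "SyntheticTruth", function(object) {
    cat(sprintf(
        "SyntheticTruth: %d injected segments, %d dosage genes, %d null genes (seed %d)\n",
        length(object@segments), nrow(object@dosageGenes),
        length(object@nullGenes), object@seed))
})

#' @describeIn simulateCohort injected aberration segments (a \code{GRanges}
#'   with direction, shift, carrier set and carrier fraction).
#' @param truth A \code{SyntheticTruth}.
#' @export
truthSegments <- function(truth) truth@segments

#' @describeIn simulateCohort data frame of dosage-affected genes and their
#'   dosage coefficients.
#' @export
truthDosageGenes <- function(truth) truth@dosageGenes

#' @describeIn simulateCohort gene symbols with no dosage effect.
#' @export
truthNullGenes <- function(truth) truth@nullGenes
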