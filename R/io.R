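## Readers and writers for the tab-separated tables the pipeline exchanges.
## Internal coordinates are 1-based inclusive base pairs; BED export converts
## to 0-based half-open. Every writer stamps the config fingerprint and seed
## into "#" header lines so a results file identifies the run that made it.

.requireCols <- function(df, cols, what) {
    miss <- setdiff(cols, colnames(df))
    if (length(miss))
        stop(sprintf("%s: missing required column(s): %s", what,
                     paste(miss, collapse = ", ")))
}

.asNumericChecked <- function(x, col, what) {
    suppressWarnings(v <- as.numeric(x))
    bad <- which(is.na(v) & !is.na(x))
    if (length(bad))
        stop(sprintf("%s: non-numeric value in column '%s' at data row %d",
                     what, col, bad[1]))
    v
}

#' Read a probe-level aCGH log2-ratio table
#'
#' Reads a tab-separated file with columns \code{probe_id}, \code{chrom},
#' \code{start}, \code{end} followed by one numeric log2(tumor/normal)
#' column per sample, and returns a karyotype-sorted \code{\link{ProbeSet}}.
#' Chromosome names are accepted with or without a \code{"chr"} prefix.
#'
#' @param path Path to the tab-separated file; \code{"#"} lines are ignored.
#' @return A \code{\link{ProbeSet}}.
#' @export
readProbeTable <- function(path) {
    df <- read.delim(path, comment.char = "#", check.names = FALSE,
                     stringsAsFactors = FALSE)
    .requireCols(df, c("probe_id", "chrom", "start", "end"), "probe table")
    if (anyDuplicated(df$probe_id))
        stop("probe table: duplicate probe_id values")
    samp <- setdiff(colnames(df), c("probe_id", "chrom", "start", "end"))
    if (!length(samp)) stop("probe table: no sample ratio columns")
    ratios <- vapply(samp, function(s)
        .asNumericChecked(df[[s]], s, "probe table"), numeric(nrow(df)))
    ratios <- matrix(ratios, nrow = nrow(df),
                     dimnames = list(NULL, samp))
    gr <- GRanges(normalizeChrom(df$chrom),
                  IRanges(as.integer(df$start), as.integer(df$end)))
    names(gr) <- df$probe_id
    ProbeSet(gr, ratios)
}

#' Write a probe table
#'
#' Inverse of \code{\link{readProbeTable}}; writing then reading reproduces
#' the \code{ProbeSet}.
#'
#' @param ps A \code{\link{ProbeSet}}.
#' @param path Output path.
#' @param config Optional \code{\link{cnvConfig}} stamped into the header.
#' @export
writeProbeTable <- function(ps, path, config = NULL) {
    gr <- probeRanges(ps)
    df <- data.frame(probe_id = names(gr),
                     chrom = as.character(seqnames(gr)),
                     start = start(gr), end = end(gr),
                     check.names = FALSE)
    r <- log2Ratios(ps)
    for (s in colnames(r)) df[[s]] <- format(r[, s], digits = 17, trim = TRUE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(.configHeader(config), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a paired expression matrix
#'
#' Tab-separated file with a \code{gene_symbol} column followed by log2
#' signal columns named \code{"<sample>T"} and \code{"<sample>N"}.
#'
#' @param path Path to the file.
#' @return A \code{\link{PairedExpression}}.
#' @export
readExpressionMatrix <- function(path) {
    df <- read.delim(path, comment.char = "#", check.names = FALSE,
                     stringsAsFactors = FALSE)
    .requireCols(df, "gene_symbol", "expression matrix")
    if (anyDuplicated(df$gene_symbol))
        stop("expression matrix: duplicate gene symbols")
    samp <- setdiff(colnames(df), "gene_symbol")
    m <- vapply(samp, function(s)
        .asNumericChecked(df[[s]], s, "expression matrix"),
        numeric(nrow(df)))
    m <- matrix(m, nrow = nrow(df), dimnames = list(df$gene_symbol, samp))
    PairedExpression(m)
}

#' Write a paired expression matrix
#' @param expr A \code{\link{PairedExpression}}.
#' @inheritParams writeProbeTable
#' @export
writeExpressionMatrix <- function(expr, path, config = NULL) {
    m <- exprSignals(expr)
    df <- data.frame(gene_symbol = rownames(m), check.names = FALSE)
    for (s in colnames(m)) df[[s]] <- format(m[, s], digits = 17, trim = TRUE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(.configHeader(config), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read gene annotation intervals
#'
#' Accepts either a tab-separated table with columns \code{gene_symbol},
#' \code{chrom}, \code{start}, \code{end}, \code{strand} (1-based inclusive)
#' or a 6-column BED file (0-based half-open; detected by a \code{.bed}
#' extension, with the gene symbol in the name field). Duplicate symbols are
#' collapsed to the longest isoform span. Strand is retained for reporting
#' but ignored by all overlap computations (copy number is strand-agnostic).
#'
#' @param path Path to the annotation file.
#' @return A \code{GRanges} named by gene symbol with a \code{gene_symbol}
#'   metadata column.
#' @export
readGeneAnnotation <- function(path) {
    if (grepl("\\.bed$", path, ignore.case = TRUE)) {
        gr <- rtracklayer::import(path, format = "BED")
        GenomeInfoDb::seqlevels(gr) <- normalizeChrom(seqlevels(gr))
        sym <- gr$name
        gr <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                      strand = strand(gr))
    } else {
        df <- read.delim(path, comment.char = "#", check.names = FALSE,
                         stringsAsFactors = FALSE)
        .requireCols(df, c("gene_symbol", "chrom", "start", "end"),
                     "gene annotation")
        if (!all(df$start < df$end))
            stop("gene annotation: start must be < end")
        st <- if ("strand" %in% colnames(df)) df$strand else "*"
        st[!st %in% c("+", "-", "*")] <- "*"
        gr <- GRanges(normalizeChrom(df$chrom),
                      IRanges(as.integer(df$start), as.integer(df$end)),
                      strand = st)
        sym <- df$gene_symbol
    }
    ## longest span per symbol
    if (anyDuplicated(sym)) {
        keep <- unlist(lapply(split(seq_along(gr), sym), function(i)
            i[which.max(width(gr)[i])]), use.names = FALSE)
        keep <- sort(keep)
        gr <- gr[keep]; sym <- sym[keep]
    }
    names(gr) <- sym
    gr$gene_symbol <- sym
    gr[.karyotypeOrder(as.character(seqnames(gr)), start(gr))]
}

.HISTOLOGY <- c("PD", "MD", "M-PD")

#' Read sample metadata
#'
#' Tab-separated table with columns \code{sample_id}, \code{t_stage}
#' (T1--T4), \code{n_stage} (N0--N3), \code{m_stage} (M0/M1),
#' \code{histology} (PD, MD, M-PD) and logical \code{srcc_flag} marking
#' samples with partial signet-ring cell carcinoma.
#'
#' @param path Path to the file.
#' @param probeSet Optional \code{\link{ProbeSet}}; sample ids are then
#'   cross-checked against its ratio columns.
#' @return A validated \code{data.frame}.
#' @export
readSampleMetadata <- function(path, probeSet = NULL) {
    df <- read.delim(path, comment.char = "#", check.names = FALSE,
                     stringsAsFactors = FALSE)
    .requireCols(df, c("sample_id", "t_stage", "n_stage", "m_stage",
                       "histology", "srcc_flag"), "sample metadata")
    df$srcc_flag <- as.logical(df$srcc_flag)
    validateSampleMetadata(df, probeSet)
}

#' Validate a sample metadata table
#'
#' Checks the enumerated stage/histology values and, when a
#' \code{\link{ProbeSet}} or \code{\link{PairedExpression}} is supplied,
#' that every assayed sample has a metadata row.
#'
#' @param meta Metadata \code{data.frame} (see
#'   \code{\link{readSampleMetadata}}).
#' @param probeSet Optional \code{ProbeSet} to cross-reference.
#' @param expression Optional \code{PairedExpression} to cross-reference.
#' @return The validated \code{data.frame}, invisibly usable downstream.
#' @export
validateSampleMetadata <- function(meta, probeSet = NULL, expression = NULL) {
    checkEnum <- function(col, allowed) {
        bad <- setdiff(unique(meta[[col]]), allowed)
        if (length(bad))
            stop(sprintf("sample metadata: invalid %s value(s): %s", col,
                         paste(bad, collapse = ", ")))
    }
    checkEnum("t_stage", paste0("T", 1:4))
    checkEnum("n_stage", paste0("N", 0:3))
    checkEnum("m_stage", paste0("M", 0:1))
    checkEnum("histology", .HISTOLOGY)
    if (anyDuplicated(meta$sample_id))
        stop("sample metadata: duplicate sample_id values")
    if (!is.logical(meta$srcc_flag) || anyNA(meta$srcc_flag))
        stop("sample metadata: srcc_flag must be TRUE/FALSE")
    if (!is.null(probeSet)) {
        off <- setdiff(colnames(probeSet), meta$sample_id)
        if (length(off))
            stop(sprintf(
                "samples present in probe table but absent in metadata: %s",
                paste(off, collapse = ", ")))
    }
    if (!is.null(expression)) {
        off <- setdiff(sampleIds(expression), meta$sample_id)
        if (length(off))
            stop(sprintf(
                "samples present in expression but absent in metadata: %s",
                paste(off, collapse = ", ")))
    }
    meta
}

#' Write sample metadata
#' @param meta Metadata \code{data.frame}.
#' @inheritParams writeProbeTable
#' @export
writeSampleMetadata <- function(meta, path, config = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(.configHeader(config), con)
    write.table(meta, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write region summaries
#'
#' Writes recurrent regions or minimal common regions either as a report
#' table (1-based inclusive coordinates, size in Mb, count and percent) or
#' as BED (0-based half-open, the carrier count in the score field). The
#' region name encodes direction and index, e.g. \code{"+3"} for the third
#' gain region.
#'
#' @param regions A \code{GRanges} of region summaries as produced by
#'   \code{\link{recurrentRegions}} or \code{\link{minimalCommonRegions}}
#'   (may be empty).
#' @param path Output path.
#' @param format \code{"report"} (default) or \code{"bed"}.
#' @param config Optional \code{\link{cnvConfig}} stamped into the header.
#' @export
writeRegions <- function(regions, path, format = c("report", "bed"),
                         config = NULL) {
    format <- match.arg(format)
    dirSign <- ifelse(regions$direction == "gain", "+", "-")
    nm <- paste0(dirSign, seq_along(regions))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(.configHeader(config), con)
    if (format == "bed") {
        df <- data.frame(chrom = as.character(seqnames(regions)),
                         start = start(regions) - 1L, end = end(regions),
                         name = nm, score = regions$count,
                         percent = regions$percent)
        write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE)
    } else {
        df <- data.frame(direction = as.character(regions$direction),
                         chrom = as.character(seqnames(regions)),
                         start = start(regions), end = end(regions),
                         size_mb = sprintf("%.2f", regions$size_mb),
                         count = regions$count, percent = regions$percent)
        write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}

#' Read a region report table written by \code{\link{writeRegions}}
#'
#' @param path Path to a \code{format = "report"} region file.
#' @return A \code{GRanges} with \code{direction}, \code{size_mb},
#'   \code{count} and \code{percent} metadata columns.
#' @export
readRegions <- function(path) {
    df <- read.delim(path, comment.char = "#", check.names = FALSE,
                     stringsAsFactors = FALSE)
    .requireCols(df, c("direction", "chrom", "start", "end", "size_mb",
                       "count", "percent"), "region table")
    gr <- GRanges(normalizeChrom(df$chrom),
                  IRanges(as.integer(df$start), as.integer(df$end)))
    gr$direction <- df$direction
    gr$size_mb <- as.numeric(df$size_mb)
    gr$count <- as.integer(df$count)
    gr$percent <- as.numeric(df$percent)
    gr
}
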