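## Relative quantification of qRT-PCR validation genes from triplicate Ct
## values by the 2^-ddCt method: each record is normalized to its ACTB
## reference (dCt = mean target Ct - mean reference Ct), the matched
## normal-tissue record serves as the calibrator (ddCt = dCt_tumor -
## dCt_calibrator), and RQ = 2^-ddCt under the perfect-doubling
## assumption. Triplicates are summarized by their mean; a replicate s.d.
## above 0.5 cycles attaches a quality warning but is not enforced.

.checkCt <- function(ct, what) {
    if (length(ct) != 3)
        stop(sprintf("%s: exactly 3 Ct replicates are required", what))
    if (any(!is.finite(ct)) || any(ct <= 0) || any(ct >= 45))
        stop(sprintf("%s: Ct values must lie in (0, 45)", what))
    invisible(ct)
}

#' Relative quantity by the 2^-ddCt method
#'
#' @param targetCt Triplicate Ct values of the target gene in the sample
#'   of interest.
#' @param targetRefCt Triplicate Ct values of the reference gene (ACTB) in
#'   the same sample.
#' @param calibratorCt,calibratorRefCt The same two triplicates in the
#'   calibrator (the matched normal tissue).
#' @return The relative quantity \code{2^-ddCt}, with \code{attr(,
#'   "ddct")} and \code{attr(, "qc_warnings")} (character vector naming
#'   records whose replicate s.d. exceeds 0.5 cycles, empty when clean).
#' @export
#' @examples
#' relativeQuantity(c(20, 20, 20), c(15, 15, 15),
#'                  c(22, 22, 22), c(15, 15, 15))  # 4
relativeQuantity <- function(targetCt, targetRefCt, calibratorCt,
                             calibratorRefCt) {
    .checkCt(targetCt, "target"); .checkCt(targetRefCt, "target reference")
    .checkCt(calibratorCt, "calibrator")
    .checkCt(calibratorRefCt, "calibrator reference")
    reps <- list(target = targetCt, `target reference` = targetRefCt,
                 calibrator = calibratorCt,
                 `calibrator reference` = calibratorRefCt)
    qc <- names(reps)[vapply(reps, sd, numeric(1)) > 0.5]
    dctT <- mean(targetCt) - mean(targetRefCt)
    dctC <- mean(calibratorCt) - mean(calibratorRefCt)
    rq <- 2^-(dctT - dctC)
    attr(rq, "ddct") <- dctT - dctC
    attr(rq, "qc_warnings") <- qc
    rq
}

#' Per-gene RQ table from a triplicate Ct table
#'
#' @param ctTable \code{data.frame} with columns \code{sample_id},
#'   \code{gene_symbol}, \code{tissue} (\code{"T"}/\code{"N"}),
#'   \code{ct1..ct3} (target) and \code{ref1..ref3} (ACTB). The matched
#'   \code{"N"} record of each sample/gene is the calibrator.
#' @return \code{data.frame} with one row per tumor record:
#'   \code{sample_id}, \code{gene_symbol}, \code{rq}, \code{log2_rq},
#'   \code{qc}.
#' @export
rqTable <- function(ctTable) {
    need <- c("sample_id", "gene_symbol", "tissue", paste0("ct", 1:3),
              paste0("ref", 1:3))
    .requireCols(ctTable, need, "Ct table")
    tum <- ctTable[ctTable$tissue == "T", , drop = FALSE]
    out <- lapply(seq_len(nrow(tum)), function(i) {
        cal <- ctTable[ctTable$tissue == "N" &
                       ctTable$sample_id == tum$sample_id[i] &
                       ctTable$gene_symbol == tum$gene_symbol[i], ,
                       drop = FALSE]
        if (nrow(cal) != 1)
            stop(sprintf("no matched normal calibrator for %s / %s",
                         tum$sample_id[i], tum$gene_symbol[i]))
        rq <- relativeQuantity(
            as.numeric(tum[i, paste0("ct", 1:3)]),
            as.numeric(tum[i, paste0("ref", 1:3)]),
            as.numeric(cal[1, paste0("ct", 1:3)]),
            as.numeric(cal[1, paste0("ref", 1:3)]))
        data.frame(sample_id = tum$sample_id[i],
                   gene_symbol = tum$gene_symbol[i],
                   rq = as.numeric(rq), log2_rq = log2(as.numeric(rq)),
                   qc = paste(attr(rq, "qc_warnings"), collapse = ";"),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Correlate qPCR relative quantities with gene copy ratios
#'
#' Per gene, the Pearson correlation between log2(RQ) and the gene-level
#' aCGH copy ratio across samples, using the same correlation machinery
#' as the microarray integration, with BH FDR across genes. Genes with
#' fewer than 3 usable samples are skipped.
#'
#' @param rq RQ table from \code{\link{rqTable}}.
#' @param geneLog2CNV Matrix of gene copy ratios (genes x samples) from
#'   \code{\link{geneCopyRatio}}.
#' @return \code{data.frame} with \code{gene_symbol}, \code{n}, \code{r},
#'   \code{p_value}, \code{fdr}.
#' @export
validationCorrelation <- function(rq, geneLog2CNV) {
    genes <- intersect(unique(rq$gene_symbol), rownames(geneLog2CNV))
    out <- lapply(genes, function(g) {
        sub <- rq[rq$gene_symbol == g, , drop = FALSE]
        keep <- sub$sample_id %in% colnames(geneLog2CNV)
        sub <- sub[keep, , drop = FALSE]
        if (nrow(sub) < 3) return(NULL)
        ct <- .pearsonTest(geneLog2CNV[g, sub$sample_id], sub$log2_rq)
        data.frame(gene_symbol = g, n = as.integer(ct["n"]), r = ct["r"],
                   p_value = ct["p"], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    if (is.null(out))
        return(data.frame(gene_symbol = character(0), n = integer(0),
                          r = numeric(0), p_value = numeric(0),
                          fdr = numeric(0)))
    out$fdr <- p.adjust(out$p_value, method = "BH")
    rownames(out) <- NULL
    out
}
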