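## Small shared helpers: chromosome naming/order and the report arithmetic
## (percent labels, Mb sizes, fold equivalents) used throughout the tables.

.KARYOTYPE <- c(as.character(1:22), "X", "Y")

#' Normalize chromosome names
#'
#' Strips any "chr" prefix and upper-cases the sex chromosomes so that
#' chromosomes are always represented by their bare names
#' (\code{"1"}--\code{"22"}, \code{"X"}, \code{"Y"}).
#'
#' @param x Character vector (or factor) of chromosome names.
#' @return Character vector of bare chromosome names.
#' @export
#' @examples
#' normalizeChrom(c("chr8", "20", "chrX"))
normalizeChrom <- function(x) {
    x <- sub("^chr", "", as.character(x), ignore.case = TRUE)
    toupper(x) -> up
    ifelse(up %in% c("X", "Y"), up, x)
}

## karyotype rank; unknown contigs sort after Y, alphabetically
.chromRank <- function(x) {
    x <- normalizeChrom(x)
    r <- match(x, .KARYOTYPE)
    extra <- sort(unique(x[is.na(r)]))
    r[is.na(r)] <- length(.KARYOTYPE) + match(x[is.na(r)], extra)
    r
}

## order GRanges rows by (karyotype chromosome, start); stable
.karyotypeOrder <- function(chrom, start) {
    order(.chromRank(chrom), start)
}

#' Round half-up
#'
#' Rounds positive values half-up at \code{digits} decimals, the convention
#' used for the Mb sizes and percent labels in the report tables (base R
#' \code{round} rounds half-to-even).
#'
#' @param x Numeric vector (non-negative use intended).
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 0) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percent label for a sample frequency
#'
#' Computes \code{100 * count / n} rounded half-up, the frequency label
#' printed next to counts in recurrence tables (e.g. 19 of 27 samples is
#' labelled 70\%, 7 of 27 is 26\%).
#'
#' @param count Integer count of samples carrying the aberration.
#' @param n Total number of samples.
#' @param digits Decimal places of the label (0 for region tables, 1 for
#'   e.g. percent of significant correlations).
#' @return Numeric percent value.
#' @export
#' @examples
#' percentLabel(19, 27)      # 70
#' percentLabel(133, 163, 1) # 81.6
percentLabel <- function(count, n, digits = 0) {
    roundHalfUp(100 * count / n, digits)
}

#' Minimum recurrent count
#'
#' Smallest integer number of samples satisfying a recurrence fraction:
#' \code{ceiling(fraction * n)}. With the default 25\% rule and 27 samples
#' this is 7.
#'
#' @param fraction Recurrence fraction in (0, 1].
#' @param n Number of samples.
#' @return Integer threshold count.
#' @export
recurrenceCount <- function(fraction, n) {
    as.integer(ceiling(fraction * n))
}

#' Linear fold change equivalent of a log2 ratio
#'
#' @param log2ratio Numeric log2 ratio(s).
#' @return \code{2^log2ratio}. A log2 ratio of 0.5 corresponds to a
#'   1.4-fold copy-number variation (rounded to one decimal).
#' @export
log2ToFold <- function(log2ratio) 2^log2ratio

#' Region size in megabases
#'
#' \code{(end - start) / 1e6} rounded half-up to two decimals, matching how
#' region sizes are printed in the recurrence report (Mb at two decimals).
#'
#' @param startBp,endBp Region bounds in base pairs.
#' @return Size in Mb, two decimals.
#' @export
#' @examples
#' sizeMb(47860000, 146270000) # 98.41
sizeMb <- function(startBp, endBp) {
    roundHalfUp((endBp - startBp) / 1e6, 2)
}

## config fingerprint written into output file headers
.configHeader <- function(config) {
    if (is.null(config)) return(character(0))
    f <- sprintf(
        "# cnvIntegrate config: adm_threshold=%g min_probes=%d min_abs_mean=%g max_regions=%d recurrence_fraction=%g fc_cutoff=%g target_fc_cutoff=%g cnv_call_log2=%g expr_signal_cutoff=%g alpha=%g",
        config@admThreshold, config@minProbes, config@minAbsMean,
        config@maxRegions, config@recurrenceFraction, config@fcCutoff,
        config@targetFcCutoff, config@cnvCallLog2, config@exprSignalCutoff,
        config@alpha)
    c(f, sprintf("# cnvIntegrate seed: %d", config@seed))
}
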