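## Unsupervised two-way hierarchical clustering of the selected genes and
## the tumor/normal sample columns. Distance is 1 - Pearson correlation
## (the convention of expression heatmap toolchains; Euclidean available),
## agglomeration is average linkage. The sample tree cut at its root's two
## children yields a two-cluster labelling whose purity against the
## tumor/normal tissue labels quantifies how well dosage-selected genes
## separate cancer from adjacent noncancerous tissue.

.corDist <- function(m) {
    ## columns of m are the items
    sds <- apply(m, 2, sd)
    if (any(sds == 0))
        warning("constant row/column: correlation undefined, distance set to 1")
    cc <- suppressWarnings(cor(m))
    cc[!is.finite(cc)] <- 0
    d <- 1 - cc
    d[d < 0] <- 0
    as.dist(d)
}

#' Two-way average-linkage clustering
#'
#' Clusters both the samples (columns) and the genes (rows) of an
#' expression matrix by agglomerative average linkage on
#' 1 - Pearson-correlation distances (or Euclidean distances), returning
#' dendrograms, leaf orders, the two-cluster sample labelling, and its
#' purity against tissue labels when provided.
#'
#' @param mat Numeric matrix, genes x samples (typically log2 signals or
#'   ratios of the dosage-selected genes; no missing values).
#' @param distance \code{"pearson"} (default) or \code{"euclidean"}.
#' @param tissue Optional character vector of per-column tissue labels
#'   (e.g. \code{"T"}/\code{"N"}) for the purity computation.
#' @return A \code{ClusterResult} with slots \code{sampleTree},
#'   \code{geneTree} (\code{hclust}), \code{sampleOrder},
#'   \code{geneOrder}, \code{twoClusterLabels} (\code{"A"}/\code{"B"} per
#'   column) and \code{separationPurity} (best label matching; NA without
#'   tissue labels).
#' @export
twoWayCluster <- function(mat, distance = c("pearson", "euclidean"),
                          tissue = NULL) {
    distance <- match.arg(distance)
    if (nrow(mat) < 2 || ncol(mat) < 2)
        stop("need at least 2 genes and 2 samples")
    if (any(!is.finite(mat))) stop("matrix must have no missing values")
    dSample <- if (distance == "pearson") .corDist(mat) else dist(t(mat))
    dGene <- if (distance == "pearson") .corDist(t(mat)) else dist(mat)
    hs <- hclust(dSample, method = "average")
    hg <- hclust(dGene, method = "average")
    labels <- c("A", "B")[cutree(hs, k = 2)]
    names(labels) <- colnames(mat)
    purity <- NA_real_
    if (!is.null(tissue)) {
        tissue <- as.character(tissue)
        lv <- unique(tissue)
        if (length(lv) == 2) {
            agree <- mean(labels == c("A", "B")[match(tissue, lv)])
            purity <- max(agree, 1 - agree)
        }
    }
    new("ClusterResult", sampleTree = hs, geneTree = hg,
        sampleOrder = as.integer(hs$order), geneOrder = as.integer(hg$order),
        twoClusterLabels = labels, separationPurity = purity)
}

#' Newick serialization of a clustering tree
#'
#' @param tree An \code{hclust}, e.g. a slot of
#'   \code{\link{twoWayCluster}}'s result.
#' @return A single Newick string (with branch lengths).
#' @export
newickTree <- function(tree) {
    ape::write.tree(ape::as.phylo(tree))
}

#' Export heatmap-ready clustering outputs
#'
#' Writes everything needed to redraw the clustered heatmap: the matrix
#' reordered by both dendrograms, the two trees as Newick files, and a
#' color-scale metadata table (symmetric log2 range at the 99th percentile
#' of |value|).
#'
#' @param result A \code{ClusterResult}.
#' @param mat The matrix that was clustered.
#' @param dir Output directory (created if needed).
#' @param config Optional \code{\link{cnvConfig}} stamped into headers.
#' @return Invisibly, the paths written.
#' @export
exportHeatmapInputs <- function(result, mat, dir, config = NULL) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ord <- mat[result@geneOrder, result@sampleOrder, drop = FALSE]
    pMat <- file.path(dir, "matrix_reordered.tsv")
    con <- file(pMat, "w")
    writeLines(.configHeader(config), con)
    write.table(data.frame(gene_symbol = rownames(ord), ord,
                           check.names = FALSE),
                con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    pS <- file.path(dir, "samples.nwk")
    writeLines(newickTree(result@sampleTree), pS)
    pG <- file.path(dir, "genes.nwk")
    writeLines(newickTree(result@geneTree), pG)
    lim <- as.numeric(quantile(abs(mat), 0.99))
    pC <- file.path(dir, "colorscale.tsv")
    write.table(data.frame(low = -lim, mid = 0, high = lim),
                pC, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(pMat, pS, pG, pC))
}
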