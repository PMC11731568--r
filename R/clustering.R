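# Average-linkage clustering, flat cuts, classical MDS, adjusted Rand
# index and the two-group test used for figure annotations.

validate_distance_matrix <- function(D) {
  D <- as.matrix(unclass(D))
  if (nrow(D) != ncol(D)) stop("distance matrix must be square",
                               call. = FALSE)
  if (max(abs(D - t(D))) > 1e-8) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(D < -1e-12)) stop("negative distances", call. = FALSE)
  if (max(abs(diag(D))) > 1e-8) {
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  }
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("s", seq_len(nrow(D)))
  }
  D
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' @param D Square symmetric distance matrix with zero diagonal.
#' @return Object of class `tsr_clust` wrapping the `hclust` merge tree,
#'   with the input labels and a hash of the distance matrix.
#' @export
average_linkage <- function(D) {
  D <- validate_distance_matrix(D)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  structure(list(hclust = hc, labels = rownames(D),
                 dist_hash = rlang::hash(round(D, 12))),
            class = "tsr_clust")
}

#' @export
print.tsr_clust <- function(x, ...) {
  cat("tsr_clust: UPGMA tree over", length(x$labels), "leaves\n")
  invisible(x)
}

#' Flat cluster labels from a merge tree
#'
#' @param result A `tsr_clust` from [average_linkage()].
#' @param k Number of clusters.
#' @return Named integer vector of cluster labels (a partition of all
#'   leaves).
#' @export
cut_clusters <- function(result, k) {
  stopifnot(inherits(result, "tsr_clust"))
  stats::cutree(result$hclust, k = k)
}

#' Export a merge tree as Newick text
#'
#' @param result A `tsr_clust`.
#' @param path Optional file to write to.
#' @return Newick string (invisibly when `path` is given).
#' @export
as_newick <- function(result, path = NULL) {
  stopifnot(inherits(result, "tsr_clust"))
  phy <- ape::as.phylo(result$hclust)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centering of squared distances followed by a truncated spectral
#' decomposition; negative eigenvalues beyond numerical noise trigger a
#' warning (the distances are then not exactly Euclidean).
#'
#' @param D Square symmetric distance matrix.
#' @param dim Embedding dimension, `1 <= dim < n`.
#' @return n x dim coordinate matrix.
#' @export
classical_mds <- function(D, dim = 2) {
  D <- validate_distance_matrix(D)
  n <- nrow(D)
  if (dim >= n) stop("dim must be smaller than the number of points",
                     call. = FALSE)
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(D), k = dim, eig = TRUE))
  neg <- fit$eig[fit$eig < -1e-8 * max(abs(fit$eig))]
  if (length(neg) > 0) {
    warning("distance matrix is not Euclidean: ", length(neg),
            " negative eigenvalue(s) truncated", call. = FALSE)
  }
  coords <- fit$points
  if (ncol(coords) < dim) {  # degenerate configurations
    coords <- cbind(coords, matrix(0, n, dim - ncol(coords)))
  }
  rownames(coords) <- rownames(D)
  coords
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement under the permutation model:
#' 1 for identical partitions (up to label renaming), around 0 for
#' independent ones, possibly negative.
#'
#' @param labels_a,labels_b Equal-length cluster label vectors.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("partitions must label the same items", call. = FALSE)
  }
  n <- length(labels_a)
  tab <- table(labels_a, labels_b)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  maximum <- (a + b) / 2
  if (maximum == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (maximum - expected)
}

#' Welch two-sample t test with star annotation
#'
#' @param x,y Numeric samples (each of size >= 2).
#' @return List with `t`, `p` (two-sided) and `stars` (`***` p < 0.001,
#'   `**` p < 0.01, `*` p < 0.05, `""` otherwise).
#' @export
two_group_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  p <- ht$p.value
  stars <- if (is.na(p)) "" else if (p < 0.001) "***" else
    if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  list(t = unname(ht$statistic), p = p, stars = stars)
}
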