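#' Shared expressed-gene background for cross-dataset tests
#'
#' The background universe for overlap testing: genes detected (value > 0)
#' in at least \code{min_cells} cells in \emph{both} datasets, over the
#' shared gene namespace.
#'
#' @param matrix_a,matrix_b genes x cells matrices with gene row names.
#' @param min_cells detection threshold per dataset (default 5, inclusive).
#' @return character vector of background gene identifiers.
#' @export
build_background <- function(matrix_a, matrix_b, min_cells = 5) {
  ga <- rownames(.label_matrix(matrix_a))
  gb <- rownames(.label_matrix(matrix_b))
  shared <- intersect(ga, gb)
  .assert(length(shared) > 0, "datasets share no gene identifiers")
  da <- Matrix::rowSums(matrix_a[shared, , drop = FALSE] > 0)
  db <- Matrix::rowSums(matrix_b[shared, , drop = FALSE] > 0)
  shared[da >= min_cells & db >= min_cells]
}

#' Hypergeometric test of DEG-list overlap
#'
#' Upper-tail hypergeometric probability of observing at least the seen
#' overlap between two gene lists drawn from a common background universe.
#' Lists are intersected with the background before testing.
#'
#' @param list_a,list_b character vectors of genes (e.g. per-cluster
#'   up-regulated DEGs from two datasets).
#' @param background background gene universe (see
#'   \code{\link{build_background}}).
#' @return list with \code{k} (overlap), \code{K} (|A|), \code{n} (|B|),
#'   \code{N} (|background|), \code{p_value} = P(X >= k).
#' @export
deg_overlap_test <- function(list_a, list_b, background) {
  .assert(length(background) > 0, "background gene set is empty")
  bg <- unique(background)
  a <- intersect(unique(list_a), bg)
  b <- intersect(unique(list_b), bg)
  k <- length(intersect(a, b))
  K <- length(a); n <- length(b); N <- length(bg)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(k = k, K = K, n = n, N = N, p_value = p)
}

#' Pairwise overlap tests between two sets of cluster DEG lists
#'
#' @param degs_a,degs_b named lists of per-cluster DEG vectors.
#' @param background background gene universe.
#' @return data.frame \code{cluster_a}, \code{cluster_b}, \code{k},
#'   \code{K}, \code{n}, \code{N}, \code{p_value}.
#' @export
deg_overlap_table <- function(degs_a, degs_b, background) {
  grid <- expand.grid(cluster_a = names(degs_a), cluster_b = names(degs_b),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    deg_overlap_test(degs_a[[grid$cluster_a[i]]],
                     degs_b[[grid$cluster_b[i]]], background)
  })
  cbind(grid, do.call(rbind, lapply(res, as.data.frame)))
}

#' Spearman correlation of cluster mean expression over top DEGs
#'
#' Builds a gene panel as the union, over clusters of both datasets, of each
#' cluster's top \code{top_n} DEGs (fewer when fewer are available),
#' intersected with the genes shared by both mean matrices, then computes
#' the Spearman rank correlation of mean expression for every cluster pair.
#'
#' @param mean_a,mean_b clusters x genes matrices of mean (log-normalized)
#'   expression per cluster.
#' @param degs_a,degs_b named lists of per-cluster DEG vectors, ordered by
#'   significance (most significant first).
#' @param top_n DEGs taken per cluster (default 100).
#' @return clusters_a x clusters_b matrix of Spearman correlations.
#' @export
cluster_correlation <- function(mean_a, mean_b, degs_a, degs_b, top_n = 100) {
  take <- function(degs) unlist(lapply(degs, utils::head, top_n), use.names = FALSE)
  panel <- unique(c(take(degs_a), take(degs_b)))
  panel <- intersect(panel, intersect(colnames(mean_a), colnames(mean_b)))
  .assert(length(panel) >= 3, "gene panel has fewer than 3 genes")
  stats::cor(t(mean_a[, panel, drop = FALSE]),
             t(mean_b[, panel, drop = FALSE]), method = "spearman")
}

#' Mean expression per cluster
#'
#' @param norm genes x cells matrix.
#' @param labels per-cell cluster labels.
#' @return clusters x genes matrix of per-cluster means.
#' @export
cluster_means <- function(norm, labels) {
  norm <- .label_matrix(.as_dense(norm))
  .assert(length(labels) == ncol(norm), "one label per cell required")
  rowsum(t(norm), labels) / as.vector(table(labels))
}
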