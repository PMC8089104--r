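#' Select highly variable genes by excess variance over a mean-variance trend
#'
#' Fits a trend of per-gene variance against per-gene mean across all genes
#' and ranks genes by the residual (observed minus trend) variance, the
#' excess not explained by the mean-variance relationship. Ties (including
#' the fully degenerate case where all residuals vanish) are broken by gene
#' order, so the selection is deterministic.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param n_hvg number of genes to return.
#' @param method trend fit: \code{"loess"} (default) or \code{"parametric"}
#'   (quadratic polynomial in the mean).
#' @return character vector of the top \code{n_hvg} gene identifiers.
#' @export
select_hvgs <- function(norm, n_hvg, method = c("loess", "parametric")) {
  method <- match.arg(method)
  norm <- .label_matrix(.as_dense(norm))
  .assert(n_hvg >= 1 && n_hvg <= nrow(norm),
          "n_hvg must be between 1 and the number of genes")
  mu <- rowMeans(norm)
  v <- apply(norm, 1, stats::var)
  fitted <- tryCatch({
    if (method == "loess") {
      stats::fitted(stats::loess(v ~ mu, span = 0.5, degree = 2))
    } else {
      stats::fitted(stats::lm(v ~ mu + I(mu^2)))
    }
  }, error = function(e) rep(mean(v), length(v)))
  resid <- v - fitted
  ord <- order(-resid, seq_along(resid))
  rownames(norm)[ord[seq_len(n_hvg)]]
}

#' Principal component analysis of cells
#'
#' Standard PCA of the cells x genes matrix (genes centered across cells).
#' If the requested number of components exceeds the matrix rank the result
#' is truncated with a warning. The sign of each component is fixed so that
#' its largest-magnitude gene loading is positive, making the embedding
#' reproducible across platforms.
#'
#' @param scaled genes x cells matrix (typically confounder-regressed,
#'   restricted to highly variable genes).
#' @param n_components number of components to keep (default 50).
#' @return list of class \code{sc_pca}: \code{embedding} (cells x
#'   components), \code{var_share} (per-component variance fraction, ordered
#'   non-increasing), \code{rotation} (genes x components).
#' @export
run_pca <- function(scaled, n_components = 50) {
  scaled <- .label_matrix(.as_dense(scaled))
  .assert(all(is.finite(scaled)), "input to PCA must be finite")
  .assert(n_components >= 1, "n_components must be >= 1")
  pc <- stats::prcomp(t(scaled), center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-10)
  nk <- min(n_components, rank)
  if (nk < n_components) {
    warning(sprintf("matrix rank %d < requested %d components; truncating",
                    rank, n_components))
  }
  emb <- pc$x[, seq_len(nk), drop = FALSE]
  rot <- pc$rotation[, seq_len(nk), drop = FALSE]
  for (j in seq_len(nk)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      emb[, j] <- -emb[, j]
    }
  }
  structure(list(embedding = emb, var_share = pc$sdev[seq_len(nk)]^2 / tot,
                 rotation = rot, center = pc$center),
            class = "sc_pca")
}

#' Exact k-nearest-neighbor graph on an embedding
#'
#' Connects every cell to its k nearest Euclidean neighbors (self excluded;
#' distance ties broken by cell index) and symmetrizes the union of the
#' directed neighbor lists into an undirected graph.
#'
#' @param emb cells x components embedding (or an \code{sc_pca} object).
#' @param k number of neighbors (default 10, the minimum population size
#'   considered a potentially rare cluster).
#' @return list of class \code{knn_graph}: \code{edges} (data.frame
#'   \code{from}, \code{to}, \code{weight}), \code{knn} (cells x k neighbor
#'   index matrix), \code{cell_ids}.
#' @export
build_knn_graph <- function(emb, k = 10) {
  if (inherits(emb, "sc_pca")) emb <- emb$embedding
  emb <- as.matrix(emb)
  n <- nrow(emb)
  .assert(k >= 1 && k < n, "k must satisfy 1 <= k < number of cells")
  ids <- rownames(emb) %||% paste0("cell_", seq_len(n))
  d <- as.matrix(stats::dist(emb))
  knn <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))   # index-order tie-break
    knn[i, ] <- setdiff(ord, i)[seq_len(k)]
  }
  from <- rep(seq_len(n), each = k)
  to <- as.integer(t(knn))
  a <- pmin(from, to); b <- pmax(from, to)
  keep <- !duplicated(cbind(a, b))
  edges <- data.frame(from = a[keep], to = b[keep], weight = 1)
  structure(list(edges = edges, knn = knn, cell_ids = ids),
            class = "knn_graph")
}

#' Prune a KNN graph by shared-nearest-neighbor similarity
#'
#' Removes spurious edges: an edge (i, j) survives iff the Jaccard index of
#' the two cells' neighbor lists is at least \code{jaccard_min}; surviving
#' edges are re-weighted by their Jaccard index.
#'
#' @param graph a \code{knn_graph}.
#' @param jaccard_min minimum admissible Jaccard similarity (default 1/15).
#' @return a \code{knn_graph} with the pruned, re-weighted edge set.
#' @export
prune_snn <- function(graph, jaccard_min = 1 / 15) {
  .assert(inherits(graph, "knn_graph"), "graph must be a knn_graph")
  knn <- graph$knn
  e <- graph$edges
  jac <- vapply(seq_len(nrow(e)), function(r) {
    a <- knn[e$from[r], ]; b <- knn[e$to[r], ]
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1))
  keep <- jac >= jaccard_min
  out <- graph
  out$edges <- data.frame(from = e$from[keep], to = e$to[keep],
                          weight = jac[keep])
  out
}

#' Louvain community detection on a cell graph
#'
#' Runs Louvain modularity optimization at the given resolution on the
#' (pruned) neighbor graph. Cells are the vertex set regardless of edges, so
#' isolated cells become singleton clusters. Labels are 0-based, contiguous,
#' and assigned by decreasing cluster size (ties by smallest member index),
#' making the labelling deterministic for a fixed seed.
#'
#' @param graph a \code{knn_graph} (typically SNN-pruned).
#' @param resolution Louvain modularity resolution (default 2.4).
#' @param seed integer RNG seed for the (stochastic) optimization.
#' @return integer vector of cluster ids named by cell identifier.
#' @export
louvain_cluster <- function(graph, resolution = 2.4, seed = 0) {
  .assert(inherits(graph, "knn_graph"), "graph must be a knn_graph")
  n <- length(graph$cell_ids)
  .assert(n > 0, "empty graph")
  .assert(resolution > 0, "resolution must be positive")
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(graph$edges) > 0) {
    g <- igraph::add_edges(g, rbind(graph$edges$from, graph$edges$to))
    igraph::E(g)$weight <- graph$edges$weight
  }
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(comm)
  sizes <- table(memb)
  first <- tapply(seq_len(n), memb, min)
  ord <- names(sizes)[order(-as.integer(sizes), first)]
  relabel <- stats::setNames(seq_along(ord) - 1L, ord)
  stats::setNames(as.integer(relabel[as.character(memb)]), graph$cell_ids)
}
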