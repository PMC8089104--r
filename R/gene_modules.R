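#' Power-free correlation adjacency
#'
#' Gene-to-gene adjacency as the absolute Pearson correlation of expression
#' profiles across cells, with no soft-threshold power applied (equivalently
#' power = 1). In sparse single-cell data even strong correlations rarely
#' approach 1, so raising them to a power would flatten the whole matrix
#' toward zero; the raw correlation magnitude is used directly instead. A
#' signed variant \code{a = (1 + r) / 2} is available.
#'
#' @param expr genes x cells expression submatrix (selected genes); constant
#'   genes are rejected with an error naming them.
#' @param signed use the signed transform instead of \code{|r|}.
#' @param method correlation estimator, \code{"pearson"} (default) or
#'   \code{"spearman"}.
#' @return symmetric genes x genes adjacency with unit diagonal, entries in
#'   [0,1].
#' @export
correlation_adjacency <- function(expr, signed = FALSE,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  expr <- .label_matrix(.as_dense(expr))
  .assert(ncol(expr) >= 3, "need at least 3 cells")
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    stop(errorCondition(
      paste0("constant genes have no defined correlation: ",
             paste(utils::head(rownames(expr)[sds == 0], 10), collapse = ", ")),
      class = c("scm_validation_error", "scm_error")))
  }
  r <- stats::cor(t(expr), method = method)
  a <- if (signed) (1 + r) / 2 else abs(r)
  a[a > 1] <- 1; a[a < 0] <- 0
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' Unsigned TOM of an adjacency matrix:
#' \deqn{TOM_{ij} = (l_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})}
#' for \eqn{i \ne j}, where \eqn{l_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}} and
#' \eqn{k_i = \sum_{u \ne i} a_{iu}}; the diagonal is 1. Two genes overlap
#' strongly when they are both directly correlated and share correlated
#' neighbors, which stabilizes module detection against noisy individual
#' correlations.
#'
#' @param adj symmetric adjacency with entries in [0,1] and unit diagonal.
#' @return symmetric TOM with entries in [0,1] and unit diagonal.
#' @export
topological_overlap <- function(adj) {
  .assert(is.matrix(adj) && nrow(adj) == ncol(adj), "adjacency must be square")
  .assert(max(abs(adj - t(adj))) < 1e-10, "adjacency must be symmetric")
  .assert(all(adj >= 0 & adj <= 1), "adjacency entries must be in [0,1]")
  a <- adj
  diag(a) <- 0
  l <- a %*% a                 # l_ij = sum_u a_iu a_uj over u != i, j
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  tom[tom > 1] <- 1; tom[tom < 0] <- 0
  tom <- (tom + t(tom)) / 2    # symmetrize away numeric fuzz
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Cut the TOM dendrogram into a fixed number of modules
#'
#' Agglomerative hierarchical clustering of genes on the dissimilarity
#' \code{1 - TOM} with Ward's squared linkage (Ward.D2), cut into exactly
#' \code{n_modules} groups (no dynamic tree cut). Module ids are assigned by
#' decreasing module size, ties broken by smallest member gene index, so the
#' labelling is deterministic.
#'
#' @param tom topological overlap matrix.
#' @param n_modules number of modules (default 100).
#' @return integer module id (1..n_modules) per gene, named by gene.
#' @export
cut_modules <- function(tom, n_modules = 100) {
  .assert(n_modules >= 1 && n_modules <= nrow(tom),
          "n_modules must be between 1 and the number of genes")
  h <- stats::hclust(stats::as.dist(1 - tom), method = "ward.D2")
  ct <- stats::cutree(h, k = n_modules)
  sizes <- table(ct)
  first <- tapply(seq_along(ct), ct, min)
  ord <- names(sizes)[order(-as.integer(sizes), first)]
  relabel <- stats::setNames(seq_along(ord), ord)
  out <- as.integer(relabel[as.character(ct)])
  names(out) <- rownames(tom) %||% names(ct)
  out
}

#' Per-cell module expression scores
#'
#' Each gene is min-max normalized to [0,1] across cells; a module's score
#' in a cell is the mean of its genes' normalized values, the module's
#' "expression pattern". Constant genes carry no pattern and contribute 0.
#'
#' @param expr genes x cells expression matrix (log-normalized by
#'   convention; any non-negative scale works since genes are min-max
#'   normalized individually).
#' @param assignment module id per gene, covering all rows of \code{expr};
#'   every id in \code{1..max} must have at least one gene.
#' @return modules x cells matrix with entries in [0,1].
#' @export
module_scores <- function(expr, assignment) {
  expr <- .label_matrix(.as_dense(expr))
  .assert(length(assignment) == nrow(expr),
          "assignment must cover all genes in expr")
  n_mod <- max(assignment)
  .assert(all(seq_len(n_mod) %in% assignment),
          paste0("empty module id(s): ",
                 paste(setdiff(seq_len(n_mod), assignment), collapse = ", ")))
  lo <- apply(expr, 1, min)
  hi <- apply(expr, 1, max)
  span <- hi - lo
  norm01 <- (expr - lo) / ifelse(span == 0, Inf, span)
  norm01[span == 0, ] <- 0
  sums <- rowsum(norm01, assignment)
  sizes <- as.vector(table(factor(assignment, levels = seq_len(n_mod))))
  scores <- sums / sizes
  rownames(scores) <- paste0("module_", seq_len(n_mod))
  scores
}

#' K-nearest-neighbor graph over modules
#'
#' Connects each module to its k most-correlated modules (Pearson on the
#' per-cell score vectors) and symmetrizes the union of directed lists,
#' keeping the correlation as edge weight. Modules with constant score
#' vectors have no defined correlation; they are excluded from neighbor
#' candidacy with a warning.
#'
#' @param scores modules x cells score matrix.
#' @param k neighbors per module (default 5).
#' @return data.frame of undirected edges \code{from}, \code{to} (module
#'   row names) and \code{weight} (correlation).
#' @export
module_knn_graph <- function(scores, k = 5) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  .assert(k >= 1 && k < n, "k must satisfy 1 <= k < number of modules")
  ids <- rownames(scores) %||% paste0("module_", seq_len(n))
  sds <- apply(scores, 1, stats::sd)
  usable <- which(sds > 0)
  if (length(usable) < n) {
    warning(sprintf("%d constant module score vector(s) excluded from the graph",
                    n - length(usable)))
  }
  .assert(length(usable) > k, "too few non-constant modules for the requested k")
  r <- stats::cor(t(scores[usable, , drop = FALSE]))
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (ii in seq_along(usable)) {
    ord <- order(-r[ii, ], seq_along(usable))
    nb <- setdiff(ord, ii)[seq_len(k)]
    from <- c(from, rep(usable[ii], k))
    to <- c(to, usable[nb])
    w <- c(w, r[ii, nb])
  }
  a <- pmin(from, to); b <- pmax(from, to)
  keep <- !duplicated(cbind(a, b))
  data.frame(from = ids[a[keep]], to = ids[b[keep]], weight = w[keep],
             stringsAsFactors = FALSE)
}
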