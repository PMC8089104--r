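#' Hurdle-model differential expression, one cluster versus the rest
#'
#' Two-part test per gene, in the spirit of single-cell hurdle models: a
#' detection component (likelihood-ratio G-test of the 2x2 table of
#' detected/undetected by group) and a continuous component (Gaussian
#' likelihood-ratio test of positive log-expression on the group indicator).
#' The combined statistic is the sum of the two component LR statistics,
#' with degrees of freedom summed over the testable components, referred to
#' a chi-square distribution. The fold change is the difference of mean
#' log-normalized expression (zeros included) divided by \code{ln 2}.
#'
#' Genes with zero expression in both groups are untestable (p = 1,
#' log2FC = 0, flagged). When one group has no positive cells the continuous
#' component is dropped and the detection component stands alone.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param labels per-cell cluster labels (any atomic type).
#' @param cluster the cluster tested against all remaining cells.
#' @return data.frame with one row per gene: \code{gene}, \code{cluster},
#'   \code{log2fc}, \code{p_value}, \code{fdr} (Benjamini-Hochberg within
#'   this cluster's family), \code{pct_in}, \code{pct_out},
#'   \code{untestable}.
#' @export
hurdle_de <- function(norm, labels, cluster) {
  norm <- .label_matrix(.as_dense(norm))
  .assert(length(labels) == ncol(norm), "one label per cell required")
  grp <- labels == cluster
  n1 <- sum(grp); n2 <- sum(!grp)
  .assert(n1 > 0, "cluster is empty")
  .assert(n2 > 0, "comparison group is empty")

  x1 <- norm[, grp, drop = FALSE]
  x2 <- norm[, !grp, drop = FALSE]
  d1 <- rowSums(x1 > 0); d2 <- rowSums(x2 > 0)
  s1 <- rowSums(x1); s2 <- rowSums(x2)
  q1 <- rowSums(x1^2); q2 <- rowSums(x2^2)

  # detection component: 2x2 LR G-test, testable unless margins degenerate
  g_stat <- .g_stat_2x2(d1, n1, d2, n2)
  disc_ok <- (d1 + d2) > 0 & (d1 + d2) < (n1 + n2)

  # continuous component on positive values: Gaussian LRT n*log(RSS0/RSS1)
  np <- d1 + d2
  m1 <- ifelse(d1 > 0, s1 / d1, 0)
  m2 <- ifelse(d2 > 0, s2 / d2, 0)
  mp <- ifelse(np > 0, (s1 + s2) / np, 0)
  rss1 <- pmax(q1 - d1 * m1^2, 0) + pmax(q2 - d2 * m2^2, 0)
  rss0 <- pmax(q1 + q2 - np * mp^2, 0)
  cont_ok <- d1 > 0 & d2 > 0 & np >= 3 & rss0 > 1e-12
  lr_cont <- ifelse(cont_ok,
                    ifelse(rss1 > 1e-12, np * log(rss0 / rss1),
                           np * log(rss0 / 1e-12)),
                    0)

  stat <- ifelse(disc_ok, g_stat, 0) + lr_cont
  df <- as.integer(disc_ok) + as.integer(cont_ok)
  p <- ifelse(df > 0, stats::pchisq(stat, df, lower.tail = FALSE), 1)

  log2fc <- (rowMeans(x1) - rowMeans(x2)) / log(2)
  untestable <- (d1 + d2) == 0
  log2fc[untestable] <- 0
  p[untestable] <- 1

  data.frame(
    gene = rownames(norm), cluster = cluster,
    log2fc = log2fc, p_value = p, fdr = bh_fdr(p),
    pct_in = d1 / n1, pct_out = d2 / n2, untestable = untestable,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Run hurdle DE for every cluster (one-vs-rest)
#'
#' @param norm genes x cells log-normalized matrix.
#' @param labels per-cell cluster labels.
#' @return data.frame stacking \code{\link{hurdle_de}} over all clusters.
#' @export
hurdle_de_all <- function(norm, labels) {
  cl <- sort(unique(labels))
  .assert(length(cl) >= 2, "need at least two clusters")
  do.call(rbind, lapply(cl, function(k) hurdle_de(norm, labels, k)))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' @param p_values numeric vector of p-values in [0,1]; NA/NaN are rejected.
#' @return step-up adjusted q-values.
#' @export
bh_fdr <- function(p_values) {
  .assert(!anyNA(p_values), "p-values contain NA/NaN")
  .assert(all(p_values >= 0 & p_values <= 1), "p-values must be in [0,1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Cluster marker genes (up-regulated, FDR-controlled)
#'
#' A gene is a marker for a cluster iff \code{log2fc > lfc_min} (strictly,
#' up-regulated only) and \code{fdr < fdr_max} (strictly).
#'
#' @param de DE table from \code{\link{hurdle_de_all}}.
#' @param lfc_min fold-change threshold (default 0.25).
#' @param fdr_max FDR threshold (default 0.01).
#' @return named list, one character vector of gene ids per cluster.
#' @export
marker_genes <- function(de, lfc_min = 0.25, fdr_max = 0.01) {
  keep <- de$log2fc > lfc_min & de$fdr < fdr_max
  sel <- de[keep, , drop = FALSE]
  cl <- sort(unique(de$cluster))
  stats::setNames(lapply(cl, function(k) sel$gene[sel$cluster == k]), cl)
}

#' Permissive gene set for module detection
#'
#' Union over clusters of genes with \code{|log2fc| > lfc_abs_min} and raw
#' \code{p_value < p_max}, the permissive regime used to collect the most
#' cluster-informative genes before co-expression analysis. Deduplicated, in
#' first-appearance order (deterministic).
#'
#' @param de_all DE table covering every cluster.
#' @param lfc_abs_min absolute fold-change threshold (default 0.1).
#' @param p_max raw p-value threshold (default 0.1).
#' @return character vector of gene identifiers.
#' @export
permissive_gene_set <- function(de_all, lfc_abs_min = 0.1, p_max = 0.1) {
  keep <- abs(de_all$log2fc) > lfc_abs_min & de_all$p_value < p_max
  unique(de_all$gene[keep])
}
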