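# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(ok, msg, class = "scm_validation_error") {
  if (!isTRUE(ok)) stop(errorCondition(msg, class = c(class, "scm_error")))
}

.as_dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else x
}

# matrix must carry gene (row) and cell (column) names; fill if absent
.label_matrix <- function(x) {
  if (is.null(rownames(x))) rownames(x) <- paste0("gene_", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("cell_", seq_len(ncol(x)))
  x
}

# likelihood-ratio (G) statistic for a 2x2 detection table, vectorised over
# genes; zero cells contribute zero by the 0*log(0) = 0 convention
.g_stat_2x2 <- function(d1, n1, d2, n2) {
  term <- function(obs, exp) ifelse(obs > 0, obs * log(obs / exp), 0)
  d <- d1 + d2
  n <- n1 + n2
  p0 <- d / n
  g <- term(d1, n1 * p0) + term(n1 - d1, n1 * (1 - p0)) +
    term(d2, n2 * p0) + term(n2 - d2, n2 * (1 - p0))
  2 * g
}

.random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

.random_aa <- function(n, len) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    paste(sample(aa, len, replace = TRUE), collapse = "")
  }, character(1))
}
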