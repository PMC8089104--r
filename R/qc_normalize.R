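#' Recover pseudo-counts from TPM-scale values
#'
#' Full-length protocols quantified as transcripts-per-million lose the read
#' depth information that count-based models expect. Multiplying each TPM
#' value by the read length and rounding to the nearest integer restores a
#' count-scale matrix suitable for detection-based QC and log-normalization.
#'
#' @param tpm genes x cells matrix of non-negative TPM-scale values.
#' @param read_length sequencing read length in base pairs (default 43).
#' @return integer matrix of the same shape; halves round away from zero.
#' @export
recover_counts <- function(tpm, read_length = 43) {
  tpm <- .label_matrix(.as_dense(tpm))
  .assert(all(is.finite(tpm)), "TPM matrix contains non-finite values")
  .assert(all(tpm >= 0), "TPM matrix contains negative values")
  .assert(read_length > 0, "read_length must be positive")
  out <- floor(tpm * read_length + 0.5)
  storage.mode(out) <- "integer"
  out
}

#' QC thresholds for cell and gene filtering
#'
#' Defaults follow the filtering rules used for full-length ILC single-cell
#' libraries: cells are discarded when the mitochondrial fraction exceeds
#' 40\% or the ribosomal fraction 50\%, when less than 50\% of counts fall on
#' protein-coding genes, or when fewer than 200 unique genes are detected;
#' genes detected in fewer than five cells are dropped.
#'
#' @param max_pct_mito,max_pct_ribo upper bounds (strict) on count fractions.
#' @param min_pct_protein_coding lower bound (strict) on protein-coding share.
#' @param min_n_genes minimum number of detected genes per cell (inclusive).
#' @param min_cells_per_gene minimum cells a gene must be detected in
#'   (inclusive).
#' @return a list of class \code{qc_thresholds}.
#' @export
qc_thresholds <- function(max_pct_mito = 0.40, max_pct_ribo = 0.50,
                          min_pct_protein_coding = 0.50, min_n_genes = 200,
                          min_cells_per_gene = 5) {
  .assert(max_pct_mito >= 0 && max_pct_mito <= 1, "max_pct_mito must be in [0,1]")
  .assert(max_pct_ribo >= 0 && max_pct_ribo <= 1, "max_pct_ribo must be in [0,1]")
  .assert(min_pct_protein_coding >= 0 && min_pct_protein_coding <= 1,
          "min_pct_protein_coding must be in [0,1]")
  .assert(min_n_genes >= 0, "min_n_genes must be >= 0")
  .assert(min_cells_per_gene >= 0, "min_cells_per_gene must be >= 0")
  structure(list(max_pct_mito = max_pct_mito, max_pct_ribo = max_pct_ribo,
                 min_pct_protein_coding = min_pct_protein_coding,
                 min_n_genes = min_n_genes,
                 min_cells_per_gene = min_cells_per_gene),
            class = "qc_thresholds")
}

#' Per-cell QC metrics
#'
#' Computes count-weighted fractions of mitochondrial, ribosomal,
#' protein-coding and non-coding genes, the number of detected genes and the
#' total counts per cell. Spike-in genes (annotation column \code{is_spike})
#' are excluded from all totals, since they are not cellular transcripts.
#'
#' @param counts genes x cells count matrix.
#' @param annotation gene annotation data.frame (see
#'   \code{\link{synthetic_gene_annotation}} for the expected columns:
#'   \code{gene_id}, \code{biotype}, logical \code{is_mito}, \code{is_ribo},
#'   \code{is_y}, optional \code{is_spike}).
#' @return data.frame with one row per cell: \code{cell_id}, \code{pct_mito},
#'   \code{pct_ribo}, \code{pct_protein_coding}, \code{pct_noncoding},
#'   \code{n_genes}, \code{total_counts}. Cells with zero total counts get
#'   \code{NA} fractions; they are always removed by the min-genes rule.
#' @export
compute_qc_metrics <- function(counts, annotation) {
  counts <- .label_matrix(.as_dense(counts))
  .assert(is.data.frame(annotation) && nrow(annotation) == nrow(counts),
          "annotation must have one row per gene")
  .assert(!anyDuplicated(annotation$gene_id), "gene_id values must be unique")
  is_spike <- annotation$is_spike %||% rep(FALSE, nrow(counts))
  cellular <- counts[!is_spike, , drop = FALSE]
  ann <- annotation[!is_spike, , drop = FALSE]

  total <- colSums(cellular)
  frac <- function(sel) {
    f <- colSums(cellular[sel, , drop = FALSE]) / total
    f[total == 0] <- NA_real_
    f
  }
  data.frame(
    cell_id = colnames(counts),
    pct_mito = frac(ann$is_mito),
    pct_ribo = frac(ann$is_ribo),
    pct_protein_coding = frac(ann$biotype == "protein_coding"),
    pct_noncoding = frac(ann$biotype == "non_coding"),
    n_genes = colSums(cellular > 0),
    total_counts = total,
    stringsAsFactors = FALSE
  )
}

#' Filter low-quality cells
#'
#' A cell is removed iff any rule fires: mitochondrial fraction strictly
#' above \code{max_pct_mito}, ribosomal fraction strictly above
#' \code{max_pct_ribo}, protein-coding fraction strictly below
#' \code{min_pct_protein_coding}, or fewer than \code{min_n_genes} detected
#' genes. Thresholds are strict in the stated direction, so a cell sitting
#' exactly on a bound is kept.
#'
#' @param qc QC table from \code{\link{compute_qc_metrics}}.
#' @param thresholds a \code{\link{qc_thresholds}} object.
#' @return character vector of kept cell identifiers, input order preserved.
#' @export
filter_cells <- function(qc, thresholds = qc_thresholds()) {
  .assert(inherits(thresholds, "qc_thresholds"), "thresholds must be qc_thresholds()")
  gt <- function(x, b) !is.na(x) & x > b
  lt <- function(x, b) !is.na(x) & x < b
  bad <- gt(qc$pct_mito, thresholds$max_pct_mito) |
    gt(qc$pct_ribo, thresholds$max_pct_ribo) |
    lt(qc$pct_protein_coding, thresholds$min_pct_protein_coding) |
    qc$n_genes < thresholds$min_n_genes
  qc$cell_id[!bad]
}

#' Filter rarely detected genes
#'
#' @param counts genes x cells count matrix.
#' @param min_cells keep a gene iff it is detected (value > 0) in at least
#'   this many cells (default 5).
#' @return character vector of kept gene identifiers, input order preserved.
#' @export
filter_genes <- function(counts, min_cells = 5) {
  counts <- .label_matrix(counts)
  detected <- Matrix::rowSums(counts > 0)
  rownames(counts)[detected >= min_cells]
}

#' Log-normalize a count matrix
#'
#' Each entry becomes \code{log(1 + count / cell_total * scale_factor)}
#' (natural log). Zero counts map to zero, so sparsity is preserved.
#'
#' @param counts genes x cells count matrix; every cell must have a positive
#'   total (filter first).
#' @param scale_factor library-size scale factor (default 1000, appropriate
#'   for full-length pseudo-counts).
#' @return dense genes x cells matrix of log-normalized values.
#' @export
lognormalize <- function(counts, scale_factor = 1000) {
  counts <- .label_matrix(.as_dense(counts))
  .assert(all(counts >= 0), "counts must be non-negative")
  totals <- colSums(counts)
  .assert(all(totals > 0),
          paste0("cells with zero total counts must be filtered first: ",
                 paste(utils::head(colnames(counts)[totals == 0], 5), collapse = ", ")))
  log1p(sweep(counts, 2, totals, "/") * scale_factor)
}

#' Regress out confounding covariates and standardize genes
#'
#' Fits, per gene, an ordinary-least-squares model of log-expression on the
#' supplied per-cell covariates (with intercept), takes the residuals and
#' standardizes them to mean zero and unit variance. Typical covariates are
#' the QC fractions (mitochondrial, ribosomal, non-coding), a sex indicator,
#' Y-chromosome fraction and cell-cycle scores. Genes whose residuals are
#' constant yield an all-zero row.
#'
#' @param norm genes x cells log-normalized matrix.
#' @param covariates cells x p numeric data.frame/matrix; may be NULL or have
#'   zero columns, in which case the result is the per-gene z-score.
#' @return genes x cells matrix of standardized residuals.
#' @export
regress_confounders <- function(norm, covariates = NULL) {
  norm <- .label_matrix(.as_dense(norm))
  n <- ncol(norm)
  if (is.null(covariates) || NCOL(covariates) == 0) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    cv <- as.matrix(covariates)
    .assert(nrow(cv) == n, "covariates must have one row per cell")
    .assert(all(is.finite(cv)), "covariates must be complete and finite")
    .assert(n >= ncol(cv) + 2, "need at least 2 more cells than covariates")
    X <- cbind("(Intercept)" = 1, cv)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop(errorCondition(
      paste0("covariate table is rank-deficient; collinear columns: ",
             paste(dropped, collapse = ", ")),
      class = c("scm_validation_error", "scm_error")))
  }
  res <- t(qr.resid(qx, t(norm)))
  sds <- sqrt(rowSums(res^2) / (n - 1))
  out <- res / ifelse(sds < 1e-12, Inf, sds)
  out[sds < 1e-12, ] <- 0
  dimnames(out) <- dimnames(norm)
  out
}
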