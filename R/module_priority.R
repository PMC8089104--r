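#' Gaussian GLM fit of a module score on a metadata factor
#'
#' Fits an identity-link Gaussian GLM of the per-cell module score on a
#' one-hot encoding of the factor (with intercept). For this family the
#' model deviance is the residual sum of squares of the group-means fit and
#' the null deviance is the total sum of squares about the grand mean.
#'
#' @param score numeric per-cell module score vector.
#' @param factor per-cell categorical labels (at least 2 levels present,
#'   fewer levels than cells).
#' @return named numeric vector \code{c(dev_model, dev_null)}.
#' @export
fit_module_glm <- function(score, factor) {
  .assert(length(score) == length(factor), "score and factor lengths differ")
  .assert(all(is.finite(score)), "scores must be finite")
  f <- droplevels(as.factor(factor))
  .assert(nlevels(f) >= 2, "factor must have at least 2 levels present")
  .assert(nlevels(f) < length(score), "more factor levels than cells")
  gm <- tapply(score, f, mean)
  dev_model <- sum((score - gm[f])^2)
  dev_null <- sum((score - mean(score))^2)
  c(dev_model = dev_model, dev_null = dev_null)
}

#' Deviance ratio of a module-metadata fit
#'
#' The fraction of the null deviance removed by the factor,
#' \code{(dev_null - dev_model) / dev_null}. For the Gaussian family this is
#' exactly the coefficient of determination R-squared of the group-means
#' fit, so it lies in [0,1] and is invariant to affine rescaling of the
#' score. A constant score (zero null deviance) explains nothing and is
#' defined to have ratio 0, with a warning.
#'
#' @param dev_null,dev_model deviances from \code{\link{fit_module_glm}}.
#' @return the deviance ratio in [0,1].
#' @export
delta_deviance <- function(dev_null, dev_model) {
  .assert(dev_model >= 0, "dev_model must be non-negative")
  if (dev_null <= 0) {
    warning("null deviance is 0 (constant score); deviance ratio defined as 0")
    return(0)
  }
  (dev_null - dev_model) / dev_null
}

#' Flag housekeeping-dominated modules
#'
#' A module is flagged when more than \code{min_frac} of its genes carry
#' ribosomal or mitochondrial annotation flags; such modules track technical
#' or housekeeping programs rather than cell-state biology.
#'
#' @param assignment module id per gene (named by gene_id).
#' @param annotation gene annotation with \code{gene_id}, \code{is_mito},
#'   \code{is_ribo}.
#' @param min_frac flagged when the housekeeping gene fraction exceeds this
#'   value (default 0.5).
#' @return logical vector, one entry per module id 1..max.
#' @export
flag_housekeeping_modules <- function(assignment, annotation, min_frac = 0.5) {
  hk <- (annotation$is_mito | annotation$is_ribo)[
    match(names(assignment), annotation$gene_id)]
  .assert(!anyNA(hk), "all assigned genes must appear in the annotation")
  frac <- tapply(hk, assignment, mean)
  out <- rep(FALSE, max(assignment))
  out[as.integer(names(frac))] <- frac > min_frac
  out
}

#' Prioritize modules by metadata association
#'
#' Scores every (module, factor) pair by the deviance ratio of a Gaussian
#' GLM fit and ranks modules within each factor (rank 1 = most explained).
#' Modules flagged as housekeeping keep their records but are excluded from
#' the ranking (rank NA).
#'
#' @param scores modules x cells score matrix.
#' @param metadata per-cell data.frame of categorical factors; must cover
#'   every cell (columns used are \code{factors}).
#' @param factors which metadata columns to test (default: all non-cell_id
#'   columns).
#' @param housekeeping optional logical per module (see
#'   \code{\link{flag_housekeeping_modules}}).
#' @return data.frame with \code{module_id}, \code{factor}, \code{dev_null},
#'   \code{dev_model}, \code{delta_dev}, \code{rank},
#'   \code{housekeeping_flag}, sorted by factor then rank.
#' @export
prioritize_modules <- function(scores, metadata, factors = NULL,
                               housekeeping = NULL) {
  scores <- as.matrix(scores)
  .assert(nrow(metadata) == ncol(scores), "metadata must cover all cells")
  bad <- which(!stats::complete.cases(metadata))
  .assert(length(bad) == 0,
          paste0("missing metadata for cell(s): ",
                 paste(utils::head(colnames(scores)[bad], 10), collapse = ", ")))
  factors <- factors %||% setdiff(colnames(metadata), "cell_id")
  mods <- rownames(scores) %||% paste0("module_", seq_len(nrow(scores)))
  hk <- housekeeping %||% rep(FALSE, nrow(scores))

  recs <- list()
  for (fc in factors) {
    fv <- metadata[[fc]]
    for (m in seq_len(nrow(scores))) {
      dv <- withCallingHandlers(
        fit_module_glm(scores[m, ], fv),
        warning = function(w) invokeRestart("muffleWarning"))
      dd <- suppressWarnings(delta_deviance(dv["dev_null"], dv["dev_model"]))
      recs[[length(recs) + 1]] <- data.frame(
        module_id = mods[m], factor = fc,
        dev_null = unname(dv["dev_null"]), dev_model = unname(dv["dev_model"]),
        delta_dev = unname(dd), housekeeping_flag = hk[m],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, recs)
  out$rank <- NA_integer_
  for (fc in factors) {
    sel <- out$factor == fc & !out$housekeeping_flag
    out$rank[sel] <- rank(-out$delta_dev[sel], ties.method = "min")
  }
  out[order(out$factor, ifelse(is.na(out$rank), Inf, out$rank),
            -out$delta_dev), , drop = FALSE]
}
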