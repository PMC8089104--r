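#' Filter clones by read count
#'
#' Removes likely false-positive clone calls: a record survives iff its read
#' count is strictly greater than \code{min_count_exclusive}.
#'
#' @param records clone data.frame (\code{cell_id}, \code{chain},
#'   \code{cdr3_nt}, \code{cdr3_aa}, \code{read_count}).
#' @param min_count_exclusive exclusive lower bound (default 5, i.e. keep
#'   count > 5).
#' @return the filtered data.frame.
#' @export
filter_clones <- function(records, min_count_exclusive = 5) {
  .assert(all(records$read_count >= 1), "read counts must be positive")
  records[records$read_count > min_count_exclusive, , drop = FALSE]
}

.CHAINS <- c("TRA", "TRB", "TRG", "TRD")

#' Dominant clone per cell and chain
#'
#' For each (cell, chain) keeps the record with the highest read count; ties
#' are broken by the lexicographically smallest CDR3 nucleotide sequence, so
#' the result does not depend on input record order.
#'
#' @param records count-filtered clone data.frame.
#' @return data.frame with at most one record per (cell, chain).
#' @export
dominant_clone_per_chain <- function(records) {
  bad <- which(!records$chain %in% .CHAINS)
  .assert(length(bad) == 0,
          paste0("unknown chain symbol in row(s): ",
                 paste(utils::head(bad, 10), collapse = ", ")))
  if (nrow(records) == 0) return(records)
  ord <- order(records$cell_id, records$chain, -records$read_count,
               records$cdr3_nt)
  r <- records[ord, , drop = FALSE]
  keep <- !duplicated(r[, c("cell_id", "chain")])
  out <- r[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify per-cell V(D)J rearrangement category
#'
#' Maps each cell's set of rearranged chains (those with a surviving
#' dominant clone) to one of four categories: \code{none} (no chain),
#' \code{TRA_B} (only alpha/beta chains), \code{TRG_D} (only gamma/delta
#' chains), or \code{TRA_B_G_D} (chains from both groups in combination).
#'
#' @param dominant dominant-clone data.frame from
#'   \code{\link{dominant_clone_per_chain}}.
#' @param cell_ids optional full cell universe; cells without any surviving
#'   clone are classified \code{none}.
#' @return data.frame \code{cell_id}, \code{category}, \code{chains}
#'   (comma-separated rearranged chain set).
#' @export
classify_rearrangement <- function(dominant, cell_ids = NULL) {
  bad <- which(!dominant$chain %in% .CHAINS)
  .assert(length(bad) == 0,
          paste0("unknown chain symbol in row(s): ",
                 paste(utils::head(bad, 10), collapse = ", ")))
  cells <- cell_ids %||% unique(dominant$cell_id)
  sets <- split(dominant$chain, factor(dominant$cell_id, levels = cells))
  cat_of <- function(chains) {
    ab <- any(chains %in% c("TRA", "TRB"))
    gd <- any(chains %in% c("TRG", "TRD"))
    if (ab && gd) "TRA_B_G_D"
    else if (ab) "TRA_B"
    else if (gd) "TRG_D"
    else "none"
  }
  data.frame(
    cell_id = cells,
    category = vapply(sets, cat_of, character(1)),
    chains = vapply(sets, function(s) paste(sort(unique(s)), collapse = ","),
                    character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Clone frequency table per cell group
#'
#' Counts, per group and chain, how many cells carry each distinct dominant
#' CDR3; clones represented by two or more cells are marked expanded.
#'
#' @param dominant dominant-clone data.frame.
#' @param groups named character vector mapping cell_id to a population
#'   label; must cover every cell present in \code{dominant}.
#' @param by clone identity key: \code{"cdr3_nt"} (default) or
#'   \code{"cdr3_aa"}.
#' @return data.frame \code{group}, \code{chain}, clone sequence,
#'   \code{n_cells}, \code{expanded}.
#' @export
clone_frequency_table <- function(dominant, groups, by = c("cdr3_nt", "cdr3_aa")) {
  by <- match.arg(by)
  missing <- setdiff(unique(dominant$cell_id), names(groups))
  .assert(length(missing) == 0,
          paste0("groups missing for cell(s): ",
                 paste(utils::head(missing, 10), collapse = ", ")))
  if (nrow(dominant) == 0) {
    return(data.frame(group = character(0), chain = character(0),
                      clone = character(0), n_cells = integer(0),
                      expanded = logical(0)))
  }
  key <- data.frame(group = unname(groups[dominant$cell_id]),
                    chain = dominant$chain, clone = dominant[[by]],
                    stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(n_cells = rep(1L, nrow(key))), key, sum)
  agg$expanded <- agg$n_cells >= 2
  agg[order(agg$group, agg$chain, -agg$n_cells, agg$clone), , drop = FALSE]
}

#' Clones shared between two cell groups
#'
#' Reports every (chain, CDR3) pair present as a dominant clone in at least
#' one cell of each group — evidence of a shared clonal origin.
#'
#' @param cells_a,cells_b character vectors of cell ids.
#' @param dominant dominant-clone data.frame.
#' @param by clone identity key (default nucleotide CDR3).
#' @return data.frame \code{chain}, \code{clone}, \code{n_cells_a},
#'   \code{n_cells_b}.
#' @export
clonal_overlap <- function(cells_a, cells_b, dominant,
                           by = c("cdr3_nt", "cdr3_aa")) {
  by <- match.arg(by)
  a <- dominant[dominant$cell_id %in% cells_a, , drop = FALSE]
  b <- dominant[dominant$cell_id %in% cells_b, , drop = FALSE]
  ka <- paste(a$chain, a[[by]], sep = "|")
  kb <- paste(b$chain, b[[by]], sep = "|")
  shared <- sort(intersect(ka, kb))
  if (length(shared) == 0) {
    return(data.frame(chain = character(0), clone = character(0),
                      n_cells_a = integer(0), n_cells_b = integer(0)))
  }
  parts <- do.call(rbind, strsplit(shared, "|", fixed = TRUE))
  data.frame(chain = parts[, 1], clone = parts[, 2],
             n_cells_a = as.integer(table(ka)[shared]),
             n_cells_b = as.integer(table(kb)[shared]),
             row.names = NULL, stringsAsFactors = FALSE)
}
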