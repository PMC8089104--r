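# Format readers and writers. On-disk convention throughout: genes as rows,
# cells as columns. Sparse matrices travel as MatrixMarket .mtx with
# "<path>.genes.tsv" / "<path>.cells.tsv" label sidecars; dense matrices as
# TSV with gene row names and cell column headers.

#' Read an expression matrix
#'
#' @param path file path; \code{.mtx} selects MatrixMarket with label
#'   sidecars, anything else is read as dense TSV (first column = gene ids,
#'   header = cell ids).
#' @param sparse return a \code{dgCMatrix} for MTX input (default FALSE:
#'   dense base matrix).
#' @return genes x cells matrix with dimnames.
#' @export
read_matrix <- function(path, sparse = FALSE) {
  .assert(file.exists(path), paste0("file not found: ", path))
  if (grepl("\\.mtx$", path)) {
    m <- Matrix::readMM(path)
    genes <- readLines(paste0(path, ".genes.tsv"))
    cells <- readLines(paste0(path, ".cells.tsv"))
    .assert(length(genes) == nrow(m) && length(cells) == ncol(m),
            "label sidecar lengths do not match matrix dimensions")
    dimnames(m) <- list(genes, cells)
    if (sparse) methods::as(m, "CsparseMatrix") else as.matrix(m)
  } else {
    df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
    as.matrix(df)
  }
}

#' Write an expression matrix
#'
#' @param mat genes x cells matrix.
#' @param path output path; \code{.mtx} writes MatrixMarket plus
#'   \code{<path>.genes.tsv} and \code{<path>.cells.tsv} sidecars, anything
#'   else a dense TSV.
#' @return \code{path}, invisibly.
#' @export
write_matrix <- function(mat, path) {
  mat <- .label_matrix(mat)
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(methods::as(methods::as(mat, "dMatrix"), "CsparseMatrix"),
                    path)
    writeLines(rownames(mat), paste0(path, ".genes.tsv"))
    writeLines(colnames(mat), paste0(path, ".cells.tsv"))
  } else {
    utils::write.table(.as_dense(mat), path, sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  invisible(path)
}

#' Read a gene annotation table
#'
#' CSV with columns \code{gene_id}, \code{symbol}, \code{biotype} and
#' \code{flags} (semicolon-separated subset of
#' \code{mitochondrial;ribosomal;y_chromosome;spike_in}), expanded into the
#' logical columns the QC functions expect.
#'
#' @param path CSV path.
#' @return annotation data.frame.
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("gene_id", "symbol", "biotype")) {
    .assert(col %in% colnames(df), paste0("annotation is missing column: ", col))
  }
  .assert(!anyDuplicated(df$gene_id), "gene_id values must be unique")
  flags <- strsplit(df$flags %||% rep("", nrow(df)), ";", fixed = TRUE)
  has <- function(f) vapply(flags, function(x) f %in% x, logical(1))
  df$is_mito <- has("mitochondrial")
  df$is_ribo <- has("ribosomal")
  df$is_y <- has("y_chromosome")
  df$is_spike <- has("spike_in")
  df
}

#' Write a gene annotation table
#'
#' @param annotation annotation data.frame with the logical flag columns.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_gene_annotation <- function(annotation, path) {
  flags <- apply(cbind(
    ifelse(annotation$is_mito, "mitochondrial", NA),
    ifelse(annotation$is_ribo, "ribosomal", NA),
    ifelse(annotation$is_y, "y_chromosome", NA),
    ifelse(annotation$is_spike %||% FALSE, "spike_in", NA)), 1,
    function(x) paste(stats::na.omit(x), collapse = ";"))
  out <- data.frame(gene_id = annotation$gene_id, symbol = annotation$symbol,
                    biotype = annotation$biotype, flags = flags,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-cell metadata
#'
#' @param path CSV path; must contain a \code{cell_id} column.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .assert("cell_id" %in% colnames(df), "metadata is missing column: cell_id")
  df
}

#' Read a TCR clone table
#'
#' Tab-separated clone export (MiXCR-style); only five columns are required
#' and their names are remappable via \code{column_map} (e.g.
#' \code{c(read_count = "cloneCount", cdr3_nt = "nSeqCDR3")}).
#'
#' @param path TSV path.
#' @param column_map named character vector mapping the canonical names
#'   (\code{cell_id}, \code{chain}, \code{cdr3_nt}, \code{cdr3_aa},
#'   \code{read_count}) to the file's column names.
#' @return clone data.frame with canonical columns.
#' @export
read_clone_table <- function(path, column_map = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  canonical <- c("cell_id", "chain", "cdr3_nt", "cdr3_aa", "read_count")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  for (cn in canonical) {
    .assert(map[[cn]] %in% colnames(df),
            paste0("clone table is missing column: ", map[[cn]]))
  }
  out <- stats::setNames(df[, unname(map[canonical])], canonical)
  out$read_count <- as.integer(out$read_count)
  bad <- which(!out$chain %in% .CHAINS)
  .assert(length(bad) == 0,
          paste0("unknown chain symbol in row(s): ",
                 paste(utils::head(bad, 10), collapse = ", ")))
  .assert(!anyNA(out$read_count) && all(out$read_count >= 1),
          "read_count must be a positive integer")
  out
}

#' Write a clone table
#'
#' @param clones clone data.frame.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_clone_table <- function(clones, path) {
  utils::write.table(clones, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
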