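#' Pipeline configuration
#'
#' Collects every stage parameter with its standard default, validating
#' types and ranges before any stage runs. Accepts a list, or a path to a
#' YAML/JSON file holding the same fields.
#'
#' @param matrix,annotation,metadata,clone_table input file paths
#'   (\code{clone_table} optional). Alternatively, in-memory objects can be
#'   passed directly to \code{\link{run_pipeline}}'s \code{data} argument.
#' @param output_dir directory for stage artifacts.
#' @param tpm_scale whether the input matrix is TPM-scale and needs count
#'   recovery (default TRUE).
#' @param read_length read length for count recovery (default 43).
#' @param qc a \code{\link{qc_thresholds}} object.
#' @param scale_factor log-normalization scale factor (default 1000).
#' @param covariates metadata/QC columns to regress out (default the three
#'   internally computed fractions plus sex and cell-cycle scores when
#'   present).
#' @param n_hvg number of highly variable genes (default 2000, capped at the
#'   gene count).
#' @param n_pcs number of principal components (default 50).
#' @param k KNN neighbors (default 10).
#' @param jaccard_min SNN pruning threshold (default 1/15).
#' @param resolution Louvain resolution (default 2.4).
#' @param marker_lfc,marker_fdr marker DE thresholds (defaults 0.25, 0.01).
#' @param permissive_lfc,permissive_p permissive DE thresholds (defaults
#'   0.1, 0.1).
#' @param n_modules modules to cut (default 100).
#' @param module_graph_k module 5-NN graph neighbors (default 5).
#' @param clone_min_count exclusive clone count filter (default 5).
#' @param priority_factors metadata columns to prioritize against (default
#'   all categorical columns).
#' @param seed integer seed driving every stochastic stage.
#' @return validated list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(matrix = NULL, annotation = NULL, metadata = NULL,
                            clone_table = NULL, output_dir = "scmodules_out",
                            tpm_scale = TRUE, read_length = 43,
                            qc = qc_thresholds(), scale_factor = 1000,
                            covariates = NULL, n_hvg = 2000, n_pcs = 50,
                            k = 10, jaccard_min = 1 / 15, resolution = 2.4,
                            marker_lfc = 0.25, marker_fdr = 0.01,
                            permissive_lfc = 0.1, permissive_p = 0.1,
                            n_modules = 100, module_graph_k = 5,
                            clone_min_count = 5, priority_factors = NULL,
                            seed = 1) {
  if (is.character(matrix) && length(matrix) == 1 && is.null(annotation) &&
      grepl("\\.(ya?ml|json)$", matrix)) {
    cfg <- if (grepl("\\.json$", matrix)) jsonlite::read_json(matrix, simplifyVector = TRUE)
    else yaml::read_yaml(matrix)
    if (!is.null(cfg$qc)) cfg$qc <- do.call(qc_thresholds, cfg$qc)
    return(do.call(pipeline_config, cfg))
  }
  .assert(read_length > 0, "read_length must be positive")
  .assert(scale_factor > 0, "scale_factor must be positive")
  .assert(n_hvg >= 2, "n_hvg must be >= 2")
  .assert(n_pcs >= 1, "n_pcs must be >= 1")
  .assert(k >= 1, "k must be >= 1")
  .assert(jaccard_min >= 0 && jaccard_min <= 1, "jaccard_min must be in [0,1]")
  .assert(resolution > 0, "resolution must be positive")
  .assert(n_modules >= 1, "n_modules must be >= 1")
  .assert(module_graph_k >= 1, "module_graph_k must be >= 1")
  .assert(clone_min_count >= 0, "clone_min_count must be >= 0")
  .assert(is.numeric(seed) && length(seed) == 1, "seed must be a single integer")
  if (!inherits(qc, "qc_thresholds")) qc <- do.call(qc_thresholds, as.list(qc))
  structure(list(
    matrix = matrix, annotation = annotation, metadata = metadata,
    clone_table = clone_table, output_dir = output_dir,
    tpm_scale = tpm_scale, read_length = read_length, qc = qc,
    scale_factor = scale_factor, covariates = covariates, n_hvg = n_hvg,
    n_pcs = n_pcs, k = k, jaccard_min = jaccard_min, resolution = resolution,
    marker_lfc = marker_lfc, marker_fdr = marker_fdr,
    permissive_lfc = permissive_lfc, permissive_p = permissive_p,
    n_modules = n_modules, module_graph_k = module_graph_k,
    clone_min_count = clone_min_count, priority_factors = priority_factors,
    seed = seed), class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(paste0("stage '", name, "': ", conditionMessage(e)),
                        class = c("scm_stage_error", "scm_error")))
  })
}

#' Run the full analysis pipeline
#'
#' Executes QC and filtering, log-normalization, confounder regression, HVG
#' selection, PCA, SNN graph construction, Louvain clustering, one-vs-rest
#' hurdle DE, the permissive gene selection, co-expression module detection
#' (adjacency, TOM, Ward.D2 cut), module scoring, module prioritization and,
#' when a clone table is supplied, TCR rearrangement classification. Every
#' stage artifact is written to \code{output_dir} together with a manifest
#' recording the configuration hash, the seed and output checksums; a rerun
#' with the same configuration and seed reproduces byte-identical tables.
#'
#' @param config a \code{\link{pipeline_config}} (or path to one).
#' @param data optional list with in-memory inputs \code{counts},
#'   \code{annotation}, \code{metadata}, \code{clones}, overriding the paths
#'   in \code{config}.
#' @return invisibly, a list with the principal in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config, data = NULL) {
  if (is.character(config)) config <- pipeline_config(matrix = config)
  .assert(inherits(config, "pipeline_config"), "config must be pipeline_config()")
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("scmodules")),
                   seed = config$seed, stages = list())
  note <- function(stage, files, dims = NULL) {
    manifest$stages[[stage]] <<- list(
      outputs = files,
      md5 = as.vector(tools::md5sum(file.path(out_dir, files))),
      dims = dims)
  }

  mat <- .stage("load", {
    if (!is.null(data$counts)) .label_matrix(.as_dense(data$counts))
    else read_matrix(config$matrix)
  })
  ann <- .stage("load", {
    if (!is.null(data$annotation)) data$annotation
    else read_gene_annotation(config$annotation)
  })
  meta <- .stage("load", {
    if (!is.null(data$metadata)) data$metadata
    else if (!is.null(config$metadata)) read_metadata(config$metadata)
    else data.frame(cell_id = colnames(mat))
  })

  counts <- .stage("qc", {
    if (config$tpm_scale && !all(mat == floor(mat))) {
      recover_counts(mat, config$read_length)
    } else mat
  })
  qc_tab <- .stage("qc", compute_qc_metrics(counts, ann))
  kept_cells <- .stage("qc", filter_cells(qc_tab, config$qc))
  counts <- counts[, kept_cells, drop = FALSE]
  spike <- ann$is_spike %||% rep(FALSE, nrow(ann))
  counts <- counts[!spike, , drop = FALSE]
  ann_f <- ann[!spike, , drop = FALSE]
  kept_genes <- .stage("qc", filter_genes(counts, config$qc$min_cells_per_gene))
  counts <- counts[kept_genes, , drop = FALSE]
  ann_f <- ann_f[match(kept_genes, ann_f$gene_id), , drop = FALSE]
  utils::write.csv(qc_tab, file.path(out_dir, "qc_table.csv"), row.names = FALSE)
  write_matrix(counts, file.path(out_dir, "filtered_counts.tsv"))
  note("qc", c("qc_table.csv", "filtered_counts.tsv"), dims = dim(counts))

  norm <- .stage("normalize", lognormalize(counts, config$scale_factor))
  qc_kept <- qc_tab[match(kept_cells, qc_tab$cell_id), , drop = FALSE]
  meta_kept <- meta[match(kept_cells, meta$cell_id), , drop = FALSE]
  cov_tab <- .stage("normalize", {
    base <- data.frame(pct_mito = qc_kept$pct_mito, pct_ribo = qc_kept$pct_ribo,
                       pct_noncoding = qc_kept$pct_noncoding)
    extra_cols <- config$covariates %||%
      intersect(c("sex", "cc_s", "cc_g2m"), colnames(meta_kept))
    for (cc in extra_cols) {
      if (cc %in% colnames(meta_kept)) base[[cc]] <- meta_kept[[cc]]
    }
    # a covariate with no variation across kept cells (e.g. sex in a
    # single-sex cohort) is collinear with the intercept; drop it
    base[, vapply(base, function(x) stats::sd(x) > 0, logical(1)),
         drop = FALSE]
  })
  scaled <- .stage("normalize", regress_confounders(norm, cov_tab))
  write_matrix(norm, file.path(out_dir, "lognorm.tsv"))
  write_matrix(scaled, file.path(out_dir, "scaled.tsv"))
  note("normalize", c("lognorm.tsv", "scaled.tsv"), dims = dim(norm))

  clusters <- .stage("cluster", {
    hvgs <- select_hvgs(norm, min(config$n_hvg, nrow(norm)))
    pca <- run_pca(scaled[hvgs, , drop = FALSE],
                   min(config$n_pcs, length(hvgs), ncol(norm) - 1))
    gr <- build_knn_graph(pca, min(config$k, ncol(norm) - 1))
    snn <- prune_snn(gr, config$jaccard_min)
    louvain_cluster(snn, config$resolution, config$seed)
  })
  utils::write.csv(data.frame(cell_id = names(clusters), cluster = clusters),
                   file.path(out_dir, "clusters.csv"), row.names = FALSE)
  note("cluster", "clusters.csv", dims = length(unique(clusters)))

  de <- .stage("de", hurdle_de_all(norm, clusters))
  utils::write.csv(de, file.path(out_dir, "de_table.csv"), row.names = FALSE)
  markers <- marker_genes(de, config$marker_lfc, config$marker_fdr)
  marker_df <- do.call(rbind, lapply(names(markers), function(k) {
    if (length(markers[[k]]) == 0) return(NULL)
    data.frame(cluster = k, gene = markers[[k]])
  })) %||% data.frame(cluster = character(0), gene = character(0))
  utils::write.table(marker_df, file.path(out_dir, "markers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("de", c("de_table.csv", "markers.tsv"), dims = nrow(de))

  perm <- .stage("permissive", permissive_gene_set(de, config$permissive_lfc,
                                                   config$permissive_p))
  writeLines(perm, file.path(out_dir, "permissive_genes.txt"))
  note("permissive", "permissive_genes.txt", dims = length(perm))

  mod_expr <- norm[perm, , drop = FALSE]
  mod_expr <- mod_expr[apply(mod_expr, 1, stats::sd) > 0, , drop = FALSE]
  assignment <- .stage("modules", {
    .assert(config$n_modules <= nrow(mod_expr),
            sprintf("n_modules (%d) exceeds the %d usable permissive genes",
                    config$n_modules, nrow(mod_expr)))
    adj <- correlation_adjacency(mod_expr)
    tom <- topological_overlap(adj)
    cut_modules(tom, config$n_modules)
  })
  scores <- .stage("modules", module_scores(mod_expr, assignment))
  mod_graph <- .stage("modules", {
    if (nrow(scores) > config$module_graph_k) {
      module_knn_graph(scores, config$module_graph_k)
    } else data.frame(from = character(0), to = character(0), weight = numeric(0))
  })
  utils::write.table(data.frame(gene_id = names(assignment), module_id = assignment),
                     file.path(out_dir, "module_assignment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix(scores, file.path(out_dir, "module_scores.tsv"))
  utils::write.table(mod_graph, file.path(out_dir, "module_graph.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("modules", c("module_assignment.tsv", "module_scores.tsv", "module_graph.tsv"),
       dims = nrow(scores))

  priority <- .stage("prioritize", {
    fac <- config$priority_factors %||% {
      cand <- setdiff(colnames(meta_kept), "cell_id")
      cand[vapply(meta_kept[cand], function(x)
        is.character(x) || is.factor(x), logical(1))]
    }
    pm <- data.frame(meta_kept, cluster = paste0("cluster_", clusters),
                     stringsAsFactors = FALSE)
    hk <- flag_housekeeping_modules(assignment, ann_f)
    prioritize_modules(scores, pm, factors = c(fac, "cluster"),
                       housekeeping = hk)
  })
  utils::write.csv(priority, file.path(out_dir, "module_priority.csv"),
                   row.names = FALSE)
  note("prioritize", "module_priority.csv", dims = nrow(priority))

  calls <- NULL
  clone_input <- data$clones %||% config$clone_table
  if (!is.null(clone_input)) {
    calls <- .stage("tcr", {
      clones <- if (is.character(clone_input)) read_clone_table(clone_input)
      else clone_input
      dom <- dominant_clone_per_chain(
        filter_clones(clones, config$clone_min_count))
      classify_rearrangement(dom, cell_ids = colnames(counts))
    })
    utils::write.csv(calls, file.path(out_dir, "rearrangement_calls.csv"),
                     row.names = FALSE)
    note("tcr", "rearrangement_calls.csv", dims = nrow(calls))
  }

  cfg_for_hash <- config
  cfg_for_hash$output_dir <- NULL
  cfg_json <- jsonlite::toJSON(cfg_for_hash, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest$config_hash <- unname(tools::md5sum(tf))
  unlink(tf)
  manifest$config <- cfg_for_hash
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)

  invisible(list(qc = qc_tab, counts = counts, norm = norm, scaled = scaled,
                 clusters = clusters, de = de, markers = markers,
                 permissive_genes = perm, assignment = assignment,
                 scores = scores, module_graph = mod_graph,
                 priority = priority, rearrangements = calls,
                 manifest = manifest))
}
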