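#' Deterministic gene annotation for synthetic data
#'
#' Assigns mitochondrial, ribosomal and Y-chromosome flags and biotypes to
#' fixed index ranges so that QC rules are testable without real annotation:
#' the first 2\% of genes are mitochondrial, the next 5\% ribosomal, the next
#' 1\% Y-chromosomal, the next 10\% non-coding; everything else is
#' protein-coding (flagged genes included).
#'
#' @param n_genes number of genes.
#' @param gene_ids optional identifiers (default \code{gene_1..gene_n}).
#' @return data.frame with columns \code{gene_id}, \code{symbol},
#'   \code{biotype}, \code{is_mito}, \code{is_ribo}, \code{is_y},
#'   \code{is_spike}.
#' @export
synthetic_gene_annotation <- function(n_genes, gene_ids = NULL) {
  .assert(n_genes >= 1, "n_genes must be >= 1")
  ids <- gene_ids %||% paste0("gene_", seq_len(n_genes))
  n_mito <- max(1L, round(0.02 * n_genes))
  n_ribo <- max(1L, round(0.05 * n_genes))
  n_y <- max(1L, round(0.01 * n_genes))
  n_nc <- max(1L, round(0.10 * n_genes))
  idx <- seq_len(n_genes)
  mito <- idx <= n_mito
  ribo <- idx > n_mito & idx <= n_mito + n_ribo
  ychr <- idx > n_mito + n_ribo & idx <= n_mito + n_ribo + n_y
  nonc <- idx > n_mito + n_ribo + n_y & idx <= n_mito + n_ribo + n_y + n_nc
  data.frame(
    gene_id = ids, symbol = ids,
    biotype = ifelse(nonc, "non_coding", "protein_coding"),
    is_mito = mito, is_ribo = ribo, is_y = ychr,
    is_spike = rep(FALSE, n_genes),
    stringsAsFactors = FALSE
  )
}

#' Convenience constructor for planted co-expression modules
#'
#' Builds \code{n_modules} disjoint gene sets of \code{module_size}
#' consecutive genes starting at \code{start_gene}, cycling the driving
#' metadata factor over tissue, subset and donor levels so that distinct
#' modules are tied to distinct factor levels.
#'
#' @param n_modules,module_size,start_gene module layout.
#' @param effect mean log-expression shift for cells at the driving level.
#' @param n_tissues,n_subsets,n_donors factor level counts to cycle over.
#' @return list of planted-module specifications for
#'   \code{\link{synthetic_config}}.
#' @export
make_planted_modules <- function(n_modules, module_size, effect = 2.0,
                                 start_gene = 1, n_tissues = 3, n_subsets = 3,
                                 n_donors = 4) {
  combos <- rbind(
    data.frame(factor = "tissue", level = paste0("tissue_", seq_len(n_tissues))),
    data.frame(factor = "subset", level = paste0("subset_", seq_len(n_subsets))),
    data.frame(factor = "donor", level = paste0("donor_", seq_len(n_donors)))
  )
  lapply(seq_len(n_modules), function(m) {
    cmb <- combos[(m - 1) %% nrow(combos) + 1, ]
    list(genes = start_gene + (m - 1) * module_size + seq_len(module_size) - 1,
         factor = cmb$factor, level = cmb$level, effect = effect)
  })
}

#' Configuration for the synthetic expression generator
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param n_tissues,n_subsets,n_donors numbers of metadata factor levels.
#' @param planted_modules list of \code{list(genes, factor, level, effect)}
#'   specifications (see \code{\link{make_planted_modules}}); gene sets must
#'   be pairwise disjoint and within range.
#' @param de_genes optional data.frame \code{(gene, subset, log2fc)} of
#'   planted subset-specific effects.
#' @param dropout_rate Bernoulli thinning probability in [0,1].
#' @param confounder_strength scale of additive cell-cycle confounding on the
#'   log-mean (0 disables).
#' @param seed integer RNG seed; the full output is reproducible from it.
#' @return validated list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_cells = 500, n_genes = 600, n_tissues = 3,
                             n_subsets = 3, n_donors = 4,
                             planted_modules = list(), de_genes = NULL,
                             dropout_rate = 0.1, confounder_strength = 0,
                             seed = 1) {
  .assert(n_cells >= 1 && n_genes >= 1, "dimensions must be positive")
  .assert(dropout_rate >= 0 && dropout_rate <= 1, "dropout_rate must be in [0,1]")
  .assert(confounder_strength >= 0, "confounder_strength must be non-negative")
  all_genes <- integer(0)
  for (pm in planted_modules) {
    .assert(all(pm$genes >= 1 & pm$genes <= n_genes),
            "planted module gene indices out of range")
    .assert(!any(pm$genes %in% all_genes), "planted module gene sets must be disjoint")
    .assert(pm$factor %in% c("tissue", "subset", "donor"),
            "module driving factor must be tissue, subset or donor")
    all_genes <- c(all_genes, pm$genes)
  }
  if (!is.null(de_genes)) {
    .assert(all(de_genes$gene >= 1 & de_genes$gene <= n_genes),
            "de_genes gene indices out of range")
    .assert(all(de_genes$subset >= 1 & de_genes$subset <= n_subsets),
            "de_genes subset indices out of range")
  }
  structure(list(n_cells = n_cells, n_genes = n_genes, n_tissues = n_tissues,
                 n_subsets = n_subsets, n_donors = n_donors,
                 planted_modules = planted_modules, de_genes = de_genes,
                 dropout_rate = dropout_rate,
                 confounder_strength = confounder_strength, seed = seed),
            class = "synthetic_config")
}

#' Generate a synthetic expression dataset with planted ground truth
#'
#' Counts follow a lognormal-Poisson model: the per-gene, per-cell log-mean
#' is a gene baseline plus the planted subset programs, plus (for module
#' genes) a gene loading times a cell-level module factor driven by the
#' module's metadata level, plus optional cell-cycle confounding; counts are
#' Poisson draws from the exponentiated log-mean, thinned by Bernoulli
#' dropout. This reproduces the overdispersion and zero inflation that the
#' hurdle differential-expression model assumes.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return list of class \code{synthetic_dataset} with elements
#'   \code{counts} (integer genes x cells), \code{annotation},
#'   \code{metadata} (per-cell tissue/subset/donor, sex, cell-cycle scores
#'   and realised QC fractions) and \code{truth} (module assignment per gene,
#'   planted DE table, cell labels, covariates).
#' @export
generate_expression <- function(config) {
  .assert(inherits(config, "synthetic_config"), "config must be synthetic_config()")
  set.seed(config$seed)
  nc <- config$n_cells; ng <- config$n_genes

  tissue <- paste0("tissue_", sample.int(config$n_tissues, nc, replace = TRUE))
  subset <- paste0("subset_", sample.int(config$n_subsets, nc, replace = TRUE))
  donor <- paste0("donor_", sample.int(config$n_donors, nc, replace = TRUE))
  donor_sex <- stats::setNames(sample(c(0L, 1L), config$n_donors, replace = TRUE),
                               paste0("donor_", seq_len(config$n_donors)))
  sex <- donor_sex[donor]
  cc_s <- stats::rnorm(nc)
  cc_g2m <- stats::rnorm(nc)
  labels <- list(tissue = tissue, subset = subset, donor = donor)

  baseline <- stats::rnorm(ng, mean = 1.5, sd = 0.7)
  logmu <- matrix(baseline, ng, nc)

  module_assignment <- rep(NA_integer_, ng)
  for (m in seq_along(config$planted_modules)) {
    pm <- config$planted_modules[[m]]
    fval <- pm$effect * (labels[[pm$factor]] == pm$level) + stats::rnorm(nc, 0, 0.3)
    loading <- stats::runif(length(pm$genes), 0.8, 1.2)
    logmu[pm$genes, ] <- logmu[pm$genes, ] + outer(loading, fval)
    module_assignment[pm$genes] <- m
  }
  if (!is.null(config$de_genes)) {
    for (i in seq_len(nrow(config$de_genes))) {
      de <- config$de_genes[i, ]
      hit <- subset == paste0("subset_", de$subset)
      logmu[de$gene, hit] <- logmu[de$gene, hit] + log(2) * de$log2fc
    }
  }
  if (config$confounder_strength > 0) {
    load_s <- stats::rnorm(ng, 0, 0.3)
    load_g2m <- stats::rnorm(ng, 0, 0.3)
    logmu <- logmu + config$confounder_strength *
      (outer(load_s, cc_s) + outer(load_g2m, cc_g2m))
  }
  logmu <- pmin(logmu, 12)  # guard against overflow-scale means

  counts <- matrix(stats::rpois(ng * nc, exp(logmu)), ng, nc)
  if (config$dropout_rate > 0) {
    keep <- matrix(stats::rbinom(ng * nc, 1L, 1 - config$dropout_rate), ng, nc)
    counts <- counts * keep
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(paste0("gene_", seq_len(ng)),
                           paste0("cell_", seq_len(nc)))

  annotation <- synthetic_gene_annotation(ng)
  qc <- compute_qc_metrics(counts, annotation)
  covariates <- data.frame(
    cell_id = colnames(counts),
    pct_mito = qc$pct_mito, pct_ribo = qc$pct_ribo,
    pct_noncoding = qc$pct_noncoding,
    sex = as.integer(sex), cc_s = cc_s, cc_g2m = cc_g2m,
    stringsAsFactors = FALSE
  )
  metadata <- data.frame(
    cell_id = colnames(counts), tissue = tissue, subset = subset,
    donor = donor, sex = as.integer(sex), cc_s = cc_s, cc_g2m = cc_g2m,
    stringsAsFactors = FALSE
  )
  truth <- list(
    module_assignment = stats::setNames(module_assignment, rownames(counts)),
    de_table = config$de_genes,
    cell_labels = metadata[, c("cell_id", "tissue", "subset", "donor")],
    covariates = covariates,
    planted_modules = config$planted_modules
  )
  structure(list(counts = counts, annotation = annotation,
                 metadata = metadata, truth = truth),
            class = "synthetic_dataset")
}

#' Generate a synthetic TCR clone table with planted rearrangement categories
#'
#' Each cell is assigned a rearrangement category; for each rearranged chain
#' a dominant clone with read count strictly above the count filter is
#' emitted (counts are 6 plus a geometric draw, giving realistic skew), plus
#' occasional sub-dominant clones (count above the filter but below the
#' dominant) and low-count decoy clones on arbitrary chains (count 1..5,
#' removed by the filter) so both sides of the count > 5 boundary are
#' exercised. CDR3 strings are unique per clone unless sharing is planted via
#' \code{shared_clone_spec}.
#'
#' @param n_cells number of cells.
#' @param category_probs named probabilities over
#'   \code{c("none","TRA_B","TRG_D","TRA_B_G_D")}; must sum to 1.
#' @param clone_size_prob geometric success probability for the
#'   above-filter read-count excess (default 0.15).
#' @param decoy_rate per-cell probability of an extra low-count decoy clone.
#' @param shared_clone_spec optional data.frame \code{(chain, size)}; for
#'   each row, \code{size} cells carrying that chain share one planted CDR3.
#' @param seed integer RNG seed.
#' @return list with \code{clones} (data.frame \code{cell_id}, \code{chain},
#'   \code{cdr3_nt}, \code{cdr3_aa}, \code{read_count}) and \code{truth}
#'   (per-cell planted category and chain sets, planted shared clones).
#' @export
generate_clone_table <- function(n_cells,
                                 category_probs = c(none = 0.4, TRA_B = 0.3,
                                                    TRG_D = 0.2, TRA_B_G_D = 0.1),
                                 clone_size_prob = 0.15, decoy_rate = 0.3,
                                 shared_clone_spec = NULL, seed = 1) {
  .assert(n_cells >= 1, "n_cells must be >= 1")
  cats <- c("none", "TRA_B", "TRG_D", "TRA_B_G_D")
  .assert(all(names(category_probs) %in% cats), "unknown category name")
  .assert(abs(sum(category_probs) - 1) < 1e-8, "category probabilities must sum to 1")
  set.seed(seed)
  cell_ids <- paste0("cell_", seq_len(n_cells))
  category <- sample(names(category_probs), n_cells, replace = TRUE,
                     prob = category_probs)

  ab <- c("TRA", "TRB"); gd <- c("TRG", "TRD")
  pick <- function(pool) {
    k <- sample.int(length(pool), 1)
    sample(pool, k)
  }
  chain_sets <- lapply(category, function(ct) {
    switch(ct,
           none = character(0),
           TRA_B = pick(ab),
           TRG_D = pick(gd),
           TRA_B_G_D = unique(c(pick(ab), pick(gd))))
  })

  rows <- list()
  clone_id <- 0
  new_cdr3 <- function() {
    clone_id <<- clone_id + 1
    list(nt = paste0(.random_dna(1, 27), sprintf("%06d", clone_id)),
         aa = .random_aa(1, 11))
  }
  for (i in seq_len(n_cells)) {
    for (ch in chain_sets[[i]]) {
      dom <- 6L + stats::rgeom(1, clone_size_prob)
      c3 <- new_cdr3()
      rows[[length(rows) + 1]] <- data.frame(
        cell_id = cell_ids[i], chain = ch, cdr3_nt = c3$nt, cdr3_aa = c3$aa,
        read_count = dom, stringsAsFactors = FALSE)
      if (dom >= 8 && stats::runif(1) < 0.25) {  # sub-dominant, survives filter
        c3b <- new_cdr3()
        rows[[length(rows) + 1]] <- data.frame(
          cell_id = cell_ids[i], chain = ch, cdr3_nt = c3b$nt,
          cdr3_aa = c3b$aa, read_count = sample(6:(dom - 1), 1),
          stringsAsFactors = FALSE)
      }
    }
    if (stats::runif(1) < decoy_rate) {  # low-count noise, removed by filter
      c3d <- new_cdr3()
      rows[[length(rows) + 1]] <- data.frame(
        cell_id = cell_ids[i], chain = sample(c(ab, gd), 1),
        cdr3_nt = c3d$nt, cdr3_aa = c3d$aa,
        read_count = sample.int(5, 1), stringsAsFactors = FALSE)
    }
  }
  clones <- do.call(rbind, rows) %||% data.frame(
    cell_id = character(0), chain = character(0), cdr3_nt = character(0),
    cdr3_aa = character(0), read_count = integer(0))

  shared_truth <- NULL
  if (!is.null(shared_clone_spec)) {
    recs <- list()
    for (i in seq_len(nrow(shared_clone_spec))) {
      ch <- shared_clone_spec$chain[i]
      size <- shared_clone_spec$size[i]
      carriers <- which(vapply(chain_sets, function(s) ch %in% s, logical(1)))
      taken <- unlist(lapply(recs, function(r) match(r$cells, cell_ids)))
      carriers <- setdiff(carriers, taken)
      .assert(length(carriers) >= size,
              "not enough cells carry the requested chain for planted sharing")
      sel <- carriers[seq_len(size)]
      c3 <- new_cdr3()
      hit <- clones$chain == ch & clones$cell_id %in% cell_ids[sel] &
        clones$read_count > 5
      # overwrite each selected cell's dominant clone on that chain
      for (cid in cell_ids[sel]) {
        j <- which(hit & clones$cell_id == cid)
        j <- j[which.max(clones$read_count[j])]
        clones$cdr3_nt[j] <- c3$nt
        clones$cdr3_aa[j] <- c3$aa
        clones$read_count[j] <- max(clones$read_count[clones$cell_id == cid &
                                                        clones$chain == ch]) + 1L
      }
      recs[[i]] <- list(chain = ch, cdr3_nt = c3$nt, cells = cell_ids[sel])
    }
    shared_truth <- recs
  }

  truth <- list(category = stats::setNames(category, cell_ids),
                chain_sets = stats::setNames(chain_sets, cell_ids),
                shared_clones = shared_truth)
  list(clones = clones, truth = truth)
}

#' Generate a QC fixture with planted rule violations
#'
#' Builds a count matrix in which known cells violate each cell-filter rule
#' (high mitochondrial fraction, high ribosomal fraction, low protein-coding
#' fraction, too few detected genes, plus one cell violating two rules at
#' once) and known genes violate the gene filter (detected in fewer than
#' five cells), so that filtering can be checked for exact recovery.
#'
#' @param seed integer RNG seed.
#' @param n_good number of passing cells.
#' @param n_genes number of genes (at least 260).
#' @return list with \code{counts}, \code{annotation} and \code{truth}
#'   (character vectors of planted violating cell/gene identifiers per rule).
#' @export
generate_qc_fixture <- function(seed = 1, n_good = 60, n_genes = 400) {
  .assert(n_genes >= 260, "need at least 260 genes for the fixture")
  set.seed(seed)
  ann <- synthetic_gene_annotation(n_genes)
  n_bad <- 5 + 4 + 3 + 6 + 1
  nc <- n_good + n_bad
  ids <- paste0("cell_", seq_len(nc))

  # baseline: every cell detects well over 200 genes, moderate QC fractions
  counts <- matrix(stats::rpois(n_genes * nc, 3) + 1L, n_genes, nc)
  dimnames(counts) <- list(ann$gene_id, ids)

  mito <- which(ann$is_mito); ribo <- which(ann$is_ribo)
  nonc <- which(ann$biotype == "non_coding")
  bad_mito <- ids[n_good + 1:5]
  bad_ribo <- ids[n_good + 5 + 1:4]
  bad_pc <- ids[n_good + 9 + 1:3]
  bad_ngenes <- ids[n_good + 12 + 1:6]
  bad_multi <- ids[n_good + 18 + 1]

  boost <- function(cells, genes, mult) {
    counts[genes, cells] <<- counts[genes, cells] * mult
  }
  boost(bad_mito, mito, 200L)       # mito fraction driven far above 40%
  boost(bad_ribo, ribo, 200L)       # ribo fraction above 50%
  boost(bad_pc, nonc, 100L)         # protein-coding share below 50%
  for (cid in bad_ngenes) {         # 150 detected genes < 200 minimum
    keep <- seq_len(150)
    counts[-keep, cid] <- 0L
  }
  counts[mito, bad_multi] <- counts[mito, bad_multi] * 200L  # high mito ...
  counts[-c(mito, seq_len(100)), bad_multi] <- 0L            # ... and few genes

  # gene-filter violations: three genes in exactly 4 cells, one all-zero gene
  good_cells <- ids[seq_len(n_good)]
  low_genes <- ann$gene_id[n_genes - 3:1]
  for (g in low_genes) {
    counts[g, ] <- 0L
    counts[g, good_cells[1:4]] <- 5L
  }
  zero_gene <- ann$gene_id[n_genes]
  counts[zero_gene, ] <- 0L

  truth <- list(bad_mito = bad_mito, bad_ribo = bad_ribo, bad_pc = bad_pc,
                bad_ngenes = bad_ngenes, bad_multi = bad_multi,
                bad_cells = c(bad_mito, bad_ribo, bad_pc, bad_ngenes, bad_multi),
                low_genes = c(low_genes, zero_gene))
  list(counts = counts, annotation = ann, truth = truth)
}
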