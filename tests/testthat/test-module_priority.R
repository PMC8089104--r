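test_that("gaussian glm fit equals the group-means closed form", {
  set.seed(51)
  score <- rnorm(300)
  fac <- sample(c("a", "b", "c"), 300, replace = TRUE)
  dv <- fit_module_glm(score, fac)
  gm <- tapply(score, fac, mean)
  expect_equal(unname(dv["dev_model"]), sum((score - gm[fac])^2),
               tolerance = 1e-10)
  expect_equal(unname(dv["dev_null"]), sum((score - mean(score))^2),
               tolerance = 1e-10)
  # score constant within levels -> zero model deviance
  s2 <- c(a = 1, b = 2, c = 3)[fac]
  expect_equal(unname(fit_module_glm(s2, fac)["dev_model"]), 0)
  # identical group means -> model deviance equals null deviance
  s3 <- rep(c(-1, 1), 150)
  f3 <- rep(c("x", "y"), each = 150)
  dv3 <- fit_module_glm(s3, f3)
  expect_equal(unname(dv3["dev_model"]), unname(dv3["dev_null"]))
  expect_error(fit_module_glm(score, rep("a", 300)), "2 levels")
})

test_that("deviance ratio equals R-squared and is affine invariant", {
  set.seed(52)
  for (i in 1:20) {
    score <- rnorm(100)
    fac <- factor(sample(3, 100, replace = TRUE))
    dv <- fit_module_glm(score, fac)
    dd <- delta_deviance(dv["dev_null"], dv["dev_model"])
    r2 <- summary(lm(score ~ fac))$r.squared
    expect_equal(unname(dd), r2, tolerance = 1e-12)
    expect_gte(dd, 0); expect_lte(dd, 1)
    dv2 <- fit_module_glm(5 * score + 3, fac)
    expect_equal(unname(delta_deviance(dv2["dev_null"], dv2["dev_model"])),
                 unname(dd), tolerance = 1e-10)
  }
  expect_equal(delta_deviance(10, 0), 1)
  expect_equal(delta_deviance(10, 10), 0)
  expect_warning(dd0 <- delta_deviance(0, 0), "constant")
  expect_equal(dd0, 0)
})

test_that("refining a factor never decreases the deviance ratio", {
  set.seed(53)
  score <- rnorm(200)
  coarse <- rep(c("a", "b"), each = 100)
  fine <- paste0(coarse, rep(c("1", "2"), 100))
  dc <- fit_module_glm(score, coarse)
  df_ <- fit_module_glm(score, fine)
  expect_gte(delta_deviance(df_["dev_null"], df_["dev_model"]),
             delta_deviance(dc["dev_null"], dc["dev_model"]) - 1e-12)
})

test_that("prioritization ranks an indicator module first and flags housekeeping", {
  set.seed(54)
  n <- 300
  tissue <- sample(c("colon", "lung", "blood"), n, replace = TRUE)
  rand_fac <- sample(c("u", "v"), n, replace = TRUE)
  scores <- rbind(module_1 = as.numeric(tissue == "colon"),
                  module_2 = runif(n),
                  module_3 = runif(n))
  meta <- data.frame(tissue = tissue, rand = rand_fac)
  pr <- prioritize_modules(scores, meta)
  tis <- pr[pr$factor == "tissue", ]
  expect_equal(tis$module_id[tis$rank == 1], "module_1")
  expect_equal(tis$delta_dev[tis$module_id == "module_1"], 1)
  expect_lt(pr$delta_dev[pr$factor == "rand" & pr$module_id == "module_1"], 0.05)
  # constant scores give ratio 0
  sc0 <- rbind(module_1 = rep(0.5, n), module_2 = runif(n))
  pr0 <- prioritize_modules(sc0, meta)
  expect_equal(pr0$delta_dev[pr0$module_id == "module_1"], c(0, 0))
  # housekeeping-flagged modules keep records but lose their rank
  prh <- prioritize_modules(scores, meta, housekeeping = c(TRUE, FALSE, FALSE))
  tish <- prh[prh$factor == "tissue", ]
  expect_true(is.na(tish$rank[tish$module_id == "module_1"]))
  expect_equal(sort(tish$rank[!is.na(tish$rank)]), 1:2)
  expect_error(prioritize_modules(scores, meta[1:10, ]), "cover")
})

test_that("housekeeping flag fires above half ribosomal/mitochondrial content", {
  ann <- data.frame(gene_id = paste0("g", 1:6),
                    is_mito = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                    is_ribo = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  ass <- stats::setNames(c(1, 1, 1, 2, 2, 2), paste0("g", 1:6))
  expect_identical(flag_housekeeping_modules(ass, ann), c(TRUE, FALSE))
})

test_that("planted tissue-driven module ranks first among detected modules", {
  pms <- make_planted_modules(10, 30, effect = 2.0)
  pms[[2]]$factor <- "donor"; pms[[2]]$level <- "donor_1"
  pms[[3]]$factor <- "donor"; pms[[3]]$level <- "donor_2"
  cfg <- synthetic_config(n_cells = 500, n_genes = 600,
                          planted_modules = pms, seed = 60)
  ds <- generate_expression(cfg)
  norm <- lognormalize(ds$counts)
  norm <- norm[apply(norm, 1, stats::sd) > 0, ]
  ct <- cut_modules(topological_overlap(correlation_adjacency(norm)), 100)
  sc <- module_scores(norm, ct)
  pr <- prioritize_modules(sc, ds$metadata[, c("tissue", "subset", "donor")])
  planted <- paste0("gene_", pms[[1]]$genes)
  best <- paste0("module_",
                 names(which.max(tapply(names(ct) %in% planted, ct, sum))))
  tis <- pr[pr$factor == "tissue", ]
  expect_equal(tis$module_id[tis$rank == 1], best)
})
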