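test_that("adjacency is the unsigned correlation with no power transform", {
  set.seed(21)
  x <- rnorm(100)
  expr <- rbind(g1 = x, g2 = x, g3 = -x + rnorm(100, 0, 1e-8),
                g4 = rnorm(100))
  a <- correlation_adjacency(expr)
  expect_equal(a["g1", "g2"], 1)
  expect_equal(a["g1", "g3"], 1, tolerance = 1e-6)   # unsigned
  expect_equal(unname(diag(a)), rep(1, 4))
  expect_true(all(a >= 0 & a <= 1))
  # independent genes at large n have small adjacency
  big <- matrix(rnorm(2 * 10000), 2, 10000)
  expect_lt(correlation_adjacency(big)[1, 2], 0.05)
  expr_const <- rbind(g1 = x, g_const = rep(1, 100))
  expect_error(correlation_adjacency(expr_const), "g_const")
  # signed variant maps r = -1 to 0
  expect_lt(correlation_adjacency(expr, signed = TRUE)["g1", "g3"], 1e-6)
})

test_that("topological overlap matches closed forms and the brute-force oracle", {
  # all off-diagonal zero -> TOM off-diagonal zero
  expect_equal(topological_overlap(diag(4)), diag(4))
  # 4-clique of perfect adjacency -> TOM exactly 1
  clique <- matrix(1, 4, 4)
  expect_equal(topological_overlap(clique), matrix(1, 4, 4))
  # hand-evaluated 3-gene case
  a <- diag(3); a[1, 2] <- a[2, 1] <- 0.5; a[1, 3] <- a[3, 1] <- 0.5
  tom <- topological_overlap(a)
  expect_equal(tom[1, 2], 0.5, tolerance = 1e-12)
  # random adjacencies: matrix implementation equals the triple loop
  for (s in 1:5) {
    adj <- random_adjacency(30, seed = 100 + s)
    expect_lt(max(abs(topological_overlap(adj) - tom_brute_force(adj))), 1e-10)
  }
})

test_that("tom respects its component lower bound and l_ij monotonicity", {
  adj <- random_adjacency(25, seed = 31)
  tom <- topological_overlap(adj)
  k <- rowSums(adj) - 1
  bound <- adj / (outer(k, k, pmin) + 1 - adj)
  off <- upper.tri(adj)
  expect_true(all(tom[off] >= bound[off] - 1e-12))
  # raising a_uv for u,v outside {i,j} never decreases TOM_ij numerator l_ij
  adj2 <- adj
  adj2[5, 6] <- adj2[6, 5] <- min(1, adj[5, 6] + 0.3)
  l <- function(a, i, j) sum(a[i, -c(i, j)] * a[-c(i, j), j])
  expect_gte(l(adj2, 1, 2), l(adj, 1, 2))
})

test_that("ward.D2 merge heights match the Lance-Williams oracle", {
  for (s in 1:3) {
    adj <- random_adjacency(15, seed = 200 + s)
    tom <- topological_overlap(adj)
    d <- stats::as.dist(1 - tom)
    h <- stats::hclust(d, method = "ward.D2")
    expect_equal(h$height, ward_d2_heights(d), tolerance = 1e-8)
  }
})

test_that("module cutting recovers separable blocks and labels deterministically", {
  # two perfect blocks
  tom <- matrix(0, 20, 20); tom[1:10, 1:10] <- 1; tom[11:20, 11:20] <- 1
  dimnames(tom) <- list(paste0("g", 1:20), paste0("g", 1:20))
  ct <- cut_modules(tom, 2)
  expect_equal(length(unique(ct[1:10])), 1)
  expect_equal(length(unique(ct[11:20])), 1)
  expect_equal(sort(unique(ct)), 1:2)
  # n_modules = n_genes: singletons
  expect_equal(sort(unname(cut_modules(tom, 20))), 1:20)
  expect_error(cut_modules(tom, 21), "n_modules")
  # ids ordered by size then first gene index
  tom3 <- matrix(0, 5, 5); diag(tom3) <- 1
  tom3[1:2, 1:2] <- 1; tom3[3:5, 3:5] <- 1
  ct3 <- cut_modules(tom3, 2)
  expect_equal(unname(ct3), c(2, 2, 1, 1, 1))
})

test_that("module scores are min-max means in [0,1]", {
  expr <- rbind(g1 = c(0, 5, 10))
  expect_equal(unname(module_scores(expr, 1)[1, ]), c(0, 0.5, 1))
  expr2 <- rbind(gA = c(0, 10), gB = c(10, 0))
  expect_equal(unname(module_scores(expr2, c(1, 1))[1, ]), c(0.5, 0.5))
  exprc <- rbind(g1 = c(3, 3, 3), g2 = c(1, 1, 1))
  expect_equal(unname(module_scores(exprc, c(1, 1))[1, ]), c(0, 0, 0))
  expect_error(module_scores(expr2, c(1, 3)), "empty module")
})

test_that("module knn graph follows correlation ranking", {
  set.seed(41)
  base <- rnorm(50)
  s <- rbind(m1 = base + rnorm(50, 0, 0.3),
             m2 = base + rnorm(50, 0, 0.3),
             m3 = rnorm(50))
  r <- cor(t(s))
  g <- module_knn_graph(s, k = 1)
  # m1 and m2 pick each other; m3 picks its top correlate
  expect_true(any(g$from == "m1" & g$to == "m2"))
  top3 <- c("m1", "m2")[which.max(r[3, 1:2])]
  key <- paste(pmin(g$from, g$to), pmax(g$from, g$to))
  expect_true(paste(pmin("m3", top3), pmax("m3", top3)) %in% key)
  # complete graph when k = n - 1
  gc <- module_knn_graph(s, k = 2)
  expect_equal(nrow(gc), 3)
  # duplicate vectors are mutual nearest neighbors
  s2 <- rbind(a = base, b = base, c = rnorm(50), d = rnorm(50))
  g2 <- module_knn_graph(s2, k = 1)
  expect_true(any((g2$from == "a" & g2$to == "b")))
  # constant module excluded with a warning
  s3 <- rbind(s, m4 = rep(1, 50))
  expect_warning(g3 <- module_knn_graph(s3, k = 1), "constant")
  expect_false("m4" %in% c(g3$from, g3$to))
})

test_that("planted modules are recovered end-to-end with high ARI", {
  ds <- fixture_modules(seed = 42)
  norm <- lognormalize(ds$counts)
  planted <- names(which(!is.na(ds$truth$module_assignment)))
  truth <- ds$truth$module_assignment[planted]
  tom <- topological_overlap(correlation_adjacency(norm[planted, ]))
  ct <- cut_modules(tom, 10)
  expect_gte(ari(ct, truth), 0.8)
  # estimator robustness: spearman-based recovery is about as good
  tom_sp <- topological_overlap(
    correlation_adjacency(norm[planted, ], method = "spearman"))
  ct_sp <- cut_modules(tom_sp, 10)
  expect_lt(abs(ari(ct, truth) - ari(ct_sp, truth)), 0.1)
})
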