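# Shared desk-scale fixtures, generated in code (no files).

fixture_modules <- function(seed = 42, n_cells = 500, n_genes = 600,
                            n_modules = 10, module_size = 30, effect = 2.0) {
  cfg <- synthetic_config(
    n_cells = n_cells, n_genes = n_genes,
    planted_modules = make_planted_modules(n_modules, module_size,
                                           effect = effect),
    seed = seed)
  generate_expression(cfg)
}

fixture_small <- function(seed = 7) {
  cfg <- synthetic_config(n_cells = 120, n_genes = 150,
                          planted_modules = make_planted_modules(3, 15),
                          seed = seed)
  generate_expression(cfg)
}

random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}
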