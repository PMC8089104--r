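clone_row <- function(cell, chain, nt, count, aa = "CASSL") {
  data.frame(cell_id = cell, chain = chain, cdr3_nt = nt, cdr3_aa = aa,
             read_count = count, stringsAsFactors = FALSE)
}

test_that("count filter is strictly exclusive at the boundary", {
  recs <- rbind(clone_row("c1", "TRA", "AAA", 5),
                clone_row("c1", "TRA", "CCC", 6),
                clone_row("c2", "TRB", "GGG", 100))
  out <- filter_clones(recs)
  expect_setequal(out$cdr3_nt, c("CCC", "GGG"))
  expect_equal(nrow(filter_clones(recs[0, ])), 0)
})

test_that("dominant clone selection keeps the top count with lexicographic ties", {
  recs <- rbind(clone_row("c1", "TRB", "TTT", 10),
                clone_row("c1", "TRB", "AAA", 7),
                clone_row("c2", "TRA", "CGT", 8),
                clone_row("c2", "TRA", "ACG", 8),   # tie: smaller cdr3 wins
                clone_row("c3", "TRG", "GGG", 9))
  dom <- dominant_clone_per_chain(recs)
  expect_equal(dom$cdr3_nt[dom$cell_id == "c1"], "TTT")
  expect_equal(dom$cdr3_nt[dom$cell_id == "c2"], "ACG")
  expect_equal(nrow(dom), 3)
  # permuting input rows never changes the result
  set.seed(61)
  dom2 <- dominant_clone_per_chain(recs[sample(nrow(recs)), ])
  expect_identical(dom, dom2)
  expect_error(dominant_clone_per_chain(clone_row("c1", "TRX", "AAA", 9)),
               "chain")
})

test_that("all 16 chain subsets map onto the four categories without gaps", {
  chains <- c("TRA", "TRB", "TRG", "TRD")
  expected_cat <- function(s) {
    ab <- any(s %in% c("TRA", "TRB")); gd <- any(s %in% c("TRG", "TRD"))
    if (ab && gd) "TRA_B_G_D" else if (ab) "TRA_B" else if (gd) "TRG_D" else "none"
  }
  for (mask in 0:15) {
    s <- chains[bitwAnd(mask, 2^(0:3)) > 0]
    dom <- if (length(s)) do.call(rbind, lapply(s, function(ch)
      clone_row("c1", ch, "AAA", 10))) else
        clone_row("x", "TRA", "AAA", 10)[0, ]
    call <- classify_rearrangement(dom, cell_ids = "c1")
    expect_equal(call$category, expected_cat(s))
    expect_true(call$category %in% c("none", "TRA_B", "TRG_D", "TRA_B_G_D"))
  }
})

test_that("synthetic cohort categories are recovered exactly", {
  out <- generate_clone_table(1000, seed = 62)
  dom <- dominant_clone_per_chain(filter_clones(out$clones))
  calls <- classify_rearrangement(dom, cell_ids = paste0("cell_", 1:1000))
  expect_equal(mean(calls$category ==
                      out$truth$category[calls$cell_id]), 1)
})

test_that("clone frequencies count cells per dominant CDR3 within groups", {
  dom <- rbind(clone_row("c1", "TRB", "AAA", 10), clone_row("c2", "TRB", "AAA", 9),
               clone_row("c3", "TRB", "AAA", 8), clone_row("c4", "TRB", "CCC", 7),
               clone_row("c5", "TRA", "GGG", 12))
  groups <- stats::setNames(c("ilc", "ilc", "ilc", "ilc", "t"), paste0("c", 1:5))
  tab <- clone_frequency_table(dom, groups)
  expect_equal(tab$n_cells[tab$clone == "AAA"], 3)
  expect_true(tab$expanded[tab$clone == "AAA"])
  expect_equal(tab$n_cells[tab$clone == "CCC"], 1)
  # counts per (group, chain) sum to the number of rearranged cells
  expect_equal(sum(tab$n_cells[tab$group == "ilc" & tab$chain == "TRB"]), 4)
  expect_error(clone_frequency_table(dom, groups[1:3]), "missing")
  # planted sharing is reproduced exactly
  gen <- generate_clone_table(400, shared_clone_spec = data.frame(
    chain = "TRB", size = 4), seed = 63)
  dg <- dominant_clone_per_chain(filter_clones(gen$clones))
  g2 <- stats::setNames(rep("all", 400), paste0("cell_", 1:400))
  t2 <- clone_frequency_table(dg, g2)
  sh <- gen$truth$shared_clones[[1]]
  expect_equal(t2$n_cells[t2$clone == sh$cdr3_nt], 4)
})

test_that("clonal overlap reports exactly the clones present in both groups", {
  dom <- rbind(clone_row("a1", "TRB", "AAA", 10), clone_row("a2", "TRG", "TTT", 9),
               clone_row("b1", "TRB", "AAA", 8), clone_row("b2", "TRB", "CCC", 7),
               clone_row("b3", "TRG", "TTT", 11))
  ov <- clonal_overlap(c("a1", "a2"), c("b1", "b2", "b3"), dom)
  expect_equal(nrow(ov), 2)
  expect_setequal(ov$clone, c("AAA", "TTT"))
  # disjoint groups share nothing
  expect_equal(nrow(clonal_overlap("a1", "b2", dom)), 0)
  # same clone sequence on a different chain does not count
  dom2 <- rbind(clone_row("a1", "TRB", "AAA", 10), clone_row("b1", "TRA", "AAA", 8))
  expect_equal(nrow(clonal_overlap("a1", "b1", dom2)), 0)
})
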