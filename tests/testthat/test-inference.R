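test_that("fraction filter: boundary passes, absent genes never retained", {
  # type A: 4 cells, G1 expressed in 1/4 (25%), G2 in 2/4;
  # type B: 5 cells, G1 expressed in 1/5 (20%)
  expr <- rbind(G1 = c(1, 0, 0, 0, 1, 0, 0, 0, 0),
                G2 = c(1, 1, 0, 0, 0, 0, 0, 0, 0),
                G3 = rep(0, 9))
  colnames(expr) <- paste0("c", 1:9)
  prof <- profile_cell_types(expr, setNames(rep(c("A", "B"), c(4, 5)),
                                            colnames(expr)))
  # the boundary passes: exactly N% stays, fewer than N% is removed
  expect_identical(apply_fraction_filter(prof, c("G1", "G2"), "A", 25),
                   c("G1", "G2"))
  expect_identical(apply_fraction_filter(prof, c("G1", "G2"), "B", 25),
                   character(0))
  expect_identical(apply_fraction_filter(prof, c("G1", "G2"), "A", 26), "G2")
  # N = 0 retains every present gene, even at fraction 0, but never absent ones
  expect_identical(apply_fraction_filter(prof, c("G1", "G3", "NOPE"), "A", 0),
                   c("G1", "G3"))
})

test_that("score_pass reproduces the hand-chained equation example", {
  d <- tiny_dataset()
  prof <- profile_cell_types(d$expr, d$meta)
  cfg <- analysis_config(min_frac_pct = 0, normalization = "none", n_perm = 9)
  tab <- score_pass(prof, tiny_kb(), cfg)
  row <- tab[tab$sender == "S" & tab$receiver == "R", ]
  expect_identical(nrow(row), 1L)
  # frozen from scalar evaluation: E = gm(2,8) - gm(1) = 3; T = 4; M = 5;
  # R = gm(2,32) = 8; MR = sqrt(25 + 64)
  expect_equal(row$E, 3, tolerance = 1e-12)
  expect_equal(row$T, 4, tolerance = 1e-12)
  expect_equal(row$M, 5, tolerance = 1e-12)
  expect_equal(row$R, 8, tolerance = 1e-12)
  expect_equal(row$MR, sqrt(89), tolerance = 1e-12)
})

test_that("receptor subunits failing the receiver filter drop the triple", {
  d <- tiny_dataset()
  d$expr["RB", "r1"] <- 0  # RB silent in the receiver
  prof <- profile_cell_types(d$expr, d$meta)
  cfg <- analysis_config(min_frac_pct = 10, normalization = "none")
  tab <- score_pass(prof, tiny_kb(), cfg)
  expect_false(any(tab$sender == "S" & tab$receiver == "R"))
})

test_that("sender with no passing machinery gives M = 0, MR = R", {
  d <- tiny_dataset()
  d$expr[c("P1", "P2", "C1", "TX1"), "s1"] <- 0
  prof <- profile_cell_types(d$expr, d$meta)
  tab <- score_pass(prof, tiny_kb(),
                    analysis_config(min_frac_pct = 10, normalization = "none"))
  row <- tab[tab$sender == "S" & tab$receiver == "R", ]
  expect_equal(row$M, 0)
  expect_equal(row$MR, row$R)
})

test_that("untestable triples (MR = 0) get p = q = 1 and stay in the table", {
  d <- tiny_dataset()
  # kill everything feeding the S -> R triple, keep genes present at N = 0
  d$expr[c("P1", "P2", "C1", "TX1"), "s1"] <- 0
  d$expr[c("RA", "RB"), "r1"] <- 0
  cfg <- analysis_config(min_frac_pct = 0, normalization = "none",
                         n_perm = 19, seed = 1)
  res <- run_analysis(d$expr, d$meta, tiny_kb(), cfg)
  row <- res[res$sender == "S" & res$receiver == "R", ]
  expect_identical(nrow(row), 1L)
  expect_false(row$testable)
  expect_equal(row$MR, 0)
  expect_equal(row$p_value, 1)
  expect_equal(row$q_value, 1)
})

test_that("permutation p-values use the add-one rule and respect their bounds", {
  kb <- make_toy_kb(2, seed = 3)
  truth <- planted_truth("T1", "T2", kb$interactions$metabolite_id[1],
                         effect_size = 30)
  d <- generate_planted_dataset(kb, truth, cells_per_type = 30, seed = 3)
  cfg <- analysis_config(n_perm = 99, seed = 3)
  res <- run_analysis(d$expr, d$meta, kb, cfg)
  expect_true(all(res$p_value >= 1 / 100 - 1e-12))
  expect_true(all(res$p_value <= 1))
  top <- res[1, ]
  # a 30x planted effect dominates every permutation: p = 1/(n_perm + 1)
  expect_identical(c(top$sender, top$receiver, top$metabolite_id),
                   c("T1", "T2", truth$metabolite_id))
  expect_equal(top$p_value, 0.01)
})

test_that("adjust_bh matches the closed form and the step-up definition", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.04), 0.04)
  expect_equal(adjust_bh(rep(1, 4)), rep(1, 4))
  expect_error(adjust_bh(c(0.5, 0)), "p-values")
  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))
    expect_equal(adjust_bh(p), bh_direct(p), tolerance = 1e-12)
  }
})

test_that("pipeline MR values equal the naive scalar reference", {
  set.seed(21)
  for (i in 1:3) {
    kb <- make_toy_kb(sample(2:4, 1), complex_fraction = 0.5, seed = 100 + i)
    d <- generate_null_dataset(kb, n_types = 3, cells_per_type = 15,
                               seed = 200 + i)
    prof <- profile_cell_types(d$expr, d$meta)
    cfg <- analysis_config(min_frac_pct = 10, normalization = "none")
    got <- score_pass(prof, kb, cfg)
    want <- naive_reference(d$expr, d$meta, kb, min_frac_pct = 10)
    key <- function(t) paste(t$sender, t$receiver, t$metabolite_id, t$receptor)
    expect_setequal(key(got), key(want))
    m <- match(key(want), key(got))
    for (col in c("E", "T", "M", "R", "MR"))
      expect_equal(got[[col]][m], want[[col]], tolerance = 1e-9,
                   ignore_attr = TRUE)
  }
})

test_that("run_analysis is deterministic and validates its inputs", {
  kb <- make_toy_kb(3, seed = 5)
  d <- generate_null_dataset(kb, cells_per_type = 12, seed = 5)
  cfg <- analysis_config(n_perm = 19, seed = 42)
  r1 <- run_analysis(d$expr, d$meta, kb, cfg)
  r2 <- run_analysis(d$expr, d$meta, kb, cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))

  # single cell type is not a communication analysis
  expect_error(run_analysis(d$expr, setNames(rep("T1", length(d$meta)),
                                             names(d$meta)), kb, cfg),
               "at least 2")

  # disjoint gene universes point at a species mismatch
  bad <- d$expr
  rownames(bad) <- paste0("x", rownames(bad))
  expect_error(run_analysis(bad, d$meta, kb, cfg), "no overlap")
})
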