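test_that("invariant columns get rate zero without optimisation", {
  tr <- validate_tree(ape::read.tree(text = "((A:0.5,B:0.5):0.5,(C:0.5,D:0.5):0.5);"))
  est <- estimate_site_rate(c(A = "T", B = "T", C = "T", D = "T"), tr)
  expect_equal(est$rate, 0)
  expect_equal(est$status, "INVARIANT_ZERO")
})

test_that("a two-taxon mismatched column clamps at the search bound", {
  # the mismatch likelihood 1/4 - 1/4 exp(-8*lambda*t/3) increases in lambda,
  # so the MLE sits on the boundary
  tr <- validate_tree(ape::read.tree(text = "(A:0.5,B:0.5);"))
  est <- estimate_site_rate(c(A = "A", B = "C"), tr, lambda_max = 20)
  expect_equal(est$status, "CLAMPED_MAX")
  expect_equal(est$rate, 20)
})

test_that("columns with fewer than two observed states are faulty", {
  tr <- validate_tree(ape::read.tree(text = "((A:0.5,B:0.5):0.5,(C:0.5,D:0.5):0.5);"))
  est <- estimate_site_rate(c(A = "A", B = "-", C = "?", D = "N"), tr)
  expect_equal(est$status, "FAULTY")
  expect_true(is.na(est$rate))
})

test_that("the toy locus summary counts rated and faulty sites", {
  tr <- validate_tree(ape::read.tree(text = "((A:0.5,B:0.5):0.5,(C:0.5,D:0.5):0.5);"))
  aln <- alignment(c(A = "AA-A", B = "AC-A", C = "AA-A", D = "AA-A"))
  est <- estimate_rates(aln, tr)
  g <- glance(est)
  expect_equal(g$n_rates, 3)
  expect_equal(g$n_faulty, 1)
  expect_equal(g$length, g$n_rates + g$n_faulty)
  expect_equal(est$rate[1], 0)
  expect_equal(est$status[2], "OK")
  expect_gt(est$rate[2], 0)
})

test_that("column caching does not change results", {
  tr <- sim_ultrametric_tree(8, depth = 1, seed = 31)
  sim <- simulate_locus(tr, 200, rates = list(shape = 1, mean = 0.8), seed = 32)
  on_ <- estimate_rates(sim$alignment, tr, cache = TRUE)
  off <- estimate_rates(sim$alignment, tr, cache = FALSE)
  expect_identical(on_$rate, off$rate)
  expect_identical(on_$status, off$status)
  expect_identical(on_$loglik, off$loglik)
})

test_that("the optimum beats a dense grid of alternatives", {
  tr <- sim_ultrametric_tree(6, depth = 1, seed = 41)
  sim <- simulate_locus(tr, 30, rates = 1, seed = 42)
  est <- estimate_rates(sim$alignment, tr)
  lambda_max <- 20
  tp <- phylopi:::tip_partials(sim$alignment, tr, substitution_model("JC69"))
  grid <- seq(0, lambda_max, length.out = 64)
  ll_grid <- vapply(grid, function(l) phylopi:::pruning_loglik(tp,
    substitution_model("JC69"), l), numeric(30))
  best_grid <- apply(ll_grid, 1, max)
  ok <- est$status %in% c("OK", "CLAMPED_MAX", "INVARIANT_ZERO")
  expect_true(all(est$loglik[ok] >= best_grid[ok] - 1e-6))
})

test_that("rescaling the tree rescales every estimate by the inverse factor", {
  tr <- sim_ultrametric_tree(8, depth = 1, seed = 51)
  sim <- simulate_locus(tr, 150, rates = list(shape = 0.7, mean = 1), seed = 52)
  base <- estimate_rates(sim$alignment, tr)
  for (c_ in c(0.1, 10)) {
    trc <- tr
    trc$edge.length <- trc$edge.length * c_
    trc <- validate_tree(trc)
    scaled <- estimate_rates(sim$alignment, trc)
    pos <- which(base$rate > 0 & !is.na(base$rate))
    expect_equal(scaled$rate[pos] * c_, base$rate[pos], tolerance = 1e-4)
    expect_identical(scaled$status, base$status)
  }
})

test_that("simulated rate heterogeneity is recovered in rank order", {
  tr <- sim_ultrametric_tree(16, depth = 1, seed = 61)
  rec <- recovery_experiment(tr, 400, rates = list(shape = 0.5, mean = 1),
                             seed = 62)
  expect_gt(rec$rank_correlation, 0.8)
  expect_equal(rec$n_estimated + rec$n_faulty, 400)
})

test_that("estimate dispersion shrinks with denser taxon sampling", {
  s8 <- recovery_experiment(sim_ultrametric_tree(8, depth = 1, seed = 1),
                            300, rates = 0.5, seed = 2)
  s32 <- recovery_experiment(sim_ultrametric_tree(32, depth = 1, seed = 1),
                             300, rates = 0.5, seed = 2)
  iqr8 <- stats::IQR(attr(s8, "sites")$estimated, na.rm = TRUE)
  iqr32 <- stats::IQR(attr(s32, "sites")$estimated, na.rm = TRUE)
  expect_lt(iqr32, iqr8)
})

test_that("an all-invariant locus reports correlation as NA", {
  tr <- sim_ultrametric_tree(8, depth = 1, seed = 71)
  rec <- recovery_experiment(tr, 50, rates = 0, seed = 72)
  expect_true(is.na(rec$rank_correlation))
  expect_equal(attr(rec, "sites")$estimated, rep(0, 50))
})

test_that("protein columns estimate under the 20-state Poisson model", {
  tr <- sim_ultrametric_tree(8, depth = 1, seed = 81)
  sim <- simulate_locus(tr, 60, rates = 1,
                        model = substitution_model("POISSON20"), seed = 82)
  expect_equal(sim$alignment$alphabet, "PROTEIN")
  est <- estimate_rates(sim$alignment, tr)
  expect_equal(unique(est$model), "POISSON20")
  expect_true(all(est$status %in%
    c("OK", "INVARIANT_ZERO", "CLAMPED_MAX", "FAULTY")))
  expect_gt(sum(est$status == "OK"), 0)
})
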