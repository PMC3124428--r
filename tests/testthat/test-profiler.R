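test_that("identical rate vectors produce identical curves", {
  rates <- dplyr::bind_rows(
    tibble::tibble(locus = "L1", site = 1:10, rate = seq(0.1, 1, 0.1),
                   status = "OK", loglik = NA_real_, model = "JC69"),
    tibble::tibble(locus = "L2", site = 1:10, rate = seq(0.1, 1, 0.1),
                   status = "OK", loglik = NA_real_, model = "JC69"))
  prof <- pi_profile(rates, depth = 2, n_grid = 50)
  expect_identical(prof$net[prof$locus == "L1"], prof$net[prof$locus == "L2"])
})

test_that("partition pseudo-locus nets sum to the whole-locus net", {
  tr <- sim_ultrametric_tree(8, depth = 1, seed = 91)
  sim <- simulate_locus(tr, 60, rates = list(shape = 1, mean = 1), seed = 92)
  aln <- sim$alignment
  set.seed(93)
  idx <- sort(sample(60, 25))
  aln$partitions <- list(p1 = idx, p2 = setdiff(1:60, idx))
  grid <- seq(0, 1, length.out = 20)
  parts <- profile_loci(aln, tr, grid = grid)
  whole <- profile_loci(sim$alignment, tr, grid = grid)
  net_sum <- parts$net[parts$locus == "p1"] + parts$net[parts$locus == "p2"]
  expect_equal(net_sum, whole$net, tolerance = 1e-10)
})

test_that("a single unit-rate site reproduces the informativeness curve", {
  rates <- tibble::tibble(locus = "one", site = 1L, rate = 1,
                          status = "OK", loglik = NA_real_, model = "JC69")
  grid <- seq(0, 2, length.out = 401)
  prof <- pi_profile(rates, depth = 2, grid = grid)
  expect_equal(prof$per_site, informativeness(grid, 1), tolerance = 1e-12)
  expect_equal(grid[which.max(prof$per_site)], 0.25, tolerance = 0.01)
})

test_that("deep epochs favor slow loci and shallow epochs fast loci", {
  rates <- fast_slow_rates()
  deep <- rank_loci(rates, epoch = c(2, 3))
  expect_equal(deep$locus[1], "slow")
  expect_equal(deep$integral_persite[deep$locus == "slow"], 0.1461649,
               tolerance = 1e-6)
  expect_equal(deep$integral_persite[deep$locus == "fast"], 1.912154e-06,
               tolerance = 1e-5)
  shallow <- rank_loci(rates, epoch = c(0, 0.2))
  expect_equal(shallow$locus[1], "fast")
})

test_that("epochs outside the tree depth are rejected", {
  rates <- fast_slow_rates()
  expect_error(rank_loci(rates, epoch = c(2, 4)), "allowed range")
  expect_error(rank_loci(rates, epoch = c(-1, 2)), "t_start")
  expect_error(rank_loci(rates, epoch = c(2, 2)), "t_start < t_end")
})

test_that("exact ties share the smaller rank and are flagged", {
  rates <- dplyr::bind_rows(
    tibble::tibble(locus = "a", site = 1:5, rate = 0.5, status = "OK",
                   loglik = NA_real_, model = "JC69"),
    tibble::tibble(locus = "b", site = 1:5, rate = 0.5, status = "OK",
                   loglik = NA_real_, model = "JC69"),
    tibble::tibble(locus = "c", site = 1:5, rate = 0.1, status = "OK",
                   loglik = NA_real_, model = "JC69"))
  rk <- rank_loci(rates, epoch = c(0.1, 0.6), depth = 1)
  expect_equal(rk$rank, c(1L, 1L, 3L))
  expect_equal(rk$locus, c("a", "b", "c"))   # ties ordered by label
  expect_equal(rk$tie, c(TRUE, TRUE, FALSE))
})

test_that("per-site ranking is invariant to duplicating every column", {
  base <- tibble::tibble(locus = "L", site = 1:20,
                         rate = rep(seq(0.2, 1, length.out = 10), 2),
                         status = "OK", loglik = NA_real_, model = "JC69")
  doubled <- dplyr::bind_rows(base, dplyr::mutate(base, site = site + 20))
  r1 <- rank_loci(base, epoch = c(0.1, 0.5), depth = 1)
  r2 <- rank_loci(doubled, epoch = c(0.1, 0.5), depth = 1)
  expect_equal(r2$integral_net, 2 * r1$integral_net, tolerance = 1e-12)
  expect_equal(r2$integral_persite, r1$integral_persite, tolerance = 1e-12)
})

test_that("multi-epoch reports are independent per epoch and additive", {
  rates <- fast_slow_rates()
  rep_ <- multi_epoch_ranking(rates, list(c(0, 1), c(1, 2), c(2, 3)))
  expect_length(rep_$rankings, 3)
  expect_named(rep_$rankings, c("0-1", "1-2", "2-3"))
  # piecewise integrals sum to the full-window integral
  full <- rank_loci(rates, epoch = c(0, 3))
  pieces <- purrr::map(rep_$rankings, function(r)
    r$integral_net[order(r$locus)])
  summed <- Reduce(`+`, pieces)
  expect_equal(summed, full$integral_net[order(full$locus)], tolerance = 1e-12)
  # duplicate epochs give identical rankings
  dup <- multi_epoch_ranking(rates, list(c(0, 1), c(0, 1)))
  expect_identical(dup$rankings[[1]]$rank, dup$rankings[[2]]$rank)
  expect_error(multi_epoch_ranking(rates, list()), "at least one epoch")
})

test_that("a crossing pair flips order between shallow and deep epochs", {
  rates <- fast_slow_rates()
  rep_ <- multi_epoch_ranking(rates, list(c(0, 1), c(1, 2)))
  r1 <- rep_$rankings[["0-1"]]
  r2 <- rep_$rankings[["1-2"]]
  expect_equal(r1$locus[1], "fast")
  expect_equal(r2$locus[1], "slow")
})

test_that("the direct-rates path profiles without an alignment", {
  rates <- fast_slow_rates()
  prof <- profile_loci(rates, n_grid = 30)
  expect_s3_class(prof, "pi_profile")
  expect_setequal(unique(prof$locus), c("fast", "slow"))
})

test_that("end-to-end rankings are invariant to time rescaling", {
  tr <- sim_ultrametric_tree(8, depth = 1, seed = 111)
  sim <- simulate_locus(tr, 80, rates = list(shape = 0.6, mean = 1), seed = 112)
  sim2 <- simulate_locus(tr, 80, rates = list(shape = 2, mean = 0.3), seed = 113)
  a1 <- sim$alignment; a1$locus <- "locA"
  a2 <- sim2$alignment; a2$locus <- "locB"
  r_base <- rank_loci(estimate_rates(list(a1, a2), tr), epoch = c(0.2, 0.6))
  for (c_ in c(0.1, 10)) {
    trc <- tr; trc$edge.length <- trc$edge.length * c_
    trc <- validate_tree(trc)
    r_scaled <- rank_loci(estimate_rates(list(a1, a2), trc),
                          epoch = c(0.2, 0.6) * c_)
    expect_identical(r_scaled$locus, r_base$locus)
    expect_identical(r_scaled$rank, r_base$rank)
    expect_equal(r_scaled$integral_persite, r_base$integral_persite,
                 tolerance = 1e-3)
  }
})
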