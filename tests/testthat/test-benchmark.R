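# Benchmark definitions: rates, bounds, ranks, similarity, evolution.

test_that("type I error divides significant by returned p-values", {
  p <- c(rep(0.01, 520), runif(9380, 0.06, 1), rep(NA, 100))
  tab <- matrix(p, ncol = 1, dimnames = list(NULL, "t"))
  expect_equal(unname(type_i_error(tab, 0.05)), 520 / 9900)
  expect_true(is.na(type_i_error(matrix(NA_real_, 5, 1), 0.05)))
  expect_equal(unname(type_i_error(matrix(0.9, 10, 1), 0.05)), 0)
})

test_that("reliability is the returned fraction of replicates", {
  tab <- matrix(c(rep(0.5, 99), NA), ncol = 1)
  expect_equal(unname(reliability(tab)), 0.99)
  expect_equal(unname(reliability(matrix(0.2, 7, 1))), 1)
  expect_equal(unname(reliability(matrix(NA_real_, 7, 1))), 0)
})

test_that("empirical power uses all replicates as denominator", {
  p <- c(rep(0.001, 400), rep(0.5, 500), rep(NA, 100))
  tab <- matrix(p, ncol = 1)
  expect_equal(unname(empirical_power(tab, 0.05)), 0.4)
  expect_equal(unname(empirical_power(matrix(NA_real_, 10, 1), 0.05)), 0)
  # power can never exceed reliability
  set.seed(44)
  P <- matrix(runif(600), 200, 3)
  P[sample(600, 80)] <- NA
  expect_true(all(empirical_power(P, 0.05) <= reliability(P)))
})

test_that("Wilson bounds straddle alpha and match an independent oracle", {
  for (a in c(0.05, 0.01, 0.001)) {
    for (n in c(1000, 10000)) {
      b <- wilson_bounds(a, n)
      expect_lt(b$lower, a); expect_gt(b$upper, a)
      ci <- oracle_wilson(a, n)
      expect_equal(b$lower, ci[1], tolerance = 1e-10)
      expect_equal(b$upper, ci[2], tolerance = 1e-10)
    }
    # interval width shrinks with the replicate count
    w1 <- with(wilson_bounds(a, 1000), upper - lower)
    w2 <- with(wilson_bounds(a, 10000), upper - lower)
    expect_lt(w2, w1)
  }
})

test_that("classification against the bounds uses strict exceedance", {
  b <- wilson_bounds(0.05, 10000)
  expect_identical(classify_type_i(0.055, b), "inflated")
  expect_identical(classify_type_i(0.050, b), "good")
  expect_identical(classify_type_i(0.040, b), "conservative")
  expect_true(is.na(classify_type_i(NA_real_, b)))
  expect_identical(classify_type_i(c(0.055, 0.05), b),
                   c("inflated", "good"))
})

test_that("power ranking shares the minimum rank on ties", {
  pm <- rbind(c(0.9, 0.5, 0.5))
  colnames(pm) <- c("a", "b", "c")
  r <- rank_by_power(pm)
  expect_equal(unname(r$ranks[1, ]), c(1, 2, 2))
  expect_equal(rank_by_power(matrix(0.4, 3, 1))$summary$average_rank, 1)
  # ranks follow ids under column permutation
  pm2 <- pm[, c("c", "a", "b"), drop = FALSE]
  r2 <- rank_by_power(pm2)
  expect_equal(r2$ranks[1, "a"], r$ranks[1, "a"])
})

test_that("uniqueness counts lone significant tests, per brute force", {
  P <- rbind(c(0.01, 0.5, 0.5),
             c(0.01, 0.01, 0.5),
             c(0.5,  0.5,  0.5),
             c(NA,   0.02, 0.9),
             c(0.03, NA,   NA),
             c(0.5,  0.5,  0.001))
  colnames(P) <- c("x", "y", "z")
  u <- uniqueness_score(P, 0.05)
  expect_equal(unname(u), c(2L, 1L, 1L))
  expect_equal(u, oracle_uniqueness(list(P), colnames(P), 0.05))
  # restricting the subset changes the competition
  u2 <- uniqueness_score(P, 0.05, subset = c("y", "z"))
  expect_equal(u2, oracle_uniqueness(list(P), c("y", "z"), 0.05))
})

test_that("decision similarity treats NA as a non-significant decision", {
  a <- c(0.01, 0.2, NA, 0.04)
  expect_equal(decision_similarity(a, a), 1)
  b <- c(0.5, 0.01, 0.01, 0.5)
  expect_equal(decision_similarity(a, b), 0)
  expect_equal(decision_similarity(c(NA, 0.5), c(0.9, NA)), 1)
})

test_that("redundancy requires exact equality of returned p-values", {
  a <- c(0.1, 0.2, NA, 0.3)
  expect_equal(redundancy_count(a, a), 3L)
  expect_equal(redundancy_count(a, a + 1e-12), 0L)
  expect_equal(redundancy_count(c(NA, NA), c(NA, NA)), 0L)
})

test_that("time evolution is (max-min)/min with an infinite sentinel", {
  expect_equal(max_evolution(c(2, 4)), 1)
  expect_equal(max_evolution(c(3, 3, 3)), 0)
  expect_identical(max_evolution(c(0, 5)), Inf)
})

test_that("scenario evolution sums consecutive changes", {
  v <- matrix(c(0.2, 0.5, 0.9), ncol = 1, dimnames = list(NULL, "t"))
  ev <- scenario_evolution(v)
  expect_equal(unname(ev$deltas[, 1]), c(0.3, 0.4))
  expect_equal(unname(ev$total), 0.7)
  expect_identical(unname(ev$direction), "increase")
  expect_equal(unname(scenario_evolution(v[3:1, , drop = FALSE])$total), -0.7)
  expect_identical(unname(scenario_evolution(matrix(0.4, 3, 1))$direction),
                   "no change")
})

test_that("the experiment runner is deterministic and shape-correct", {
  pool <- fixture_pool()
  reg <- default_registry(c("cast_chisq", "burden_score"))
  cfg <- experiment_config("t1", "null", cohort_size = 60, replicates = 5,
                           prevalence = 0.05)
  tab1 <- run_experiment(cfg, pool, reg, seed = 77)
  tab2 <- run_experiment(cfg, pool, reg, seed = 77)
  expect_identical(tab1$pvalues, tab2$pvalues)
  expect_identical(dim(tab1$pvalues), c(5L, 2L))
  expect_true(all(is.na(tab1$pvalues) |
                    (tab1$pvalues >= 0 & tab1$pvalues <= 1)))
  long <- results_to_long(tab1)
  expect_identical(nrow(long), 10L)
  expect_setequal(unique(long$test_id), c("cast_chisq", "burden_score"))
})

test_that("the preset grid matches the published scenario structure", {
  grid <- experiment_grid()
  expect_length(grid, 27L)
  modes <- vapply(grid, `[[`, "", "mode")
  expect_equal(sum(modes == "null"), 9L)
  expect_equal(sum(modes == "power"), 18L)
  # no duplicated parameter combinations
  keys <- vapply(grid, function(g)
    paste(g$mode, g$prop_cases, g$cohort_size, g$pct_protective,
          g$pct_causal, g$variant_mode, g$causal_maf_cutoff, g$region_size),
    "")
  expect_false(any(duplicated(keys)))
  # default replicate counts
  expect_equal(grid$t1$replicates, 10000L)
  expect_equal(grid$p11$replicates, 1000L)
})
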