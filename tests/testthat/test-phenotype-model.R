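# Case-control phenotype generation under the logistic model.

test_that("the intercept solver hits the target marginal prevalence", {
  expect_equal(solve_intercept(0.5, c(0, 0)), 0, tolerance = 1e-8)
  # Monte-Carlo oracle at the study's 1% prevalence
  b0 <- solve_intercept(0.01)
  set.seed(23)
  x1 <- rnorm(1e7); x2 <- rbinom(1e7, 1, 0.5)
  expect_lt(abs(mean(plogis(b0 + 0.5 * x1 + 0.5 * x2)) - 0.01), 2e-4)
  # monotone in prevalence
  expect_lt(solve_intercept(0.001), solve_intercept(0.01))
  expect_lt(solve_intercept(0.01), solve_intercept(0.1))
  expect_error(solve_intercept(0), "prevalence")
  # plain logit mode
  expect_equal(solve_intercept(0.01, mode = "logit"), qlogis(0.01))
})

test_that("effect sizes follow c|log10(MAF)|/2 and its consequences", {
  c20 <- log(5) / 4
  expect_equal(effect_size(0.01, c20), c20 * 2 / 2, tolerance = 1e-12)
  expect_equal(round(effect_size(0.01, c20), 4), 0.4024)
  expect_equal(effect_size(0.3, 0), 0)
  expect_equal(effect_size(1e-4, c20), 2 * effect_size(1e-2, c20))
  mafs <- c(0.001, 0.005, 0.01, 0.05, 0.3)
  expect_true(all(diff(effect_size(mafs, c20)) < 0))
  expect_error(effect_size(0, c20), "maf")
})

test_that("the scale constant shrinks with the causal percentage", {
  expect_equal(scale_constant(20), log(5) / 4)
  expect_equal(scale_constant(10), log(7) / 4)
  expect_equal(scale_constant(5), log(13) / 4)
  expect_equal(scale_constant(1), log(13) / 4)   # configurable default
  expect_equal(scale_constant(1, c_at_1pct = 0.8), 0.8)
  expect_error(scale_constant(15), "pct_causal")
})

test_that("causal assignment selects the right counts, signs and variants", {
  mafs <- c(0.005, 0.008, 0.2)
  set.seed(1)
  cm <- assign_causal_variants(mafs, 100, 0, 0.01, c = log(5) / 4)
  expect_identical(cm$causal_indices, 1:2)
  expect_true(all(cm$signs == 1))
  expect_equal(cm$betas, effect_size(mafs[1:2], log(5) / 4),
               ignore_attr = TRUE, tolerance = 1e-12)

  # m_c is deterministic; each eligible variant is hit at rate pct/100
  mafs50 <- runif(50, 1e-4, 0.009)
  hits <- integer(50)
  n_draw <- 2000
  set.seed(9)
  for (i in seq_len(n_draw)) {
    cm <- assign_causal_variants(mafs50, 20, 0, 0.01)
    expect_length(cm$causal_indices, 10L)
    hits[cm$causal_indices] <- hits[cm$causal_indices] + 1L
  }
  se <- sqrt(0.2 * 0.8 / n_draw)
  expect_true(all(abs(hits / n_draw - 0.2) < 4 * se))

  # protective count rounds from the percentage
  set.seed(3)
  cm <- assign_causal_variants(mafs50, 20, 20, 0.01)
  expect_equal(sum(cm$signs == -1), 2L)
  expect_error(assign_causal_variants(c(0.2, 0.3), 20, 0, 0.01),
               class = "degenerate_region_error")
})

test_that("cohort sampling is reproducible and fills the exact quotas", {
  pool <- fixture_pool()
  b0 <- solve_intercept(0.01)
  set.seed(4)
  region <- draw_region(pool, 3000)
  set.seed(5)
  c1 <- sample_cohort(pool, region, 60, 40, b0)
  set.seed(5)
  c2 <- sample_cohort(pool, region, 60, 40, b0)
  expect_identical(c1$genotypes$G, c2$genotypes$G)
  expect_identical(c1$phenotypes$y, c2$phenotypes$y)
  expect_identical(sum(c1$phenotypes$y), 60L)
  expect_identical(length(c1$phenotypes$y), 100L)
  expect_true(all(c1$genotypes$G %in% 0:2))
})

test_that("null cohorts carry no genotype-phenotype association", {
  pool <- fixture_pool()
  b0 <- solve_intercept(0.05)  # cheaper rejection sampling for this check
  set.seed(6)
  diffs <- replicate(120, {
    region <- draw_region(pool, 3000)
    coh <- sample_cohort(pool, region, 50, 50, b0)
    y <- coh$phenotypes$y
    mean(coh$genotypes$G[y == 1, ]) - mean(coh$genotypes$G[y == 0, ])
  })
  expect_gt(t.test(diffs)$p.value, 0.001)
})

test_that("risk and protective causal alleles shift carriers as expected", {
  pool <- fixture_pool()
  b0 <- solve_intercept(0.05)
  enrich <- function(sign, seed) {
    set.seed(seed)
    replicate(60, {
      region <- draw_region(pool, 3000)
      mafs <- pmin(pool$daf[region$site_indices],
                   1 - pool$daf[region$site_indices])
      j <- which(mafs >= 0.01 & mafs <= 0.1)[1]
      if (is.na(j)) return(NA_real_)
      cm <- structure(list(causal_indices = j, signs = sign, betas = 2,
                           c = NA, pct_causal = NA, pct_protective = NA,
                           causal_maf_cutoff = NA), class = "causal_model")
      coh <- sample_cohort(pool, region, 50, 50, b0, causal = cm)
      y <- coh$phenotypes$y
      mean(coh$genotypes$G[y == 1, j] > 0) - mean(coh$genotypes$G[y == 0, j] > 0)
    })
  }
  up <- enrich(+1, 31)
  expect_lt(binom.test(sum(up > 0, na.rm = TRUE),
                       sum(!is.na(up) & up != 0),
                       alternative = "greater")$p.value, 0.01)
  down <- enrich(-1, 32)
  expect_lt(binom.test(sum(down < 0, na.rm = TRUE),
                       sum(!is.na(down) & down != 0),
                       alternative = "greater")$p.value, 0.01)
})

test_that("zero causal effects reduce the alternative model to the null", {
  pool <- fixture_pool()
  b0 <- solve_intercept(0.05)
  set.seed(8)
  region <- draw_region(pool, 3000)
  cm <- structure(list(causal_indices = 1:2, signs = c(1, 1), betas = c(0, 0),
                       c = 0, pct_causal = NA, pct_protective = NA,
                       causal_maf_cutoff = NA), class = "causal_model")
  diffs <- replicate(80, {
    coh <- sample_cohort(pool, region, 40, 40, b0, causal = cm)
    y <- coh$phenotypes$y
    mean(coh$genotypes$G[y == 1, ]) - mean(coh$genotypes$G[y == 0, ])
  })
  expect_gt(t.test(diffs)$p.value, 0.001)
})

test_that("phenotype export matches the application-mode reader", {
  pool <- fixture_pool()
  set.seed(10)
  region <- draw_region(pool, 3000)
  coh <- sample_cohort(pool, region, 20, 20, solve_intercept(0.05))
  f <- tempfile(fileext = ".tsv")
  write_phenotypes(coh$phenotypes, f)
  back <- load_phenotypes(f)
  expect_identical(back$y, coh$phenotypes$y)
  expect_equal(unname(back$X), unname(coh$phenotypes$X))
})
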