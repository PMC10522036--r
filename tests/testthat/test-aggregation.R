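# The aggregation-test registry.

test_that("the null model matches direct likelihood maximisation", {
  # intercept-only: fitted probability is the case fraction
  y <- rep(c(1, 0), c(30, 70))
  fit <- fit_null_model(y)
  expect_equal(unique(round(fit$mu, 10)), 0.3)
  expect_lt(abs(sum(fit$res)), 1e-6)
  expect_error(fit_null_model(rep(1, 10)), "single class")

  # against a brute-force optimiser on the log-likelihood
  set.seed(12)
  X <- cbind(rnorm(200), rbinom(200, 1, 0.5))
  y <- rbinom(200, 1, plogis(-0.5 + 0.8 * X[, 1]))
  fit <- fit_null_model(y, X)
  D <- cbind(1, X)
  nll <- function(b) -sum(y * (D %*% b) - log1p(exp(D %*% b)))
  grad <- function(b) -drop(crossprod(D, y - plogis(drop(D %*% b))))
  opt <- optim(c(0, 0, 0), nll, grad, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
  mu_opt <- plogis(drop(D %*% opt$par))
  expect_lt(max(abs(fit$mu - mu_opt)), 1e-4)
})

test_that("Beta MAF weights are uniform at (1,1) and favour rarer variants", {
  expect_equal(beta_maf_weights(c(0.001, 0.1, 0.4), 1, 1), rep(1, 3))
  w <- beta_maf_weights(c(0.001, 0.01, 0.05, 0.2))
  expect_true(all(diff(w) < 0))
})

test_that("CAST detects a perfectly separating carrier pattern exactly", {
  G <- matrix(c(rep(1, 10), rep(0, 10)), ncol = 1)
  y <- rep(c(1, 0), each = 10)
  # hypergeometric enumeration: only the two perfect tables are as extreme
  p_exact <- 2 / choose(20, 10)
  expect_equal(cast_test(G, y, "fisher"), p_exact, tolerance = 1e-10)
  expect_lt(cast_test(G, y, "chisq"), 1e-4)
  # degenerate tables fail (and become NA through the safe wrapper)
  expect_error(cast_test(matrix(0, 20, 2), y), "degenerate")
  spec <- default_registry("cast_chisq")[[1]]
  res <- run_test_safe(spec, matrix(0, 20, 2), y)
  expect_true(is.na(res$pvalue))
})

test_that("CMC with a single rare bin equals the carrier score test", {
  dat <- fixture_dataset(seed = 21)
  p_cmc <- cmc_test(dat$G, dat$y, dat$X, maf = dat$maf, bins = 0.01)
  carrier <- as.numeric(rowSums(dat$G) > 0)
  p_score <- burden_score_test(matrix(carrier, ncol = 1), dat$y, dat$X,
                               weights = 1)
  expect_equal(p_cmc, p_score, tolerance = 1e-9)
})

test_that("burden score test: symmetry null case and agreement with the LRT", {
  # U = 0 by construction -> p = 1
  G <- matrix(c(1, 1, 0, 0), ncol = 1)
  y <- c(1, 0, 1, 0)
  expect_equal(burden_score_test(G, y, weights = 1), 1)
  # zero weights give a zero-variance score
  expect_error(burden_score_test(G, y, weights = 0), "zero variance")
  # asymptotic equivalence with the likelihood-ratio test at n = 2000
  set.seed(14)
  n <- 2000
  X <- cbind(rnorm(n))
  s <- rpois(n, 1)
  y <- rbinom(n, 1, plogis(-1 + 0.1 * s + 0.3 * X[, 1]))
  p_score <- burden_score_test(matrix(s, ncol = 1), y, X, weights = 1)
  m0 <- glm(y ~ X, family = binomial)
  m1 <- glm(y ~ s + X, family = binomial)
  p_lrt <- anova(m0, m1, test = "LRT")$`Pr(>Chi)`[2]
  expect_lt(abs(p_score - p_lrt), 0.005)
})

test_that("weighted-sum test honours its permutation conventions", {
  dat <- fixture_dataset(seed = 22)
  # constant scores: every permutation ties the observed rank sum
  expect_equal(wss_test(matrix(1, 40, 2), rep(c(1, 0), 20),
                        permutations = 200), 1)
  expect_error(wss_test(dat$G, dat$y, permutations = 0), "permutations")
  # observed more extreme than every permutation: floor 1/(B+1)
  G <- matrix(c(rep(2, 10), rep(0, 30)), ncol = 1)
  y <- rep(c(1, 0), c(10, 30))
  set.seed(2)
  expect_equal(wss_test(G, y, permutations = 1000), 1 / 1001)
})

test_that("SSU with one variant collapses to the 1-df score test", {
  dat <- fixture_dataset(seed = 23)
  j <- which.max(colSums(dat$G))
  G1 <- dat$G[, j, drop = FALSE]
  p_ssu <- ssu_test(G1, dat$y, dat$X)
  p_burden <- burden_score_test(G1, dat$y, dat$X, weights = 1)
  expect_lt(abs(p_ssu - p_burden), 1e-6)
})

test_that("C-alpha favours case-private variants and its modes agree", {
  set.seed(25)
  n <- 100
  y <- rep(c(1, 0), each = n / 2)
  # all 8 minor alleles in cases vs evenly split: smaller p when private
  G_priv <- matrix(0, n, 4); G_even <- matrix(0, n, 4)
  for (j in 1:4) {
    G_priv[j * 2 + 0:1, j] <- 1                 # cases only
    G_even[c(j * 2, n / 2 + j * 2), j] <- 1     # one case, one control
  }
  p_priv <- calpha_test(G_priv, y)
  p_even <- calpha_test(G_even, y)
  expect_lt(p_priv, p_even)
  # asymptotic and permutation modes agree on moderate data
  dat <- fixture_dataset(seed = 26)
  p_asy <- calpha_test(dat$G, dat$y)
  set.seed(1)
  p_perm <- calpha_test(dat$G, dat$y, mode = "permutation",
                        permutations = 2000)
  expect_lt(abs(p_asy - p_perm), 0.05)
  expect_error(calpha_test(matrix(0, 10, 2), rep(c(1, 0), 5)),
               "no minor alleles")
})

test_that("SKAT reduces to the burden test on a rank-one kernel", {
  dat <- fixture_dataset(seed = 27)
  j <- which.max(colSums(dat$G))
  G1 <- dat$G[, j, drop = FALSE]
  p_skat <- skat_test(G1, dat$y, dat$X, weights = 1)
  p_burden <- burden_score_test(G1, dat$y, dat$X, weights = 1)
  expect_lt(abs(p_skat - p_burden), 1e-6)
})

test_that("SKAT-O reduces exactly to SKAT and to burden at the grid edges", {
  for (seed in c(31, 32, 33)) {
    dat <- fixture_dataset(seed = seed)
    w <- beta_maf_weights(dat$maf)
    p0 <- skato_test(dat$G, dat$y, dat$X, maf = dat$maf, rho_grid = 0)
    p_skat <- skat_test(dat$G, dat$y, dat$X, maf = dat$maf)
    expect_lt(abs(p0 - p_skat), 1e-6)
    p1 <- skato_test(dat$G, dat$y, dat$X, maf = dat$maf, rho_grid = 1)
    p_burden <- burden_score_test(dat$G, dat$y, dat$X, maf = dat$maf,
                                  weights = w)
    expect_lt(abs(p1 - p_burden), 1e-6)
    # full grid: bounded by the most significant member, above its floor
    pfull <- skato_test(dat$G, dat$y, dat$X, maf = dat$maf)
    expect_gte(pfull, min(p_skat, p_burden))
    expect_lte(pfull, min(1, 11 * min(p_skat, p_burden)) + 1e-12)
  }
})

test_that("moment-adjusted SKAT agrees with asymptotic SKAT at large n", {
  set.seed(37)
  n <- 2000
  G <- matrix(rbinom(n * 12, 2, 0.02), n, 12)
  X <- cbind(rnorm(n))
  y <- rbinom(n, 1, plogis(-0.2 + 0.3 * X[, 1]))
  p_asy <- skat_test(G, y, X)
  expect_gt(p_asy, 0.01); expect_lt(p_asy, 0.5)
  set.seed(1); p_adj1 <- skat_binary_adjusted(G, y, X, n_resample = 5000)
  set.seed(1); p_adj2 <- skat_binary_adjusted(G, y, X, n_resample = 5000)
  expect_identical(p_adj1, p_adj2)  # reproducible under a fixed seed
  expect_lt(abs(p_adj1 - p_asy), 0.01)
  expect_error(skat_binary_adjusted(G, y, X, n_resample = 50), "100")
})

test_that("threshold burden honours its floor and tracks the score test", {
  dat <- fixture_dataset(seed = 36)
  expect_error(threshold_burden_test(dat$G, dat$y, maf = dat$maf,
                                     threshold = 1e-6), "below threshold")
  # permutation p within noise of the asymptotic unweighted burden p at a
  # sample size where the score statistic is close to normal
  set.seed(8)
  n <- 3000
  G <- matrix(rbinom(n * 25, 2, 0.004), n, 25)
  y <- rbinom(n, 1, 0.5)
  B <- 2000
  set.seed(3)
  p_perm <- threshold_burden_test(G, y, maf = colMeans(G) / 2,
                                  threshold = 0.05, permutations = B)
  p_asy <- burden_score_test(G, y, weights = rep(1, 25))
  expect_lt(abs(p_perm - p_asy), 4 * sqrt(p_asy * (1 - p_asy) / B) + 0.01)
  # floor at 1/(B+1) for a perfectly separating burden
  G <- matrix(c(rep(2, 10), rep(0, 30)), ncol = 1)
  y <- rep(c(1, 0), c(10, 30))
  set.seed(4)
  expect_equal(threshold_burden_test(G, y, maf = 0.01, threshold = 0.05,
                                     permutations = 1000), 1 / 1001)
})

test_that("the safe wrapper converts failures to NA and records timing", {
  boom <- test_spec("boom", function(G, y) stop("deliberate"))
  res <- run_test_safe(boom, matrix(0, 4, 1), c(1, 0, 1, 0))
  expect_true(is.na(res$pvalue))
  expect_match(res$error, "deliberate")
  expect_gte(res$elapsed, 0)
  # out-of-range p-values are rejected, not propagated
  bad <- test_spec("bad", function(G, y) 1.5)
  expect_true(is.na(run_test_safe(bad, matrix(0, 4, 1), c(1, 0, 1, 0))$pvalue))
  ok <- test_spec("ok", function(G, y) 0.42)
  expect_equal(run_test_safe(ok, matrix(0, 4, 1), c(1, 0, 1, 0))$pvalue, 0.42)
})

test_that("deterministic tests are invariant to joint relabelling", {
  dat <- fixture_dataset(seed = 38)
  perm <- sample(length(dat$y))
  for (id in c("cast_chisq", "cmc", "burden_score", "ssu", "ssuw",
               "calpha_asymptotic", "skat_linear_weighted", "skato")) {
    spec <- default_registry(id)[[1]]
    p1 <- run_test_safe(spec, dat$G, dat$y, dat$X, maf = dat$maf)$pvalue
    p2 <- run_test_safe(spec, dat$G[perm, , drop = FALSE], dat$y[perm],
                        dat$X[perm, , drop = FALSE], maf = dat$maf)$pvalue
    expect_equal(p1, p2, tolerance = 1e-8, label = id)
  }
})

test_that("the registry exposes the fifteen core tests", {
  reg <- default_registry()
  expect_length(reg, 15L)
  expect_setequal(unique(list_tests(reg)$class),
                  c("burden", "variance", "omnibus"))
  expect_error(default_registry("nope"), "unknown test id")
})
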