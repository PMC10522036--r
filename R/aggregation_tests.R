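## Region-based association tests.
##
## Every test maps (G, y, X, ...) to a p-value. G is an n x m minor-allele
## dosage matrix (0/1/2), y a binary phenotype vector, X an optional
## covariate matrix. Tests that cannot produce a p-value raise a condition;
## run_test_safe() converts failures to NA. Covariate handling follows each
## test's original: CAST, WSS, C-alpha and the fixed-threshold burdens
## ignore covariates; score/SKAT-family tests adjust through the logistic
## null model.

#' Fit the logistic null model
#'
#' Maximum-likelihood logistic regression of the phenotype on an intercept
#' plus covariates (no genotypes), the shared nuisance fit behind all
#' score-type tests.
#'
#' @param y Binary 0/1 phenotype vector with both classes present.
#' @param X Optional numeric covariate matrix (n rows), without intercept.
#' @return A \code{null_model_fit}: list with \code{mu} (fitted case
#'   probabilities), \code{res} (\code{y - mu}), \code{v}
#'   (\code{mu * (1 - mu)}), \code{D} (design including intercept),
#'   \code{DtVD_inv}, \code{converged}.
#' @export
fit_null_model <- function(y, X = NULL) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2L)
    stop("phenotype has a single class; null model undefined", call. = FALSE)
  D <- if (is.null(X)) matrix(1, length(y), 1L) else cbind(1, as.matrix(X))
  fit <- suppressWarnings(
    stats::glm.fit(D, y, family = stats::binomial(),
                   control = list(epsilon = 1e-10, maxit = 25L)))
  mu <- fit$fitted.values
  v <- mu * (1 - mu)
  structure(list(mu = mu, res = y - mu, v = v, D = D,
                 DtVD_inv = solve(crossprod(D, D * v)),
                 converged = isTRUE(fit$converged)),
            class = "null_model_fit")
}

## Z1 = M V^{1/2} Z, so that crossprod(Z1) = Z' P Z with P the null-model
## variance-projection matrix. Shared by SKAT/SSU/burden variance terms.
project_genotypes <- function(fit, Z) {
  sv <- sqrt(fit$v)
  VZ <- Z * fit$v
  adj <- (sv * fit$D) %*% (fit$DtVD_inv %*% crossprod(fit$D, VZ))
  sv * Z - adj
}

#' Beta-density MAF weights
#'
#' Standard variant weighting \code{w_j = dbeta(maf_j, a1, a2)}; the default
#' Beta(1, 25) up-weights rarer variants sharply.
#'
#' @param mafs Minor-allele frequencies.
#' @param a1,a2 Beta shape parameters.
#' @return Weight vector.
#' @export
beta_maf_weights <- function(mafs, a1 = 1, a2 = 25) {
  stats::dbeta(mafs, a1, a2)
}

#' CAST: cohort allelic sums test
#'
#' Collapses the region to a per-individual carrier indicator (any dosage
#' greater than zero) and tests the 2x2 carrier-by-status table, either by
#' Pearson chi-square (no continuity correction) or a two-sided Fisher exact
#' test. Covariates are ignored, as in the original method.
#'
#' @param G Dosage matrix.
#' @param y Binary phenotype.
#' @param method \code{"chisq"} or \code{"fisher"}.
#' @return A p-value.
#' @export
cast_test <- function(G, y, method = c("chisq", "fisher")) {
  method <- match.arg(method)
  if (ncol(G) < 1L) stop("no variants", call. = FALSE)
  carrier <- as.integer(rowSums(G > 0) > 0)
  if (all(carrier == 0L) || all(carrier == 1L))
    stop("degenerate carrier table", call. = FALSE)
  tab <- table(factor(carrier, levels = 0:1), factor(y, levels = 0:1))
  if (method == "chisq") {
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  } else {
    stats::fisher.test(tab)$p.value
  }
}

#' CMC: combined multivariate and collapsing test
#'
#' Rare variants (MAF below each bin bound) are collapsed into per-bin
#' carrier indicators; common variants are kept as individual columns. All
#' resulting columns are tested jointly against the phenotype with a
#' multivariate logistic score test adjusting for covariates; the statistic
#' is chi-square with one degree of freedom per (non-degenerate) column.
#'
#' @param G Dosage matrix.
#' @param y Binary phenotype.
#' @param X Optional covariates.
#' @param maf Per-variant MAF (defaults to sample estimate).
#' @param bins Upper MAF bounds of the collapsing bins (default one bin,
#'   variants below 0.01).
#' @param null_fit Optional precomputed \code{\link{fit_null_model}}.
#' @return A p-value.
#' @export
cmc_test <- function(G, y, X = NULL, maf = colMeans(G) / 2, bins = 0.01,
                     null_fit = NULL) {
  bins <- sort(bins)
  lower <- c(0, bins[-length(bins)])
  cols <- list()
  for (b in seq_along(bins)) {
    in_bin <- maf >= lower[b] & maf < bins[b]
    if (any(in_bin))
      cols[[length(cols) + 1L]] <- as.numeric(rowSums(G[, in_bin, drop = FALSE]) > 0)
  }
  common <- maf >= bins[length(bins)]
  if (any(common))
    cols <- c(cols, lapply(which(common), function(j) G[, j]))
  if (!length(cols)) stop("no analysable columns", call. = FALSE)
  C <- do.call(cbind, cols)
  C <- C[, apply(C, 2, stats::var) > 0, drop = FALSE]
  if (!ncol(C)) stop("all columns constant", call. = FALSE)
  fit <- if (is.null(null_fit)) fit_null_model(y, X) else null_fit
  U <- crossprod(C, fit$res)
  C1 <- project_genotypes(fit, C)
  V <- crossprod(C1)
  ## prune to numerical rank
  ev <- eigen(V, symmetric = TRUE)
  keep <- ev$values > max(ev$values) * 1e-8
  if (!any(keep)) stop("score covariance numerically zero", call. = FALSE)
  Ut <- crossprod(ev$vectors[, keep, drop = FALSE], U)
  stat <- sum(Ut^2 / ev$values[keep])
  stats::pchisq(stat, df = sum(keep), lower.tail = FALSE)
}

#' Weighted burden score test
#'
#' Collapses the region into one weighted score per individual,
#' \eqn{s_i = \sum_j w_j G_{ij}}, and performs the 1-df logistic score test
#' of \code{s} adjusting for covariates: \eqn{U = \sum_i s_i (y_i - \mu_i)},
#' \eqn{V = s'Ps}, \eqn{p = P(\chi^2_1 > U^2/V)}.
#'
#' @inheritParams cmc_test
#' @param weights Per-variant weights; default Beta(1, 25) in MAF.
#' @return A p-value.
#' @export
burden_score_test <- function(G, y, X = NULL, maf = colMeans(G) / 2,
                              weights = beta_maf_weights(maf),
                              null_fit = NULL) {
  s <- drop(G %*% weights)
  fit <- if (is.null(null_fit)) fit_null_model(y, X) else null_fit
  s1 <- project_genotypes(fit, matrix(s, ncol = 1L))
  V <- sum(s1^2)
  if (V <= .Machine$double.eps * length(s))
    stop("burden score has zero variance", call. = FALSE)
  U <- sum(s * fit$res)
  stats::pchisq(U^2 / V, df = 1, lower.tail = FALSE)
}

#' Madsen-Browning weighted-sum test
#'
#' Variants are weighted by the inverse binomial standard deviation of their
#' control-group allele frequency (with one pseudo-allele of smoothing),
#' individuals are scored and ranked, and the statistic is the sum of case
#' ranks (midranks for ties). The p-value is by permutation of the phenotype
#' with the add-one estimator. Covariates are ignored.
#'
#' @param G Dosage matrix.
#' @param y Binary phenotype.
#' @param permutations Number of label permutations (default 1000).
#' @return A p-value.
#' @export
wss_test <- function(G, y, permutations = 1000L) {
  if (permutations < 1L) stop("permutations must be >= 1", call. = FALSE)
  ctrl <- y == 0
  n_ctrl <- sum(ctrl)
  q <- (colSums(G[ctrl, , drop = FALSE]) + 1) / (2 * n_ctrl + 2)
  w <- 1 / sqrt(n_ctrl * q * (1 - q))
  score <- drop(G %*% w)
  r <- rank(score)  # midranks
  obs <- sum(r[y == 1])
  perm <- replicate(permutations, sum(r[sample(y) == 1]))
  (1 + sum(perm >= obs)) / (1 + permutations)
}

#' SSU: sum of squared score test
#'
#' The statistic is \eqn{U'WU} for the per-variant logistic score vector
#' \eqn{U = G'(y - \hat\mu)}, with \eqn{W = I} (SSU) or the inverse
#' per-variant score variances (SSUw). The null distribution is a weighted
#' chi-square mixture with eigenvalues of
#' \eqn{W^{1/2}\,\mathrm{Cov}(U)\,W^{1/2}}, evaluated through
#' \code{\link{quadform_pvalue}}.
#'
#' @inheritParams cmc_test
#' @param weighted \code{TRUE} for SSUw.
#' @return A p-value.
#' @export
ssu_test <- function(G, y, X = NULL, weighted = FALSE, null_fit = NULL) {
  fit <- if (is.null(null_fit)) fit_null_model(y, X) else null_fit
  Z1 <- project_genotypes(fit, G)
  CovU <- crossprod(Z1)
  dv <- diag(CovU)
  keep <- dv > max(dv, 0) * 1e-10
  if (!any(keep) || max(dv) <= 0)
    stop("score covariance numerically zero", call. = FALSE)
  U <- crossprod(G, fit$res)[keep, , drop = FALSE]
  CovU <- CovU[keep, keep, drop = FALSE]
  if (weighted) {
    wh <- 1 / sqrt(diag(CovU))
    U <- U * wh
    CovU <- CovU * tcrossprod(wh)
  }
  stat <- sum(U^2)
  lam <- eigen(CovU, symmetric = TRUE, only.values = TRUE)$values
  quadform_pvalue(quadform_spec(stat, lam))$p
}

#' C-alpha test of variance inflation in case allele counts
#'
#' For each variant, compares the number of minor alleles observed in cases
#' with its binomial expectation under the overall case fraction:
#' \eqn{T = \sum_j [(c_j - n_j\bar p)^2 - n_j\bar p(1-\bar p)]}. The
#' asymptotic p-value is one-sided normal with the exact binomial variance of
#' T; the permutation mode shuffles phenotypes. Covariates are ignored.
#'
#' @param G Dosage matrix.
#' @param y Binary phenotype.
#' @param mode \code{"asymptotic"} or \code{"permutation"}.
#' @param permutations Permutation count for the permutation mode.
#' @return A p-value.
#' @export
calpha_test <- function(G, y, mode = c("asymptotic", "permutation"),
                        permutations = 1000L) {
  mode <- match.arg(mode)
  n_j <- colSums(G)
  keep <- n_j > 0
  if (!any(keep)) stop("no minor alleles observed", call. = FALSE)
  G <- G[, keep, drop = FALSE]
  n_j <- n_j[keep]
  p_bar <- mean(y)
  t_stat <- function(yy) {
    c_j <- colSums(G[yy == 1, , drop = FALSE])
    sum((c_j - n_j * p_bar)^2 - n_j * p_bar * (1 - p_bar))
  }
  T_obs <- t_stat(y)
  if (mode == "permutation") {
    perm <- replicate(permutations, t_stat(sample(y)))
    return((1 + sum(perm >= T_obs)) / (1 + permutations))
  }
  ## exact variance of each variant's term under binomial(n_j, p_bar)
  var_T <- sum(vapply(n_j, function(nj) {
    u <- 0:nj
    term <- (u - nj * p_bar)^2 - nj * p_bar * (1 - p_bar)
    sum(term^2 * stats::dbinom(u, nj, p_bar))
  }, numeric(1)))
  if (var_T <= 0) stop("degenerate C-alpha variance", call. = FALSE)
  stats::pnorm(T_obs / sqrt(var_T), lower.tail = FALSE)
}

#' SKAT: sequence kernel association test
#'
#' Variance-component score test
#' \eqn{Q = (y-\hat\mu)'\tilde G \tilde G'(y-\hat\mu)} with
#' \eqn{\tilde G = G\,\mathrm{diag}(w)}; the null distribution is the
#' chi-square mixture with eigenvalues of \eqn{\tilde G' P \tilde G}.
#'
#' @inheritParams cmc_test
#' @param kernel \code{"linear_weighted"} (Beta(1,25) weights, the default)
#'   or \code{"linear"} (unit weights).
#' @param weights Explicit weights overriding the kernel choice.
#' @return A p-value.
#' @export
skat_test <- function(G, y, X = NULL, kernel = c("linear_weighted", "linear"),
                      maf = colMeans(G) / 2, weights = NULL, null_fit = NULL) {
  kernel <- match.arg(kernel)
  if (is.null(weights))
    weights <- if (kernel == "linear") rep(1, ncol(G)) else beta_maf_weights(maf)
  fit <- if (is.null(null_fit)) fit_null_model(y, X) else null_fit
  Z <- G * rep(weights, each = nrow(G))
  U <- crossprod(Z, fit$res)
  Q <- sum(U^2)
  Z1 <- project_genotypes(fit, Z)
  lam <- eigen(crossprod(Z1), symmetric = TRUE, only.values = TRUE)$values
  if (max(lam) <= 0) stop("kernel numerically zero", call. = FALSE)
  quadform_pvalue(quadform_spec(Q, lam))$p
}

#' SKAT-O: optimal combination of SKAT and burden
#'
#' Evaluates the family \eqn{Q_\rho = (1-\rho)Q_{SKAT} + \rho Q_{burden}}
#' over a grid of mixing weights and combines the per-\eqn{\rho} p-values
#' through the minimum-p statistic with the standard one-dimensional
#' integration over the shared burden factor. With a single-element grid the
#' result reduces exactly to SKAT (\code{rho_grid = 0}) or to the weighted
#' burden score test (\code{rho_grid = 1}).
#'
#' @inheritParams skat_test
#' @param rho_grid Mixing grid; default \eqn{\{0, 0.1^2, ..., 0.9^2, 1\}}.
#' @return A p-value. On integration failure the Bonferroni bound over the
#'   grid (\code{min(1, n_grid * min p)}) is returned with a warning.
#' @export
skato_test <- function(G, y, X = NULL, maf = colMeans(G) / 2,
                       weights = beta_maf_weights(maf),
                       rho_grid = c((0:9 / 10)^2, 1), null_fit = NULL) {
  fit <- if (is.null(null_fit)) fit_null_model(y, X) else null_fit
  n <- nrow(G); m <- ncol(G)
  Z <- G * rep(weights, each = n)
  S <- drop(crossprod(Z, fit$res))
  Z1 <- project_genotypes(fit, Z)
  M <- crossprod(Z1)  # Z' P Z
  Q_rho <- (1 - rho_grid) * sum(S^2) + rho_grid * sum(S)^2

  lam_rho <- lapply(rho_grid, function(r) {
    Rh <- rho_half(m, r)
    eigen(Rh %*% M %*% Rh, symmetric = TRUE, only.values = TRUE)$values
  })
  p_rho <- mapply(function(q, lam) {
    lam <- lam[lam > max(lam) * 1e-10]
    if (!length(lam) || max(lam) <= 0) return(NA_real_)
    quadform_pvalue(quadform_spec(q, lam))$p
  }, Q_rho, lam_rho)
  if (all(is.na(p_rho))) stop("all grid p-values failed", call. = FALSE)
  if (length(rho_grid) == 1L) return(p_rho[[1]])
  p_min <- min(p_rho, na.rm = TRUE)

  ## moments of the shared-factor decomposition (burden direction vs rest)
  zbar <- rowMeans(Z1)
  zbar_sq <- sum(zbar^2)
  if (zbar_sq <= 0) return(min(1, length(rho_grid) * p_min))
  cof <- drop(crossprod(zbar, Z1)) / zbar_sq
  Z_res <- Z1 - outer(zbar, cof)
  lam_k <- eigen(crossprod(Z_res), symmetric = TRUE, only.values = TRUE)$values
  lam_k <- lam_k[lam_k > max(lam_k, 0) * 1e-10]
  if (!length(lam_k)) return(min(1, length(rho_grid) * p_min))
  var_remain <- 4 * sum(crossprod(outer(zbar, cof)) * crossprod(Z_res))
  mu_q <- sum(lam_k)
  var_q <- 2 * sum(lam_k^2) + var_remain
  tau <- (m^2 * rho_grid + (1 - rho_grid) * sum(cof^2)) * zbar_sq

  qmin <- vapply(lam_rho, function(lam) {
    lam <- lam[lam > max(lam) * 1e-10]
    liu_quantile(lam, p_min)
  }, numeric(1))

  r_cap <- pmin(rho_grid, 0.999)  # rho = 1 handled in the limit
  kpar <- liu_params(lam_k)
  integrand <- function(x) {
    ## conditional quantile for the kappa term given the chi1 factor x
    qt <- vapply(x, function(xx)
      min((qmin - tau * xx) / (1 - r_cap)), numeric(1))
    qt_adj <- (qt - mu_q) / sqrt(var_q) * sqrt(2 * sum(lam_k^2)) + mu_q
    xq <- (qt_adj - kpar$muQ) / kpar$sigmaQ * kpar$sigmaX + kpar$muX
    Fk <- stats::pchisq(xq, df = kpar$l, ncp = kpar$d)
    Fk * stats::dchisq(x, df = 1)
  }
  int <- tryCatch(
    stats::integrate(integrand, lower = 0, upper = 40, subdivisions = 500L,
                     abs.tol = 1e-10, stop.on.error = FALSE),
    error = function(e) NULL)
  if (is.null(int) || !is.finite(int$value)) {
    warning("SKAT-O integration failed; returning Bonferroni bound over grid")
    return(min(1, length(rho_grid) * p_min))
  }
  p <- 1 - int$value
  ## numerical floor: never report below the per-rho minimum
  min(max(p, p_min), min(1, length(rho_grid) * p_min))
}

## Symmetric square root of the exchangeable correlation matrix
## R = (1-rho) I + rho J.
rho_half <- function(m, rho) {
  a <- sqrt(1 - rho)
  b <- sqrt(1 - rho + m * rho)
  diag(a, m) + (b - a) / m * matrix(1, m, m)
}

#' Moment-adjusted SKAT / SKAT-O for small or unbalanced binary samples
#'
#' Estimates the null variance and kurtosis of the SKAT statistic by
#' parametric resampling of the binary outcome from the fitted null
#' probabilities, and computes the p-value from a moment-matched chi-square
#' with degrees of freedom \code{12 / kurtosis}. For the omnibus base the
#' adjustment is applied to every mixing weight in the grid and the grid
#' minimum is Bonferroni-corrected.
#'
#' @inheritParams skato_test
#' @param base \code{"skat"} or \code{"skato"}.
#' @param n_resample Resampling budget (minimum 100, default 2000).
#' @return A p-value.
#' @export
skat_binary_adjusted <- function(G, y, X = NULL, base = c("skat", "skato"),
                                 maf = colMeans(G) / 2,
                                 weights = beta_maf_weights(maf),
                                 rho_grid = c((0:9 / 10)^2, 1),
                                 n_resample = 2000L, null_fit = NULL) {
  base <- match.arg(base)
  if (n_resample < 100L) stop("n_resample must be >= 100", call. = FALSE)
  fit <- if (is.null(null_fit)) fit_null_model(y, X) else null_fit
  n <- nrow(G)
  Z <- G * rep(weights, each = n)
  S <- drop(crossprod(Z, fit$res))
  rhos <- if (base == "skat") 0 else rho_grid
  Q_obs <- (1 - rhos) * sum(S^2) + rhos * sum(S)^2

  ## resampled scores under the fitted binary null; residuals are projected
  ## for the estimated covariate effects so that Cov(S*) targets Z'PZ, the
  ## covariance of the observed score
  Rstar <- matrix(stats::rbinom(n * n_resample, 1L, fit$mu), nrow = n) - fit$mu
  Radj <- fit$v * (fit$D %*% (fit$DtVD_inv %*% crossprod(fit$D, Rstar)))
  Sstar <- crossprod(Z, Rstar - Radj)  # m x B
  ss_sq <- colSums(Sstar^2)
  ss_sum <- colSums(Sstar)^2
  p_each <- vapply(seq_along(rhos), function(k) {
    Qs <- (1 - rhos[k]) * ss_sq + rhos[k] * ss_sum
    moment_matched_p(Q_obs[k], Qs)
  }, numeric(1))
  if (base == "skat") p_each[1] else min(1, length(rhos) * min(p_each))
}

## Chi-square moment matching from a resampled null sample.
moment_matched_p <- function(q, qs) {
  mu <- mean(qs)
  s2 <- stats::var(qs)
  if (s2 <= 0) return(1)
  kurt <- mean((qs - mu)^4) / s2^2 - 3
  df <- if (kurt > 0) 12 / kurt else 1e5
  stats::pchisq((q - mu) / sqrt(s2) * sqrt(2 * df) + df, df = df,
                lower.tail = FALSE)
}

#' Fixed-threshold burden test with permutation p-value
#'
#' Counts minor alleles across variants with MAF below the threshold (the
#' T1/T5 convention for thresholds 0.01/0.05) and assesses the centred case
#' burden by permutation of the phenotype (two-sided, add-one estimator).
#' Covariates are ignored.
#'
#' @param G Dosage matrix.
#' @param y Binary phenotype.
#' @param maf Per-variant MAF.
#' @param threshold MAF threshold (0.01 or 0.05 classically).
#' @param permutations Permutation count.
#' @return A p-value.
#' @export
threshold_burden_test <- function(G, y, maf = colMeans(G) / 2,
                                  threshold = 0.05, permutations = 1000L) {
  keep <- maf < threshold
  if (!any(keep)) stop("no variants below threshold", call. = FALSE)
  s <- rowSums(G[, keep, drop = FALSE])
  stat <- function(yy) abs(sum(s * (yy - mean(yy))))
  obs <- stat(y)
  perm <- replicate(permutations, stat(sample(y)))
  (1 + sum(perm >= obs)) / (1 + permutations)
}
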