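#' Quadratic-form specification
#'
#' Bundles an observed statistic value with the eigenvalue weights of a
#' quadratic form in independent standard normal variables,
#' \eqn{Q = \sum_k \lambda_k \chi^2_1}. Eigenvalues are sorted in decreasing
#' order and values below \code{1e-10 * max(lambda)} are truncated (numerical
#' rank of projected kernels).
#'
#' @param q Observed statistic value (scalar, non-negative in practice).
#' @param lambdas Numeric vector of non-negative eigenvalue weights; at least
#'   one must be positive.
#' @return An object of class \code{quadform_spec} with elements \code{q} and
#'   \code{lambdas}.
#' @export
quadform_spec <- function(q, lambdas) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q))
    stop("`q` must be a single finite number", call. = FALSE)
  lambdas <- as.numeric(lambdas)
  lambdas <- lambdas[!is.na(lambdas)]
  if (length(lambdas) == 0L || all(lambdas <= 0))
    stop("at least one positive eigenvalue is required", call. = FALSE)
  if (any(lambdas < 0)) lambdas <- pmax(lambdas, 0)
  lambdas <- lambdas[lambdas > 1e-10 * max(lambdas)]
  lambdas <- sort(lambdas, decreasing = TRUE)
  structure(list(q = q, lambdas = lambdas), class = "quadform_spec")
}

#' Davies-type tail probability for a quadratic form
#'
#' Computes \eqn{P(\sum_k \lambda_k \chi^2_1 > q)} by adaptive numerical
#' inversion of the characteristic function in Imhof's form,
#' \deqn{p = 1/2 + \frac{1}{\pi}\int_0^\infty
#'   \frac{\sin\theta(u)}{u\,\rho(u)}\,du,}
#' with \eqn{\theta(u) = \frac12\sum_k \arctan(\lambda_k u) - \frac12 q u}
#' and \eqn{\rho(u) = \prod_k (1+\lambda_k^2u^2)^{1/4}}.
#'
#' @param spec A \code{\link{quadform_spec}}.
#' @param accuracy Absolute accuracy requested from the integrator.
#' @return A list with \code{p} (clamped to \code{[0, 1]}), \code{converged}
#'   (logical) and \code{abs_error} (the integrator's error estimate).
#' @export
davies_pvalue <- function(spec, accuracy = 1e-9) {
  stopifnot(inherits(spec, "quadform_spec"))
  lam <- spec$lambdas
  q <- spec$q
  if (q <= 0) return(list(p = 1, converged = TRUE, abs_error = 0))
  ## single eigenvalue: exact chi-square tail
  if (length(lam) == 1L) {
    return(list(p = stats::pchisq(q / lam, df = 1, lower.tail = FALSE),
                converged = TRUE, abs_error = 0))
  }
  ## two eigenvalues: exact smooth conditional integral (the oscillatory
  ## inversion converges poorly at the slow u^-2 tail decay of k = 2)
  if (length(lam) == 2L) {
    g <- function(v)
      stats::pchisq((q - lam[2] * v) / lam[1], df = 1, lower.tail = FALSE) *
        stats::dchisq(v, df = 1)
    res <- tryCatch(
      stats::integrate(g, 0, q / lam[2], rel.tol = 1e-10,
                       subdivisions = 500L, stop.on.error = FALSE),
      error = function(e) NULL)
    if (!is.null(res) && is.finite(res$value)) {
      p <- res$value + stats::pchisq(q / lam[2], df = 1, lower.tail = FALSE)
      return(list(p = min(max(p, 0), 1),
                  converged = res$abs.error <= max(accuracy, 1e-8),
                  abs_error = res$abs.error))
    }
    # fall through to the inversion if the conditional integral fails
  }
  k <- length(lam)
  lam2 <- lam^2
  integrand <- function(u) {
    nu <- length(u)
    lu <- lam %o% u
    theta <- 0.5 * .colSums(atan(lu), k, nu) - 0.5 * q * u
    log_rho <- 0.25 * .colSums(log1p(lam2 %o% (u * u)), k, nu)
    out <- sin(theta) / (u * exp(log_rho))
    out[u == 0] <- 0.5 * (sum(lam) - q)  # limit u -> 0
    out
  }
  res <- tryCatch(
    stats::integrate(integrand, lower = 0, upper = Inf,
                     abs.tol = accuracy,
                     rel.tol = max(1e-6, accuracy * 100),
                     subdivisions = 500L, stop.on.error = FALSE),
    error = function(e) NULL)
  if (is.null(res) || !is.finite(res$value)) {
    return(list(p = NA_real_, converged = FALSE, abs_error = NA_real_))
  }
  p <- 0.5 + res$value / pi
  ## a subdivision-capped result with a small error estimate is acceptable
  converged <- res$message %in%
    c("OK", "maximum number of subdivisions reached") &&
    res$abs.error <= max(accuracy, 5e-5)
  ## out-of-range values beyond integration error are a convergence failure
  if (p < -1e-6 || p > 1 + 1e-6) converged <- FALSE
  list(p = min(max(p, 0), 1), converged = converged, abs_error = res$abs.error)
}

#' Liu moment-matched p-value for a quadratic form
#'
#' Matches the cumulants of \eqn{\sum_k \lambda_k \chi^2_1} to a (possibly
#' non-central) chi-square distribution (Liu-Tang-Zhang approximation,
#' skewness-matched in the degenerate branch). Exact when all eigenvalues
#' are equal.
#'
#' @inheritParams davies_pvalue
#' @return A single probability in \code{[0, 1]}.
#' @export
liu_pvalue <- function(spec) {
  stopifnot(inherits(spec, "quadform_spec"))
  par <- liu_params(spec$lambdas, modified = FALSE)
  tstar <- (spec$q - par$muQ) / par$sigmaQ
  x <- tstar * par$sigmaX + par$muX
  p <- stats::pchisq(x, df = par$l, ncp = par$d, lower.tail = FALSE)
  min(max(p, 0), 1)
}

## Cumulant matching shared by liu_pvalue and the SKAT-O machinery.
## modified = TRUE matches kurtosis in the degenerate branch (the
## convention of the omnibus-test construction), FALSE matches skewness
## (the classic approximation, closer to the inversion in the upper tail).
liu_params <- function(lam, modified = TRUE) {
  c1 <- sum(lam); c2 <- sum(lam^2); c3 <- sum(lam^3); c4 <- sum(lam^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else if (modified) {
    l <- 1 / s2
    a <- sqrt(l)
    d <- 0
  } else {
    l <- 1 / s1^2
    a <- 1 / s1
    d <- 0
  }
  list(muQ = c1, sigmaQ = sqrt(2 * c2), muX = l + d, sigmaX = sqrt(2) * a,
       l = l, d = d)
}

## Quantile of the quadratic form at upper-tail probability p, by the same
## moment matching (used for SKAT-O minimum-p quantiles).
liu_quantile <- function(lam, p_upper) {
  par <- liu_params(lam)
  x <- stats::qchisq(p_upper, df = par$l, ncp = par$d, lower.tail = FALSE)
  (x - par$muX) / par$sigmaX * par$sigmaQ + par$muQ
}

#' Robust quadratic-form p-value with fallback
#'
#' Tries the Davies/Imhof inversion first and falls back to the Liu
#' moment-matched approximation when the inversion does not converge or
#' returns a value outside \code{[0, 1]}. The branch taken is recorded.
#'
#' @inheritParams davies_pvalue
#' @return A list with \code{p} and \code{method} (\code{"davies"} or
#'   \code{"liu"}); \code{p} is \code{NA} if both routes fail.
#' @export
quadform_pvalue <- function(spec, accuracy = 1e-9) {
  dav <- davies_pvalue(spec, accuracy = accuracy)
  if (dav$converged && !is.na(dav$p) && dav$p >= 0 && dav$p <= 1) {
    return(list(p = dav$p, method = "davies"))
  }
  liu <- tryCatch(liu_pvalue(spec), error = function(e) NA_real_)
  if (is.na(liu)) return(list(p = NA_real_, method = "none"))
  list(p = liu, method = "liu")
}
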