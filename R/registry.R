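#' Declare a test for the registry
#'
#' A test spec couples an identifier with a callable of contract
#' \code{function(G, y, X, maf, null_fit, ...) -> p-value} and a fixed
#' parameter list. Registered tests are pure given the RNG state.
#'
#' @param test_id Unique identifier string.
#' @param fun The callable.
#' @param params Named list of fixed arguments merged into each call.
#' @param class Test class label (\code{"burden"}, \code{"variance"},
#'   \code{"omnibus"}), informational.
#' @param uses_covariates Whether the test adjusts for covariates.
#' @return A \code{test_spec}.
#' @export
test_spec <- function(test_id, fun, params = list(), class = "burden",
                      uses_covariates = TRUE) {
  stopifnot(is.character(test_id), length(test_id) == 1L, is.function(fun))
  structure(list(test_id = test_id, fun = fun, params = params,
                 class = class, uses_covariates = uses_covariates),
            class = "test_spec")
}

#' Run a registered test, never raising
#'
#' Wraps any test call: internal errors become an \code{NA} p-value, the
#' elapsed wall time is recorded, and out-of-range p-values are rejected.
#'
#' @param spec A \code{\link{test_spec}}.
#' @param G Dosage matrix.
#' @param y Binary phenotype.
#' @param X Optional covariates.
#' @param maf Per-variant MAF (defaults to the sample estimate).
#' @param null_fit Optional shared \code{\link{fit_null_model}} result.
#' @return A \code{test_result}: list with \code{test_id}, \code{pvalue}
#'   (in \code{[0, 1]} or \code{NA}), \code{elapsed} (seconds),
#'   \code{error} (message or \code{NA}).
#' @export
run_test_safe <- function(spec, G, y, X = NULL, maf = NULL, null_fit = NULL) {
  stopifnot(inherits(spec, "test_spec"))
  if (is.null(maf)) maf <- colMeans(G) / 2
  t0 <- proc.time()[["elapsed"]]
  err <- NA_character_
  p <- tryCatch({
    args <- c(list(G = G, y = y), spec$params)
    fml <- names(formals(spec$fun))
    if ("X" %in% fml) args$X <- X
    if ("maf" %in% fml) args$maf <- maf
    if ("null_fit" %in% fml && spec$uses_covariates) args$null_fit <- null_fit
    out <- do.call(spec$fun, args)
    as.numeric(out)[1]
  }, error = function(e) {
    err <<- conditionMessage(e)
    NA_real_
  })
  if (!is.na(p) && (p < 0 || p > 1)) {
    err <- sprintf("p-value %g outside [0, 1]", p)
    p <- NA_real_
  }
  structure(list(test_id = spec$test_id, pvalue = p,
                 elapsed = proc.time()[["elapsed"]] - t0, error = err),
            class = "test_result")
}

#' The default test registry
#'
#' Fifteen canonical region-based tests covering the three classes: burden
#' (CAST chi-square/Fisher, CMC, weighted burden score, Madsen-Browning WSS,
#' T1/T5 fixed-threshold burdens), variance-component (SSU, SSUw, asymptotic
#' C-alpha, SKAT with linear and linear-weighted kernels) and omnibus/robust
#' (SKAT-O, moment-adjusted SKAT and SKAT-O). Additional tests can be
#' appended as \code{\link{test_spec}} objects.
#'
#' @param only Optional character vector restricting to these ids.
#' @param permutations Permutation budget for the permutation-based members.
#' @param n_resample Resampling budget for the moment-adjusted members.
#' @return Named list of \code{test_spec} objects.
#' @export
default_registry <- function(only = NULL, permutations = 1000L,
                             n_resample = 2000L) {
  reg <- list(
    test_spec("cast_chisq", function(G, y) cast_test(G, y, "chisq"),
              class = "burden", uses_covariates = FALSE),
    test_spec("cast_fisher", function(G, y) cast_test(G, y, "fisher"),
              class = "burden", uses_covariates = FALSE),
    test_spec("cmc", cmc_test, class = "burden"),
    test_spec("burden_score", burden_score_test, class = "burden"),
    test_spec("wss", wss_test, list(permutations = permutations),
              class = "burden", uses_covariates = FALSE),
    test_spec("t1p", threshold_burden_test,
              list(threshold = 0.01, permutations = permutations),
              class = "burden", uses_covariates = FALSE),
    test_spec("t5p", threshold_burden_test,
              list(threshold = 0.05, permutations = permutations),
              class = "burden", uses_covariates = FALSE),
    test_spec("ssu", ssu_test, list(weighted = FALSE), class = "variance"),
    test_spec("ssuw", ssu_test, list(weighted = TRUE), class = "variance"),
    test_spec("calpha_asymptotic", calpha_test, list(mode = "asymptotic"),
              class = "variance", uses_covariates = FALSE),
    test_spec("skat_linear", skat_test, list(kernel = "linear"),
              class = "variance"),
    test_spec("skat_linear_weighted", skat_test,
              list(kernel = "linear_weighted"), class = "variance"),
    test_spec("skato", skato_test, class = "omnibus"),
    test_spec("robust_skat", skat_binary_adjusted,
              list(base = "skat", n_resample = n_resample), class = "omnibus"),
    test_spec("robust_skato", skat_binary_adjusted,
              list(base = "skato", n_resample = n_resample), class = "omnibus"))
  names(reg) <- vapply(reg, `[[`, "", "test_id")
  if (!is.null(only)) {
    missing <- setdiff(only, names(reg))
    if (length(missing))
      stop("unknown test id(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    reg <- reg[only]
  }
  reg
}

#' List registered tests
#'
#' @param registry A registry (named list of \code{test_spec}).
#' @return A data frame with test id, class and covariate handling.
#' @export
list_tests <- function(registry = default_registry()) {
  data.frame(test_id = vapply(registry, `[[`, "", "test_id"),
             class = vapply(registry, `[[`, "", "class"),
             uses_covariates = vapply(registry, `[[`, TRUE, "uses_covariates"),
             row.names = NULL)
}
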