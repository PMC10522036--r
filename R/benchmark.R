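## Experiment grid, simulation runner, and every summary statistic of the
## benchmark: type I error, reliability, empirical power, calibration
## classification, ranks, uniqueness scores, decision similarity,
## redundancy, computational-time evolution and scenario evolution.

#' Experiment configuration
#'
#' @param experiment_id Identifier string.
#' @param mode \code{"null"} (type I error) or \code{"power"}.
#' @param prop_cases Fraction of cases in the cohort (0.2, 0.5, 0.8).
#' @param cohort_size Total individuals n (100, 500, 1000, 5000).
#' @param pct_protective Percentage of causal variants with protective effect
#'   (power mode).
#' @param pct_causal Percentage of eligible rare variants made causal
#'   (power mode).
#' @param variant_mode \code{"rare_only"} or \code{"rare_and_common"}.
#' @param causal_maf_cutoff MAF threshold separating rare from common.
#' @param region_size Region size in bp.
#' @param replicates Number of simulation replicates.
#' @param prevalence Population disease prevalence (default 0.01).
#' @return An \code{experiment_config}.
#' @export
experiment_config <- function(experiment_id, mode = c("null", "power"),
                              prop_cases = 0.5, cohort_size = 500L,
                              pct_protective = 0, pct_causal = 20,
                              variant_mode = "rare_only",
                              causal_maf_cutoff = 0.01, region_size = 3000,
                              replicates = if (mode == "null") 10000L else 1000L,
                              prevalence = 0.01) {
  mode <- match.arg(mode)
  structure(list(experiment_id = experiment_id, mode = mode,
                 prop_cases = prop_cases, cohort_size = as.integer(cohort_size),
                 pct_protective = pct_protective, pct_causal = pct_causal,
                 variant_mode = variant_mode,
                 causal_maf_cutoff = causal_maf_cutoff,
                 region_size = region_size, replicates = as.integer(replicates),
                 prevalence = prevalence),
            class = "experiment_config")
}

#' The benchmark experiment grid
#'
#' Nine type-I-error presets (\code{t1..t9}) and eighteen empirical-power
#' presets (\code{p1..p18}), reconstructed from the published scenario
#' groupings around a baseline of balanced cohorts, prevalence 1\% and 3 kb
#' regions. The null scenarios vary case proportion (t1-t3), cohort size
#' (t4-t6 around the t1 baseline of 500), inclusion of common variants (t7)
#' and region size (t8, t9). The power scenarios vary MAF cutoff (p1 vs
#' p11), percentage causal (p2-p5), cohort size (p6-p9), common-variant
#' inclusion (p10 vs p18), proportion protective (p11-p13), case proportion
#' (p14, p15) and region size (p16, p17). The grid is a plain list and can
#' be edited before running.
#'
#' @param replicates_null,replicates_power Replicates per preset.
#' @return Named list of \code{\link{experiment_config}} objects.
#' @export
experiment_grid <- function(replicates_null = 10000L,
                            replicates_power = 1000L) {
  ec <- function(id, mode, prop, n, prot, caus, vmode, cutoff, region) {
    reps <- if (mode == "null") replicates_null else replicates_power
    experiment_config(id, mode, prop, n, prot, caus, vmode, cutoff, region,
                      replicates = reps)
  }
  grid <- list(
    ## type I error: baseline t1 = (0.5, 500, rare-only@0.01, 3 kb)
    ec("t1", "null", 0.5, 500,  0, 0, "rare_only",       0.01, 3000),
    ec("t2", "null", 0.2, 500,  0, 0, "rare_only",       0.01, 3000),
    ec("t3", "null", 0.8, 500,  0, 0, "rare_only",       0.01, 3000),
    ec("t4", "null", 0.5, 100,  0, 0, "rare_only",       0.01, 3000),
    ec("t5", "null", 0.5, 1000, 0, 0, "rare_only",       0.01, 3000),
    ec("t6", "null", 0.5, 5000, 0, 0, "rare_only",       0.01, 3000),
    ec("t7", "null", 0.5, 500,  0, 0, "rare_and_common", 0.01, 3000),
    ec("t8", "null", 0.5, 500,  0, 0, "rare_only",       0.01, 1000),
    ec("t9", "null", 0.5, 500,  0, 0, "rare_only",       0.01, 5000),
    ## empirical power
    ec("p1",  "power", 0.5, 1000, 5,  20, "rare_only",       0.01, 3000),
    ec("p2",  "power", 0.5, 1000, 0,  1,  "rare_only",       0.01, 3000),
    ec("p3",  "power", 0.5, 1000, 0,  5,  "rare_only",       0.01, 3000),
    ec("p4",  "power", 0.5, 1000, 0,  10, "rare_only",       0.01, 3000),
    ec("p5",  "power", 0.5, 1000, 0,  20, "rare_only",       0.01, 3000),
    ec("p6",  "power", 0.5, 100,  5,  5,  "rare_only",       0.01, 3000),
    ec("p7",  "power", 0.5, 500,  5,  5,  "rare_only",       0.01, 3000),
    ec("p8",  "power", 0.5, 1000, 5,  5,  "rare_only",       0.01, 3000),
    ec("p9",  "power", 0.5, 5000, 5,  5,  "rare_only",       0.01, 3000),
    ec("p10", "power", 0.5, 1000, 5,  20, "rare_and_common", 0.01, 5000),
    ec("p11", "power", 0.5, 1000, 5,  20, "rare_only",       0.03, 3000),
    ec("p12", "power", 0.5, 1000, 10, 20, "rare_only",       0.03, 3000),
    ec("p13", "power", 0.5, 1000, 20, 20, "rare_only",       0.03, 3000),
    ec("p14", "power", 0.2, 1000, 5,  20, "rare_only",       0.03, 3000),
    ec("p15", "power", 0.8, 1000, 5,  20, "rare_only",       0.03, 3000),
    ec("p16", "power", 0.5, 1000, 5,  5,  "rare_only",       0.03, 5000),
    ec("p17", "power", 0.5, 1000, 5,  5,  "rare_only",       0.03, 3000),
    ec("p18", "power", 0.5, 1000, 5,  20, "rare_only",       0.01, 5000))
  names(grid) <- vapply(grid, `[[`, "", "experiment_id")
  grid
}

#' Run one experiment
#'
#' Per replicate: draw a fresh region (distinct start offset within the
#' experiment), select the analysed variants per the variant mode, sample a
#' case-control cohort from the null or alternative logistic model, and run
#' every registered test through \code{\link{run_test_safe}}. Replicate-level
#' failures (regions without enough variants, exhausted draw budgets) are
#' recorded as NA rows. Deterministic for a fixed seed.
#'
#' @param config An \code{\link{experiment_config}}.
#' @param pool A haplotype pool.
#' @param registry Named list of \code{\link{test_spec}} objects.
#' @param seed Integer seed for the experiment stream.
#' @param region_redraws Redraw budget for degenerate regions per replicate.
#' @param progress Print a progress line every so many replicates
#'   (\code{0} = silent).
#' @return A \code{results_table}: list with \code{pvalues} and
#'   \code{elapsed} (replicates x tests matrices), \code{config}.
#' @export
run_experiment <- function(config, pool, registry = default_registry(),
                           seed = 1L, region_redraws = 20L, progress = 0L) {
  stopifnot(inherits(config, "experiment_config"),
            inherits(pool, "haplotype_pool"))
  rng <- local_rng(seed)
  on.exit(rng$restore(), add = TRUE)
  n_cases <- round(config$cohort_size * config$prop_cases)
  n_controls <- config$cohort_size - n_cases
  beta0 <- solve_intercept(config$prevalence)
  ids <- names(registry)
  P <- matrix(NA_real_, config$replicates, length(ids),
              dimnames = list(NULL, ids))
  E <- matrix(NA_real_, config$replicates, length(ids),
              dimnames = list(NULL, ids))
  exclusions <- numeric(0)
  for (r in seq_len(config$replicates)) {
    dat <- tryCatch(
      simulate_replicate(config, pool, n_cases, n_controls, beta0,
                         exclusions, region_redraws),
      error = function(e) NULL)
    if (is.null(dat)) next  # replicate failure -> NA row
    exclusions <- c(exclusions, dat$start)
    nf <- tryCatch(fit_null_model(dat$phen$y, dat$phen$X),
                   error = function(e) NULL)
    for (k in seq_along(registry)) {
      res <- run_test_safe(registry[[k]], dat$G, dat$phen$y, dat$phen$X,
                           maf = dat$maf, null_fit = nf)
      P[r, k] <- res$pvalue
      E[r, k] <- res$elapsed
    }
    if (progress > 0L && r %% progress == 0L)
      message(sprintf("[%s] replicate %d/%d", config$experiment_id, r,
                      config$replicates))
  }
  structure(list(pvalues = P, elapsed = E, config = config),
            class = "results_table")
}

## One replicate's data: region, analysed variant set, cohort.
simulate_replicate <- function(config, pool, n_cases, n_controls, beta0,
                               exclusions, region_redraws) {
  for (attempt in seq_len(region_redraws)) {
    region <- draw_region(pool, config$region_size, min_variants = 2L,
                          exclusions = exclusions)
    maf_all <- pmin(pool$daf[region$site_indices],
                    1 - pool$daf[region$site_indices])
    keep <- tryCatch(
      select_variants(maf_all, config$causal_maf_cutoff, config$variant_mode),
      error = function(e) NULL)
    if (is.null(keep)) next
    causal <- NULL
    if (config$mode == "power") {
      causal <- tryCatch(
        assign_causal_variants(maf_all, config$pct_causal,
                               config$pct_protective,
                               config$causal_maf_cutoff),
        error = function(e) NULL)
      if (is.null(causal)) next
    }
    cohort <- sample_cohort(pool, region, n_cases, n_controls, beta0,
                            causal = causal)
    G <- cohort$genotypes$G[, keep, drop = FALSE]
    return(list(start = region$start, G = G,
                maf = cohort$genotypes$maf[keep], phen = cohort$phenotypes))
  }
  stop(degenerate_region_error(0L))
}

#' Type I error of each test
#'
#' Number of significant p-values (\code{p <= alpha}) divided by the number
#' of returned (non-NA) p-values. A test with no returned p-values gets NA.
#'
#' @param table A \code{results_table} or a p-value matrix.
#' @param alpha Significance level.
#' @return Named per-test rates.
#' @export
type_i_error <- function(table, alpha = 0.05) {
  P <- pvalue_matrix(table)
  apply(P, 2, function(p) {
    ret <- sum(!is.na(p))
    if (ret == 0L) return(NA_real_)
    sum(p <= alpha, na.rm = TRUE) / ret
  })
}

#' Reliability of each test
#'
#' Fraction of replicates for which the test returned any p-value.
#'
#' @inheritParams type_i_error
#' @return Named per-test fractions in \code{[0, 1]}.
#' @export
reliability <- function(table) {
  P <- pvalue_matrix(table)
  colMeans(!is.na(P))
}

#' Empirical power of each test
#'
#' Number of significant p-values divided by the total number of replicates
#' (an NA counts against power — the deliberate asymmetry with
#' \code{\link{type_i_error}}, whose denominator is returned p-values only).
#'
#' @inheritParams type_i_error
#' @return Named per-test rates.
#' @export
empirical_power <- function(table, alpha = 0.05) {
  P <- pvalue_matrix(table)
  colSums(P <= alpha, na.rm = TRUE) / nrow(P)
}

pvalue_matrix <- function(table) {
  if (inherits(table, "results_table")) table$pvalues
  else as.matrix(table)
}

#' Binomial calibration bounds for an empirical type I error
#'
#' 95\% Wilson score interval for a binomial proportion with the given
#' number of replicates at the nominal level. A test is inflated above the
#' upper bound and conservative below the lower bound.
#'
#' @param alpha Nominal level.
#' @param n_replicates Replicates entering the rate.
#' @param conf Confidence level of the interval (default 0.95).
#' @return A \code{calibration_bounds}: list with \code{alpha},
#'   \code{n_replicates}, \code{lower}, \code{upper}.
#' @export
wilson_bounds <- function(alpha, n_replicates, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- alpha; n <- n_replicates
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  denom <- 1 + z^2 / n
  structure(list(alpha = alpha, n_replicates = n,
                 lower = (centre - half) / denom,
                 upper = (centre + half) / denom),
            class = "calibration_bounds")
}

#' Classify a type I error rate against its calibration bounds
#'
#' @param rate Empirical type I error (may be NA).
#' @param bounds A \code{\link{wilson_bounds}} result.
#' @return \code{"inflated"}, \code{"good"}, \code{"conservative"} or
#'   \code{NA}. "Controlled" means not inflated (good or conservative).
#' @export
classify_type_i <- function(rate, bounds) {
  stopifnot(inherits(bounds, "calibration_bounds"))
  if (length(rate) > 1L)
    return(vapply(rate, classify_type_i, "", bounds = bounds))
  if (is.na(rate)) return(NA_character_)
  if (rate > bounds$upper) "inflated"
  else if (rate < bounds$lower) "conservative"
  else "good"
}

#' Rank tests by power
#'
#' Ranks every column of a power matrix (experiments/alpha combinations in
#' rows, tests in columns): rank 1 is the highest power; ties share the
#' minimum rank.
#'
#' @param power_matrix Numeric matrix, rows = results, columns = tests.
#' @return A list with \code{ranks} (same shape) and \code{summary} (data
#'   frame of average/best/worst rank per test).
#' @export
rank_by_power <- function(power_matrix) {
  power_matrix <- as.matrix(power_matrix)
  if (is.null(colnames(power_matrix)))
    colnames(power_matrix) <- paste0("test", seq_len(ncol(power_matrix)))
  ranks <- t(apply(power_matrix, 1, function(p)
    rank(-p, ties.method = "min", na.last = "keep")))
  if (ncol(power_matrix) == 1L) ranks <- matrix(ranks, ncol = 1L)
  colnames(ranks) <- colnames(power_matrix)
  summary <- data.frame(
    test_id = colnames(power_matrix),
    average_rank = colMeans(ranks, na.rm = TRUE),
    best_rank = suppressWarnings(apply(ranks, 2, min, na.rm = TRUE)),
    worst_rank = suppressWarnings(apply(ranks, 2, max, na.rm = TRUE)),
    row.names = NULL)
  list(ranks = ranks, summary = summary)
}

#' Uniqueness score
#'
#' For each replicate, if exactly one test of the subset is significant,
#' that test's score is incremented. NA p-values are never significant.
#'
#' @inheritParams type_i_error
#' @param subset Character vector of test ids forming the comparison set
#'   (default all columns).
#' @return Named integer counts over the subset.
#' @export
uniqueness_score <- function(table, alpha = 0.05, subset = NULL) {
  P <- pvalue_matrix(table)
  if (!is.null(subset)) P <- P[, subset, drop = FALSE]
  sig <- !is.na(P) & P <= alpha
  lone <- rowSums(sig) == 1L
  counts <- colSums(sig[lone, , drop = FALSE])
  storage.mode(counts) <- "integer"
  counts
}

#' Decision similarity between two tests
#'
#' Fraction of replicates on which both columns make the same significance
#' decision at the given level; an NA p-value counts as a non-significant
#' decision.
#'
#' @param pa,pb P-value vectors of equal length.
#' @param alpha Significance level.
#' @return A proportion in \code{[0, 1]}.
#' @export
decision_similarity <- function(pa, pb, alpha = 0.05) {
  da <- !is.na(pa) & pa <= alpha
  db <- !is.na(pb) & pb <= alpha
  mean(da == db)
}

#' Redundancy count between two tests
#'
#' Number of replicates where both tests returned exactly the same p-value
#' (full floating-point equality; NA-NA pairs are not counted, as no
#' p-value was produced).
#'
#' @inheritParams decision_similarity
#' @return An integer count.
#' @export
redundancy_count <- function(pa, pb) {
  sum(!is.na(pa) & !is.na(pb) & pa == pb)
}

#' Maximum evolution of computational time
#'
#' \code{(max(times) - min(times)) / min(times)}; \code{Inf} when the
#' minimum time is zero. Used as a tie-break when removing redundant tests.
#'
#' @param times Per-dataset elapsed times of one test.
#' @return A non-negative ratio (possibly \code{Inf}).
#' @export
max_evolution <- function(times) {
  times <- times[!is.na(times)]
  if (!length(times)) return(NA_real_)
  mn <- min(times)
  if (mn == 0) return(Inf)
  (max(times) - mn) / mn
}

#' Scenario evolution of a summary along an ordered experiment sequence
#'
#' Consecutive differences of a per-test summary (power or type I error)
#' along a parameter sweep (e.g. cohort 100, 500, 1000, 5000), with their
#' sum ("total evolution") and a direction label.
#'
#' @param values Matrix or data frame, rows = ordered experiments, columns =
#'   tests; or a vector for one test.
#' @return A list with \code{deltas} (one fewer row), \code{total} (per-test
#'   sums) and \code{direction} (\code{"increase"}, \code{"decrease"},
#'   \code{"no change"} per test).
#' @export
scenario_evolution <- function(values) {
  V <- as.matrix(values)
  if (nrow(V) < 2L) stop("need at least two experiments", call. = FALSE)
  deltas <- V[-1L, , drop = FALSE] - V[-nrow(V), , drop = FALSE]
  total <- colSums(deltas)
  direction <- ifelse(total > 0, "increase",
                      ifelse(total < 0, "decrease", "no change"))
  list(deltas = deltas, total = total, direction = direction)
}

#' Long-format export of a results table
#'
#' @param table A \code{results_table}.
#' @param file Optional CSV path; when given the table is written there.
#' @return Data frame (experiment_id, replicate, test_id, pvalue, elapsed).
#' @export
results_to_long <- function(table, file = NULL) {
  stopifnot(inherits(table, "results_table"))
  P <- table$pvalues
  long <- data.frame(
    experiment_id = table$config$experiment_id,
    replicate = rep(seq_len(nrow(P)), times = ncol(P)),
    test_id = rep(colnames(P), each = nrow(P)),
    pvalue = as.vector(P),
    elapsed = as.vector(table$elapsed))
  if (!is.null(file)) utils::write.csv(long, file, row.names = FALSE)
  long
}
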