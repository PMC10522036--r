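## Min-p Bonferroni ensembles and the data-driven construction algorithms.

#' Ensemble p-value: minimum member p-value after Bonferroni correction
#'
#' With \code{k} the number of members that returned a p-value, the ensemble
#' reports \code{min(1, k * min(p))}. Members that failed (NA) do not enter
#' \code{k}, so failures never deflate power; all-NA gives NA.
#'
#' @param pvalues Member p-values (may contain NA).
#' @return A single p-value or NA.
#' @export
ensemble_pvalue <- function(pvalues) {
  if (length(pvalues) == 0L) stop("empty member list", call. = FALSE)
  p <- pvalues[!is.na(pvalues)]
  if (!length(p)) return(NA_real_)
  min(1, length(p) * min(p))
}

#' Apply an ensemble to a results table
#'
#' Computes the per-replicate ensemble p-value over the member columns.
#'
#' @param table A \code{results_table} or p-value matrix.
#' @param members Character vector of member test ids.
#' @return Numeric vector of ensemble p-values, one per replicate.
#' @export
ensemble_apply <- function(table, members) {
  P <- pvalue_matrix(table)
  missing <- setdiff(members, colnames(P))
  if (length(missing))
    stop("members absent from table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  apply(P[, members, drop = FALSE], 1, ensemble_pvalue)
}

new_ensemble_spec <- function(members, algorithm, iterations = list()) {
  if (!length(members)) stop("ensemble has no members", call. = FALSE)
  stopifnot(!anyDuplicated(members))
  structure(list(members = members, algorithm = algorithm,
                 iterations = iterations),
            class = "ensemble_spec")
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat(sprintf("ensemble_spec (%s): %d members\n", x$algorithm,
              length(x$members)))
  cat(" ", paste(x$members, collapse = ", "), "\n")
  invisible(x)
}

#' Baseline ensemble: every registered test
#'
#' @param registry A test registry (named list) or character vector of ids.
#' @return An \code{ensemble_spec} with all tests, order preserved.
#' @export
build_baseline <- function(registry) {
  ids <- if (is.character(registry)) registry else names(registry)
  new_ensemble_spec(ids, "baseline")
}

## Proportion of (experiment x alpha) results in which each test is
## inflated, from a list of null results_tables (or p-value matrices).
proportion_inflated <- function(null_tables, alphas = c(0.05, 0.01, 0.001)) {
  ids <- colnames(pvalue_matrix(null_tables[[1]]))
  flags <- sapply(ids, function(id) 0)
  total <- 0L
  for (tab in null_tables) {
    P <- pvalue_matrix(tab)
    for (a in alphas) {
      rate <- type_i_error(P, a)
      b <- wilson_bounds(a, nrow(P))
      cls <- classify_type_i(rate, b)
      flags <- flags + (!is.na(cls) & cls == "inflated")
      total <- total + 1L
    }
  }
  flags / total
}

## Uniqueness scores summed across all power tables, within the given subset.
total_uniqueness <- function(power_tables, subset, alpha = 0.05) {
  out <- stats::setNames(integer(length(subset)), subset)
  for (tab in power_tables)
    out <- out + uniqueness_score(tab, alpha, subset)
  out
}

## Median reliability of each test across power tables.
median_reliability <- function(power_tables, ids) {
  rel <- sapply(power_tables, function(tab) reliability(tab)[ids])
  if (is.null(dim(rel))) rel <- matrix(rel, nrow = length(ids))
  apply(rel, 1, stats::median)
}

#' Build the well-calibrated ensemble
#'
#' Three-step filter over the full registry: (1) keep tests whose proportion
#' of inflated type-I-error results is exactly zero across all null
#' experiments and levels; (2) within the survivors, drop tests whose
#' uniqueness score across all power simulations is zero (they are never the
#' only significant test); (3) drop tests with median reliability at or
#' below the threshold.
#'
#' @param null_tables List of null-experiment \code{results_table}s (or
#'   p-value matrices).
#' @param power_tables List of power-experiment tables.
#' @param alphas Levels entering the inflation assessment.
#' @param alpha_power Level for uniqueness scores.
#' @param reliability_threshold Median reliability kept must exceed this
#'   (default 0.9).
#' @return An \code{ensemble_spec} with an iteration log of every drop.
#' @export
build_good_type1 <- function(null_tables, power_tables,
                             alphas = c(0.05, 0.01, 0.001),
                             alpha_power = 0.05,
                             reliability_threshold = 0.9) {
  ids <- colnames(pvalue_matrix(null_tables[[1]]))
  log <- list()
  prop_inf <- proportion_inflated(null_tables, alphas)
  set_b <- ids[prop_inf[ids] == 0]
  log$inflated_dropped <- setdiff(ids, set_b)
  if (!length(set_b)) stop("no test controls type I error", call. = FALSE)
  score <- total_uniqueness(power_tables, set_b, alpha_power)
  set_c <- set_b[score[set_b] > 0]
  log$zero_score_dropped <- setdiff(set_b, set_c)
  if (!length(set_c)) stop("all candidate scores are zero", call. = FALSE)
  med_rel <- median_reliability(power_tables, set_c)
  keep <- set_c[med_rel > reliability_threshold]
  log$low_reliability_dropped <- setdiff(set_c, keep)
  if (!length(keep)) stop("no test passes the reliability filter", call. = FALSE)
  new_ensemble_spec(keep, "good_type1",
                    c(log, list(scores = score, prop_inflated = prop_inf)))
}

## Shared stopping rule of the two greedy expansions: the candidate set is
## accepted only while the candidates-ensemble itself is never inflated.
ensemble_is_clean <- function(candidates, null_tables,
                              alphas = c(0.05, 0.01, 0.001)) {
  for (tab in null_tables) {
    P <- pvalue_matrix(tab)
    ep <- ensemble_apply(P, candidates)
    for (a in alphas) {
      rate <- type_i_error(matrix(ep, ncol = 1L), a)
      b <- wilson_bounds(a, nrow(P))
      cls <- classify_type_i(rate, b)
      if (!is.na(cls) && cls == "inflated") return(FALSE)
    }
  }
  TRUE
}

#' Greedily expand an ensemble by uniqueness score
#'
#' Starting from a seed ensemble, repeatedly: restrict the remaining pool to
#' the tests minimising the proportion of inflated type-I-error results
#' (Set B); compute uniqueness scores within Set B across all power
#' simulations; add the highest-scoring test(s) (ties all added) to the
#' candidates; recompute the candidates-ensemble type I error over all null
#' experiments. While the ensemble's proportion of inflated results stays
#' zero the loop continues; the first inflating addition is rolled back and
#' the previous candidate set is returned. An exhausted pool returns all
#' candidates with a completion flag.
#'
#' @param seed_ensemble An \code{ensemble_spec} or character vector of ids.
#' @param pool_ids Remaining candidate test ids.
#' @param null_tables,power_tables Experiment tables as in
#'   \code{\link{build_good_type1}}.
#' @param alphas,alpha_power Levels, as in \code{\link{build_good_type1}}.
#' @return An \code{ensemble_spec}; the iteration log records each loop's
#'   Set B, scores, additions and inflation-check outcome.
#' @export
build_greedy_uniqueness <- function(seed_ensemble, pool_ids, null_tables,
                                    power_tables,
                                    alphas = c(0.05, 0.01, 0.001),
                                    alpha_power = 0.05) {
  candidates <- if (inherits(seed_ensemble, "ensemble_spec"))
    seed_ensemble$members else seed_ensemble
  pool <- setdiff(pool_ids, candidates)
  prop_inf <- proportion_inflated(null_tables, alphas)
  iterations <- list()
  exhausted <- FALSE
  repeat {
    if (!length(pool)) { exhausted <- TRUE; break }
    set_b <- pool[prop_inf[pool] == min(prop_inf[pool])]
    score <- total_uniqueness(power_tables, set_b, alpha_power)
    added <- set_b[score == max(score)]
    trial <- c(candidates, added)
    clean <- ensemble_is_clean(trial, null_tables, alphas)
    iterations[[length(iterations) + 1L]] <-
      list(set_b = set_b, scores = score, added = added, clean = clean)
    if (!clean) break  # roll back the last addition
    candidates <- trial
    pool <- setdiff(pool, added)
  }
  new_ensemble_spec(candidates, "greedy_uniqueness",
                    c(iterations, list(pool_exhausted = exhausted)))
}

#' Greedily expand an ensemble by combined rank
#'
#' The orthogonal expansion: over the whole remaining pool, tests are ranked
#' by decreasing uniqueness score (rank 1 = highest) and by increasing
#' proportion of inflated results (rank 1 = smallest); the test(s) with the
#' minimum combined (summed) rank are added. The stopping rule is the same
#' roll-back-on-inflation check as \code{\link{build_greedy_uniqueness}}.
#'
#' @inheritParams build_greedy_uniqueness
#' @return An \code{ensemble_spec}.
#' @export
build_combined_rank <- function(seed_ensemble, pool_ids, null_tables,
                                power_tables,
                                alphas = c(0.05, 0.01, 0.001),
                                alpha_power = 0.05) {
  candidates <- if (inherits(seed_ensemble, "ensemble_spec"))
    seed_ensemble$members else seed_ensemble
  pool <- setdiff(pool_ids, candidates)
  prop_inf <- proportion_inflated(null_tables, alphas)
  iterations <- list()
  exhausted <- FALSE
  repeat {
    if (!length(pool)) { exhausted <- TRUE; break }
    score <- total_uniqueness(power_tables, pool, alpha_power)
    rank_score <- rank(-score[pool], ties.method = "min")
    rank_t1 <- rank(prop_inf[pool], ties.method = "min")
    combined <- rank_score + rank_t1
    added <- pool[combined == min(combined)]
    trial <- c(candidates, added)
    clean <- ensemble_is_clean(trial, null_tables, alphas)
    iterations[[length(iterations) + 1L]] <-
      list(scores = score, combined_rank = combined, added = added,
           clean = clean)
    if (!clean) break
    candidates <- trial
    pool <- setdiff(pool, added)
  }
  new_ensemble_spec(candidates, "combined_rank",
                    c(iterations, list(pool_exhausted = exhausted)))
}

#' Preliminary computational filtering of a registry
#'
#' The four-step scalability filter applied before any ensemble is built:
#' (1) drop tests whose mean or maximum per-call time exceeds the caps, and
#' tests that never return a p-value; (2) among pairs that are redundant
#' (at least one exactly equal returned p-value over shared analyses), keep
#' the member with the smaller maximum time evolution; (3) re-apply the time
#' caps on scaled datasets; (4) re-check redundancy on power-simulation
#' p-values. Caps are configurable because they are hardware-dependent.
#'
#' @param pvalues P-value matrix (analyses x tests) from the screening runs.
#' @param elapsed Matching elapsed-time matrix.
#' @param scaled_elapsed Optional elapsed matrix from the scaled datasets
#'   (step 3); \code{NULL} skips the step.
#' @param power_pvalues Optional p-value matrix from power simulations
#'   (step 4); \code{NULL} skips the step.
#' @param mean_cap,max_cap Time caps in seconds (defaults 10).
#' @param evol_cap Maximum allowed time evolution in step 3 (default 10).
#' @return A list with \code{retained} (test ids) and \code{removals}
#'   (data frame: test_id, step, reason).
#' @export
preliminary_filter <- function(pvalues, elapsed, scaled_elapsed = NULL,
                               power_pvalues = NULL, mean_cap = 10,
                               max_cap = 10, evol_cap = 10) {
  pvalues <- as.matrix(pvalues); elapsed <- as.matrix(elapsed)
  ids <- colnames(pvalues)
  removals <- data.frame(test_id = character(), step = character(),
                         reason = character())
  drop <- function(id, step, reason) {
    removals[nrow(removals) + 1L, ] <<- list(id, step, reason)
  }
  retained <- ids
  for (id in ids) {
    tm <- elapsed[, id]
    if (mean(tm, na.rm = TRUE) > mean_cap)
      drop(id, "1.A", "mean time above cap")
    else if (max(tm, na.rm = TRUE) > max_cap)
      drop(id, "1.B", "max time above cap")
    else if (all(is.na(pvalues[, id])))
      drop(id, "1.C", "never returns a p-value")
  }
  retained <- setdiff(retained, removals$test_id)

  prune_redundant <- function(retained, P, step) {
    repeat {
      dropped_any <- FALSE
      for (i in seq_along(retained)) {
        for (j in seq_along(retained)) {
          if (j <= i) next
          a <- retained[i]; b <- retained[j]
          if (redundancy_count(P[, a], P[, b]) > 0) {
            ev_a <- max_evolution(elapsed[, a])
            ev_b <- max_evolution(elapsed[, b])
            loser <- if (ev_a <= ev_b) b else a
            drop(loser, step, sprintf("redundant with %s",
                                      if (loser == a) b else a))
            retained <- setdiff(retained, loser)
            dropped_any <- TRUE
            break
          }
        }
        if (dropped_any) break
      }
      if (!dropped_any) return(retained)
    }
  }
  retained <- prune_redundant(retained, pvalues, "2")

  if (!is.null(scaled_elapsed)) {
    scaled_elapsed <- as.matrix(scaled_elapsed)
    for (id in intersect(retained, colnames(scaled_elapsed))) {
      tm <- scaled_elapsed[, id]
      if (max(tm, na.rm = TRUE) > max_cap &&
          max_evolution(tm) > evol_cap)
        drop(id, "3", "slow and badly scaling on larger datasets")
    }
    retained <- setdiff(retained, removals$test_id)
  }
  if (!is.null(power_pvalues)) {
    power_pvalues <- as.matrix(power_pvalues)
    keep <- intersect(retained, colnames(power_pvalues))
    retained <- c(setdiff(retained, keep),
                  prune_redundant(keep, power_pvalues, "4"))
  }
  list(retained = retained, removals = removals)
}
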