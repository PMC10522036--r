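# Shared fixtures and independent oracles for the suite. Oracles are kept
# as plain loops so that they exercise the definitions, not the package's
# code paths.

# A moderate pool shared across test files (built once per run).
.fixture_env <- new.env()
fixture_pool <- function() {
  if (is.null(.fixture_env$pool))
    .fixture_env$pool <- generate_haplotype_pool(2000, 2e5, 4000, seed = 101)
  .fixture_env$pool
}

# One simulated dataset (genotypes restricted to rare variants + phenotypes)
# from the shared pool.
fixture_dataset <- function(n_cases = 100, n_controls = 100, seed = 1,
                            causal = NULL, cutoff = 0.01) {
  pool <- fixture_pool()
  set.seed(seed)
  b0 <- solve_intercept(0.01)
  repeat {
    region <- draw_region(pool, 3000)
    mafs <- pmin(pool$daf[region$site_indices],
                 1 - pool$daf[region$site_indices])
    keep <- tryCatch(select_variants(mafs, cutoff), error = function(e) NULL)
    if (!is.null(keep)) break
  }
  cm <- NULL
  if (!is.null(causal))
    cm <- assign_causal_variants(mafs, causal$pct_causal,
                                 causal$pct_protective, cutoff)
  coh <- sample_cohort(pool, region, n_cases, n_controls, b0, causal = cm)
  list(G = coh$genotypes$G[, keep, drop = FALSE],
       maf = coh$genotypes$maf[keep],
       y = coh$phenotypes$y, X = coh$phenotypes$X)
}

# ---------------------------------------------------------------------------
# Hand-built 6-test fixture for the ensemble-construction algorithms.
# Two null experiments (100 replicates each) and two power experiments
# (50 replicates each), engineered so every construction step is exercised:
#   A: calibrated, unique power rows          -> kept everywhere
#   B: inflated in null experiment 1          -> dropped at step 1
#   C: individually calibrated but its null hits are disjoint from the
#      others, so adding it inflates the ensemble; low reliability
#   D: significant only alongside A (uniqueness 0 in the full set) but
#      unique within {C, D}
#   E, F: calibrated with unique power rows (F conservative under the null)
fixture_tables <- function() {
  ids <- c("A", "B", "C", "D", "E", "F")
  sig <- 0.001; ns <- 0.5
  mk <- function(n) matrix(ns, n, 6, dimnames = list(NULL, ids))

  N1 <- mk(100)
  N1[1:5, c("A", "E")] <- sig
  N1[1:4, "D"] <- sig
  N1[1:20, "B"] <- sig          # 20% > Wilson upper (0.1117) -> inflated
  N1[1:5, "C"] <- sig
  N2 <- mk(100)
  N2[1:5, c("A", "B", "E")] <- sig
  N2[1:4, "D"] <- sig
  N2[11:21, "C"] <- sig         # 11% individually fine, inflates the ensemble

  P1 <- mk(50)
  P1[1:3, "A"] <- sig           # A unique x3
  P1[4:7, "E"] <- sig           # E unique x4
  P1[8, "F"] <- sig             # F unique x1
  P1[9:14, c("A", "D")] <- sig  # D never unique in the full set
  P1[21:23, "C"] <- sig         # C unique x3
  P1[24:50, "C"] <- NA          # C reliability 23/50 in this experiment
  P2 <- mk(50)
  P2[1:2, "A"] <- sig
  P2[3, "E"] <- sig

  list(ids = ids, null = list(N1, N2), power = list(P1, P2))
}

# ---------------------------------------------------------------------------
# Independent re-implementations of the benchmark definitions (plain loops).

oracle_wilson <- function(alpha, n) {
  # Wilson score interval through prop.test (continuity correction off)
  stats::prop.test(round(alpha * n), n, correct = FALSE)$conf.int
}

oracle_rate <- function(p, alpha) {
  returned <- p[!is.na(p)]
  if (!length(returned)) return(NA_real_)
  sum(returned <= alpha) / length(returned)
}

oracle_inflated <- function(p, alpha) {
  up <- oracle_wilson(alpha, length(p))[2]
  r <- oracle_rate(p, alpha)
  !is.na(r) && r > up
}

oracle_prop_inflated <- function(null_list, ids, alphas) {
  out <- numeric(length(ids)); names(out) <- ids
  for (id in ids) {
    n_inf <- 0; n_tot <- 0
    for (N in null_list) for (a in alphas) {
      n_tot <- n_tot + 1
      if (oracle_inflated(N[, id], a)) n_inf <- n_inf + 1
    }
    out[id] <- n_inf / n_tot
  }
  out
}

oracle_uniqueness <- function(power_list, subset, alpha) {
  out <- integer(length(subset)); names(out) <- subset
  for (P in power_list) for (r in seq_len(nrow(P))) {
    hits <- character()
    for (id in subset) {
      p <- P[r, id]
      if (!is.na(p) && p <= alpha) hits <- c(hits, id)
    }
    if (length(hits) == 1L) out[hits] <- out[hits] + 1L
  }
  out
}

oracle_ensemble_p <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) return(NA_real_)
  min(1, length(p) * min(p))
}

oracle_ensemble_clean <- function(members, null_list, alphas) {
  for (N in null_list) {
    ep <- numeric(nrow(N))
    for (r in seq_len(nrow(N))) ep[r] <- oracle_ensemble_p(N[r, members])
    for (a in alphas) if (oracle_inflated(ep, a)) return(FALSE)
  }
  TRUE
}

oracle_good_type1 <- function(fix, alphas = 0.05, alpha_power = 0.05,
                              rel_thr = 0.9) {
  prop_inf <- oracle_prop_inflated(fix$null, fix$ids, alphas)
  set_b <- fix$ids[prop_inf == 0]
  score <- oracle_uniqueness(fix$power, set_b, alpha_power)
  set_c <- set_b[score[set_b] > 0]
  med_rel <- sapply(set_c, function(id)
    stats::median(sapply(fix$power, function(P) mean(!is.na(P[, id])))))
  set_c[med_rel > rel_thr]
}

oracle_greedy <- function(seed_ids, fix, alphas = 0.05, alpha_power = 0.05) {
  members <- seed_ids
  pool <- setdiff(fix$ids, members)
  prop_inf <- oracle_prop_inflated(fix$null, fix$ids, alphas)
  trace <- list()
  while (length(pool)) {
    set_b <- pool[prop_inf[pool] == min(prop_inf[pool])]
    score <- oracle_uniqueness(fix$power, set_b, alpha_power)
    added <- set_b[score == max(score)]
    ok <- oracle_ensemble_clean(c(members, added), fix$null, alphas)
    trace[[length(trace) + 1L]] <- list(added = added, clean = ok)
    if (!ok) break
    members <- c(members, added)
    pool <- setdiff(pool, added)
  }
  list(members = members, trace = trace)
}

oracle_combined_rank <- function(seed_ids, fix, alphas = 0.05,
                                 alpha_power = 0.05) {
  members <- seed_ids
  pool <- setdiff(fix$ids, members)
  prop_inf <- oracle_prop_inflated(fix$null, fix$ids, alphas)
  trace <- list()
  while (length(pool)) {
    score <- oracle_uniqueness(fix$power, pool, alpha_power)
    r_score <- rank(-score[pool], ties.method = "min")
    r_t1 <- rank(prop_inf[pool], ties.method = "min")
    combined <- r_score + r_t1
    added <- pool[combined == min(combined)]
    ok <- oracle_ensemble_clean(c(members, added), fix$null, alphas)
    trace[[length(trace) + 1L]] <- list(added = added, clean = ok)
    if (!ok) break
    members <- c(members, added)
    pool <- setdiff(pool, added)
  }
  list(members = members, trace = trace)
}
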