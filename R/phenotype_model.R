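#' Solve the logistic intercept for a target disease prevalence
#'
#' Finds \eqn{\beta_0} such that the marginal disease probability under the
#' generating model \eqn{logit^{-1}(\beta_0 + a_1 X_1 + a_2 X_2)} equals the
#' target prevalence, where \eqn{X_1 \sim N(0,1)} and
#' \eqn{X_2 \sim Bernoulli(0.5)}. The expectation over \eqn{X_1} is taken by
#' Gauss-Hermite-style quadrature on a fine normal grid; the root is found by
#' \code{uniroot} (the map is strictly monotone in \eqn{\beta_0}).
#'
#' @param prevalence Target marginal disease probability in (0, 1).
#' @param covariate_coefs Length-2 numeric, coefficients of the continuous and
#'   the binary covariate (defaults \code{c(0.5, 0.5)}).
#' @param mode \code{"marginal"} solves the expectation above;
#'   \code{"logit"} simply returns \code{qlogis(prevalence)}.
#' @return The intercept \eqn{\beta_0} (log-odds scale); achieved marginal
#'   prevalence is within 1e-6 of the target.
#' @export
solve_intercept <- function(prevalence, covariate_coefs = c(0.5, 0.5),
                            mode = c("marginal", "logit")) {
  mode <- match.arg(mode)
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must be in (0, 1)", call. = FALSE)
  if (mode == "logit") return(stats::qlogis(prevalence))
  a1 <- covariate_coefs[1]; a2 <- covariate_coefs[2]
  ## quadrature nodes for E over N(0,1): midpoint rule on probability scale
  pr <- (seq_len(2000L) - 0.5) / 2000L
  z <- stats::qnorm(pr)
  marginal <- function(b0) {
    0.5 * mean(stats::plogis(b0 + a1 * z)) +
      0.5 * mean(stats::plogis(b0 + a1 * z + a2)) - prevalence
  }
  stats::uniroot(marginal, lower = -50, upper = 50, tol = 1e-10)$root
}

#' Per-variant effect magnitude from minor-allele frequency
#'
#' Rarer variants receive larger effects:
#' \eqn{|\beta_j| = c\,|\log_{10}(MAF_j)| / 2}, so a variant with MAF 1e-4
#' gets exactly twice the effect of one with MAF 1e-2.
#'
#' @param maf Minor-allele frequency in (0, 0.5].
#' @param c Effect-size scale constant (see \code{\link{scale_constant}}).
#' @param base Logarithm base (default 10, the convention of the
#'   case-control simulation literature this design follows).
#' @return Non-negative effect magnitude, strictly decreasing in MAF.
#' @export
effect_size <- function(maf, c, base = 10) {
  if (any(maf <= 0) || any(maf > 0.5))
    stop("maf must be in (0, 0.5]", call. = FALSE)
  c * abs(log(maf, base = base)) / 2
}

#' Effect-size scale constant for a causal percentage
#'
#' The scale constant shrinks as the percentage of causal variants grows:
#' \code{ln(5)/4} at 20\%, \code{ln(7)/4} at 10\%, \code{ln(13)/4} at 5\%.
#' No value is defined at 1\% by the experiment design; the default there is
#' \code{ln(13)/4} (the largest stated value), overridable via
#' \code{c_at_1pct}.
#'
#' @param pct_causal One of 1, 5, 10, 20.
#' @param c_at_1pct Value returned at 1\% causal.
#' @return The scale constant \code{c}.
#' @export
scale_constant <- function(pct_causal, c_at_1pct = log(13) / 4) {
  switch(as.character(pct_causal),
         "20" = log(5) / 4,
         "10" = log(7) / 4,
         "5"  = log(13) / 4,
         "1"  = c_at_1pct,
         stop("pct_causal must be one of 1, 5, 10, 20", call. = FALSE))
}

#' Assign causal variants and effect directions
#'
#' Chooses \code{m_c = max(min_causal, round(pct_causal/100 * n_eligible))}
#' causal variants uniformly without replacement among variants with
#' MAF below the cutoff, and marks
#' \code{round(pct_protective/100 * m_c)} of them (chosen uniformly) as
#' protective (sign -1).
#'
#' @param mafs Per-variant minor-allele frequencies.
#' @param pct_causal Percentage of eligible variants made causal.
#' @param pct_protective Percentage of causal variants with protective effect.
#' @param cutoff Causal MAF cutoff.
#' @param min_causal Minimum causal count (default 1).
#' @param c Effect-size scale constant; default derived from
#'   \code{pct_causal} via \code{\link{scale_constant}}.
#' @return A \code{causal_model}: list with \code{causal_indices},
#'   \code{signs}, \code{betas} (magnitudes), \code{c} and the calling
#'   percentages.
#' @export
assign_causal_variants <- function(mafs, pct_causal, pct_protective = 0,
                                   cutoff = 0.01, min_causal = 1L,
                                   c = scale_constant(pct_causal)) {
  eligible <- which(mafs < cutoff)
  m_c <- max(min_causal, round(pct_causal / 100 * length(eligible)))
  if (length(eligible) < m_c) stop(degenerate_region_error(length(eligible)))
  causal <- sort(sample(eligible, m_c))
  n_prot <- round(pct_protective / 100 * m_c)
  signs <- rep(1, m_c)
  if (n_prot > 0) signs[sample.int(m_c, n_prot)] <- -1
  structure(list(causal_indices = causal, signs = signs,
                 betas = effect_size(mafs[causal], c), c = c,
                 pct_causal = pct_causal, pct_protective = pct_protective,
                 causal_maf_cutoff = cutoff),
            class = "causal_model")
}

#' Sample a case-control cohort from the null or alternative logistic model
#'
#' Individuals are generated as a pair of pool haplotypes plus the two
#' covariates \eqn{X_1 \sim N(0,1)} and \eqn{X_2 \sim Bernoulli(0.5)};
#' disease status is Bernoulli with probability
#' \eqn{logit^{-1}(\beta_0 + 0.5X_1 + 0.5X_2 + \sum_j \beta_j G_{ij})}
#' (the genotype term being zero under the null). Sampling is retrospective:
#' the population is drawn until both the case and the control quota are
#' filled, the standard draw-until-quota rejection scheme for case-control
#' ascertainment.
#'
#' @param pool Haplotype pool.
#' @param region A \code{\link{draw_region}} result.
#' @param n_cases,n_controls Quotas (each >= 1).
#' @param beta0 Logistic intercept (see \code{\link{solve_intercept}}).
#' @param causal Optional \code{causal_model}; \code{NULL} gives the null
#'   model. Causal indices refer to columns of the region's variant set.
#' @param covariate_coefs Generating coefficients for \eqn{X_1, X_2}.
#' @param max_draws Total population draw budget before failing.
#' @return A list with \code{genotypes} (a \code{genotype_matrix} over all
#'   region variants) and \code{phenotypes} (a \code{phenotype_set}: \code{y},
#'   \code{X} two-column covariate matrix, \code{n_cases}, \code{n_controls},
#'   \code{beta0}).
#' @export
sample_cohort <- function(pool, region, n_cases, n_controls, beta0,
                          causal = NULL, covariate_coefs = c(0.5, 0.5),
                          max_draws = 1e6) {
  stopifnot(n_cases >= 1L, n_controls >= 1L)
  H <- region_haplotypes(pool, region)
  daf <- pool$daf[region$site_indices]
  flip <- daf > 0.5
  if (any(flip)) H[, flip] <- 1 - H[, flip]

  beta_vec <- numeric(ncol(H))
  if (!is.null(causal))
    beta_vec[causal$causal_indices] <- causal$signs * causal$betas
  has_geno_effect <- any(beta_vec != 0)

  prev_guess <- stats::plogis(beta0 + 0.25)  # rough acceptance rate for cases
  batch <- max(2000L, ceiling(1.5 * max(n_cases / prev_guess,
                                        n_controls / (1 - prev_guess))))
  acc <- list()
  got_case <- 0L; got_ctrl <- 0L; drawn <- 0
  while ((got_case < n_cases || got_ctrl < n_controls) && drawn < max_draws) {
    nb <- as.integer(min(batch, max_draws - drawn)); drawn <- drawn + nb
    x1 <- stats::rnorm(nb)
    x2 <- stats::rbinom(nb, 1L, 0.5)
    h1 <- sample.int(pool$n_hap, nb, replace = TRUE)
    h2 <- sample.int(pool$n_hap - 1L, nb, replace = TRUE)
    h2 <- h2 + (h2 >= h1)  # distinct pair within an individual
    lp <- beta0 + covariate_coefs[1] * x1 + covariate_coefs[2] * x2
    if (has_geno_effect) {
      Gb <- H[h1, , drop = FALSE] + H[h2, , drop = FALSE]
      lp <- lp + drop(Gb %*% beta_vec)
    }
    y <- stats::rbinom(nb, 1L, stats::plogis(lp))
    need_case <- which(y == 1L)[seq_len(min(sum(y), n_cases - got_case))]
    need_ctrl <- which(y == 0L)[seq_len(min(sum(1L - y), n_controls - got_ctrl))]
    keep <- c(need_case, need_ctrl)
    if (length(keep)) {
      Gk <- if (has_geno_effect) Gb[keep, , drop = FALSE]
            else H[h1[keep], , drop = FALSE] + H[h2[keep], , drop = FALSE]
      rec <- list(G = Gk, x1 = x1[keep], x2 = x2[keep],
                  is_case = rep(c(TRUE, FALSE),
                                c(length(need_case), length(need_ctrl))))
      acc[[length(acc) + 1L]] <- rec
      got_case <- got_case + length(need_case)
      got_ctrl <- got_ctrl + length(need_ctrl)
    }
  }
  if (got_case < n_cases || got_ctrl < n_controls)
    stop("draw budget exhausted before filling case/control quotas",
         call. = FALSE)
  G <- do.call(rbind, lapply(acc, `[[`, "G"))
  x1 <- unlist(lapply(acc, `[[`, "x1"))
  x2 <- unlist(lapply(acc, `[[`, "x2"))
  is_case <- unlist(lapply(acc, `[[`, "is_case"))
  ord <- order(!is_case)  # cases first, stable
  G <- G[ord, , drop = FALSE]
  phen <- structure(list(y = as.integer(is_case[ord]),
                         X = cbind(X1 = x1[ord], X2 = x2[ord]),
                         n_cases = as.integer(n_cases),
                         n_controls = as.integer(n_controls),
                         beta0 = beta0),
                    class = "phenotype_set")
  gm <- new_genotype_matrix(G, maf = pmin(daf, 1 - daf),
                            positions = pool$positions[region$site_indices])
  list(genotypes = gm, phenotypes = phen)
}

#' @export
print.phenotype_set <- function(x, ...) {
  cat(sprintf("phenotype_set: %d cases / %d controls, beta0 = %.3f\n",
              x$n_cases, x$n_controls, x$beta0))
  invisible(x)
}

#' Export phenotypes and covariates as a delimited table
#'
#' Writes a tab-delimited table with header \code{id, phenotype} followed by
#' one column per covariate, compatible with \code{\link{load_phenotypes}}.
#'
#' @param phen A \code{phenotype_set}.
#' @param file Output path.
#' @param ids Sample identifiers (default \code{S1..Sn}).
#' @return The path, invisibly.
#' @export
write_phenotypes <- function(phen, file, ids = NULL) {
  n <- length(phen$y)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  df <- data.frame(id = ids, phenotype = phen$y, phen$X,
                   check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
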