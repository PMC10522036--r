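---
title: "Models, simulation design and numerical choices in rvensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, simulation design and numerical choices in rvensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it implements:
the association models, the simulation design behind the benchmark, the
ensemble-construction algorithms, and the numerical decisions a maintainer
would want written down.

## 1. The association model

For a region of `m` variants genotyped in `n` individuals, `G[i, j]` counts
copies of the *minor* allele (0/1/2), `y` is a binary phenotype and `X`
holds covariates. All tests address the logistic model

    logit P(y_i = 1) = beta0 + alpha' X_i + beta' G_i

with the null hypothesis `beta = 0`. Score-type members (burden score, CMC,
SSU/SSUw, SKAT, SKAT-O and their moment-adjusted versions) fit the null
model `y ~ 1 + X` once by IRLS (`stats::glm.fit`, gradient tolerance 1e-10,
25 iterations) and share that fit; CAST, the weighted-sum test, C-alpha and
the fixed-threshold burdens ignore covariates, as their original
formulations do. This per-test covariate behaviour is recorded in the
registry (`list_tests()`).

Weighted members use the Beta(1, 25) density in MAF as their default weight
(`beta_maf_weights`), the standard sharp up-weighting of rarer variants.
In simulation the MAF entering weights and thresholds is the *pool*
frequency carried by the genotype matrix; in application mode it is the
observed sample frequency — the distinction matters for singletons.

## 2. Quadratic-form p-values

SKAT-type statistics are quadratic forms whose null law is a mixture
`sum_k lambda_k * chi2_1`. `davies_pvalue()` inverts the characteristic
function in Imhof's form with `stats::integrate` on `[0, Inf)` (default
absolute target 1e-9, relative 1e-6). Results are flagged non-converged
when the integrator's error estimate exceeds `max(accuracy, 5e-5)` — a
practical threshold far below any tolerance used for decisions — or when
the value leaves `[0, 1]` by more than the error budget; `quadform_pvalue()`
then falls back to the Liu moment-matched approximation and records which
branch fired. Eigenvalues below `1e-10 * lambda_max` are truncated as
numerical noise of the projected kernels. `liu_pvalue()` uses the classic
skewness-matched parameters, which track the inversion more closely in the
upper tail than the kurtosis-matched variant; the kurtosis-matched
parameters are kept for the SKAT-O internals below, whose construction
expects them. Both are exact when all eigenvalues are equal.

SKAT-O evaluates `Q_rho = (1 - rho) * Q_SKAT + rho * Q_burden` on the grid
`rho in {0, 0.1^2, ..., 0.9^2, 1}`, takes the minimum per-rho p-value
(each by Davies), and integrates the one-dimensional mixture
representation over the shared burden factor. The integrand's conditional
CDF uses the moment-matched chi-square (with the variance deflated by the
mixed term, `sqrt(VarQ - VarRemain) / sqrt(VarQ)`) rather than a Davies
call per quadrature point: the moment form is vectorisable, numerically
robust for the small kernels typical of 1–5 kb regions, and its accuracy
is checked in the suite against the exact single-element-grid reductions
(grid `{0}` must equal SKAT and grid `{1}` the weighted burden test to
1e-6, which the implementation achieves analytically because a
single-eigenvalue Davies call collapses to `pchisq`). `rho = 1` enters the
minimisation as 0.999, the usual continuity device. If the integral fails,
the Bonferroni bound over the grid is returned with a warning.

The moment-adjusted members (`skat_binary_adjusted`, registry ids
`robust_skat`/`robust_skato`) estimate the null variance and kurtosis of Q
by parametric resampling of the binary outcome from the fitted
probabilities (default 2000 resamples, minimum 100). The resampled
residuals are projected for the estimated covariate effects so that the
resampled score covariance targets `Z'PZ`, the covariance of the observed
score — without this projection the adjusted p-values are biased upward.
The p-value comes from a chi-square with `12/kurtosis` degrees of freedom
matched to the resampled moments; for the omnibus base the adjustment is
applied per grid point and the grid minimum Bonferroni-corrected.

## 3. The synthetic haplotype pool

`generate_haplotype_pool()` substitutes a coalescent simulator with a
deliberately minimal model: derived-allele counts are drawn from the
neutral spectrum `P(count = i) proportional to 1/i`, carriers are assigned
uniformly, and positions are distinct uniform draws over the span
(0-based, half-open windows throughout). Defaults are 10,000 haplotypes
over 1 Mb at 20 variant sites per kb — chosen so that 3 kb regions almost
never violate the `m >= 2` constraint and, by the folded 1/i mass, more
than half of all sites sit below MAF 0.01, the regime the rare-variant
tests consume. The published density of the coalescent haplotypes this
replaces is not stated anywhere we could verify, so density is an explicit
parameter rather than a claim.

What the pool deliberately does *not* model: linkage disequilibrium,
recombination hotspots, demography, selection, multiple populations.
Passing calibration and power checks on this pool therefore says nothing
about LD-induced behaviour of the tests (e.g. eigenvalue concentration in
SKAT kernels under strong LD); users who need that realism can import
external haplotypes via `read_haplotype_pool()` (plain 0/1 matrix plus a
positions file).

Regions are drawn uniformly by start offset, must contain at least two
variants, and are kept distinct within an experiment *by start offset* —
the cheapest faithful reading of "different regions per replicate"; two
overlapping windows with different starts count as different regions.

## 4. Phenotype simulation

Case-control cohorts are sampled retrospectively: population individuals
`(haplotype pair, X1 ~ N(0,1), X2 ~ Bernoulli(0.5))` are drawn, disease is
Bernoulli with `logit^{-1}(beta0 + 0.5 X1 + 0.5 X2 + sum_j beta_j G_ij)`,
and draws continue until both the case and the control quota are filled
(draw budget 1e6 per replicate). The intercept is solved so that the
*marginal* prevalence equals the target (default 1%), by root finding over
quadrature on the covariate distribution, accurate to 1e-6; the
alternative reading `beta0 = logit(prevalence)` is available via
`mode = "logit"` because descriptions equating the intercept with
prevalence are ambiguous between the two.

Causal variants are drawn uniformly among variants with MAF below the
causal cutoff; `m_c = max(min_causal, round(pct_causal/100 * n_eligible))`
with `min_causal = 1` by default (the minimum causal count is otherwise
unspecified in the designs this follows). Effect magnitudes are
`|beta_j| = c * |log10(MAF_j)| / 2`, the convention of the SKAT simulation
literature (the base of the logarithm is a parameter). The scale constant
is `ln(5)/4`, `ln(7)/4`, `ln(13)/4` at 20/10/5% causal; no value is
defined at 1% causal, so the package defaults to `ln(13)/4` (the largest
stated value) and exposes it as `c_at_1pct`. Protective signs are assigned
to `round(pct_protective/100 * m_c)` causal variants chosen uniformly.

## 5. The experiment grid and its reconstruction

`experiment_grid()` ships 9 null presets (`t1..t9`) and 18 power presets
(`p1..p18`): 10,000 and 1,000 replicates respectively, prevalence 1%,
levels 0.05/0.01/0.001. The published table describing the grid is
corrupted in the source available to us, so the presets were reconstructed
once from the scenario groupings given alongside the results (case
proportion varied over {0.2, 0.5, 0.8}; cohort size over {100, 500, 1000,
5000}; protective percentage over {5, 10, 20}; causal percentage over
{1, 5, 10, 20}; rare-only versus rare-plus-common; cutoff 0.01 versus
0.03; regions of 1/3/5 kb) around a baseline of balanced cohorts and 3 kb
regions. The causal-percentage cells carry 0% protective so that all 18
presets are distinct. The grid is an ordinary list and is meant to be
edited.

Summary definitions (all implemented literally, with their deliberate
asymmetry):

- *type I error* = significant / **returned** p-values;
- *reliability* = returned / replicates;
- *power* = significant / **replicates** (an NA counts against power);
- "significant" means `p <= alpha`;
- calibration classes use the 95% Wilson score interval at the replicate
  count: inflated above the upper bound, conservative below the lower.
  The Wilson interval reproduces the published upper thresholds at 10,000
  replicates (0.054, 0.0121, 0.0018) and the 0.046 lower bound at 0.05;
  the published lower bounds at the two smaller levels (0.0079, 0.0002)
  match no interval we could identify (Wilson gives 0.0082 and 0.0005) and
  are not reproduced;
- *uniqueness score* counts replicates where a test is the only significant
  member of its comparison set; NA is never significant;
- *decision similarity* treats NA as a non-significant decision, mirroring
  the power denominator convention;
- *redundancy* counts exactly equal returned p-values (full precision;
  NA–NA pairs produced no p-value and do not count);
- *max evolution* = (max − min)/min elapsed time, with an infinite
  sentinel at min = 0.

## 6. Ensembles

`ensemble_pvalue()` reports `min(1, k * min p)` where `k` counts members
that returned a p-value — failures shrink the correction factor instead of
poisoning the minimum, a choice the source designs leave open. The three
construction algorithms operate on stored simulation tables:

1. **good_type1** — keep tests never inflated across all (experiment,
   level) results; drop uniqueness-score-zero tests; drop median
   reliability <= 0.9.
2. **greedy_uniqueness** — iteratively add the highest-uniqueness test(s)
   among the never-inflated remainder, recomputing the *ensemble's own*
   type I error each round; the first addition that inflates it is rolled
   back and the previous set returned. The published description of this
   final step is internally inconsistent ("removed the last candidates
   from Set A; this Set A constituted the new ensemble"); the rollback
   reading is the only one consistent with the loop's purpose and is what
   the package implements. The recomputation is ensemble-level (the
   per-replicate combined p-value), which is the reading consistent with
   the construction's goal of certifying the combination, not the members.
3. **combined_rank** — rank the whole remaining pool by uniqueness score
   (descending) and by proportion inflated (ascending), add the minimum
   summed rank, same stopping rule.

Ties in either greedy step add *all* tied tests in one iteration. Both
expansions log every iteration (candidate set, scores, outcome) so a
construction can be replayed; the suite checks the traces against an
independent brute-force enumeration on a hand-built six-test fixture.

`preliminary_filter()` implements the four-step scalability screen (time
caps, redundancy with the max-evolution tie-break, re-screening on scaled
data and on power p-values). The 10-second caps are hardware-dependent
inputs, not validated constants, and timing plays no role in any
correctness check.

## 7. Problem sizes used by the checks

The unit suite runs on a 2,000-haplotype / 200 kb pool and cohorts of
100–200; permutation tests use 1,000–2,000 permutations. The end-to-end
calibration check and the acceptance script run the full study condition:
the default 10,000-haplotype / 1 Mb pool, 10,000 null replicates of 500
balanced individuals on 3 kb regions at cutoff 0.01, with the seven-member
asymptotic core ensemble. Power directionality (cohort size, causal load,
common-variant dilution) is checked at 200 replicates per cell — large
enough for the ordering, deliberately not a precision estimate of power
itself. Monte-Carlo oracles for the quadratic-form engine use 1e6 draws
per eigenvalue set.

## 8. Known limitations

- No LD in the generator (see section 3); absolute power numbers are not
  comparable to benchmarks on coalescent haplotypes, only orderings.
- The registry implements 15 canonical tests, not the dozens of published
  variants; external tests plug in through `test_spec()` but their
  p-value provenance is the caller's responsibility.
- The asymptotic C-alpha variance assumes independent allele placement;
  at very small cohort sizes its normal approximation is rough — the
  permutation mode exists for that regime.
- Permutation members (`wss`, `t1p`, `t5p`) consume the ambient RNG
  stream: reproducibility requires seeding the replicate loop, which
  `run_experiment()` does.
- `skat_binary_adjusted` adjusts moments, not the full distribution; it is
  not an exact small-sample method.
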