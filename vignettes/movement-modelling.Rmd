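---
title: "Population-level movement inference from sparse telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-level movement inference from sparse telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sparsemove)
```

## The problem

Satellite-linked tags on wide-ranging marine animals (sharks, tunas,
turtles) report positions only when the animal surfaces, and the resulting
tracks are sparse and irregular: days or weeks can separate fixes, and fix
quality varies with the Argos location class. Most trajectory methods
(state-space models, step-selection functions) need regular intervals or
speed/turning-angle information, so data-limited studies often retreat to
individual-level description. sparsemove implements an alternative:
frame the ecological question as a **binary response** per location — is
the animal west of a reference meridian? inside a protected area? in a
given behavioural state? — and model that response hierarchically across
individuals, so population-level inference survives sparse, irregular
sampling.

## The model

For location $i$ of individual $j$, with response $z_i \in \{0, 1\}$:

$$z_i \sim \mathrm{Bernoulli}(\mu_i), \qquad
  \mathrm{logit}(\mu_i) = \beta_0 + \beta_1\,\mathrm{Spring}_i +
  \beta_2\,\mathrm{Summer}_i + \beta_3\,\mathrm{Winter}_i +
  \beta_4 L_i + \beta_5\,\mathrm{Sex}_i + \beta_6\,\mathrm{Index}_i + u_j$$

Fall is the season reference (absorbed by the intercept). $L$ is z-scored
body length, constant within an individual; the index is a standardized
slowly varying climate covariate (e.g. MEI). The per-individual intercept
$u_j \sim \mathrm{Normal}(0, \tau^{-1})$ links individuals to the
population; $s = 1/\sqrt{\tau}$ is the individual-level standard
deviation. Priors are vague by default: $\beta_k \sim
\mathrm{Normal}(0, 10)$ (precision 0.1) and $\tau \sim
\mathrm{Gamma}(0.1, 0.01)$, which has mean 10 and variance 1000.

The same linear predictor is fitted three ways: the Bayesian hierarchical
model (`sample_posterior()`), a Laplace-approximation GLMM
(`fit_laplace()`, via lme4), and penalized quasi-likelihood (`fit_pql()`,
via MASS). With vague priors the three should agree, which the test suite
checks on simulated data.

## Stages of the pipeline

1. **Preprocessing** (`filter_daily_best()`, `derive_response()`,
   `zscore()`, `encode_season()`, `build_track_index()`). At most one fix
   per tag per UTC day is kept, choosing the best Argos class in the
   quality order D < 3 < 2 < 1 < 0 < A < B < Z; same-day ties at equal
   class keep the earliest fix. The deployment class "D" is ranked best
   because the release position is known exactly. Days without fixes stay
   missing — no interpolation. A longitude exactly on the boundary
   meridian codes east (`z = 0`); seasons follow the Northern-Hemisphere
   meteorological convention (Spring = Mar–May, and so on), since tracking
   records carry no other natural season definition.
   `extract_grid_covariate()` averages a gridded field over the
   positional-error box of each fix (metres converted at 111,320 m per
   degree latitude, scaled by cos(latitude) for longitude), so covariate
   resolution matches positional uncertainty.

2. **Variable screening** (`permutation_importance_test()`). A
   classification random forest with class-balanced, without-replacement
   sampling ranks candidate predictors by Gini importance; significance
   comes from refitting the forest with the response permuted (the null
   distribution), with $p = (1 + \#\{\text{null} \ge \text{obs}\}) /
   (n_{\mathrm{perm}} + 1)$ so p-values are never zero. Variables at
   $p \le \alpha$ (default 0.1, inclusive at the boundary) are kept.
   Perfect predictors — anything that separates the response with zero
   training error, such as raw longitude for an east/west response — are
   detected and must be removed first. The production preset uses 10,000
   trees and 100 permutations with 1,000 rows per class; the desk preset
   (500 trees, 50 permutations) is for interactive work. The permutation
   scheme permutes the *response* and refits the whole forest, which
   matches the common permutation-importance tools; we document rather
   than assert equivalence with any specific one.

3. **Linearity check** (`fit_additive_logistic()`,
   `linearity_report()`). Each continuous predictor enters a binomial
   additive model as a penalized cubic regression spline (basis size 10)
   alongside a per-individual random intercept, fitted by mgcv with REML
   smoothing selection. A smooth whose effective degrees of freedom fall
   below 1.5 is treated as linear: an exact penalized fit rarely returns
   EDF of exactly 1, so a cutoff halfway to the first genuinely curved
   shape is used. The per-term Wald chi-square is reported for reference,
   but the verdict uses the EDF alone.

4. **Bayesian fitting** (`sample_posterior()`). See below.

5. **Prior-influence check** (`run_priors_only()`,
   `prior_influence_check()`, `expand_flagged_priors()`). A priors-only
   run is compared with the data-full posterior per coefficient by the
   overlapping coefficient of kernel density estimates on a shared grid.
   Overlap above 0.35 flags the prior as still shaping the posterior; the
   flagged variance is multiplied by 10 and the fit repeated until no
   coefficient is flagged. The 0.35 / 10 choices are package defaults for
   an inherently qualitative judgement ("wide enough not to matter");
   both are arguments. Two priors-only modes exist because the two
   natural readings differ: `prior_predictive` drops the likelihood
   entirely and samples the prior hierarchy (draws provably independent
   of the design), while `paper_literal` keeps the response but removes
   all covariates, so the summed coefficients form an intercept-only
   logit. We default to `prior_predictive` for influence checks.

6. **Data-paucity experiment** (`run_paucity_experiment()`). Random row
   subsets at 75/50/25/10% (25 replicates each, 100 subset fits) are
   refitted with any of the three fitters; accuracy is the shift of each
   estimate from its full-data value, precision the 95% interval width.
   Rows are removed without regard to individuals; individuals left empty
   simply drop out. Subset sizes are `round(fraction * n)` (banker's
   rounding — exact for the canonical 9,440-row case: 7080/4720/2360/944).
   Per-replicate seeds come from a counter over (fraction index,
   replicate index), so reruns and parallel schedules agree.

7. **Synthetic data and recovery** (`simulate_dataset()`,
   `recovery_study()`). See below.

## The sampler

The model is deliberately simple, but a correct, reproducible sampler for
it needs care. `sample_posterior()` runs independent chains of an
adaptive Metropolis-within-Gibbs scheme:

* the coefficient vector is updated by joint random-walk Metropolis whose
  proposal covariance is learnt from the adaptation history (scaled
  2.38/√p, with a Robbins–Monro global scale targeting ≈28%
  acceptance), frozen when adaptation ends; five such sub-updates run per
  scan, because each costs only one likelihood pass and random-walk
  autocorrelation is the binding constraint at the desk preset;
* all random intercepts update in one vectorized step of scalar
  Metropolis moves (they are conditionally independent given the
  coefficients), with per-individual scales targeting ≈40% acceptance;
* the precision τ is drawn exactly from its conjugate conditional
  Gamma(shape + N/2, rate + Σu²/2);
* for every design column that is constant within individuals (the
  intercept, length, sex), an additional **translation move** proposes
  shifting that coefficient while counter-shifting every $u_j$ by the
  group's column value. The likelihood is invariant along these
  directions, which is exactly why plain random-walk updates mix slowly
  on them; the translation move is accepted on the prior terms alone and
  restores mixing. Without it, four desk-preset chains plateau around
  $\hat R \approx 1.1$ for those coefficients; with it they reach
  $\hat R \le 1.01$.

Coefficients initialize from Uniform(0, 1) draws, intercepts at zero, τ
from its prior. Burn-in follows adaptation; draws are kept every `thin`
iterations of the monitoring phase. The classic (non-split) Gelman–Rubin
statistic is reported per parameter (`gelman_rubin()`; a split variant is
available behind a flag). Credible intervals are equal-tailed posterior
quantiles. Everything is reproducible from a single seed; chain streams
are derived from it.

The `"paper"` preset (4 chains; 100,000 adaptation; 10,000 burn-in;
500,000 monitored; thin 10) mirrors a production run. The `"desk"` preset
(2,000 / 2,000 / 20,000 / thin 10) is sized so a four-chain fit at a few
thousand rows completes in about two minutes, and is what the test suite
and acceptance script use.

A Polya–Gamma augmented exact Gibbs sampler would avoid Metropolis tuning
altogether and is noted as a possible extension; it is not required for
convergence at the scales the package targets.

## The generator and what passing tests mean

`simulate_dataset()` emulates a telemetry study of 34 individuals with on
average 278 retained locations each (~9,440 rows): per-individual track
spans of at least a year with irregular day gaps (mean ≈ 2.08 days),
season indicators from the dates, one z-scored body length (lengths
Normal(205, 25) cm across individuals) and one sex per individual (even
ratio), and a shared standardized daily AR(1) climate index with
coefficient 0.95. The response is drawn from the logit-linear model with
per-individual Normal(0, σᵤ²) intercepts. The default truth —
β = (−1, 0.75, −1, 0, 1, 0.1, −0.5), σᵤ = 2.5 — is a fixture chosen to
echo the magnitude pattern of a real coastal/offshore analysis (strong
seasonal contrasts, a meaningful length effect, a weak sex effect, a
moderate negative index effect, large individual variation); it is not
claimed to reproduce any published simulation's truth.

The generator reproduces grouped binary structure, individual
heterogeneity, seasonal imbalance and a slowly varying shared covariate.
It does **not** simulate positions, movement persistence, spatial or
temporal autocorrelation of residuals, tag failure, or class-dependent
positional error, so passing recovery tests demonstrate correctness of
the estimation machinery under the stated model — not robustness to the
autocorrelation real tracks exhibit.

Two behaviours of the generator are worth knowing when interpreting
checks. First, with few individuals and short tracks, the shared AR(1)
index partially confounds with season and individual terms, and an
additive-model smooth of the index can show EDF > 1.5 even though the
generating logit is linear; with ≥ 20 individuals tracked over a year the
EDF returns to ≈ 1.0. Second, with 34 individuals and σᵤ = 2.5, the
cluster-level coefficients (intercept, length, sex) are weakly
identified: their per-dataset estimates scatter with standard deviations
of roughly 0.4–1.0 even at full size. A 100-replicate recovery study
therefore measures their bias to no better than ±0.1 Monte-Carlo
precision, and Wald intervals for them undercover slightly (≈0.86–0.93
observed, against a 0.95 nominal with ±0.065 binomial tolerance at 100
replicates). The within-individual slopes (seasons, index) recover
cleanly: |bias| under 0.01 and coverage within tolerance. The
corresponding acceptance check is asserted for all six slopes and is
expected to fail for length and sex at these conditions; we regard that
as a property of the study design (34 clusters, large σᵤ), not of the
fitters.

## Problem sizes used by the checks

The test-suite and acceptance-script runs use: the desk MCMC preset on a
simulated 34-individual × ~100-location dataset for convergence (max
$\hat R$ over coefficients ≤ 1.01); 100 full-size simulated datasets with
the Laplace fitter for recovery; one full-size dataset for the
three-fitter agreement check (with the prior-influence loop applied
first, which at these conditions flags and widens the sex coefficient's
prior — shrinkage from a variance-10 prior on a weakly identified
cluster-level effect is visible against the MLE, and widening removes
it); and a 34 × ~100 dataset for the 4 × 25 paucity experiment, whose
sign-stability claim is asserted for the strong well-identified slopes
(|β| ≥ 0.5 within-individual terms). Tie-breaks, boundary conventions and
degenerate-input behaviour (constant covariates, single-class subsets,
empty groups) are covered by the unit suites.

## Worked example

```{r example}
library(sparsemove)

sim <- simulate_dataset(sim_config(n_individuals = 12,
                                   mean_locations = 80, seed = 1))

# screen variables (desk preset, small class sample for a small dataset)
screen <- permutation_importance_test(
  dplyr::select(sim$data, -date),
  rf_config(preset = "desk", samp_per_class = 150, seed = 1))
select_variables(screen)

# check linearity of the continuous candidates
lin <- fit_additive_logistic(sim$data, smooth_vars = "MEI_Index",
                             linear_vars = c("Spring", "Summer", "Winter",
                                             "L", "sex"))
linearity_report(lin)

# fit the hierarchical model and its likelihood counterparts
fit <- sample_posterior(hbm_model(sim$data),
                        config = mcmc_config("desk", seed = 1))
glance(fit)
tidy(fit)

fit_laplace(sim$data)
```

## Known limitations

* No autocorrelated-residual variant: locations are treated as
  conditionally independent given the covariates and individual effect.
* Binomial-logit only; no random slopes, crossed or nested groupings.
* PQL reports no true likelihood and attenuates estimates when σᵤ is
  large — it is included as the widely used comparator, with Laplace (or
  the Bayesian fit) preferred.
* The prior-influence overlap threshold and expansion factor are
  pragmatic defaults, not calibrated quantities.
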