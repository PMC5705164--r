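# sparsemove

Population-level movement inference from sparse satellite telemetry.

Tracks from satellite-linked tags on wide-ranging marine animals are
sparse and irregular: fixes arrive only when the animal surfaces, gaps of
days to weeks are common, and positional quality varies by Argos location
class. sparsemove is for researchers who want population-level answers
from such data without interpolation, regular sampling, or speed/turning
information. It frames the ecological question as a binary response per
location — is the animal west of a reference meridian (the packaged
convention: `z = 1` strictly west of 125°W), inside a reserve, in one
behavioural state or another — and models it hierarchically across
individuals.

## The model

For location *i* of individual *j*:

```
z_i ~ Bernoulli(mu_i)
logit(mu_i) = B0 + B1*Spring_i + B2*Summer_i + B3*Winter_i
              + B4*L_i + B5*Sex_i + B6*Index_i + u_j
u_j ~ Normal(0, 1/tau)
```

with Fall as the season reference, `L` the z-scored body length, and a
standardized climate index (e.g. MEI) as the environmental covariate.
Default priors are vague: `B_k ~ Normal(0, var 10)` (precision 0.1) and
`tau ~ Gamma(0.1, 0.01)` (mean 10, variance 1000); `s = 1/sqrt(tau)` is
the individual-level standard deviation. The model is fitted by a
bespoke adaptive Metropolis-within-Gibbs sampler (`sample_posterior()`),
and — for comparison, as frequentist counterparts — by a Laplace GLMM
(`fit_laplace()`, lme4) and penalized quasi-likelihood (`fit_pql()`,
MASS).

Around the model sit the stages a full analysis needs: Argos-class
daily filtering and covariate standardization
(`filter_daily_best()`, `zscore()`, `build_analysis_table()`),
balanced random-forest variable screening with permutation p-values
(`permutation_importance_test()`), a penalized-spline linearity check
with per-term effective degrees of freedom (`fit_additive_logistic()`),
a priors-only run and prior-influence check
(`run_priors_only()`, `prior_influence_check()`), a data-paucity
robustness experiment (`run_paucity_experiment()`), and a synthetic
telemetry generator with a parameter-recovery harness
(`simulate_dataset()`, `recovery_study()`).

## Worked example

Simulate a small study (12 individuals, ~80 locations each), fit the
hierarchical model at the desk preset, and compare with the Laplace GLMM:

```r
library(sparsemove)

sim <- simulate_dataset(sim_config(n_individuals = 12,
                                   mean_locations = 80, seed = 1))
fit <- sample_posterior(hbm_model(sim$data),
                        config = mcmc_config("desk", seed = 1))
glance(fit)
#>   n_chains n_kept max_rhat_beta accept_beta accept_u preset
#> 1        4   2000          1.00       0.270    0.390 desk
tidy(fit)
#>   parameter    mean     sd     q2.5  q97.5
#> 1 B0         0.598  1.05   -1.57     2.58
#> 2 B1         0.507  0.257   0.00380  1.01
#> 3 B2        -0.870  0.263  -1.38    -0.372
#> 4 B3        -0.0581 0.269  -0.585    0.477
#> 5 B4         0.492  0.686  -0.864    1.87
#> 6 B5        -2.34   1.27   -4.84     0.166
#> 7 B6        -0.488  0.0994 -0.687   -0.297
#> 8 s          2.18   0.673   1.28     3.83
#> ...
```

All four chains converged (`max_rhat_beta` ≈ 1.00). Summer (`B2`) and
the climate index (`B6`) have 95% credible intervals excluding zero: at
this simulation's truth, animals are less likely to be west of the line
in summer and under positive index anomalies. The frequentist
counterpart agrees:

```r
fit_laplace(sim$data)
#>   term        estimate std.error conf.low conf.high
#> 1 (Intercept)   0.955     0.891   -0.790      2.70
#> 2 Spring        0.493     0.261   -0.0194     1.00
#> 3 Summer       -0.872     0.260   -1.38      -0.362
#> 4 Winter       -0.0636    0.266   -0.585      0.458
#> 5 L             0.435     0.541   -0.626      1.50
#> 6 sex          -2.76      1.10    -4.92      -0.605
#> 7 MEI_Index    -0.487     0.0982  -0.679     -0.295
#> sigma_u = 1.671
```

(Within-individual slopes match the Bayesian means to ~0.02; the
cluster-level terms `B0`/`B4`/`B5` differ more, as expected with 12
individuals and large individual variation — see the vignette.)

`autoplot()` methods draw posterior densities, importance bars, paucity
histograms and recovery densities; `tidy()`/`glance()` return tibbles
throughout, so results pipe straight into dplyr/ggplot2 workflows.
`run_pipeline()` chains the stages and writes a seeded, md5-stamped
artifact manifest. The methods vignette
(`vignettes/movement-modelling.Rmd`) documents the sampler, the
generator, all defaults, and known limitations.

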