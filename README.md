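# offsetTD

Hierarchical Bayesian modelling of intertemporal choice under cue exposure:
hyperbolic temporal discounting with softmax choice and a multiplicative
**subjective-value offset**.

## The problem

In delay-discounting tasks people choose between a fixed immediate reward
(20 € now — the smaller-sooner option, SS) and a larger-later option (LL;
e.g. 38 € in 14 days). The classical account is hyperbolic devaluation,
`SV(LL) = A / (1 + k·D)`, with a softmax mapping value differences to choice
probabilities. But real choice data often show a delay-*independent* bias
against the delayed option that the discount rate `k` cannot absorb. offsetTD
implements a model family that separates the two, within a two-condition
(neutral vs. appetitive cue exposure) within-subject design:

- **Base model** — per subject: `log k`, inverse temperature `β`, plus
  additive condition-shift parameters `S_k` (on `log k`) and `S_β`.
- **Offset model** — adds `ω ∈ (0, 1]`, a multiplicative offset on the LL's
  subjective value (applied to the LL only; `ω = 1` recovers the pure
  hyperbolic model exactly), with its own condition shift `S_ω`.

All six parameters are modelled hierarchically (group-level Gaussians,
subject-level partial pooling), estimated by MCMC with informative group-mean
priors, and compared by WAIC. Condition effects are evaluated with highest
density intervals, Savage-Dickey `BF01` against the point null at zero, and
directional Bayes factors (posterior mass below vs. above zero). Posterior
predictive checks target the fraction of LL choices across the eight design
delays. A synthetic-cohort generator reproduces the task's 128-trial designs
(16 multipliers × 8 delays, two printed sets) so every stage of the pipeline
can be exercised with ground-truth-labelled data.

## Worked example

```r
library(offsetTD)

# simulate a 36-subject cohort at the default generative settings
cohort <- simulate_cohort(td_ground_truth(), n_subjects = 36, seed = 1)

# fit both model variants (reduced sampler configuration for a quick run;
# the default is 4 chains x 1500 warmup x 4000 retained draws)
fit  <- td_fit(cohort$data, "offset", chains = 2, warmup = 400,
               retained = 400, seed = 1)
fit0 <- td_fit(cohort$data, "base",   chains = 2, warmup = 400,
               retained = 400, seed = 1)
#> Warning message:
#> convergence gate failed: max split R-hat = 7.215
print(fit)
#> Hierarchical discounting model fit (offset variant)
#>   36 subjects, 9216 valid trials
#>   2 chains, 400 warmup, 400 retained draws (logit offset link)
#>   convergence: max split R-hat 1.042 (pass, threshold 1.05)

rank_models(waic(fit), waic(fit0))
#>    model     waic      lppd   p_waic        se rank
#> 1 offset 3139.336 -1437.147 132.5205  91.81791    1
#> 2   base 5828.952 -2638.033 276.4429 112.63440    2

# parameter recovery against the simulation ground truth
cs <- coef(fit)$subjects
cor(cohort$truth$subjects$log_k, cs$log_k_neut)
#> [1] 0.9611546

# condition-shift inference (the cohort was generated with a mean log-k
# shift of +0.15 and null effects on beta and omega)
shift_report(fit)[, 1:5]
#>     parameter        mean         sd        dbf     bf01
#> 1     s_ero_k  0.18174763 0.11777215 0.06951872 1.733929
#> 2 s_ero_omega -0.01156721 0.05368996 1.50000000 7.277935
#> 3  s_ero_beta -0.03538831 0.02946198 7.88888889 1.600832
```

Reading the output: the warning comes from the *base* fit — on data with a
real offset the misspecified base model converges poorly, which is itself
diagnostic; the offset fit passes the gate. The offset model ranks first by
WAIC (lower is better); recovered subject-level `log k` values correlate
0.96 with the generating values. The `log k` shift — truly present with
mean +0.15 — shows a directional BF far below 1 (posterior mass above
zero), while the null offset shift shows `BF01 > 3`, moderate evidence for
no condition effect. A posterior predictive check of the delay profile is
one call away: `plot(fit, n_datasets = 400)`.

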