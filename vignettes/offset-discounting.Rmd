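---
title: "Cue-modulated hyperbolic discounting with a subjective-value offset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cue-modulated hyperbolic discounting with a subjective-value offset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(offsetTD)
```

## The task and the model

offsetTD models intertemporal choice in a two-condition, within-subject
cue-exposure design. On every trial a participant chooses between a fixed
immediate 20 EUR reward (the smaller-sooner option, SS, never shown on
screen) and a larger-later option (LL) defined by an amount and a delay. The
128 trials of a session cross 16 amount multipliers with 8 delays; two
slightly different multiplier/delay sets exist, one per testing day
(`td_design(1)`, `td_design(2)`). Sessions are run once after neutral and
once after appetitive (erotic) cue exposure, coded by the indicator
$I_{Ero} \in \{0, 1\}$.

Choices are modelled hierarchically. For subject $s$ on trial $t$:

$$k(t) = \exp\!\big(\log k_{neut} + I_{Ero}(t)\, S_{k}\big), \qquad
  \beta(t) = \beta_{neut} + I_{Ero}(t)\, S_{\beta}$$

$$SV(LL) = \frac{A}{1 + k(t)\,D}, \qquad
  SV(LL) \leftarrow SV(LL)\,\big(\omega_{neut} + I_{Ero}(t)\, S_{\omega}\big)
  \quad\text{(offset variant only)}$$

$$P(LL) = \frac{1}{1 + e^{-\beta(t)\,(SV(LL) - SV(SS))}}, \qquad SV(SS) = 20.$$

The discount rate $k$ captures how steeply delayed rewards are devalued
(log-space, so condition shifts are multiplicative on $k$); the inverse
temperature $\beta$ scales how strongly value differences determine choice;
the offset $\omega \in (0, 1]$ is a delay-independent down-scaling of the
LL's subjective value — a choice bias against the delayed option that is
separate from discounting proper. At $\omega = 1$ the offset variant reduces
exactly (bitwise, in this implementation) to the base variant. The offset
applies to the LL only: an offset above 1 would value the LL above its
objective amount at delay zero, which is why the domain is capped at 1.

Each of the six parameters ($\log k_{neut}, S_k, \beta_{neut}, S_\beta,
\omega_{neut}, S_\omega$) has a group-level Gaussian; subjects are partial
pooled toward the group means. Group-mean priors (see `td_priors()`):

| parameter | prior |
|---|---|
| $\log k_{neut}$ | Normal(-4.2, 2.01) |
| $S_{k}$ | Normal(0.15, 0.64) |
| $\beta_{neut}$ | Normal(0.51, 0.30) |
| $S_{\beta}$ | Normal(0.02, 0.11) |
| $\omega_{neut}$ | Uniform(0, 1) |
| $S_{\omega}$ | Normal(0, 0.40) |

Normal parameters are (mean, SD). The group SDs are not pinned down by the
published analysis; we use half-Normal(0, 1) priors throughout, a weakly
informative default that still allows strong shrinkage.

### The offset constraint

The effective offset $\omega_{neut} + I_{Ero} S_\omega$ must stay in
$(0, 1]$, but a literal additive shift can leave that interval. The sampler
therefore composes the subject-level offset and its shift on the logit scale
by default (`omega_link = "logit"`): subject values and shifts are Gaussian
in logit space, and the effective multiplier `plogis(logit_omega + I *
s_ero_omega)` is plugged into the value equation, so the constraint holds by
construction in both conditions. The Uniform(0, 1) prior on the group-typical
offset maps to a standard-logistic prior on the logit scale — the two
formulations describe the same prior mass. The shift prior Normal(0, 0.4)
then applies on the logit scale. A literal natural-scale parameterization is
available (`omega_link = "identity"`); it rejects proposals whose effective
offset leaves $(0, 1]$. Subject-level offsets are modelled hierarchically
like every other parameter.

The cohort simulator uses the same logit-scale construction, so simulated
subjects always satisfy the constraint, and `td_ground_truth()` reports both
the logit-scale values and the implied natural-scale offsets per condition.

## Sampling

`td_fit()` estimates the joint posterior with an adaptive
Metropolis-within-Gibbs sampler written for this model. Each recorded sweep
comprises four full update cycles of:

* componentwise random-walk MH on the subject-level parameters, vectorized
  across subjects, with per-subject proposal scales adapted toward 44%
  acceptance during warmup and frozen afterwards;
* joint full-covariance MH moves per subject, whose proposal Cholesky
  factors are learned from the chain's own warmup history — these capture
  cross-parameter ridges such as the trade-off between $\log k$ and
  $\omega$ in subjects who almost always choose the LL;
* an MH move per (baseline, shift) pair proposing $(+e, -e)$ steps, the
  direction in which the two are posterior-correlated (erotic trials
  constrain only their sum);
* conjugate Gibbs draws of the Normal-prior group means; a slice step for
  the offset group mean; univariate slice sampling of the group SDs;
* interweaved non-centred ("ASIS") scale moves per parameter block, which
  jointly rescale a group SD and its subject deviations — this is what
  keeps the shift-parameter SDs mixing when the per-subject shifts are
  weakly identified.

The per-trial likelihood sums are evaluated in compiled code (a single-pass
mirror of the exported model math; the test suite asserts their agreement to
near machine precision).

The default configuration matches the full analysis (4 chains, 1500 warmup,
4000 retained draws, no thinning). Tests and examples use a reduced
configuration (2 chains, 400 warmup, 400 retained) at which a 36-subject,
9216-trial fit takes on the order of a minute and still passes the
convergence gate. Convergence is assessed by split-chain $\widehat{R}$ over
all sampled parameters with the conventional 1.05 threshold
(`compute_rhat()`); a failed gate warns but still returns the draws, so the
diagnostics can be inspected. Structurally constant parameters (the shifts
in a single-condition fit) are reported as $\widehat{R} = 1$ with a
zero-variance flag.

The sampler was validated two ways: against analytic scalar oracles for
every model equation, and against an independent MCMC route — the identical
model in JAGS (centred parameterization) agrees with the package sampler to
within a tenth of a posterior SD on all group-level means on a test cohort.
Prior sampling (`prior_only = TRUE`) reproduces the group-mean priors.

## Model comparison and checking

`waic()` computes the widely applicable information criterion on the
deviance scale, $-2(\text{lppd} - p_{WAIC})$, from the draws-by-trials
pointwise log-likelihood matrix; the pointwise unit is the trial, so WAIC
magnitudes scale with the number of valid trials. `rank_models()` orders
fits ascending by WAIC (rank 1 = best), breaking ties by fewer effective
parameters and then by name.

Posterior predictive checks target the behavioural signature the model must
reproduce: the fraction of LL choices across the eight delays.
`posterior_predictive()` simulates one dataset per selected posterior draw on
each subject's own trials (the full analysis uses 4000 datasets);
`ppc_summary()` compares the observed group-mean LL proportion per delay bin
and condition with the simulated central 95% interval. When the two design
sets are pooled, each Set-2 delay maps to the nearest Set-1 delay (ties to
the shorter delay), giving eight bins as in the task's design; the pooling
rule is exposed via `delay_bins()` and can be overridden.

Inference on the condition shifts uses `shift_report()`: posterior mean and
SD, 85%/95% highest density intervals (`hdi()`, shortest-interval
definition), the Savage-Dickey $BF_{01}$ (posterior over prior density at
zero; a Gaussian kernel estimate with Silverman's bandwidth, evaluated
exactly at the null after variance-preserving shrinkage of the draws —
kernel smoothing otherwise inflates the posterior spread by the bandwidth
and biases tail densities — with a normal approximation as an option), and
the directional Bayes factor
(posterior mass below zero over mass above zero, exactly in that
orientation). Evidence labels follow the conventional 1/3/10 thresholds.
`bayes_cor()` provides default-prior Bayesian correlations (uniform prior on
$\rho$, i.e. stretched beta with $\kappa = 1$) for brain–behaviour-style
covariate analyses, with the Bayes factor obtained by numerical integration
of the correlation likelihood.

## The synthetic cohort generator

`simulate_cohort()` emulates the study design: two 128-trial sessions per
subject, design sets counterbalanced deterministically by subject index
(odd subjects get Set 1 in the neutral session; the published task
randomized this per participant — determinism was chosen so that tests are
exactly reproducible, and the assignment is configurable). Group means
default to the prior centres above. Between-subject SDs are not published;
the defaults — 1.5 for $\log k$, 0.3 for $S_k$, 0.2 for $\beta$, 0.1 for
$S_\beta$, 0.5 for logit-$\omega$, 0.2 for $S_\omega$ (logit) — were chosen
once as realistic for this task: an SD of 1.5 on $\log k$ spreads subjects
across most of the indifference range the design can resolve
($\log((m-1)/D)$ spans roughly $-9$ to $1$ across the trial set), while the
shift SDs keep condition effects of plausible single-session size. A
configurable miss rate marks trials INVALID (missed 4-s response window);
INVALID trials are excluded from all likelihoods and from the model-agnostic
SS-proportion measure.

What the generator does *not* emulate: response times, trial order and
timing (jitter, ITI), sequential dependencies (fatigue, learning), and any
deviation from the hyperbolic-softmax generative form. Passing recovery and
model-selection tests on these cohorts therefore demonstrates correctness of
the inference machinery under the model's own assumptions — not that the
model is right for any particular empirical dataset.

## Numerical choices and edge cases

* Exponents inside `exp()` and the logistic are clipped at $\pm 30$; the
  clip is far outside the plausible parameter range and exists so that a
  wandering chain cannot produce overflow, `-Inf` log-likelihoods, or
  degenerate 0/1 probabilities.
* $\beta(t)$ is applied literally and may go negative (the priors allow
  it); a warning is raised but nothing is truncated, so the likelihood is
  exactly the composed equations.
* LL amounts are rounded to euro cents, matching the currency display.
* Subjects whose minority-option count across both sessions is below 2
  (e.g. a single SS choice in 256 trials) are excluded by
  `exclude_degenerate_subjects()` — such a pattern is uninformative about
  the trade-off and destabilizes the hierarchy. The published analysis
  describes this exclusion narratively; the count threshold here is a
  documented operationalization, and the threshold is a parameter.
* WAIC requires at least two draws (the pointwise variance is undefined
  otherwise); the log-mean-exp is computed stably.
* `directional_bf()` counts exact zeros to neither side and caps one-sided
  posteriors at $n \pm 0.5$ with a warning.

## Problem sizes used by the tests

The package's own checks run at deliberately desk-sized scales, chosen as
the package's test conditions: recovery uses 36 subjects times two 128-trial
sessions with the reduced sampler configuration; model-selection replicates
use 10 cohorts of 12 subjects; oracle comparisons (WAIC, Bayes factors,
HDIs) use small matrices or $10^5$ analytic draws. The full-scale
configuration (4 chains, 1500/4000) is the default of `td_fit()` and is what
an actual analysis should use.

## Known limitations

* The sampler is a random-walk scheme: for much larger designs (hundreds of
  subjects) a gradient-based sampler would scale better.
* WAIC is the only comparison criterion implemented (no PSIS-LOO).
* Only the hyperbolic discount function is implemented; exponential or
  quasi-hyperbolic alternatives are out of scope, as are response-time
  models.
* One published summary statistic is not internally consistent: the arousal
  ratings' t-statistic cannot be reproduced from the printed means and SDs
  (the pooled-t formula gives roughly 117, not the printed value). The
  package reproduces the valence t-statistic, which is consistent, and does
  not attempt to "fix" the other.
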