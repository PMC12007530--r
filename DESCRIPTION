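Package: offsetTD
Title: Hierarchical Bayesian Hyperbolic Discounting with a Subjective-Value Offset
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling intertemporal choice under cue exposure: a
    hierarchical Bayesian hyperbolic temporal-discounting model with softmax
    choice, a multiplicative subjective-value offset restricted to (0, 1], and
    per-subject condition-shift parameters. Includes a task simulator for the
    128-trial delay-discounting design (fixed 20 EUR smaller-sooner option, 16
    multipliers crossed with 8 delays), an adaptive MCMC sampler with split-chain
    R-hat diagnostics, WAIC model comparison, posterior predictive checks of
    larger-later choice proportions across delays, highest density intervals,
    Savage-Dickey and directional Bayes factors, default-prior Bayesian
    correlations, and summary-statistic t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite, Rcpp
Suggests: testthat (>= 3.0.0), rjags, coda, withr
Config/testthat/edition: 3
LinkingTo: Rcpp
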