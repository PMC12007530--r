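# Priors for the group-level model parameters.

#' Group-level prior specification
#'
#' Default group-mean priors: Normal(-4.2, 2.01) for log k, Normal(0.15, 0.64)
#' for its shift, Normal(0.51, 0.3) for beta, Normal(0.02, 0.11) for its
#' shift, Uniform(0, 1) for the offset omega, and Normal(0, 0.4) for the
#' offset shift (on the sampler's logit scale). Normal parameters are
#' (mean, SD). Group SDs share a half-Normal(0, `group_sd_scale`) prior, a
#' weakly informative default for hierarchical shrinkage.
#'
#' @param mean_log_k,mean_s_k,mean_beta,mean_s_beta,mean_s_omega Length-2
#'   numeric `(mean, sd)` of the Normal group-mean prior for the respective
#'   parameter.
#' @param omega_uniform Length-2 numeric bounds of the Uniform prior on the
#'   group-typical offset (natural scale).
#' @param group_sd_scale Scale of the half-Normal prior shared by all group
#'   SDs.
#' @return A list of class `"td_priors"`.
#' @export
td_priors <- function(mean_log_k = c(-4.2, 2.01),
                      mean_s_k = c(0.15, 0.64),
                      mean_beta = c(0.51, 0.30),
                      mean_s_beta = c(0.02, 0.11),
                      omega_uniform = c(0, 1),
                      mean_s_omega = c(0, 0.40),
                      group_sd_scale = 1) {
  chk <- function(x, nm) {
    if (length(x) != 2L || any(!is.finite(x)) || x[2] <= 0)
      stop(sprintf("`%s` must be (mean, sd) with sd > 0", nm), call. = FALSE)
    x
  }
  if (length(omega_uniform) != 2L || omega_uniform[1] < 0 ||
      omega_uniform[2] > 1 || omega_uniform[1] >= omega_uniform[2])
    stop("`omega_uniform` must be valid bounds inside [0, 1]", call. = FALSE)
  if (group_sd_scale <= 0)
    stop("`group_sd_scale` must be positive", call. = FALSE)
  structure(list(
    mean_log_k = chk(mean_log_k, "mean_log_k"),
    mean_s_k = chk(mean_s_k, "mean_s_k"),
    mean_beta = chk(mean_beta, "mean_beta"),
    mean_s_beta = chk(mean_s_beta, "mean_s_beta"),
    omega_uniform = omega_uniform,
    mean_s_omega = chk(mean_s_omega, "mean_s_omega"),
    group_sd_scale = group_sd_scale
  ), class = "td_priors")
}

#' Prior density of a group shift mean at its null value
#'
#' Used as the denominator of the Savage-Dickey density ratio for the three
#' condition-shift parameters.
#'
#' @param priors A [td_priors()] object.
#' @param parameter One of `"s_ero_k"`, `"s_ero_beta"`, `"s_ero_omega"`.
#' @param null_value Point of evaluation (default 0).
#' @return Prior density (a positive number).
#' @export
prior_density_at_null <- function(priors, parameter = c("s_ero_k",
                                                        "s_ero_beta",
                                                        "s_ero_omega"),
                                  null_value = 0) {
  parameter <- match.arg(parameter)
  p <- switch(parameter,
              s_ero_k = priors$mean_s_k,
              s_ero_beta = priors$mean_s_beta,
              s_ero_omega = priors$mean_s_omega)
  stats::dnorm(null_value, p[1], p[2])
}
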