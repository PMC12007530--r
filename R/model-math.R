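# Model mathematics for the cue-modulated hyperbolic discounting model.
#
# Per trial t with condition indicator I in {0, 1} (1 = erotic cue condition):
#   k(t)     = exp(log k_neut + I * S_k)          discount rate, log-space shift
#   beta(t)  = beta_neut + I * S_beta             softmax inverse temperature
#   SV(LL)   = A / (1 + k(t) * D)                 hyperbolic discounting
#   SV(LL)  <- SV(LL) * (omega_neut + I * S_omega)   offset model only,
#                                                    effective omega in (0, 1]
#   P(choice) = logistic(beta(t) * (SV_chosen - SV_other))
# The SS option is the fixed immediate amount: SV(SS) = ss_amount (delay 0,
# never offset-scaled).

# exponent clipping keeps exp()/logistic() overflow-safe; +-30 is far outside
# the plausible parameter range so the clip is inert in practice
.clip <- function(x, lim = 30) pmax(-lim, pmin(lim, x))

.check_finite <- function(...) {
  args <- list(...)
  for (nm in names(args))
    if (any(!is.finite(args[[nm]])))
      stop(sprintf("`%s` must be finite", nm), call. = FALSE)
  invisible(TRUE)
}

#' Condition-modulated discount rate
#'
#' `k(t) = exp(log_k_neut + i_ero * s_ero_k)`: the neutral-condition discount
#' rate lives in log-space and the cue condition shifts it additively there.
#' Strictly positive; the exponent is clipped at +-30 for numerical safety.
#'
#' @param log_k_neut Neutral-condition discount rate, log scale.
#' @param s_ero_k Condition shift applied to `log k` when `i_ero = 1`.
#' @param i_ero Condition indicator, 0 (neutral) or 1 (erotic). Vectorized.
#' @return Discount rate(s) `k > 0` on the natural scale.
#' @examples
#' modulated_k(-4.2, 0.15, 0) # exp(-4.2) = 0.0150
#' modulated_k(-4.2, 0.15, 1) # exp(-4.05) = 0.0174
#' @export
modulated_k <- function(log_k_neut, s_ero_k, i_ero) {
  .check_finite(log_k_neut = log_k_neut, s_ero_k = s_ero_k, i_ero = i_ero)
  if (any(!i_ero %in% c(0, 1)))
    stop("`i_ero` must be 0 or 1", call. = FALSE)
  exp(.clip(log_k_neut + i_ero * s_ero_k))
}

#' Condition-modulated inverse temperature
#'
#' `beta(t) = beta_neut + i_ero * s_ero_beta`, applied literally: the shift is
#' additive on the natural scale and the result may be negative (the priors
#' permit it), in which case a warning is raised but no truncation occurs.
#'
#' @inheritParams modulated_k
#' @param beta_neut Neutral-condition softmax inverse temperature.
#' @param s_ero_beta Condition shift applied to `beta` when `i_ero = 1`.
#' @return Effective inverse temperature(s).
#' @export
modulated_beta <- function(beta_neut, s_ero_beta, i_ero) {
  .check_finite(beta_neut = beta_neut, s_ero_beta = s_ero_beta, i_ero = i_ero)
  if (any(!i_ero %in% c(0, 1)))
    stop("`i_ero` must be 0 or 1", call. = FALSE)
  b <- beta_neut + i_ero * s_ero_beta
  if (any(b < 0))
    warning("effective inverse temperature is negative; choice probabilities ",
            "will favour the lower-valued option", call. = FALSE)
  b
}

#' Hyperbolic subjective value of a delayed reward
#'
#' `SV = amount / (1 + k * delay)`. Equals `amount` at delay 0 or `k = 0`, and
#' decreases strictly in both delay and `k` otherwise.
#'
#' @param amount Objective amount (euros), `> 0`.
#' @param delay_days Delay to receipt in days, `>= 0`.
#' @param k Hyperbolic discount rate, `>= 0`.
#' @return Subjective value, in the same units as `amount`.
#' @examples
#' sv_hyperbolic(38, 14, exp(-4.2)) # 31.41
#' @export
sv_hyperbolic <- function(amount, delay_days, k) {
  .check_finite(amount = amount, delay_days = delay_days, k = k)
  if (any(amount <= 0)) stop("`amount` must be positive", call. = FALSE)
  if (any(delay_days < 0)) stop("`delay_days` must be >= 0", call. = FALSE)
  if (any(k < 0)) stop("`k` must be non-negative", call. = FALSE)
  amount / (1 + k * delay_days)
}

#' Multiplicative subjective-value offset
#'
#' Scales the discounted LL value by the effective offset
#' `omega = omega_neut + i_ero * s_ero_omega`, a delay-independent choice bias
#' restricted to `(0, 1]` (an offset above 1 would value the LL above its
#' objective amount at delay 0). Applies to the LL option only; the SS value is
#' never offset-scaled.
#'
#' @inheritParams modulated_k
#' @param sv Discounted subjective value of the LL option.
#' @param omega_neut Neutral-condition offset, in `(0, 1]`.
#' @param s_ero_omega Additive condition shift of the offset.
#' @return Offset-scaled subjective value.
#' @examples
#' apply_offset(31.41, 0.8, 0, 0)    # 25.13
#' apply_offset(31.41, 0.8, -0.1, 1) # 21.99
#' @export
apply_offset <- function(sv, omega_neut, s_ero_omega, i_ero) {
  .check_finite(sv = sv, omega_neut = omega_neut,
                s_ero_omega = s_ero_omega, i_ero = i_ero)
  if (any(!i_ero %in% c(0, 1)))
    stop("`i_ero` must be 0 or 1", call. = FALSE)
  eff <- omega_neut + i_ero * s_ero_omega
  if (any(eff <= 0 | eff > 1))
    stop("effective offset must lie in (0, 1]", call. = FALSE)
  sv * eff
}

#' Softmax choice probability
#'
#' Probability of the chosen option under a two-option softmax:
#' `P = logistic(beta * (sv_chosen - sv_other))`, computed in an overflow-safe
#' form. Always strictly inside (0, 1), and
#' `choice_prob(a, b, beta) + choice_prob(b, a, beta) = 1`.
#'
#' @param sv_chosen Subjective value of the chosen option.
#' @param sv_other Subjective value of the other option.
#' @param beta Inverse temperature; 0 gives random choice (P = 0.5).
#' @return Choice probability in (0, 1).
#' @examples
#' choice_prob(31.41, 20, 0.51) # 0.997
#' @export
choice_prob <- function(sv_chosen, sv_other, beta) {
  .check_finite(sv_chosen = sv_chosen, sv_other = sv_other, beta = beta)
  stats::plogis(.clip(beta * (sv_chosen - sv_other)))
}

#' Subject-level model parameters
#'
#' Bundles the six parameters of one subject: neutral-condition discount rate
#' (log scale), inverse temperature and offset, plus the three erotic-condition
#' shifts. The base model ignores the offset fields (treat `omega_neut = 1`,
#' `s_ero_omega = 0`).
#'
#' @param log_k_neut Neutral log discount rate.
#' @param beta_neut Neutral inverse temperature.
#' @param s_ero_k,s_ero_beta,s_ero_omega Condition shifts (default 0).
#' @param omega_neut Neutral offset in `(0, 1]` (default 1).
#' @return A list of class `"td_params"`.
#' @export
td_params <- function(log_k_neut, beta_neut, s_ero_k = 0, s_ero_beta = 0,
                      omega_neut = 1, s_ero_omega = 0) {
  .check_finite(log_k_neut = log_k_neut, beta_neut = beta_neut,
                s_ero_k = s_ero_k, s_ero_beta = s_ero_beta,
                omega_neut = omega_neut, s_ero_omega = s_ero_omega)
  if (omega_neut <= 0 || omega_neut > 1)
    stop("`omega_neut` must lie in (0, 1]", call. = FALSE)
  structure(list(log_k_neut = log_k_neut, s_ero_k = s_ero_k,
                 beta_neut = beta_neut, s_ero_beta = s_ero_beta,
                 omega_neut = omega_neut, s_ero_omega = s_ero_omega),
            class = "td_params")
}

# shared log-likelihood core: per-row log P(observed choice), y = 1 for LL.
# All parameter vectors are row-aligned (length 1 or nrow). Used by the
# exported trial-level functions, the sampler and WAIC so the arithmetic is
# identical everywhere.
.ll_core <- function(ll_amount, delay_days, i_ero, y, log_k, s_k, beta, s_b,
                     omega, s_o, ss_amount, offset) {
  k <- exp(.clip(log_k + i_ero * s_k))
  sv <- ll_amount / (1 + k * delay_days)
  if (offset) sv <- sv * (omega + i_ero * s_o)
  x <- .clip((beta + i_ero * s_b) * (sv - ss_amount))
  # log plogis(x) for LL choices, log plogis(-x) for SS
  -log1p(exp(ifelse(y == 1, -x, x)))
}

#' Log-likelihood of observed choices, trial by trial
#'
#' Composes the modulated parameters, hyperbolic discounting, (for the offset
#' variant) the subjective-value offset, and the softmax rule into the log
#' probability of each observed choice. Vectorized over trials; the SS option
#' is valued at `ss_amount` (delay 0).
#'
#' @param ll_amount,delay_days,i_ero Trial attributes (vectorized).
#' @param choice Character vector over `"SS"`/`"LL"` (INVALID trials must be
#'   excluded upstream).
#' @param params A [td_params()] object.
#' @param variant `"offset"` or `"base"`. With `omega_neut = 1` and
#'   `s_ero_omega = 0` the two variants agree exactly.
#' @param ss_amount Fixed immediate amount (default 20).
#' @return Numeric vector of per-trial log-likelihoods, all `<= 0` and finite.
#' @export
trial_loglik <- function(ll_amount, delay_days, i_ero, choice, params,
                         variant = c("offset", "base"), ss_amount = 20) {
  variant <- match.arg(variant)
  if (!inherits(params, "td_params"))
    stop("`params` must be a td_params object", call. = FALSE)
  if (any(!choice %in% c("SS", "LL")))
    stop("`choice` must be 'SS' or 'LL' (exclude INVALID trials first)",
         call. = FALSE)
  if (variant == "offset") {
    eff <- params$omega_neut + i_ero * params$s_ero_omega
    if (any(eff <= 0 | eff > 1))
      stop("effective offset must lie in (0, 1]", call. = FALSE)
  }
  b <- params$beta_neut + i_ero * params$s_ero_beta
  if (any(b < 0))
    warning("effective inverse temperature is negative", call. = FALSE)
  lp <- .ll_core(ll_amount, delay_days, i_ero, as.integer(choice == "LL"),
                 params$log_k_neut, params$s_ero_k, params$beta_neut,
                 params$s_ero_beta, params$omega_neut, params$s_ero_omega,
                 ss_amount, offset = (variant == "offset"))
  if (any(!is.finite(lp)))
    stop("non-finite log-likelihood", call. = FALSE)
  lp
}

#' Pointwise log-likelihood of a choice dataset
#'
#' One log-likelihood per valid trial (INVALID rows dropped), order-preserving.
#' This is the pointwise unit fed to [waic()].
#'
#' @param data A choice data frame with columns `ll_amount`, `delay_days`,
#'   `i_ero`, `choice` (see [read_choice_table()] for the schema).
#' @inheritParams trial_loglik
#' @return Numeric vector, one element per valid trial.
#' @export
pointwise_loglik <- function(data, params, variant = c("offset", "base"),
                             ss_amount = 20) {
  variant <- match.arg(variant)
  keep <- data$choice != "INVALID"
  d <- data[keep, , drop = FALSE]
  if (nrow(d) == 0L)
    stop("no valid trials after excluding INVALID responses", call. = FALSE)
  trial_loglik(d$ll_amount, d$delay_days, d$i_ero, d$choice, params,
               variant = variant, ss_amount = ss_amount)
}

#' Model-agnostic temporal discounting measure
#'
#' The relative proportion of smaller-sooner choices,
#' `TD = n_SS / (n_SS + n_LL)`, computed per subject and condition over valid
#' trials. 1 means every choice was the immediate option; INVALID trials are
#' excluded.
#'
#' @param data A choice data frame (columns `subject_id`, `condition`,
#'   `choice`).
#' @return Data frame with one row per subject x condition: `ss_count`,
#'   `ll_count`, `td_model_agnostic`.
#' @export
td_model_agnostic <- function(data) {
  d <- data[data$choice != "INVALID", , drop = FALSE]
  if (nrow(d) == 0L)
    stop("no valid trials", call. = FALSE)
  agg <- aggregate(cbind(ss = d$choice == "SS", ll = d$choice == "LL"),
                   by = list(subject_id = d$subject_id,
                             condition = d$condition), FUN = sum)
  if (any(agg$ss + agg$ll == 0))
    stop("a subject/condition cell has no valid trials", call. = FALSE)
  data.frame(subject_id = agg$subject_id, condition = agg$condition,
             ss_count = agg$ss, ll_count = agg$ll,
             td_model_agnostic = agg$ss / (agg$ss + agg$ll))
}
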