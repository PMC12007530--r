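# Generative simulation of subjects and cohorts from the hierarchical
# discounting model, so every downstream stage has ground-truth-labelled input.

#' Group-level ground truth for cohort simulation
#'
#' Defines the generative hierarchy: each parameter has a group mean and a
#' group SD, and subject values are drawn from Gaussians. The offset omega and
#' its shift are Gaussian on the logit scale and mapped back to (0, 1), which
#' keeps every subject's effective offset inside its domain in both conditions;
#' `mean_omega` is given on the natural scale for convenience and converted
#' internally.
#'
#' Mean defaults are the group-mean prior centres of the model (log k = -4.2,
#' S_k = 0.15, beta = 0.51, S_beta = 0.02, omega = 0.5, S_omega = 0); SD
#' defaults are realistic between-subject spreads for this task (see the
#' package vignette).
#'
#' @param mean_log_k,sd_log_k Group mean/SD of the neutral log discount rate.
#' @param mean_s_k,sd_s_k Group mean/SD of the log-k condition shift.
#' @param mean_beta,sd_beta Group mean/SD of the neutral inverse temperature.
#' @param mean_s_beta,sd_s_beta Group mean/SD of the beta shift.
#' @param mean_omega Group-typical neutral offset, natural scale in (0, 1).
#' @param sd_logit_omega Group SD of the neutral offset on the logit scale.
#' @param mean_s_omega,sd_s_omega Group mean/SD of the offset shift, logit
#'   scale.
#' @return A list of class `"td_ground_truth"`.
#' @export
td_ground_truth <- function(mean_log_k = -4.2, sd_log_k = 1.5,
                            mean_s_k = 0.15, sd_s_k = 0.3,
                            mean_beta = 0.51, sd_beta = 0.2,
                            mean_s_beta = 0.02, sd_s_beta = 0.1,
                            mean_omega = 0.5, sd_logit_omega = 0.5,
                            mean_s_omega = 0, sd_s_omega = 0.2) {
  sds <- c(sd_log_k, sd_s_k, sd_beta, sd_s_beta, sd_logit_omega, sd_s_omega)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("group SDs must be finite and >= 0", call. = FALSE)
  if (mean_omega <= 0 || mean_omega >= 1)
    stop("`mean_omega` must lie strictly in (0, 1)", call. = FALSE)
  structure(list(
    group_means = c(log_k = mean_log_k, s_ero_k = mean_s_k,
                    beta = mean_beta, s_ero_beta = mean_s_beta,
                    logit_omega = stats::qlogis(mean_omega),
                    s_ero_omega = mean_s_omega),
    group_sds = c(log_k = sd_log_k, s_ero_k = sd_s_k,
                  beta = sd_beta, s_ero_beta = sd_s_beta,
                  logit_omega = sd_logit_omega, s_ero_omega = sd_s_omega)
  ), class = "td_ground_truth")
}

#' Simulate one subject's choices on a trial set
#'
#' Draws each choice from a Bernoulli with the model's softmax probability
#' (composed exactly as in [trial_loglik()]); reproducible given the seed. An
#' optional miss rate marks trials INVALID, emulating responses outside the
#' 4-second response window.
#'
#' @param params A [td_params()] object.
#' @param trials A [td_design()] trial set (or any data frame with columns
#'   `trial_index`, `ll_amount`, `delay_days`).
#' @param i_ero Condition indicator for this dataset, 0 or 1.
#' @param seed Integer seed; required for reproducibility.
#' @param variant `"offset"` or `"base"` generative model.
#' @param miss_rate Probability a trial is marked `INVALID` (default 0).
#' @param subject_id Label for the subject.
#' @param ss_amount Fixed immediate amount.
#' @return A choice data frame (one row per trial) with columns `subject_id`,
#'   `condition`, `i_ero`, `trial_index`, `ll_amount`, `delay_days`, `choice`.
#' @export
simulate_subject <- function(params, trials, i_ero, seed,
                             variant = c("offset", "base"),
                             miss_rate = 0, subject_id = "s1",
                             ss_amount = 20) {
  variant <- match.arg(variant)
  if (missing(seed)) stop("`seed` must be given explicitly", call. = FALSE)
  if (length(i_ero) != 1L || !i_ero %in% c(0, 1))
    stop("`i_ero` must be a single 0 or 1", call. = FALSE)
  if (miss_rate < 0 || miss_rate >= 1)
    stop("`miss_rate` must be in [0, 1)", call. = FALSE)
  if (variant == "offset") {
    eff <- params$omega_neut + i_ero * params$s_ero_omega
    if (eff <= 0 || eff > 1)
      stop("effective offset must lie in (0, 1]", call. = FALSE)
  }
  n <- nrow(trials)
  k <- modulated_k(params$log_k_neut, params$s_ero_k, i_ero)
  sv <- sv_hyperbolic(trials$ll_amount, trials$delay_days, k)
  if (variant == "offset")
    sv <- apply_offset(sv, params$omega_neut, params$s_ero_omega, i_ero)
  beta <- params$beta_neut + i_ero * params$s_ero_beta
  p_ll <- choice_prob(sv, ss_amount, beta)
  set.seed(seed)
  y <- stats::rbinom(n, 1L, p_ll)
  choice <- ifelse(y == 1L, "LL", "SS")
  if (miss_rate > 0)
    choice[stats::runif(n) < miss_rate] <- "INVALID"
  out <- data.frame(
    subject_id = subject_id,
    condition = if (i_ero == 1) "erotic" else "neutral",
    i_ero = as.integer(i_ero),
    trial_index = trials$trial_index,
    ll_amount = trials$ll_amount,
    delay_days = trials$delay_days,
    choice = choice
  )
  attr(out, "ss_amount") <- ss_amount
  out
}

#' Simulate a full two-condition cohort
#'
#' Draws per-subject parameters from the group-level Gaussians of `truth`
#' (offset parameters on the logit scale) and simulates one neutral and one
#' erotic 128-trial dataset per subject. Design Sets 1 and 2 are assigned to
#' conditions alternately by subject index (`"alternate"`, the default,
#' deterministic counterbalancing), or a fixed set can be used for all.
#'
#' @param truth A [td_ground_truth()] object.
#' @param n_subjects Number of subjects, `>= 2`.
#' @param seed Integer seed driving both the parameter draws and the choices.
#' @param variant Generative model variant.
#' @param miss_rate Per-trial INVALID probability.
#' @param design_assignment `"alternate"` (counterbalanced by subject index),
#'   `"fixed1"` or `"fixed2"`.
#' @param ss_amount Fixed immediate amount.
#' @return A list of class `"td_cohort"` with elements `data` (long choice data
#'   frame, `2 * 128 * n_subjects` rows) and `truth` (list: `group` = the input
#'   ground truth, `subjects` = realized per-subject parameters, both on the
#'   sampling scale and as natural-scale [td_params()] fields).
#' @export
simulate_cohort <- function(truth = td_ground_truth(), n_subjects, seed,
                            variant = c("offset", "base"), miss_rate = 0,
                            design_assignment = c("alternate", "fixed1",
                                                  "fixed2"),
                            ss_amount = 20) {
  variant <- match.arg(variant)
  design_assignment <- match.arg(design_assignment)
  if (!inherits(truth, "td_ground_truth"))
    stop("`truth` must be a td_ground_truth object", call. = FALSE)
  if (missing(seed)) stop("`seed` must be given explicitly", call. = FALSE)
  if (n_subjects < 2) stop("`n_subjects` must be >= 2", call. = FALSE)

  m <- truth$group_means; s <- truth$group_sds
  set.seed(seed)
  th <- cbind(
    log_k = stats::rnorm(n_subjects, m["log_k"], s["log_k"]),
    s_ero_k = stats::rnorm(n_subjects, m["s_ero_k"], s["s_ero_k"]),
    beta = stats::rnorm(n_subjects, m["beta"], s["beta"]),
    s_ero_beta = stats::rnorm(n_subjects, m["s_ero_beta"], s["s_ero_beta"]),
    logit_omega = stats::rnorm(n_subjects, m["logit_omega"], s["logit_omega"]),
    s_ero_omega = stats::rnorm(n_subjects, m["s_ero_omega"], s["s_ero_omega"])
  )
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_subjects)

  ids <- sprintf("s%02d", seq_len(n_subjects))
  designs <- list(td_design(1, ss_amount), td_design(2, ss_amount))
  rows <- vector("list", 2L * n_subjects)
  subj <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    neut_set <- switch(design_assignment,
                       alternate = if (i %% 2L == 1L) 1L else 2L,
                       fixed1 = 1L, fixed2 = 2L)
    ero_set <- switch(design_assignment,
                      alternate = if (i %% 2L == 1L) 2L else 1L,
                      fixed1 = 1L, fixed2 = 2L)
    omega_neut <- stats::plogis(th[i, "logit_omega"])
    omega_ero <- stats::plogis(th[i, "logit_omega"] + th[i, "s_ero_omega"])
    p <- td_params(log_k_neut = th[i, "log_k"], s_ero_k = th[i, "s_ero_k"],
                   beta_neut = th[i, "beta"], s_ero_beta = th[i, "s_ero_beta"],
                   omega_neut = omega_neut,
                   s_ero_omega = omega_ero - omega_neut)
    rows[[2L * i - 1L]] <- simulate_subject(
      p, designs[[neut_set]], i_ero = 0, seed = sub_seeds[2L * i - 1L],
      variant = variant, miss_rate = miss_rate, subject_id = ids[i],
      ss_amount = ss_amount)
    rows[[2L * i]] <- simulate_subject(
      p, designs[[ero_set]], i_ero = 1, seed = sub_seeds[2L * i],
      variant = variant, miss_rate = miss_rate, subject_id = ids[i],
      ss_amount = ss_amount)
    subj[[i]] <- data.frame(subject_id = ids[i],
                            log_k = th[i, "log_k"], s_ero_k = th[i, "s_ero_k"],
                            beta = th[i, "beta"],
                            s_ero_beta = th[i, "s_ero_beta"],
                            logit_omega = th[i, "logit_omega"],
                            s_ero_omega_logit = th[i, "s_ero_omega"],
                            omega_neut = omega_neut,
                            omega_ero = omega_ero,
                            neutral_set = neut_set, erotic_set = ero_set)
  }
  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  attr(data, "ss_amount") <- ss_amount
  structure(list(data = data,
                 truth = list(group = truth,
                              subjects = do.call(rbind, subj))),
            class = "td_cohort")
}
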