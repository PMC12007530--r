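# S3 methods for the fitted-model object and result classes.

#' @export
print.td_fit <- function(x, ...) {
  cat("Hierarchical discounting model fit (", x$variant, " variant)\n",
      sep = "")
  cat(sprintf("  %d subjects, %d valid trials%s\n", length(x$subjects),
              nrow(x$data),
              if (x$single_condition) " (single condition)" else ""))
  cat(sprintf("  %d chains, %d warmup, %d retained draws (%s offset link)\n",
              x$chains, x$warmup, x$retained, x$omega_link))
  if (!is.null(x$convergence)) {
    cat(sprintf("  convergence: max split R-hat %.3f (%s, threshold %.2f)\n",
                max(x$convergence$rhat, na.rm = TRUE),
                if (attr(x$convergence, "pass")) "pass" else "FAIL",
                x$rhat_threshold))
  }
  invisible(x)
}

#' Posterior summary of the group-level parameters
#'
#' @param object A `"td_fit"` object.
#' @param ... Unused.
#' @return Data frame: posterior mean, SD, central 95% quantile interval,
#'   split R-hat and ESS per group-level parameter.
#' @export
summary.td_fit <- function(object, ...) {
  grp <- grep("^(mu_|sd_)", colnames(object$draws), value = TRUE)
  dr <- object$draws[, grp, drop = FALSE]
  out <- data.frame(
    parameter = grp,
    mean = colMeans(dr),
    sd = apply(dr, 2L, stats::sd),
    q2.5 = apply(dr, 2L, stats::quantile, 0.025),
    q97.5 = apply(dr, 2L, stats::quantile, 0.975))
  if (!is.null(object$convergence)) {
    cv <- object$convergence
    out$rhat <- cv$rhat[match(grp, cv$parameter)]
    out$ess <- cv$ess[match(grp, cv$parameter)]
  }
  rownames(out) <- NULL
  out
}

#' Posterior-mean parameter estimates
#'
#' @param object A `"td_fit"` object.
#' @param ... Unused.
#' @return A list with `group` (posterior means of the group-level
#'   parameters) and `subjects` (data frame of per-subject posterior-mean
#'   parameters on the natural [td_params()] scale).
#' @export
coef.td_fit <- function(object, ...) {
  grp <- grep("^(mu_|sd_)", colnames(object$draws), value = TRUE)
  subjects <- do.call(rbind, lapply(seq_along(object$subjects), function(s)
    data.frame(subject_id = object$subjects[s],
               t(colMeans(.subject_param_draws(object, s))))))
  list(group = colMeans(object$draws[, grp, drop = FALSE]),
       subjects = subjects)
}

#' Model choice probabilities or predicted choices
#'
#' Evaluates the model at the posterior means of the subject-level parameters
#' on the fitted trials (or new trials with the same columns).
#'
#' @param object A `"td_fit"` object.
#' @param newdata Optional choice data frame; defaults to the fitted data.
#' @param type `"prob"` for P(LL) per trial, `"choice"` for the
#'   higher-probability option label.
#' @param ... Unused.
#' @return Numeric vector of probabilities, or character vector of
#'   `"SS"`/`"LL"`.
#' @export
predict.td_fit <- function(object, newdata = NULL, type = c("prob", "choice"),
                           ...) {
  type <- match.arg(type)
  d <- if (is.null(newdata)) object$data else
    newdata[newdata$choice != "INVALID", , drop = FALSE]
  if (any(!d$subject_id %in% object$subjects))
    stop("unknown subject in `newdata`", call. = FALSE)
  cs <- coef(object)$subjects
  i <- match(d$subject_id, cs$subject_id)
  iero <- if (object$single_condition) rep(0L, nrow(d)) else
    as.integer(d$i_ero)
  k <- exp(.clip(cs$log_k_neut[i] + iero * cs$s_ero_k[i]))
  sv <- d$ll_amount / (1 + k * d$delay_days)
  if (object$variant == "offset")
    sv <- sv * (cs$omega_neut[i] + iero * cs$s_ero_omega[i])
  p <- stats::plogis(.clip((cs$beta_neut[i] + iero * cs$s_ero_beta[i]) *
                             (sv - object$ss_amount)))
  if (type == "prob") p else ifelse(p >= 0.5, "LL", "SS")
}

#' Response residuals of the fitted choices
#'
#' Observed choice (LL = 1, SS = 0) minus the model probability of choosing
#' LL at posterior-mean parameters.
#'
#' @param object A `"td_fit"` object.
#' @param ... Unused.
#' @return Numeric vector, one element per valid fitted trial.
#' @export
residuals.td_fit <- function(object, ...) {
  as.integer(object$data$choice == "LL") - predict(object, type = "prob")
}

#' Simulate datasets from the posterior predictive distribution
#'
#' Thin wrapper over [posterior_predictive()].
#'
#' @param object A `"td_fit"` object.
#' @param nsim Number of simulated datasets (default: all retained draws).
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A `"td_ppc_sims"` object.
#' @export
simulate.td_fit <- function(object, nsim = NULL, seed = 1, ...) {
  posterior_predictive(object, n_datasets = nsim, seed = seed)
}

#' Posterior predictive check plot
#'
#' Observed group-mean LL-choice proportions per delay bin (points with
#' across-subject standard errors) against the simulated central interval
#' (shaded band), one panel per condition.
#'
#' @param x A `"td_fit"` object.
#' @param ppc Optional precomputed [ppc_summary()].
#' @param ... Passed to [ppc_summary()] when `ppc` is missing.
#' @return The `"td_ppc"` summary, invisibly.
#' @export
plot.td_fit <- function(x, ppc = NULL, ...) {
  if (is.null(ppc)) ppc <- ppc_summary(x, ...)
  conds <- unique(ppc$condition)
  op <- graphics::par(mfrow = c(1, length(conds)))
  on.exit(graphics::par(op))
  for (cc in conds) {
    p <- ppc[ppc$condition == cc, ]
    xx <- seq_len(nrow(p))
    graphics::plot(xx, p$observed_mean, ylim = c(0, 1), pch = 19,
                   xaxt = "n", xlab = "delay bin (days)",
                   ylab = "P(LL choice)", main = cc)
    graphics::axis(1, at = xx, labels = p$delay_bin)
    graphics::polygon(c(xx, rev(xx)),
                      c(p$simulated_lower, rev(p$simulated_upper)),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
    graphics::lines(xx, p$simulated_mean, col = "steelblue", lwd = 2)
    graphics::arrows(xx, p$observed_mean - p$observed_se,
                     xx, p$observed_mean + p$observed_se,
                     angle = 90, code = 3, length = 0.03)
    graphics::points(xx, p$observed_mean, pch = 19)
  }
  invisible(ppc)
}

#' @export
print.td_waic <- function(x, ...) {
  cat(sprintf("WAIC %s: %.2f (lppd %.2f, p_waic %.2f, SE %.2f, %d trials)\n",
              if (is.null(x$model)) "" else paste0("[", x$model, "]"),
              x$waic, x$lppd, x$p_waic, x$se, x$n_trials))
  invisible(x)
}

#' @export
print.td_cor <- function(x, ...) {
  cat(sprintf("Bayesian correlation: r = %.3f (n = %d), BF10 = %.3f, ",
              x$r, x$n, x$bf10))
  cat(sprintf("BF01 = %.3f, %d%% CI [%.3f, %.3f]\n", x$bf01,
              round(100 * x$interval), x$ci_lower, x$ci_upper))
  invisible(x)
}
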