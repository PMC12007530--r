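# Posterior predictive checks of LL-choice proportions across delays.

#' Simulate datasets from the fitted posterior
#'
#' Draws `n_datasets` retained posterior draws (without replacement) and, for
#' each, simulates one complete dataset of choices on every subject's own
#' trials and condition indicators.
#'
#' @param fit A `"td_fit"` object.
#' @param n_datasets Number of simulated datasets; must not exceed the number
#'   of retained draws. Defaults to all retained draws (the full analysis
#'   uses 4000).
#' @param seed Integer seed.
#' @return A list of class `"td_ppc_sims"`: `trials` (the observed data frame
#'   without its choices) and `choices`, an `n_datasets x n_trials` 0/1 matrix
#'   (1 = LL).
#' @export
posterior_predictive <- function(fit, n_datasets = NULL, seed = 1) {
  stopifnot(inherits(fit, "td_fit"))
  ndr <- nrow(fit$draws)
  if (is.null(n_datasets)) n_datasets <- ndr
  if (n_datasets > ndr)
    stop("`n_datasets` must not exceed the retained draws", call. = FALSE)
  set.seed(seed)
  sel <- sort(sample.int(ndr, n_datasets))
  d <- fit$data
  iero <- if (fit$single_condition) rep(0L, nrow(d)) else as.integer(d$i_ero)
  subj <- match(d$subject_id, fit$subjects)
  pars <- lapply(seq_along(fit$subjects),
                 function(s) as.matrix(.subject_param_draws(fit, s)))
  pm <- matrix(NA_real_, n_datasets, nrow(d))
  for (i in seq_len(n_datasets)) {
    th <- t(vapply(pars, function(m) m[sel[i], ], numeric(6L)))
    k <- exp(.clip(th[subj, 1L] + iero * th[subj, 2L]))
    sv <- d$ll_amount / (1 + k * d$delay_days)
    if (fit$variant == "offset")
      sv <- sv * (th[subj, 5L] + iero * th[subj, 6L])
    pm[i, ] <- stats::plogis(.clip((th[subj, 3L] + iero * th[subj, 4L]) *
                                     (sv - fit$ss_amount)))
  }
  choices <- matrix(stats::rbinom(length(pm), 1L, pm), nrow(pm), ncol(pm))
  structure(list(trials = d[, setdiff(names(d), "choice")],
                 choices = choices, draw_index = sel),
            class = "td_ppc_sims")
}

#' Observed LL-choice proportion per delay bin
#'
#' Group mean of the per-subject LL-choice fractions in each delay bin, with
#' the across-subject standard error, split by condition. Delays are pooled
#' into the eight canonical bins via [delay_bins()] unless `bin_map` says
#' otherwise.
#'
#' @param data Long-format choice data frame; INVALID trials are excluded.
#' @param bin_map Optional named numeric vector mapping each delay (name) to
#'   its bin label (value); defaults to nearest-Set-1-delay pooling.
#' @return Data frame: `condition`, `delay_bin`, `n_subjects`, `observed_mean`,
#'   `observed_se`.
#' @export
ll_proportion_by_delay <- function(data, bin_map = NULL) {
  d <- data[data$choice != "INVALID", , drop = FALSE]
  if (nrow(d) == 0L) stop("no valid trials", call. = FALSE)
  if (is.null(bin_map)) {
    bins <- delay_bins(d$delay_days)
  } else {
    if (any(!as.character(d$delay_days) %in% names(bin_map)))
      stop("`bin_map` does not cover all delays present", call. = FALSE)
    bins <- unname(bin_map[as.character(d$delay_days)])
  }
  frac <- aggregate(list(frac = d$choice == "LL"),
                    by = list(subject_id = d$subject_id,
                              condition = d$condition, delay_bin = bins),
                    FUN = mean)
  out <- aggregate(list(observed_mean = frac$frac),
                   by = list(condition = frac$condition,
                             delay_bin = frac$delay_bin), FUN = mean)
  se <- aggregate(list(observed_se = frac$frac),
                  by = list(condition = frac$condition,
                            delay_bin = frac$delay_bin),
                  FUN = function(v) stats::sd(v) / sqrt(length(v)))
  n <- aggregate(list(n_subjects = frac$subject_id),
                 by = list(condition = frac$condition,
                           delay_bin = frac$delay_bin),
                 FUN = function(v) length(unique(v)))
  out <- merge(merge(out, se), n)
  out$observed_se[is.na(out$observed_se)] <- 0
  out[order(out$condition, out$delay_bin),
      c("condition", "delay_bin", "n_subjects", "observed_mean",
        "observed_se")]
}

#' Posterior predictive check summary per delay bin
#'
#' Compares the observed group-mean LL-choice proportion per delay bin and
#' condition against the distribution of the same statistic across simulated
#' datasets, giving a central interval (default 95%).
#'
#' @param fit A `"td_fit"` object.
#' @param sims Optional `"td_ppc_sims"` from [posterior_predictive()];
#'   simulated on the fly otherwise.
#' @param n_datasets,seed Passed to [posterior_predictive()] when `sims` is
#'   missing.
#' @param interval Central interval mass for the simulated statistic.
#' @param bin_map Optional delay-to-bin map (see [ll_proportion_by_delay()]).
#' @return Data frame of class `"td_ppc"`: observed mean and SE plus
#'   `simulated_mean`, `simulated_lower`, `simulated_upper`,
#'   `n_simulated_datasets` per condition x delay bin.
#' @export
ppc_summary <- function(fit, sims = NULL, n_datasets = NULL, seed = 1,
                        interval = 0.95, bin_map = NULL) {
  stopifnot(inherits(fit, "td_fit"))
  if (is.null(sims)) sims <- posterior_predictive(fit, n_datasets, seed)
  obs <- ll_proportion_by_delay(fit$data, bin_map)
  tr <- sims$trials
  bins <- if (is.null(bin_map)) delay_bins(tr$delay_days) else
    unname(bin_map[as.character(tr$delay_days)])
  cell <- interaction(tr$subject_id, tr$condition, bins, drop = TRUE)
  cmeans <- t(rowsum(t(sims$choices), cell) / as.vector(table(cell)))
  info <- do.call(rbind, strsplit(colnames(cmeans), ".", fixed = TRUE))
  grp <- interaction(info[, 2], info[, 3], drop = TRUE)
  gmeans <- t(rowsum(t(cmeans), grp) / as.vector(table(grp)))
  ginfo <- do.call(rbind, strsplit(colnames(gmeans), ".", fixed = TRUE))
  a <- (1 - interval) / 2
  sim <- data.frame(condition = ginfo[, 1],
                    delay_bin = as.numeric(ginfo[, 2]),
                    simulated_mean = colMeans(gmeans),
                    simulated_lower = apply(gmeans, 2L, stats::quantile, a),
                    simulated_upper = apply(gmeans, 2L, stats::quantile,
                                            1 - a))
  out <- merge(obs, sim, by = c("condition", "delay_bin"))
  out$n_simulated_datasets <- nrow(sims$choices)
  out <- out[order(out$condition, out$delay_bin), ]
  rownames(out) <- NULL
  class(out) <- c("td_ppc", "data.frame")
  out
}
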