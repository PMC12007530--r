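# WAIC model comparison on the deviance scale.

#' Widely applicable information criterion
#'
#' From a draws x trials matrix of pointwise log-likelihoods:
#' `lppd = sum_i log mean_s exp(ll_si)` (computed by log-sum-exp),
#' `p_waic = sum_i var_s(ll_si)`, and `waic = -2 (lppd - p_waic)` (deviance
#' scale, lower is better). The standard error is that of the pointwise WAIC
#' contributions.
#'
#' @param x A draws x trials matrix of pointwise log-likelihoods, or a
#'   `"td_fit"` object (the matrix is then computed from its retained draws).
#' @param model Optional label used by [rank_models()].
#' @return A list of class `"td_waic"`: `waic`, `lppd`, `p_waic`, `se`,
#'   `n_trials`, `n_draws`, `pointwise` (per-trial elpd contributions),
#'   `model`.
#' @export
waic <- function(x, model = NULL) {
  if (inherits(x, "td_fit")) {
    if (is.null(model)) model <- x$variant
    x <- .fit_pointwise_loglik(x)
  }
  if (!is.matrix(x)) stop("`x` must be a matrix or td_fit", call. = FALSE)
  if (nrow(x) < 2L) stop("need at least 2 draws", call. = FALSE)
  if (ncol(x) < 1L) stop("need at least 1 trial", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite log-likelihood entries",
                               call. = FALSE)
  ns <- nrow(x)
  # column-wise log mean exp, overflow-safe
  mx <- apply(x, 2L, max)
  lppd_i <- mx + log(colMeans(exp(sweep(x, 2L, mx))))
  p_i <- apply(x, 2L, stats::var)
  elpd_i <- lppd_i - p_i
  waic_i <- -2 * elpd_i
  structure(list(
    waic = sum(waic_i), lppd = sum(lppd_i), p_waic = sum(p_i),
    se = sqrt(ncol(x) * stats::var(waic_i)),
    n_trials = ncol(x), n_draws = ns, pointwise = elpd_i, model = model
  ), class = "td_waic")
}

#' Rank models by WAIC
#'
#' Ascending WAIC (rank 1 = best fit); ties are broken by smaller `p_waic`
#' (fewer effective parameters), then by model name.
#'
#' @param ... Two or more `"td_waic"` objects, or a single list of them.
#' @return Data frame with columns `model`, `waic`, `lppd`, `p_waic`, `se`,
#'   `rank`, sorted by rank.
#' @export
rank_models <- function(...) {
  res <- list(...)
  if (length(res) == 1L && !inherits(res[[1]], "td_waic")) res <- res[[1]]
  if (length(res) < 2L) stop("need at least 2 models to rank", call. = FALSE)
  if (!all(vapply(res, inherits, logical(1), "td_waic")))
    stop("all arguments must be td_waic objects", call. = FALSE)
  nm <- vapply(seq_along(res), function(i) {
    m <- res[[i]]$model
    if (is.null(m)) paste0("model", i) else as.character(m)
  }, character(1))
  tab <- data.frame(model = nm,
                    waic = vapply(res, `[[`, numeric(1), "waic"),
                    lppd = vapply(res, `[[`, numeric(1), "lppd"),
                    p_waic = vapply(res, `[[`, numeric(1), "p_waic"),
                    se = vapply(res, `[[`, numeric(1), "se"))
  o <- order(tab$waic, tab$p_waic, tab$model)
  tab <- tab[o, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' Choice-prediction accuracy at posterior-mean parameters
#'
#' Fraction of valid trials on which the option with the higher model choice
#' probability (evaluated at the posterior means of the subject-level
#' parameters) matches the observed choice.
#'
#' @param fit A `"td_fit"` object.
#' @return A single proportion in `[0, 1]`.
#' @export
choice_accuracy <- function(fit) {
  stopifnot(inherits(fit, "td_fit"))
  p <- predict(fit, type = "prob")
  mean((p >= 0.5) == (fit$data$choice == "LL"))
}
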