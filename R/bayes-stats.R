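# Posterior summarization and hypothesis evaluation: highest density
# intervals, Savage-Dickey and directional Bayes factors, default-prior
# Bayesian correlations, and pooled t-tests from summary statistics.

#' Highest density interval
#'
#' Shortest contiguous interval containing at least `mass` of the draws:
#' among all windows of `ceiling(mass * n)` consecutive sorted draws, the
#' narrowest.
#'
#' @param draws Numeric vector of posterior draws (at least 100).
#' @param mass Probability mass in (0, 1); default 0.95.
#' @return Numeric `c(lower, upper)` with attribute `mass`.
#' @export
hdi <- function(draws, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("`mass` must be in (0, 1)", call. = FALSE)
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 100L) stop("need at least 100 draws", call. = FALSE)
  x <- sort(draws)
  m <- ceiling(mass * n)
  w <- x[m:n] - x[seq_len(n - m + 1L)]
  i <- which.min(w)
  structure(c(lower = x[i], upper = x[i + m - 1L]), mass = mass)
}

#' Savage-Dickey density-ratio Bayes factor
#'
#' `BF01` for a point null: the posterior density of the parameter at the null
#' value (Gaussian kernel estimate with Silverman's bandwidth by default, or a
#' normal approximation) divided by the prior density there. `BF01 > 1`
#' favours the restricted (null) model.
#'
#' @param posterior_draws Numeric vector of posterior draws.
#' @param prior_density_at_null Prior density evaluated at the null (positive
#'   number; see [prior_density_at_null()]).
#' @param null_value The restricted value (default 0).
#' @param method `"kde"` (default) or `"normal"` posterior density estimate.
#' @return Positive scalar `BF01`.
#' @export
savage_dickey_bf01 <- function(posterior_draws, prior_density_at_null,
                               null_value = 0, method = c("kde", "normal")) {
  method <- match.arg(method)
  if (!is.numeric(prior_density_at_null) || prior_density_at_null <= 0)
    stop("`prior_density_at_null` must be positive", call. = FALSE)
  x <- posterior_draws[is.finite(posterior_draws)]
  if (length(x) < 100L) stop("need at least 100 draws", call. = FALSE)
  post <- if (method == "kde") {
    # Gaussian kernel estimate, evaluated exactly at the null, with
    # variance-preserving shrinkage of the draws (kernel smoothing inflates
    # the spread by the bandwidth; shrinking the draws toward their mean by
    # sqrt(1 - (h/s)^2) restores the posterior's first two moments)
    h <- stats::bw.nrd0(x)
    s <- stats::sd(x)
    m <- mean(x)
    xs <- m + (x - m) * sqrt(max(1 - (h / s)^2, 0))
    mean(stats::dnorm(null_value, xs, h))
  } else {
    stats::dnorm(null_value, mean(x), stats::sd(x))
  }
  if (!is.finite(post) || post <= 0) {
    warning("posterior density at the null is numerically zero; ",
            "returning machine floor", call. = FALSE)
    post <- .Machine$double.xmin
  }
  post / prior_density_at_null
}

#' Directional Bayes factor
#'
#' Ratio of the posterior mass below zero to the posterior mass above zero.
#' Exact zeros count to neither side. If all draws fall on one side the ratio
#' is capped by treating the empty side as half a draw, with a warning.
#'
#' @param posterior_draws Numeric vector of posterior draws (at least 100).
#' @return Positive scalar `dBF`.
#' @export
directional_bf <- function(posterior_draws) {
  x <- posterior_draws[is.finite(posterior_draws)]
  if (length(x) < 100L) stop("need at least 100 draws", call. = FALSE)
  nb <- sum(x < 0)
  na <- sum(x > 0)
  if (nb == 0L || na == 0L) {
    warning("posterior is one-sided; directional Bayes factor capped",
            call. = FALSE)
    return(max(nb, 0.5) / max(na, 0.5))
  }
  if (min(nb, na) < 5L)
    warning("posterior is nearly one-sided; directional Bayes factor is ",
            "unstable", call. = FALSE)
  nb / na
}

#' Evidence category of a Bayes factor
#'
#' Categorizes the strength of evidence: Bayes factors in (1, 3] are
#' anecdotal, in (3, 10] moderate, above 10 strong; reciprocal values mirror
#' these categories in favour of the opposite hypothesis.
#'
#' @param bf Positive Bayes factor(s).
#' @return Character vector of labels such as `"moderate"`, or
#'   `"moderate (reciprocal)"` when `bf < 1`.
#' @export
evidence_label <- function(bf) {
  if (any(bf <= 0)) stop("Bayes factors must be positive", call. = FALSE)
  vapply(bf, function(b) {
    recip <- b < 1
    m <- max(b, 1 / b)
    lab <- if (m <= 1) "none" else if (m <= 3) "anecdotal" else
      if (m <= 10) "moderate" else "strong"
    if (recip && lab != "none") paste(lab, "(reciprocal)") else lab
  }, character(1))
}

# correlation-coefficient likelihood kernel in rho, normalized so that
# rho = 0 gives 1 (Jeffreys); the r- and n-only factors cancel in the BF
.cor_kernel <- function(rho, r, n) {
  (1 - rho^2)^((n - 1) / 2) * (1 - rho * r)^((3 - 2 * n) / 2)
}

#' Default-prior Bayesian correlation
#'
#' Pearson correlation with a default Bayes factor computed by numerical
#' integration of the correlation likelihood under a uniform prior on the
#' population correlation (stretched beta with kappa = 1), plus a central
#' credible interval for the population correlation from the same posterior.
#'
#' @param x,y Numeric vectors of equal length (at least 5), finite values.
#' @param interval Credible-interval mass (default 0.95).
#' @return A list of class `"td_cor"`: `r`, `n`, `bf10`, `bf01`,
#'   `ci_lower`, `ci_upper`.
#' @export
bayes_cor <- function(x, y, interval = 0.95) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length",
                                   call. = FALSE)
  n <- length(x)
  if (n < 5L) stop("need at least 5 observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("values must be finite", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in `x` or `y`", call. = FALSE)
  r <- stats::cor(x, y)
  if (1 - r^2 < 1e-12) {
    # perfectly correlated data: the likelihood piles onto rho = r and the
    # point null is ruled out
    return(structure(list(r = r, n = n, bf10 = Inf, bf01 = 0,
                          ci_lower = r, ci_upper = r, interval = interval),
                     class = "td_cor"))
  }
  bf10 <- stats::integrate(function(rho) .cor_kernel(rho, r, n) / 2,
                           -1, 1, rel.tol = 1e-10)$value
  # posterior of rho on a fine grid for the credible interval
  grid <- seq(-0.9999, 0.9999, length.out = 4001L)
  dens <- .cor_kernel(grid, r, n)
  cdf <- cumsum(dens) / sum(dens)
  a <- (1 - interval) / 2
  ci <- stats::approx(cdf, grid, xout = c(a, 1 - a), ties = "ordered")$y
  structure(list(r = r, n = n, bf10 = bf10, bf01 = 1 / bf10,
                 ci_lower = ci[1], ci_upper = ci[2], interval = interval),
            class = "td_cor")
}

#' Pooled two-sample t-test from summary statistics
#'
#' Equal-variance two-sample t computed from group means, SDs and sizes:
#' `t = (m1 - m2) / (sp * sqrt(1/n1 + 1/n2))` with the pooled SD `sp` and
#' `df = n1 + n2 - 2`.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return List with `t`, `df` and the two-sided `p`.
#' @examples
#' # valence ratings of the two image pools (90 images each)
#' pooled_two_sample_t(64.92, 3.39, 90, 48.90, 9.84, 90) # t = 14.60, df = 178
#' @export
pooled_two_sample_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("SDs must be >= 0", call. = FALSE)
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 == 0) stop("zero pooled variance", call. = FALSE)
  df <- n1 + n2 - 2
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Posterior summary of the condition-shift parameters
#'
#' For each group-level shift mean of a two-condition fit (log-k shift, offset
#' shift, beta shift): posterior mean and SD, the directional Bayes factor
#' (mass below zero over mass above zero), the Savage-Dickey `BF01` against
#' the point null at zero, and 85%/95% highest density intervals.
#'
#' @param fit A two-condition `"td_fit"` object.
#' @param method Density estimator passed to [savage_dickey_bf01()].
#' @return Data frame with one row per shift parameter.
#' @export
shift_report <- function(fit, method = c("kde", "normal")) {
  stopifnot(inherits(fit, "td_fit"))
  method <- match.arg(method)
  if (fit$single_condition)
    stop("shift parameters are absent from a single-condition fit",
         call. = FALSE)
  pars <- c(s_ero_k = "mu_s_ero_k", s_ero_beta = "mu_s_ero_beta")
  if (fit$variant == "offset")
    pars <- c(pars[1], s_ero_omega = "mu_s_ero_omega", pars[2])
  rows <- lapply(names(pars), function(p) {
    dr <- fit$draws[, pars[[p]]]
    h85 <- hdi(dr, 0.85)
    h95 <- hdi(dr, 0.95)
    data.frame(parameter = p, mean = mean(dr), sd = stats::sd(dr),
               dbf = directional_bf(dr),
               bf01 = savage_dickey_bf01(
                 dr, prior_density_at_null(fit$priors, p), 0, method),
               hdi85_lower = h85[1], hdi85_upper = h85[2],
               hdi95_lower = h95[1], hdi95_upper = h95[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
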