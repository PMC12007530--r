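# Hierarchical Bayesian estimation of the discounting model.
#
# Sampler: adaptive Metropolis-within-Gibbs on the centred parameterization.
# Each recorded sweep comprises `cycles` full update cycles of:
#   1.  per-subject, per-parameter random-walk MH, vectorized across
#       subjects, with Robbins-Monro adaptation of proposal scales during
#       warmup;
#   1b. joint full-covariance subject moves whose proposal Cholesky factors
#       are learned from the chain's own history (captures e.g. the log k /
#       offset ridge of near-always-LL subjects);
#   2.  per-subject "trade-off" moves along (neutral +e, shift -e) for each
#       (baseline, shift) pair -- these directions are strongly correlated
#       in the posterior because erotic-condition trials constrain only the
#       sum;
#   3.  conjugate Gibbs draws of the Normal-prior group means (slice step
#       for the offset group mean, whose Uniform prior is logistic on the
#       sampling scale);
#   4.  univariate slice draws of the half-Normal group SDs;
#   5.  interweaved non-centred (ASIS) scale moves on each (group SD,
#       subject deviations) block, which decorrelates the SDs from the
#       subject values and removes the funnel that slows the centred scheme.
# All proposal adaptation happens during warmup only and is frozen after.
# Likelihood sums are computed by the compiled .cohort_loglik_sums(), a
# single-pass mirror of the R-level .ll_core() arithmetic (their agreement
# is asserted by the test suite).

# stepping-out univariate slice sampler (Neal 2003)
.slice1 <- function(x0, logf, w = 0.5, lower = -Inf, upper = Inf,
                    max_steps = 50L) {
  ly <- logf(x0) - stats::rexp(1)
  L <- x0 - stats::runif(1) * w
  R <- L + w
  i <- 0L
  while (L > lower && logf(L) > ly && i < max_steps) { L <- L - w; i <- i + 1L }
  i <- 0L
  while (R < upper && logf(R) > ly && i < max_steps) { R <- R + w; i <- i + 1L }
  L <- max(L, lower); R <- min(R, upper)
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) > ly) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

# truncated-normal draw via inverse CDF (used for the identity-link offset
# group mean, whose Uniform prior is conjugate-truncated)
.rtruncnorm1 <- function(mean, sd, lower, upper) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  if (pu - pl < 1e-12) return(min(max(mean, lower), upper))
  stats::qnorm(stats::runif(1, pl, pu), mean, sd)
}

# per-subject log-likelihood sums for a full parameter matrix th (S x 6);
# compiled single-pass version of the .ll_core() arithmetic (their agreement
# is asserted by the test suite)
.cohort_loglik <- function(th, dat, offset, link) {
  if (dat$prior_only) return(rep(0, dat$S))
  .cohort_loglik_sums(th, dat$subj, dat$iero, dat$ll, dat$d, dat$y,
                      dat$ss, dat$S, offset, link == "logit")
}

.td_chain <- function(dat, prior, active, offset, link, warmup, kept, seed,
                      cycles = 4L) {
  S <- dat$S
  set.seed(seed)
  # prior (mean, sd) per column on the sampling scale; col 5 handled apart
  pm <- c(prior$mean_log_k[1], prior$mean_s_k[1], prior$mean_beta[1],
          prior$mean_s_beta[1], NA, prior$mean_s_omega[1])
  ps <- c(prior$mean_log_k[2], prior$mean_s_k[2], prior$mean_beta[2],
          prior$mean_s_beta[2], NA, prior$mean_s_omega[2])
  ob <- prior$omega_uniform
  lob <- if (link == "logit") stats::qlogis(pmin(pmax(ob, 1e-12), 1 - 1e-12)) else ob

  mu <- c(pm[1], 0, pm[3], 0, 0, 0)
  if (active[2]) mu[2] <- pm[2]
  if (active[4]) mu[4] <- pm[4]
  mu[5] <- if (link == "logit") 0 else 0.5
  sigma <- ifelse(active, 0.5, 0)
  th <- matrix(0, S, 6L)
  for (j in which(active)) th[, j] <- mu[j] + stats::rnorm(S, 0, 0.1)
  if (offset && link == "identity")
    th[, 5L] <- pmin(pmax(th[, 5L], 0.05), 0.95)

  lsc <- matrix(log(0.1), S, 6L)           # per-(subject, param) MH log-scales
  pair_cols <- list(c(1L, 2L), c(3L, 4L), c(5L, 6L))
  pairs_on <- vapply(pair_cols, function(p) all(active[p]), logical(1))
  lsp <- matrix(log(0.1), S, 3L)           # pair-move log-scales
  lss <- rep(log(0.3), 6L)                 # ASIS log-scales

  # adaptive joint (full-covariance) subject moves: running moments of the
  # subject vectors feed per-subject Cholesky proposal factors, capturing
  # cross-correlations (e.g. log k with the offset for near-always-LL
  # subjects) that componentwise moves miss
  acols <- which(active)
  nact <- length(acols)
  lam <- rep(log(1), S)                    # per-subject joint-move log-scale
  M1 <- matrix(0, S, 6L)
  M2 <- array(0, c(S, 6L, 6L))
  ncov <- 0L
  Lchol <- rep(list(diag(0.05, nact)), S)

  cll <- .cohort_loglik(th, dat, offset, link)
  nm_mu <-c("mu_log_k", "mu_s_ero_k", "mu_beta", "mu_s_ero_beta",
             if (link == "logit") "mu_logit_omega" else "mu_omega",
             "mu_s_ero_omega")
  nm_sd <- c("sd_log_k", "sd_s_ero_k", "sd_beta", "sd_s_ero_beta",
             if (link == "logit") "sd_logit_omega" else "sd_omega",
             "sd_s_ero_omega")
  par_nm <- c("log_k", "s_ero_k", "beta", "s_ero_beta",
              if (link == "logit") "logit_omega" else "omega", "s_ero_omega")
  use_cols <- if (offset) 1:6 else 1:4
  subj_nm <- as.vector(outer(seq_len(S), par_nm[use_cols],
                             function(i, p) sprintf("%s[%d]", p, i)))
  cn <- c(nm_mu[use_cols], nm_sd[use_cols],
          if (offset && link == "logit") "mu_omega", subj_nm)
  keep <- matrix(NA_real_, kept, length(cn), dimnames = list(NULL, cn))

  total <- warmup + kept
  for (it in seq_len(total)) {
    ad <- if (it <= warmup) 1 / sqrt(it) else 0
    for (cyc in seq_len(cycles)) {

    ## 1. subject-level componentwise MH
    for (j in acols) {
      prop <- th
      prop[, j] <- th[, j] + stats::rnorm(S) * exp(lsc[, j])
      pll <- .cohort_loglik(prop, dat, offset, link)
      lr <- pll - cll +
        stats::dnorm(prop[, j], mu[j], sigma[j], log = TRUE) -
        stats::dnorm(th[, j], mu[j], sigma[j], log = TRUE)
      u <- stats::runif(S) < exp(lr)
      th[u, j] <- prop[u, j]
      cll[u] <- pll[u]
      if (ad > 0) lsc[, j] <- lsc[, j] + (as.numeric(u) - 0.44) * ad
    }

    ## 1b. joint full-covariance subject moves (two per sweep once the
    ##     proposal covariances have accumulated)
    if (it <= warmup && it > 50L) {
      M1 <- M1 + th
      for (a in acols) for (b in acols)
        M2[, a, b] <- M2[, a, b] + th[, a] * th[, b]
      ncov <- ncov + 1L
      if (ncov >= 50L && it %% 25L == 0L) {
        sc <- 2.38^2 / nact
        for (s in seq_len(S)) {
          mns <- M1[s, acols] / ncov
          C <- M2[s, acols, acols] / ncov - tcrossprod(mns)
          R <- tryCatch(chol(sc * C + diag(1e-8, nact)),
                        error = function(e) NULL)
          if (!is.null(R)) Lchol[[s]] <- R
        }
      }
    }
    if (ncov >= 50L) {
      for (rep_ in 1:2) {
        prop <- th
        z <- matrix(stats::rnorm(S * nact), S, nact)
        for (s in seq_len(S))
          prop[s, acols] <- th[s, acols] +
            exp(lam[s]) * drop(crossprod(Lchol[[s]], z[s, ]))
        pll <- .cohort_loglik(prop, dat, offset, link)
        lr <- pll - cll
        for (j in acols)
          lr <- lr + stats::dnorm(prop[, j], mu[j], sigma[j], log = TRUE) -
            stats::dnorm(th[, j], mu[j], sigma[j], log = TRUE)
        u <- stats::runif(S) < exp(lr)
        th[u, ] <- prop[u, , drop = FALSE]
        cll[u] <- pll[u]
        if (ad > 0) lam <- lam + (as.numeric(u) - 0.28) * ad
      }
    }

    ## 2. pair trade-off moves
    for (pi in which(pairs_on)) {
      j1 <- pair_cols[[pi]][1]; j2 <- pair_cols[[pi]][2]
      e <- stats::rnorm(S) * exp(lsp[, pi])
      prop <- th
      prop[, j1] <- th[, j1] + e
      prop[, j2] <- th[, j2] - e
      pll <- .cohort_loglik(prop, dat, offset, link)
      lr <- pll - cll +
        stats::dnorm(prop[, j1], mu[j1], sigma[j1], log = TRUE) +
        stats::dnorm(prop[, j2], mu[j2], sigma[j2], log = TRUE) -
        stats::dnorm(th[, j1], mu[j1], sigma[j1], log = TRUE) -
        stats::dnorm(th[, j2], mu[j2], sigma[j2], log = TRUE)
      u <- stats::runif(S) < exp(lr)
      th[u, j1] <- prop[u, j1]
      th[u, j2] <- prop[u, j2]
      cll[u] <- pll[u]
      if (ad > 0) lsp[, pi] <- lsp[, pi] + (as.numeric(u) - 0.44) * ad
    }

    ## 3. group means
    for (j in acols) {
      if (j == 5L) next
      v <- 1 / (S / sigma[j]^2 + 1 / ps[j]^2)
      mu[j] <- stats::rnorm(1, v * (sum(th[, j]) / sigma[j]^2 +
                                      pm[j] / ps[j]^2), sqrt(v))
    }
    if (5L %in% acols) {
      if (link == "logit") {
        # Uniform prior on the natural-scale group offset = logistic on logit
        mu[5] <- .slice1(mu[5], function(m)
          sum(stats::dnorm(th[, 5L], m, sigma[5], log = TRUE)) +
            stats::dlogis(m, log = TRUE),
          w = 1, lower = lob[1], upper = lob[2])
      } else {
        v <- sigma[5]^2 / S
        mu[5] <- .rtruncnorm1(mean(th[, 5L]), sqrt(v), ob[1], ob[2])
      }
    }

    ## 4. group SDs (half-Normal prior, slice)
    for (j in acols) {
      res2 <- sum((th[, j] - mu[j])^2)
      hs2 <- 2 * prior$group_sd_scale^2
      sigma[j] <- .slice1(sigma[j], function(sg) {
        if (sg <= 0) return(-Inf)
        -S * log(sg) - res2 / (2 * sg^2) - sg^2 / hs2
      }, w = 0.5, lower = 1e-6, upper = Inf)
    }

    ## 5. ASIS non-centred scale moves
    for (rep_ in 1:2) {
      for (j in acols) {
        sg2 <- sigma[j] * exp(stats::rnorm(1) * exp(lss[j]))
        prop <- th
        prop[, j] <- mu[j] + (sg2 / sigma[j]) * (th[, j] - mu[j])
        pll <- .cohort_loglik(prop, dat, offset, link)
        lr <- sum(pll - cll) - sg2^2 / (2 * prior$group_sd_scale^2) +
          sigma[j]^2 / (2 * prior$group_sd_scale^2) + log(sg2) - log(sigma[j])
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          th <- prop; cll <- pll; sigma[j] <- sg2; a <- 1
        } else a <- 0
        if (ad > 0) lss[j] <- lss[j] + (a - 0.44) * ad
      }
    }

    }  # end cycles
    if (it > warmup) {
      row <- c(mu[use_cols], sigma[use_cols],
               if (offset && link == "logit") stats::plogis(mu[5]),
               as.vector(th[, use_cols]))
      keep[it - warmup, ] <- row
    }
  }
  keep
}

#' Fit the hierarchical discounting model
#'
#' Estimates the joint posterior of the hierarchical hyperbolic discounting
#' model (base or offset variant) across subjects and conditions by MCMC, with
#' the default group-level priors of [td_priors()]. Defaults follow the full
#' analysis configuration (4 chains, 1500 warmup sweeps, 4000 retained draws
#' in total, no thinning); tests and quick runs use a reduced configuration
#' such as `chains = 2, warmup = 400, retained = 400`.
#'
#' If the data contain a single condition, the condition-shift parameters are
#' structurally absent and their draws are exactly 0. Convergence is assessed
#' by split-chain R-hat ([compute_rhat()]); a failed gate produces a warning
#' but the draws are still returned.
#'
#' The offset and its shift are sampled on the logit scale by default
#' (`omega_link = "logit"`), which keeps every subject's effective offset in
#' (0, 1) in both conditions. `omega_link = "identity"` instead samples the
#' offset and shift on the natural scale, rejecting draws whose effective
#' offset leaves (0, 1].
#'
#' @param data Long-format choice data frame (see [read_choice_table()] for
#'   the schema). INVALID trials are excluded. At least 2 subjects.
#' @param variant `"offset"` (default) or `"base"`.
#' @param priors A [td_priors()] object.
#' @param chains Number of chains (>= 2 for convergence diagnostics).
#' @param warmup Adaptation/burn-in sweeps per chain, discarded.
#' @param retained Total retained draws across chains (split evenly).
#' @param seed Integer seed; chain seeds are derived from it deterministically.
#' @param omega_link `"logit"` or `"identity"` parameterization of the offset.
#' @param rhat_threshold Convergence gate (default 1.05).
#' @param ss_amount Fixed immediate amount (default 20).
#' @param prior_only If TRUE, the likelihood is dropped and the sampler
#'   targets the prior of the hierarchy (the data only define the subjects).
#' @return An object of class `"td_fit"`; see [summary.td_fit()],
#'   [coef.td_fit()], [predict.td_fit()], [simulate.td_fit()], [waic()].
#' @export
td_fit <- function(data, variant = c("offset", "base"), priors = td_priors(),
                   chains = 4, warmup = 1500, retained = 4000, seed = 1,
                   omega_link = c("logit", "identity"),
                   rhat_threshold = 1.05, ss_amount = 20,
                   prior_only = FALSE) {
  variant <- match.arg(variant)
  omega_link <- match.arg(omega_link)
  offset <- variant == "offset"
  stopifnot(chains >= 1, warmup >= 0, retained >= chains)

  d <- data[data$choice != "INVALID", , drop = FALSE]
  if (nrow(d) == 0L) stop("no valid trials", call. = FALSE)
  ids <- unique(d$subject_id)
  if (length(ids) < 2L) stop("need at least 2 subjects", call. = FALSE)
  subj <- match(d$subject_id, ids)
  single_condition <- length(unique(d$i_ero)) == 1L
  iero <- if (single_condition) rep(0L, nrow(d)) else as.integer(d$i_ero)

  active <- c(TRUE, !single_condition, TRUE, !single_condition,
              offset, offset && !single_condition)
  dat <- list(subj = subj, iero = iero, ll = d$ll_amount, d = d$delay_days,
              y = as.integer(d$choice == "LL"), S = length(ids),
              ss = ss_amount, prior_only = prior_only)

  kept <- ceiling(retained / chains)
  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)
  runs <- lapply(seq_len(chains), function(ch)
    .td_chain(dat, priors, active, offset, omega_link, warmup, kept,
              chain_seeds[ch]))
  draws <- do.call(rbind, runs)
  chain <- rep(seq_len(chains), each = kept)

  fit <- structure(list(
    draws = draws, chain = chain, variant = variant,
    omega_link = omega_link, chains = chains, warmup = warmup,
    retained = nrow(draws), seed = seed, priors = priors,
    ss_amount = ss_amount, data = d, subjects = ids,
    single_condition = single_condition, prior_only = prior_only,
    rhat_threshold = rhat_threshold, convergence = NULL
  ), class = "td_fit")
  if (chains >= 2L) {
    fit$convergence <- compute_rhat(fit, threshold = rhat_threshold)
    if (!attr(fit$convergence, "pass"))
      warning("convergence gate failed: max split R-hat = ",
              signif(max(fit$convergence$rhat, na.rm = TRUE), 4),
              call. = FALSE)
  }
  fit
}

# posterior draws of one subject's parameters on the natural td_params scale,
# as a data.frame with one row per retained draw
.subject_param_draws <- function(fit, s) {
  dr <- fit$draws
  g <- function(p) {
    cn <- sprintf("%s[%d]", p, s)
    if (cn %in% colnames(dr)) dr[, cn] else rep(0, nrow(dr))
  }
  out <- data.frame(log_k_neut = g("log_k"), s_ero_k = g("s_ero_k"),
                    beta_neut = g("beta"), s_ero_beta = g("s_ero_beta"))
  if (fit$variant == "offset") {
    if (fit$omega_link == "logit") {
      lo <- g("logit_omega"); so <- g("s_ero_omega")
      out$omega_neut <- stats::plogis(lo)
      out$s_ero_omega <- stats::plogis(lo + so) - out$omega_neut
    } else {
      out$omega_neut <- g("omega")
      out$s_ero_omega <- g("s_ero_omega")
    }
  } else {
    out$omega_neut <- 1
    out$s_ero_omega <- 0
  }
  out
}

# draws x trials matrix of pointwise log-likelihoods (the WAIC input)
.fit_pointwise_loglik <- function(fit) {
  d <- fit$data
  iero <- if (fit$single_condition) rep(0L, nrow(d)) else as.integer(d$i_ero)
  subj <- match(d$subject_id, fit$subjects)
  ndr <- nrow(fit$draws)
  out <- matrix(NA_real_, ndr, nrow(d))
  pars <- lapply(seq_along(fit$subjects),
                 function(s) as.matrix(.subject_param_draws(fit, s)))
  y <- as.integer(d$choice == "LL")
  for (i in seq_len(ndr)) {
    th <- t(vapply(pars, function(m) m[i, ], numeric(6L)))
    out[i, ] <- .ll_core(d$ll_amount, d$delay_days, iero, y,
                         th[subj, 1L], th[subj, 2L], th[subj, 3L],
                         th[subj, 4L], th[subj, 5L], th[subj, 6L],
                         fit$ss_amount, offset = fit$variant == "offset")
  }
  out
}
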