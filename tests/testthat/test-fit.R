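test_that("fitting is deterministic given data, config and seed", {
  sc <- make_small_cohort(n_subjects = 4, every = 4, seed = 21)
  f1 <- suppressWarnings(td_fit(sc$data, "offset", chains = 2, warmup = 60,
                                retained = 80, seed = 99))
  f2 <- suppressWarnings(td_fit(sc$data, "offset", chains = 2, warmup = 60,
                                retained = 80, seed = 99))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(td_fit(sc$data, "offset", chains = 2, warmup = 60,
                                retained = 80, seed = 100))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("single-condition fits have structurally zero shift draws", {
  sc <- make_small_cohort(n_subjects = 4, every = 4, seed = 22)
  neut <- sc$data[sc$data$i_ero == 0, ]
  f <- suppressWarnings(td_fit(neut, "offset", chains = 2, warmup = 80,
                               retained = 100, seed = 3))
  shift_cols <- grep("s_ero", colnames(f$draws), value = TRUE)
  expect_gt(length(shift_cols), 0)
  expect_true(all(f$draws[, shift_cols] == 0))
  expect_true(f$single_condition)
  # flagged as zero-variance, not as failed convergence
  cv <- f$convergence
  expect_true(all(cv$zero_variance[cv$parameter %in% shift_cols]))
})

test_that("fit requires at least two subjects and some valid trials", {
  sc <- make_small_cohort(n_subjects = 4, every = 4, seed = 23)
  one <- sc$data[sc$data$subject_id == sc$data$subject_id[1], ]
  expect_error(td_fit(one, "offset"), "2 subjects")
  inv <- sc$data
  inv$choice <- "INVALID"
  expect_error(td_fit(inv, "offset"), "valid")
})

test_that("prior-only sampling reproduces the group-mean priors", {
  sc <- make_small_cohort(n_subjects = 4, every = 16, seed = 24)
  f <- suppressWarnings(td_fit(sc$data, "offset", chains = 2, warmup = 500,
                               retained = 3000, seed = 12, prior_only = TRUE))
  dr <- f$draws
  # Monte-Carlo tolerances: a few standard errors at the realized ESS
  expect_equal(mean(dr[, "mu_log_k"]), -4.2, tolerance = 0.5)
  expect_equal(sd(dr[, "mu_log_k"]), 2.01, tolerance = 0.4)
  expect_equal(mean(dr[, "mu_beta"]), 0.51, tolerance = 0.1)
  expect_equal(sd(dr[, "mu_beta"]), 0.30, tolerance = 0.08)
  expect_equal(mean(dr[, "mu_s_ero_k"]), 0.15, tolerance = 0.2)
  expect_equal(mean(dr[, "mu_omega"]), 0.5, tolerance = 0.06)
  # Uniform(0,1) prior mass spreads over the unit interval
  expect_gt(sd(dr[, "mu_omega"]), 0.15)
})

test_that("the sampler posterior agrees with an independent JAGS fit", {
  # dual-route check: same model, same priors, centred parameterization in
  # JAGS vs the package's adaptive sampler; posterior means must agree to a
  # fraction of the posterior SD
  sc <- make_small_cohort(n_subjects = 4, every = 2, seed = 11)
  dat <- sc$data
  fit <- suppressWarnings(td_fit(dat, "offset", chains = 2, warmup = 600,
                                 retained = 2000, seed = 7))
  s <- summary(fit)
  model <- "
  model {
    mu1 ~ dnorm(-4.2, 0.24752)
    mu2 ~ dnorm(0.15, 2.44141)
    mu3 ~ dnorm(0.51, 11.11111)
    mu4 ~ dnorm(0.02, 82.64463)
    m_omega ~ dunif(0.000001, 0.999999)
    mu5 <- logit(m_omega)
    mu6 ~ dnorm(0, 6.25)
    for (j in 1:6) { sigma[j] ~ dnorm(0,1) T(0.000001,)
                     tau[j] <- pow(sigma[j], -2) }
    for (s in 1:S) {
      th1[s] ~ dnorm(mu1, tau[1]); th2[s] ~ dnorm(mu2, tau[2])
      th3[s] ~ dnorm(mu3, tau[3]); th4[s] ~ dnorm(mu4, tau[4])
      th5[s] ~ dnorm(mu5, tau[5]); th6[s] ~ dnorm(mu6, tau[6])
    }
    for (i in 1:N) {
      kk[i] <- exp(th1[subj[i]] + iero[i]*th2[subj[i]])
      sv[i] <- ll[i]/(1 + kk[i]*d[i]) *
               ilogit(th5[subj[i]] + iero[i]*th6[subj[i]])
      p[i] <- max(1.0E-9, min(1-1.0E-9,
               ilogit((th3[subj[i]]+iero[i]*th4[subj[i]])*(sv[i]-20))))
      y[i] ~ dbern(p[i])
    }
  }"
  set.seed(1)
  jm <- rjags::jags.model(
    textConnection(model),
    data = list(S = length(unique(dat$subject_id)), N = nrow(dat),
                subj = match(dat$subject_id, unique(dat$subject_id)),
                iero = dat$i_ero, ll = dat$ll_amount, d = dat$delay_days,
                y = as.integer(dat$choice == "LL")),
    n.chains = 2, n.adapt = 500, quiet = TRUE)
  update(jm, 1500, progress.bar = "none")
  sam <- rjags::coda.samples(jm, c("mu1", "mu2", "mu3", "mu4", "m_omega",
                                   "mu6"), n.iter = 3000,
                             progress.bar = "none")
  jmat <- as.matrix(sam)
  pairs <- rbind(
    c("mu_log_k", "mu1"), c("mu_s_ero_k", "mu2"), c("mu_beta", "mu3"),
    c("mu_s_ero_beta", "mu4"), c("mu_omega", "m_omega"),
    c("mu_s_ero_omega", "mu6"))
  for (i in seq_len(nrow(pairs))) {
    mine <- s$mean[s$parameter == pairs[i, 1]]
    ref <- mean(jmat[, pairs[i, 2]])
    tol <- max(0.25 * sd(jmat[, pairs[i, 2]]), 0.02)
    expect_lt(abs(mine - ref), tol, label = paste("posterior mean of",
                                                  pairs[i, 1]))
  }
})

test_that("the identity-link offset parameterization stays in range", {
  sc <- make_small_cohort(n_subjects = 4, every = 4, seed = 25,
                          truth = td_ground_truth(mean_omega = 0.8))
  f <- suppressWarnings(td_fit(sc$data, "offset", chains = 2, warmup = 150,
                               retained = 200, seed = 4,
                               omega_link = "identity"))
  om <- f$draws[, "mu_omega"]
  expect_true(all(om > 0 & om <= 1))
  subj_om <- f$draws[, grep("^omega\\[", colnames(f$draws))]
  expect_true(all(subj_om > 0 & subj_om <= 1))
})

test_that("fit methods expose coherent views of the posterior", {
  sc <- make_small_cohort(n_subjects = 4, every = 4, seed = 26)
  f <- suppressWarnings(td_fit(sc$data, "offset", chains = 2, warmup = 150,
                               retained = 200, seed = 6))
  # print and summary run
  expect_output(print(f), "offset variant")
  s <- summary(f)
  expect_true(all(c("mean", "sd", "rhat") %in% names(s)))
  # coefficients on the natural scale
  cs <- coef(f)$subjects
  expect_equal(nrow(cs), 4L)
  expect_true(all(cs$omega_neut > 0 & cs$omega_neut < 1))
  # predictions are probabilities aligned with the data
  p <- predict(f, type = "prob")
  expect_length(p, nrow(f$data))
  expect_true(all(p > 0 & p < 1))
  expect_setequal(unique(predict(f, type = "choice")), c("SS", "LL"))
  # residuals are bounded response residuals
  r <- residuals(f)
  expect_true(all(abs(r) < 1))
  # accuracy beats chance on its own training data
  expect_gt(choice_accuracy(f), 0.5)
  # the fit's pointwise likelihood agrees with the exported math
  lp <- offsetTD:::.fit_pointwise_loglik(f)
  expect_equal(dim(lp), c(200L, nrow(f$data)))
  cs1 <- cs[1, ]
  pars <- td_params(cs1$log_k_neut, cs1$beta_neut, cs1$s_ero_k,
                    cs1$s_ero_beta, cs1$omega_neut, cs1$s_ero_omega)
  idx <- which(f$data$subject_id == cs1$subject_id)
  manual <- pointwise_loglik(f$data[idx, ], pars, "offset")
  expect_equal(length(manual), length(idx))
})

test_that("subjects with degenerate choice patterns are excluded", {
  # hand-built cohort: 256 valid trials per subject across both conditions
  mk <- function(id, n_ss) {
    ch <- rep("LL", 256)
    if (n_ss > 0) ch[seq_len(n_ss)] <- "SS"
    data.frame(subject_id = id,
               condition = rep(c("neutral", "erotic"), each = 128),
               i_ero = rep(0:1, each = 128), trial_index = rep(1:128, 2),
               ll_amount = 30, delay_days = 5L, choice = ch)
  }
  d <- rbind(mk("deg", 1), mk("edge", 2), mk("ok", 100))
  res <- suppressMessages(exclude_degenerate_subjects(d, 2))
  expect_equal(res$excluded, "deg")  # 1 SS / 255 LL is out, 2 SS is kept
  expect_false("deg" %in% res$kept$subject_id)
  expect_true(all(c("edge", "ok") %in% res$kept$subject_id))
  # threshold 0 excludes nobody even for an all-LL subject
  d0 <- rbind(mk("allLL", 0), mk("ok", 100))
  expect_length(exclude_degenerate_subjects(d0, 0)$excluded, 0)
  # excluding everyone is an error
  expect_error(
    suppressMessages(exclude_degenerate_subjects(rbind(mk("a", 0),
                                                       mk("b", 1)), 2)),
    "all subjects")
})

test_that("the compiled likelihood agrees with the composed model math", {
  sc <- make_small_cohort(n_subjects = 4, every = 4, seed = 33)
  d <- sc$data
  dat <- list(subj = match(d$subject_id, unique(d$subject_id)),
              iero = as.integer(d$i_ero), ll = d$ll_amount,
              d = d$delay_days, y = as.integer(d$choice == "LL"),
              S = 4L, ss = 20, prior_only = FALSE)
  set.seed(1)
  for (rep in 1:5) {
    th <- cbind(rnorm(4, -4, 1), rnorm(4, 0.2, 0.3), runif(4, 0.1, 1),
                rnorm(4, 0, 0.1), rnorm(4, 0, 1), rnorm(4, 0, 0.3))
    fast <- offsetTD:::.cohort_loglik(th, dat, offset = TRUE,
                                      link = "logit")
    slow <- vapply(1:4, function(s) {
      i <- dat$subj == s
      om <- plogis(th[s, 5] + dat$iero[i] * th[s, 6])
      sum(offsetTD:::.ll_core(dat$ll[i], dat$d[i], dat$iero[i], dat$y[i],
                              th[s, 1], th[s, 2], th[s, 3], th[s, 4],
                              om, 0, 20, TRUE))
    }, numeric(1))
    expect_equal(fast, slow, tolerance = 1e-12)
    # base variant
    fast_b <- offsetTD:::.cohort_loglik(th, dat, offset = FALSE,
                                        link = "logit")
    slow_b <- vapply(1:4, function(s) {
      i <- dat$subj == s
      sum(offsetTD:::.ll_core(dat$ll[i], dat$d[i], dat$iero[i], dat$y[i],
                              th[s, 1], th[s, 2], th[s, 3], th[s, 4],
                              1, 0, 20, FALSE))
    }, numeric(1))
    expect_equal(fast_b, slow_b, tolerance = 1e-12)
  }
  # identity link rejects out-of-range effective offsets with -Inf
  th_bad <- cbind(rnorm(4, -4, 1), 0, 0.5, 0, c(0.5, 0.9, 0.5, 0.5),
                  c(0, 0.3, 0, 0))
  bad <- offsetTD:::.cohort_loglik(th_bad, dat, offset = TRUE,
                                   link = "identity")
  expect_true(is.infinite(bad[2]) && bad[2] < 0)
  expect_true(all(is.finite(bad[-2])))
})
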