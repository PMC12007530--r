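# Scalar oracles are direct arithmetic on the model equations, independent of
# the package's composed implementation.

test_that("condition-modulated parameters match scalar evaluation", {
  expect_equal(modulated_k(-4.2, 0.15, 0), exp(-4.2), tolerance = 1e-12)
  expect_equal(modulated_k(-4.2, 0.15, 1), exp(-4.05), tolerance = 1e-12)
  expect_equal(modulated_k(-4.2, 0.15, 0), 0.014996, tolerance = 1e-4)
  expect_equal(modulated_k(-4.2, 0.15, 1), 0.017422, tolerance = 1e-4)
  # indicator off leaves the baseline untouched, whatever the shift
  for (s in c(-2, 0, 3)) expect_equal(modulated_k(-1, s, 0), exp(-1))
  expect_equal(modulated_beta(0.51, 0.02, 1), 0.53)
  expect_equal(modulated_beta(0.51, 0.02, 0), 0.51)
  expect_warning(b <- modulated_beta(0.1, -0.3, 1), "negative")
  expect_equal(b, -0.2)
  expect_error(modulated_k(Inf, 0, 0), "finite")
})

test_that("hyperbolic subjective value matches the closed form", {
  expect_equal(sv_hyperbolic(38, 14, 0.0149956), 38 / (1 + 0.0149956 * 14),
               tolerance = 1e-12)
  expect_equal(sv_hyperbolic(38, 14, 0.0149956), 31.41, tolerance = 1e-3)
  expect_equal(sv_hyperbolic(38, 0, 0.5), 38)   # zero delay
  expect_equal(sv_hyperbolic(38, 100, 0), 38)   # zero discount rate
  # monotone decreasing in delay and in k
  dl <- sv_hyperbolic(38, c(1, 5, 30, 122), 0.02)
  expect_true(all(diff(dl) < 0))
  kk <- sv_hyperbolic(38, 14, c(0.001, 0.01, 0.1, 1))
  expect_true(all(diff(kk) < 0))
  expect_error(sv_hyperbolic(38, 14, -0.1), "non-negative")
})

test_that("the multiplicative offset scales the LL value within (0, 1]", {
  expect_equal(apply_offset(31.41, 0.8, 0, 0), 25.128)
  expect_equal(apply_offset(31.41, 0.8, -0.1, 1), 31.41 * 0.7)
  expect_equal(apply_offset(17.3, 1, 0, 1), 17.3)  # unit offset is identity
  expect_error(apply_offset(31.41, 0.8, 0.3, 1), "0, 1")
  expect_error(apply_offset(31.41, 0.8, -0.8, 1), "0, 1")
})

test_that("softmax probabilities are proper and overflow-safe", {
  expect_equal(choice_prob(31.41, 20, 0.51),
               1 / (1 + exp(-0.51 * (31.41 - 20))), tolerance = 1e-12)
  expect_equal(choice_prob(31.41, 20, 0.51), 0.99703, tolerance = 1e-4)
  expect_equal(choice_prob(7, 7, 2.3), 0.5)
  expect_equal(choice_prob(100, -50, 0), 0.5)
  # complement property over a random grid
  set.seed(1)
  for (i in 1:50) {
    a <- runif(1, -50, 80); b <- runif(1, -50, 80); be <- runif(1, -2, 5)
    expect_equal(choice_prob(a, b, be) + choice_prob(b, a, be), 1,
                 tolerance = 1e-12)
  }
  # extreme value differences stay strictly inside (0, 1)
  p <- choice_prob(1e6, 0, 50)
  expect_true(p < 1 && p > 0)
})

test_that("trial log-likelihood composes the equations and stays finite", {
  p0 <- td_params(log_k_neut = -4.2, beta_neut = 0.51)
  ll <- trial_loglik(38, 14, 0, "LL", p0, "offset")
  sv <- 38 / (1 + exp(-4.2) * 14)
  expect_equal(ll, log(1 / (1 + exp(-0.51 * (sv - 20)))), tolerance = 1e-10)
  expect_equal(ll, -0.002975, tolerance = 2e-3)
  expect_equal(trial_loglik(38, 14, 0, "SS", p0, "offset"), -5.8206,
               tolerance = 1e-3)
  # beta = 0 is random choice on any trial
  pz <- td_params(log_k_neut = -1, beta_neut = 0)
  expect_equal(trial_loglik(55, 60, 0, "SS", pz), log(0.5))
  expect_equal(trial_loglik(55, 60, 1, "LL", pz), log(0.5))
  # never positive, never -Inf even when the model is confidently wrong
  pw <- td_params(log_k_neut = -20, beta_neut = 100)
  bad <- trial_loglik(77, 1, 0, "SS", pw)
  expect_true(bad <= 0 && is.finite(bad))
  expect_error(trial_loglik(38, 14, 0, "INVALID", p0), "SS")
})

test_that("offset variant with unit offset reproduces the base variant bitwise", {
  p <- td_params(log_k_neut = -3, beta_neut = 0.4, s_ero_k = 0.2,
                 s_ero_beta = -0.05, omega_neut = 1, s_ero_omega = 0)
  d <- td_design(1)
  ie <- rep(c(0L, 1L), length.out = 128)
  ch <- rep(c("SS", "LL"), length.out = 128)
  expect_identical(
    trial_loglik(d$ll_amount, d$delay_days, ie, ch, p, "offset"),
    trial_loglik(d$ll_amount, d$delay_days, ie, ch, p, "base"))
})

test_that("pointwise log-likelihood excludes INVALID trials and is additive", {
  d <- make_manual_table()
  sub <- d[d$subject_id == "b", ]
  p <- td_params(log_k_neut = -3, beta_neut = 0.5)
  lp <- pointwise_loglik(sub, p)
  expect_length(lp, 3L)  # one of b's four trials is INVALID
  one_by_one <- vapply(which(sub$choice != "INVALID"), function(i)
    trial_loglik(sub$ll_amount[i], sub$delay_days[i], sub$i_ero[i],
                 sub$choice[i], p), numeric(1))
  expect_equal(sum(lp), sum(one_by_one))
  all_inv <- sub
  all_inv$choice <- "INVALID"
  expect_error(pointwise_loglik(all_inv, p), "valid")
})

test_that("near-deterministic correct predictions give near-zero loglik", {
  d <- td_design(1)
  p <- td_params(log_k_neut = -30, beta_neut = 50)
  dat <- data.frame(subject_id = "x", condition = "neutral", i_ero = 0L,
                    trial_index = d$trial_index, ll_amount = d$ll_amount,
                    delay_days = d$delay_days, choice = "LL")
  lp <- pointwise_loglik(dat, p)
  expect_length(lp, 128L)
  expect_true(all(lp > -1e-3))
})

test_that("model-agnostic TD is the SS proportion over valid trials", {
  d <- make_manual_table()
  td <- td_model_agnostic(d)
  a_n <- td[td$subject_id == "a" & td$condition == "neutral", ]
  expect_equal(a_n$td_model_agnostic, 0.5)
  b_e <- td[td$subject_id == "b" & td$condition == "erotic", ]
  expect_equal(b_e$ss_count + b_e$ll_count, 1L)  # INVALID excluded
  # boundary cases
  all_ss <- d; all_ss$choice <- "SS"
  expect_true(all(td_model_agnostic(all_ss)$td_model_agnostic == 1))
  all_ll <- d; all_ll$choice <- "LL"
  expect_true(all(td_model_agnostic(all_ll)$td_model_agnostic == 0))
  mixed <- data.frame(subject_id = "z", condition = "neutral", i_ero = 0L,
                      trial_index = 1:40, ll_amount = 30, delay_days = 5L,
                      choice = rep(c("SS", "LL"), c(10, 30)))
  expect_equal(td_model_agnostic(mixed)$td_model_agnostic, 0.25)
})

test_that("model-agnostic TD tracks the true discount rate across a cohort", {
  co <- simulate_cohort(td_ground_truth(), n_subjects = 24, seed = 5)
  td <- td_model_agnostic(co$data)
  per_subj <- aggregate(td_model_agnostic ~ subject_id, td, mean)
  r <- cor(per_subj$td_model_agnostic,
           co$truth$subjects$log_k[match(per_subj$subject_id,
                                         co$truth$subjects$subject_id)])
  expect_gt(r, 0.5)
})
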