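# Shared fixtures: all data are generated in code, no files.

# small cohort with shortened trial sets, for fast fitting tests
make_small_cohort <- function(n_subjects = 4, every = 2, seed = 11,
                              truth = td_ground_truth()) {
  co <- simulate_cohort(truth, n_subjects = n_subjects, seed = seed)
  tr <- co$truth$subjects
  des1 <- td_design(1)[seq(1, 128, by = every), ]
  des2 <- td_design(2)[seq(1, 128, by = every), ]
  rows <- vector("list", 2L * n_subjects)
  for (i in seq_len(n_subjects)) {
    p <- td_params(tr$log_k[i], tr$beta[i], tr$s_ero_k[i], tr$s_ero_beta[i],
                   tr$omega_neut[i], tr$omega_ero[i] - tr$omega_neut[i])
    dn <- if (tr$neutral_set[i] == 1) des1 else des2
    de <- if (tr$erotic_set[i] == 1) des1 else des2
    rows[[2L * i - 1L]] <- simulate_subject(p, dn, 0, seed = 1000 + i,
                                            subject_id = tr$subject_id[i])
    rows[[2L * i]] <- simulate_subject(p, de, 1, seed = 2000 + i,
                                       subject_id = tr$subject_id[i])
  }
  list(data = do.call(rbind, rows), truth = co$truth)
}

# a tiny hand-built choice table for I/O and summary tests
make_manual_table <- function() {
  data.frame(
    subject_id = rep(c("a", "b"), each = 4),
    condition = rep(c("neutral", "neutral", "erotic", "erotic"), 2),
    i_ero = rep(c(0L, 0L, 1L, 1L), 2),
    trial_index = rep(1:2, 4),
    ll_amount = rep(c(25, 40), 4),
    delay_days = rep(c(5L, 30L), 4),
    choice = c("SS", "LL", "LL", "LL", "SS", "SS", "LL", "INVALID")
  )
}
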