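test_that("datasets are reproducible and have the configured size", {
  cfg <- synth_config(n_subjects = 3, n_trials_per_subject = 4, seed = 7)
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds1, ds2)
  expect_equal(nrow(dplyr::distinct(ds1$trials, subject_id, trial_id)), 12)
  expect_equal(sort(unique(ds1$trials$subject_id)), 1:3)

  cfg2 <- synth_config(n_subjects = 2, n_trials_per_subject = 1, seed = 1)
  ds <- generate_dataset(cfg2)
  expect_equal(nrow(dplyr::distinct(ds$trials, subject_id, trial_id)), 2)
  expect_setequal(unique(ds$trials$subject_id), 1:2)
})

test_that("zero between-subject spread yields identical templates", {
  cfg <- synth_config(n_subjects = 4, n_trials_per_subject = 2,
                      inter_subject_sd = 0, seed = 3)
  t1 <- generate_subject_template(cfg, 1)
  t3 <- generate_subject_template(cfg, 3)
  u <- seq(0, 1, by = 0.01)
  for (ch in cfg$channels$channel) {
    expect_equal(template_eval(t1, ch, u), template_eval(t3, ch, u))
  }
  expect_equal(t1$body_weight, t3$body_weight)
  # determinism of the template draw
  expect_equal(generate_subject_template(cfg, 2),
               generate_subject_template(cfg, 2))
})

test_that("vertical GRF templates vanish outside the stance window", {
  cfg <- synth_config(n_subjects = 2, n_trials_per_subject = 1, seed = 5)
  tpl <- generate_subject_template(cfg, 1)
  st <- tpl$stance$right
  u_out <- c(seq(st[2] + 1e-6, 1.3, length.out = 50), seq(-0.3, -1e-6,
                                                          length.out = 20))
  expect_true(all(template_eval(tpl, "grf_r_vert", u_out) == 0))
  u_in <- seq(st[1] + 0.2, st[2] - 0.2, length.out = 20)
  expect_true(all(template_eval(tpl, "grf_r_vert", u_in) > 0))
})

test_that("noise-free trials reproduce the template on the time grid", {
  cfg <- synth_config(n_subjects = 2, n_trials_per_subject = 2,
                      intra_subject_sd = 0, stride_duration_sd = 0, seed = 9)
  tpl <- generate_subject_template(cfg, 1)
  tr <- generate_trial(tpl, cfg, 1)
  ch <- "grf_r_vert"
  rate <- cfg$channels$sampling_rate[cfg$channels$channel == ch]
  t <- seq(-0.15 * tr$stride_duration, 1.15 * tr$stride_duration,
           by = 1 / rate)
  expect_equal(tr$series[[ch]],
               template_eval(tpl, ch, t / tr$stride_duration))
  # and with noise on, two trials of one subject differ
  cfg2 <- synth_config(n_subjects = 2, n_trials_per_subject = 2, seed = 9)
  tpl2 <- generate_subject_template(cfg2, 1)
  a <- generate_trial(tpl2, cfg2, 1)
  b <- generate_trial(tpl2, cfg2, 2)
  expect_false(identical(a$series, b$series))
  # same trial id twice is identical (stream keyed by ids, not call order)
  expect_identical(generate_trial(tpl2, cfg2, 2), b)
})

test_that("rendered vertical GRF stays below threshold outside the stride", {
  cfg <- synth_config(n_subjects = 5, n_trials_per_subject = 6,
                      channels = grf_channels(), seed = 13)
  for (s in 1:5) {
    tpl <- generate_subject_template(cfg, s)
    for (k in 1:6) {
      tr <- generate_trial(tpl, cfg, k)
      v <- tr$series[["grf_r_vert"]]
      contact <- detect_contact(v, 10)
      inside <- seq(contact[1], contact[2] - 1L)
      expect_true(all(v[-inside] < 10))
      # detected stance spans roughly the configured stance fraction
      rate <- 1000
      dur_frac <- (contact[2] - contact[1]) / rate / tr$stride_duration
      expect_gt(dur_frac, 0.5)
      expect_lt(dur_frac, 0.8)
    }
  }
})

test_that("a planted signature separates the designated subject inside its window", {
  cfg <- synth_config(n_subjects = 2, n_trials_per_subject = 3,
                      channels = grf_channels(), inter_subject_sd = 0,
                      intra_subject_sd = 0, stride_duration_sd = 0,
                      planted_signature = list(channel = "grf_r_vert",
                                               window = c(60, 70),
                                               amplitude = 0.4),
                      seed = 21)
  t1 <- generate_subject_template(cfg, 1)
  t2 <- generate_subject_template(cfg, 2)
  u <- seq(0, 1, by = 0.001)
  d_vert <- abs(template_eval(t1, "grf_r_vert", u) -
                  template_eval(t2, "grf_r_vert", u))
  in_window <- u >= 0.60 & u <= 0.70
  # the mean curves differ maximally inside the window, and the signature
  # support (sub-bump tails included) stays in its immediate vicinity
  expect_gt(max(d_vert[in_window]), 0)
  expect_gt(max(d_vert[in_window]), max(d_vert[!in_window]))
  expect_equal(max(d_vert[u < 0.55 | u > 0.75]), 0)
  # other channels are identical
  d_other <- abs(template_eval(t1, "grf_l_vert", u) -
                   template_eval(t2, "grf_l_vert", u))
  expect_equal(max(d_other), 0)
})

test_that("classification difficulty rises as within-subject noise swamps the spread", {
  accs <- sapply(1:5, function(seed) {
    sapply(c(0.25, 1, 4), function(ratio) {
      cfg <- synth_config(n_subjects = 5, n_trials_per_subject = 8,
                          channels = grf_channels(),
                          inter_subject_sd = ratio, intra_subject_sd = 1,
                          seed = seed)
      ds <- generate_dataset(cfg)
      plan <- make_folds(ds, k = 4, seed = seed)
      fit_pairs <- plan[plan$fold <= 3, c("subject_id", "trial_id")]
      smp <- build_samples(ds, "grf", fitting = fit_pairs)
      fold_of <- gaitlrp:::match_plan(smp, plan)
      tr <- gaitlrp:::samples_subset(smp, which(fold_of <= 3))
      te <- gaitlrp:::samples_subset(smp, which(fold_of == 4))
      m <- train_linear_svm(tr)
      accuracy(predict(m, te), te$subject_id)
    })
  })
  # test accuracy non-decreasing in the inter/intra ratio, per seed
  expect_true(all(diff(rowMeans(accs)) >= 0))
  for (s in 1:5) expect_true(all(diff(accs[, s]) >= -1e-9))
})

test_that("configuration errors are caught", {
  expect_error(synth_config(n_subjects = 1), "n_subjects")
  expect_error(synth_config(n_trials_per_subject = 0), "n_trials")
  expect_error(synth_config(intra_subject_sd = -1), "multipliers")
  bad <- synth_channels()
  bad$kind[1] <- "unknown"
  expect_error(synth_config(channels = bad), "kind")
  expect_error(synth_config(planted_signature = list(channel = "nope",
                                                     window = c(1, 2),
                                                     amplitude = 1)),
               "channel list")
  cfg <- synth_config(n_subjects = 2, n_trials_per_subject = 1)
  expect_error(generate_subject_template(cfg, 5), "range")
})
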