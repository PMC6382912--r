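test_that("contact detection thresholds and composes into a stride window", {
  # first/last sample at or above 10 N, half-open (1-based)
  expect_equal(detect_contact(c(0, 4, 11, 500, 480, 11, 4, 0), 10), c(3, 7))
  expect_error(detect_contact(rep(0, 10), 10), class = "gaitlrp_no_contact")
  expect_error(detect_contact(numeric(0)), "empty")
  # stride window: right heel strike to left toe off
  right <- c(0, 0, 20, 30, 40, 0, 0, 0, 0)
  left <- c(0, 0, 0, 0, 15, 25, 30, 12, 0)
  rc <- detect_contact(right)
  lc <- detect_contact(left)
  expect_equal(c(rc[1], lc[2]), c(3, 9))
})

test_that("zero-phase Butterworth filter has unit DC gain and the squared magnitude response", {
  const <- rep(3.7, 400)
  expect_equal(butterworth_lowpass(const, 12, 1000), const, tolerance = 1e-10)

  # tone far above cutoff: attenuation matches |H(f)|^2 of the second-order
  # Butterworth evaluated directly (independent frequency-domain oracle)
  t <- seq(0, 2, by = 1 / 1000)
  tone <- sin(2 * pi * 200 * t)
  out <- butterworth_lowpass(tone, 12, 1000)
  mid <- seq(500, length(out) - 500)
  meas <- max(abs(out[mid]))
  expect_lt(meas, 0.05)
  expect_lt(meas, 5 * butter2_bidir_gain(200, 12))

  # a tone well below cutoff passes nearly unchanged
  slow <- sin(2 * pi * 1 * t)
  out_slow <- butterworth_lowpass(slow, 12, 1000)
  expect_equal(out_slow[mid], slow[mid], tolerance = 0.01)

  # bidirectional symmetry: filtering the reversed series and reversing
  # equals filtering forward
  set.seed(4)
  x <- cumsum(rnorm(600))
  expect_equal(rev(butterworth_lowpass(rev(x), 12, 1000)),
               butterworth_lowpass(x, 12, 1000), tolerance = 1e-8)

  expect_error(butterworth_lowpass(x, 600, 1000), "Nyquist")
})

test_that("body-weight normalization is the definitional division", {
  expect_equal(normalize_bodyweight(667.08, 68), 667.08 / (68 * 9.81))
  expect_equal(normalize_bodyweight(68 * 9.81, 68), 1.0)
  expect_equal(normalize_bodyweight(0, 68), 0)
  x <- c(100, 200, 300)
  expect_equal(normalize_bodyweight(2 * x, 70), 2 * normalize_bodyweight(x, 70))
  expect_error(normalize_bodyweight(x, 0), "body_weight")
})

test_that("time normalization interpolates onto 101 points and is idempotent there", {
  x <- sin(seq(0, 3, length.out = 101))
  expect_equal(time_normalize(x), x)
  expect_equal(time_normalize(rep(2.5, 37)), rep(2.5, 101))
  ramp <- seq(0, 1, length.out = 201)
  expect_equal(time_normalize(ramp), (0:100) / 100)
  expect_error(time_normalize(1), "2 samples")
  expect_length(time_normalize(rnorm(57)), 101)
})

test_that("z-transform uses the population convention and flags degenerate channels", {
  zt <- z_transform(c(1, 2, 3))
  expect_equal(zt$values, c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(zt$scale, sqrt(2 / 3))
  # already standardized input is unchanged
  x <- zt$values
  expect_equal(z_transform(x)$values, x, tolerance = 1e-12)
  # constant channel: centered zeros, degenerate flag
  zc <- z_transform(rep(4, 10))
  expect_true(zc$degenerate)
  expect_equal(zc$values, rep(0, 10))
  # reusing fitted parameters on new data
  z2 <- z_transform(c(10, 20), center = zt$center, scale = zt$scale)
  expect_equal(z2$values, (c(10, 20) - 2) / sqrt(2 / 3))
})

test_that("min-max scaling maps the fitting data into [-1, 1] without clipping held-out values", {
  fit <- matrix(c(-2, 0, 2, 1, 2, 3), ncol = 2)
  sc <- scale_minmax(fit)
  expect_equal(range(sc$values), c(-1, 1))
  expect_equal(sc$values[2, 1], 0)  # value 0 with min -2, max 2 -> 0
  # value 1 against fitted min -2 / max 2 -> 0.5
  held <- scale_minmax(matrix(c(1, 5), ncol = 2), state = sc)
  expect_equal(held$values[1, 1], 0.5)
  expect_gt(held$values[1, 2], 1)  # outside the fitted range, not clipped
  # constant component -> 0 and flagged
  cc <- scale_minmax(matrix(c(1, 2, 5, 5), ncol = 2))
  expect_true(cc$degenerate[2])
  expect_equal(cc$values[, 2], c(0, 0))
})

test_that("the full chain emits channels x 101 samples scaled on the fitting split", {
  smp <- small_samples()
  expect_s3_class(smp, "gait_samples")
  expect_equal(dim(smp$x), c(12, 6 * 101))
  expect_true(all(smp$x >= -1 - 1e-12 & smp$x <= 1 + 1e-12))
  expect_equal(smp$n_points, 101)
  long <- as_tibble(smp)
  expect_equal(nrow(long), 12 * 6 * 101)
  expect_setequal(unique(long$channel), grf_channels()$channel)
})

test_that("normalization is fitted on the training split only (no leakage)", {
  ds <- small_dataset()
  fitting <- dplyr::distinct(ds$trials, subject_id, trial_id)[1:8, ]
  s1 <- build_samples(ds, "grf", fitting = fitting)
  # removing held-out trials entirely must not change the fitted state
  keep <- paste(ds$trials$subject_id, ds$trials$trial_id) %in%
    paste(fitting$subject_id, fitting$trial_id)
  ds_train_only <- gaitlrp:::new_gait_dataset(ds$trials[keep, ], ds$channels,
                                              ds$subjects)
  s2 <- build_samples(ds_train_only, "grf", fitting = fitting)
  expect_equal(s1$norm_state$minmax, s2$norm_state$minmax)
  expect_equal(s1$norm_state$kinetic_center, s2$norm_state$kinetic_center)
  expect_equal(s1$norm_state$kinetic_scale, s2$norm_state$kinetic_scale)
  # fitting-split rows are within [-1, 1]; held-out rows may exceed it
  fit_idx <- gaitlrp:::fitting_indices(
    tibble::tibble(subject_id = s1$subject_id, trial_id = s1$trial_id),
    fitting)
  expect_true(all(abs(s1$x[fit_idx, ]) <= 1 + 1e-12))
})

test_that("zero within-subject noise preprocesses every trial identically", {
  cfg <- synth_config(n_subjects = 2, n_trials_per_subject = 3,
                      channels = grf_channels(), intra_subject_sd = 0,
                      stride_duration_sd = 0, seed = 5)
  smp <- build_samples(generate_dataset(cfg), "grf")
  for (s in 1:2) {
    rows <- smp$x[smp$subject_id == s, ]
    expect_equal(rows[2, ], rows[1, ])
    expect_equal(rows[3, ], rows[1, ])
  }
  # pipeline determinism: identical raw inputs give identical samples
  smp2 <- build_samples(generate_dataset(cfg), "grf")
  expect_identical(smp$x, smp2$x)
})

test_that("variable-set selection and missing channels are validated", {
  ds <- small_dataset()
  lb <- build_samples(ds, "lbjax")
  expect_equal(dim(lb$x), c(12, 6 * 101))
  one <- build_samples(ds, c("grf_r_vert", "ang_l_knee"))
  expect_equal(nrow(one$channels), 2)
  expect_error(build_samples(ds, "no_such_channel"), "unknown channels")
  # a trial missing a needed channel is reported with its ids
  broken <- ds
  drop <- !(broken$trials$subject_id == 1 & broken$trials$trial_id == 2 &
              broken$trials$channel == "grf_l_vert")
  broken$trials <- broken$trials[drop, ]
  expect_error(build_samples(broken, "grf"), "grf_l_vert")
})
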