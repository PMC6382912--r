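# Synthetic multi-subject gait data with the statistical structure the
# downstream analysis assumes: each subject owns a characteristic set of
# continuous waveforms (double-hump vertical GRF, braking/propulsion
# fore-aft GRF, low-amplitude medial-lateral GRF, smooth sagittal joint
# angles) and every trial is a noisy, amplitude-scaled, time-warped
# rendering of those templates.

#' Default synthetic channel set
#'
#' Six ground reaction force channels (fore-aft, medial-lateral and vertical
#' component for each foot, force plates sampling at 1000 Hz) and six
#' lower-body sagittal-plane joint angle channels (hip, knee and ankle
#' flexion-extension for each side, motion capture at 250 Hz).
#'
#' @param grf include the force-plate channels.
#' @param angles include the joint-angle channels.
#' @param kinetic_rate,kinematic_rate sampling rates in Hz.
#' @return A tibble with columns `channel`, `kind` (`"kinetic"` or
#'   `"kinematic"`), `side` (`"right"`/`"left"`), `component` and
#'   `sampling_rate`.
#' @export
synth_channels <- function(grf = TRUE, angles = TRUE,
                           kinetic_rate = 1000, kinematic_rate = 250) {
  rows <- list()
  if (grf) {
    for (side in c("right", "left")) {
      for (comp in c("fore_aft", "med_lat", "vert")) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          channel = sprintf("grf_%s_%s", substr(side, 1, 1), comp),
          kind = "kinetic", side = side, component = comp,
          sampling_rate = kinetic_rate
        )
      }
    }
  }
  if (angles) {
    for (side in c("right", "left")) {
      for (joint in c("hip", "knee", "ankle")) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          channel = sprintf("ang_%s_%s", substr(side, 1, 1), joint),
          kind = "kinematic", side = side,
          component = paste0(joint, "_flex_ext"),
          sampling_rate = kinematic_rate
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (anyDuplicated(out$channel)) abort("channel names must be unique")
  out
}

#' Configuration for the synthetic gait generator
#'
#' The defaults mirror the scale of a typical single-session gait study:
#' 57 subjects performing 20 barefoot walking trials each.  Between- and
#' within-subject variability are dimensionless multipliers where 1 is a
#' realistic, calibrated level: between-subject template differences of
#' 10-15% in amplitude against trial-to-trial fluctuations of a few percent
#' (amplitude, timing and additive noise).  At these defaults a linear
#' classifier identifies subjects from ground reaction forces in the
#' mid-90% range and a linear SVM near 100% - the operating regime
#' instrumented-gait identification studies report.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param n_trials_per_subject trials per subject (>= 1).
#' @param channels channel specification, see [synth_channels()].
#' @param inter_subject_sd multiplier on the spread of subject-specific
#'   template coefficients around the population base waveforms.
#' @param intra_subject_sd multiplier on trial-level amplitude scaling,
#'   smooth time warping and additive band-limited noise.
#' @param stride_duration_mean,stride_duration_sd stride duration draw in
#'   seconds (right heel strike to left toe off).
#' @param planted_signature optional list with elements `channel`,
#'   `window` (two percentages of the stride), `amplitude` and optionally
#'   `subject` (default 1): adds a signature bump pattern to that channel
#'   inside the window for the designated subject only, so that subject's
#'   class identity is localized there (used to test explanation
#'   localization).
#' @param seed root seed; subjects and trials derive independent child
#'   streams from it, so generation is order-independent.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_subjects = 57, n_trials_per_subject = 20,
                         channels = synth_channels(),
                         inter_subject_sd = 1, intra_subject_sd = 1,
                         stride_duration_mean = 1.1,
                         stride_duration_sd = 0.05,
                         planted_signature = NULL, seed = 1) {
  if (n_subjects < 2) abort("`n_subjects` must be >= 2")
  if (n_trials_per_subject < 1) abort("`n_trials_per_subject` must be >= 1")
  if (inter_subject_sd < 0 || intra_subject_sd < 0) {
    abort("variability multipliers must be >= 0")
  }
  assert_scalar_number(stride_duration_mean, "stride_duration_mean", positive = TRUE)
  if (stride_duration_sd < 0) abort("`stride_duration_sd` must be >= 0")
  if (!all(channels$kind %in% c("kinetic", "kinematic"))) {
    abort("channel `kind` must be 'kinetic' or 'kinematic'")
  }
  if (!is.null(planted_signature)) {
    stopifnot(is.list(planted_signature),
              all(c("channel", "window", "amplitude") %in% names(planted_signature)))
    if (!planted_signature$channel %in% channels$channel) {
      abort("planted_signature$channel is not in the channel list")
    }
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_trials_per_subject = as.integer(n_trials_per_subject),
    channels = channels,
    inter_subject_sd = inter_subject_sd,
    intra_subject_sd = intra_subject_sd,
    stride_duration_mean = stride_duration_mean,
    stride_duration_sd = stride_duration_sd,
    planted_signature = planted_signature,
    seed = as.integer(seed)
  ), class = "synth_config")
}

GRAVITY <- 9.81

# Population base coefficients, in body-weight units for forces and degrees
# for angles.  Shapes are qualitative: an M-shaped vertical GRF, a
# braking/propulsion fore-aft force, a small medial-lateral oscillation and
# smooth low-order Fourier joint-angle curves.
base_grf_coefs <- function(component) {
  switch(component,
    vert = list(amp = c(0.85, 0.85, 0.50),
                center = c(0.28, 0.75, 0.50),
                width = c(0.28, 0.28, 0.45)),
    fore_aft = list(amp = c(-0.17, 0.20),
                    center = c(0.22, 0.78),
                    width = c(0.20, 0.20)),
    med_lat = list(amp = c(0.050, -0.035, 0.045),
                   center = c(0.12, 0.45, 0.80),
                   width = c(0.12, 0.25, 0.18)),
    abort(sprintf("unknown GRF component '%s'", component))
  )
}

base_angle_coefs <- function(joint) {
  # a0, cosine and sine coefficients of orders 1..6 (degrees)
  switch(joint,
    hip = list(a0 = 8, ac = c(18, -2.0, 0.8, 0.3, 0.1, 0.05),
               as = c(6, 1.0, -0.5, 0.2, 0.1, 0.05)),
    knee = list(a0 = 25, ac = c(-5, -12, 2.0, 0.8, 0.3, 0.1),
                as = c(-18, 6, 2.0, -0.6, 0.2, 0.1)),
    ankle = list(a0 = 2, ac = c(3, -5, 1.5, 0.5, 0.2, 0.1),
                 as = c(-8, 3, -1.0, 0.4, 0.2, 0.1)),
    abort(sprintf("unknown joint '%s'", joint))
  )
}

angle_joint <- function(component) sub("_flex_ext$", "", component)

signature_eval <- function(sig, u) {
  out <- numeric(length(u))
  for (b in seq_along(sig$centers)) {
    out <- out + sig$coef[b] * cos2_bump(u, sig$centers[b], sig$halfwidth)
  }
  sig$amplitude * out
}

#' Draw a subject's template waveforms
#'
#' Builds the subject's per-channel mean curves from the shared population
#' base waveforms plus subject-specific coefficient offsets whose spread is
#' controlled by `inter_subject_sd`.  Deterministic given `(config,
#' subject_id)`: the subject's random stream is derived from the root seed
#' by stable hashing, independent of generation order.
#'
#' @param config a [synth_config()].
#' @param subject_id integer in `1..n_subjects`.
#' @return A `subject_template` with the realized coefficients, the stance
#'   windows (fractions of the stride) and the subject's body weight in kg.
#' @export
generate_subject_template <- function(config, subject_id) {
  stopifnot(inherits(config, "synth_config"))
  if (subject_id < 1 || subject_id > config$n_subjects) {
    abort("`subject_id` out of range")
  }
  isd <- config$inter_subject_sd
  with_child_seed(config$seed, 101L, subject_id, expr = {
    body_weight <- max(45, rnorm(1, 67.9, isd * 11.3))
    stance <- list(
      right = c(0, min(0.72, 0.68 + isd * 0.015 * rnorm(1))),
      left = c(max(0.28, 0.32 + isd * 0.015 * rnorm(1)), 1)
    )
    coefs <- list()
    for (i in seq_len(nrow(config$channels))) {
      ch <- config$channels[i, ]
      if (ch$kind == "kinetic") {
        base <- base_grf_coefs(ch$component)
        amp_scale <- switch(ch$component,
                            vert = 0.12, fore_aft = 0.05, med_lat = 0.02)
        co <- list(
          amp = base$amp + isd * amp_scale * rnorm(length(base$amp)),
          center = base$center + isd * 0.02 * rnorm(length(base$center)),
          width = pmax(0.06, base$width + isd * 0.02 * rnorm(length(base$width)))
        )
        if (ch$component == "med_lat" && ch$side == "left") {
          co$amp <- -co$amp  # mirror the medial-lateral force for the left foot
        }
        co$kind <- "kinetic"
      } else {
        base <- base_angle_coefs(angle_joint(ch$component))
        k <- seq_along(base$ac)
        co <- list(
          a0 = base$a0 + isd * 2.5 * rnorm(1),
          ac = base$ac + isd * 2.5 / k * rnorm(length(k)),
          as = base$as + isd * 2.5 / k * rnorm(length(k)),
          phase = if (ch$side == "left") 0.5 else 0,
          kind = "kinematic"
        )
      }
      coefs[[ch$channel]] <- co
    }
    signature <- NULL
    if (!is.null(config$planted_signature)) {
      # subject-specific pattern of three narrow bumps spanning the window,
      # so the window carries enough dimensions to separate many subjects
      ps <- config$planted_signature
      w0 <- min(ps$window) / 100
      w1 <- max(ps$window) / 100
      centers <- w0 + (w1 - w0) * c(1, 3, 5) / 6
      # the designated signature subject gets a fixed sign pattern over the
      # sub-bumps (plus a small random jitter); all other subjects carry no
      # signature, so that subject's class identity is localized in the
      # window by construction
      sig_subject <- ps$subject %||% 1L
      base_coef <- if (subject_id == sig_subject) c(1, -1, 1) else c(0, 0, 0)
      signature <- list(
        channel = ps$channel,
        centers = centers,
        halfwidth = (w1 - w0) / 4,
        amplitude = ps$amplitude,
        subject = sig_subject,
        coef = base_coef + 0.15 * rnorm(3) * (subject_id == sig_subject)
      )
    }
    structure(list(
      subject_id = as.integer(subject_id),
      body_weight = body_weight,
      stance = stance,
      coefs = coefs,
      signature = signature,
      channels = config$channels
    ), class = "subject_template")
  })
}

stance_for_channel <- function(template, channel) {
  side <- template$channels$side[match(channel, template$channels$channel)]
  template$stance[[side]]
}

#' Evaluate a subject template on normalized stride time
#'
#' @param template a `subject_template`.
#' @param channel channel name.
#' @param u normalized stride time (0 = right heel strike, 1 = left toe
#'   off); values outside a foot's stance window evaluate to 0 for force
#'   channels.
#' @return Numeric vector: Newtons for kinetic channels, degrees for
#'   kinematic ones.
#' @export
template_eval <- function(template, channel, u) {
  co <- template$coefs[[channel]]
  if (is.null(co)) abort(sprintf("unknown channel '%s'", channel))
  if (co$kind == "kinetic") {
    st <- stance_for_channel(template, channel)
    s <- (u - st[1]) / (st[2] - st[1])
    val <- numeric(length(u))
    for (b in seq_along(co$amp)) {
      val <- val + co$amp[b] * cos2_bump(s, co$center[b], co$width[b])
    }
    val[s < 0 | s > 1] <- 0
    if (!is.null(template$signature) && template$signature$channel == channel) {
      sig <- template$signature
      bump <- signature_eval(sig, u)
      bump[s < 0 | s > 1] <- 0  # forces remain supported on the stance window
      val <- val + bump
    }
    comp <- template$channels$component[match(channel, template$channels$channel)]
    if (comp == "vert") val <- pmax(0, val)
    val * template$body_weight * GRAVITY
  } else {
    uu <- u + co$phase
    val <- rep(co$a0, length(u))
    for (k in seq_along(co$ac)) {
      val <- val + co$ac[k] * cos(2 * pi * k * uu) + co$as[k] * sin(2 * pi * k * uu)
    }
    if (!is.null(template$signature) && template$signature$channel == channel) {
      sig <- template$signature
      val <- val + signature_eval(sig, u)
    }
    val
  }
}

#' Render one noisy trial from a subject template
#'
#' Samples a stride duration, renders every channel at its sampling rate on
#' a raw window that includes pre- and post-stride baseline, and applies the
#' trial-level variability controlled by `intra_subject_sd`: a per-channel
#' amplitude factor, a smooth time warp and additive band-limited noise.
#' Force channels are exactly zero (and therefore below any contact
#' threshold) outside the foot's stance window.
#'
#' @param template a `subject_template`.
#' @param config the [synth_config()] used to build the template.
#' @param trial_id integer trial index; together with the root seed it
#'   determines the trial's random stream.
#' @return A `gait_trial` list with per-channel numeric series.
#' @export
generate_trial <- function(template, config, trial_id) {
  stopifnot(inherits(template, "subject_template"))
  nsd <- config$intra_subject_sd
  with_child_seed(config$seed, 202L, template$subject_id, trial_id, expr = {
    dur <- NA_real_
    for (try in 1:20) {
      dur <- rnorm(1, config$stride_duration_mean, config$stride_duration_sd)
      if (dur > 0.3) break
      dur <- NA_real_
    }
    if (is.na(dur)) abort("could not draw a positive stride duration")
    series <- list()
    for (i in seq_len(nrow(config$channels))) {
      ch <- config$channels[i, ]
      t <- seq(-0.15 * dur, 1.15 * dur, by = 1 / ch$sampling_rate)
      u <- t / dur
      # smooth trial-level time warp, anchored at the stride boundaries
      w1 <- rnorm(1); w2 <- rnorm(1)
      uw <- u + nsd * 0.032 * (w1 * sin(pi * pmin(pmax(u, 0), 1)) +
                                 0.5 * w2 * sin(2 * pi * pmin(pmax(u, 0), 1)))
      val <- template_eval(template, ch$channel, uw)
      amp <- 1 + nsd * 0.08 * rnorm(1)
      val <- val * amp
      ref <- max(abs(val))
      if (ref > 0 && nsd > 0) {
        noise <- numeric(length(u))
        for (k in 1:8) {
          noise <- noise + (rnorm(1) * cos(2 * pi * k * u) +
                              rnorm(1) * sin(2 * pi * k * u)) / k
        }
        noise <- nsd * 0.04 * ref * noise
        if (ch$kind == "kinetic") {
          st <- stance_for_channel(template, ch$channel)
          s <- (uw - st[1]) / (st[2] - st[1])
          noise[s < 0 | s > 1] <- 0  # keep forces supported on stance
        }
        val <- val + noise
        if (ch$kind == "kinetic" && ch$component == "vert") val <- pmax(0, val)
      } else if (nsd > 0) {
        for (k in 1:8) { rnorm(2) }  # keep the stream aligned across channels
      }
      series[[ch$channel]] <- val
    }
    structure(list(
      subject_id = template$subject_id,
      trial_id = as.integer(trial_id),
      stride_duration = dur,
      body_weight = template$body_weight,
      channels = config$channels,
      series = series
    ), class = "gait_trial")
  })
}

#' Generate a full synthetic gait dataset
#'
#' @param config a [synth_config()].
#' @return A `gait_dataset`: a list with the long `trials` table
#'   (`subject_id`, `trial_id`, `channel`, `sample_index`, `value`), the
#'   `channels` metadata table, the `subjects` table (`body_weight` in kg)
#'   and a format `version`.  Fully reproducible from the config seed.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  trial_tabs <- vector("list", config$n_subjects * config$n_trials_per_subject)
  subjects <- vector("list", config$n_subjects)
  k <- 0L
  for (s in seq_len(config$n_subjects)) {
    template <- generate_subject_template(config, s)
    subjects[[s]] <- tibble::tibble(subject_id = s,
                                    body_weight = template$body_weight)
    for (tr in seq_len(config$n_trials_per_subject)) {
      trial <- generate_trial(template, config, tr)
      k <- k + 1L
      trial_tabs[[k]] <- tibble::tibble(
        subject_id = trial$subject_id,
        trial_id = trial$trial_id,
        channel = rep(names(trial$series), lengths(trial$series)),
        sample_index = unlist(lapply(trial$series, seq_along), use.names = FALSE),
        value = unlist(trial$series, use.names = FALSE)
      )
    }
  }
  new_gait_dataset(
    trials = dplyr::bind_rows(trial_tabs),
    channels = config$channels,
    subjects = dplyr::bind_rows(subjects)
  )
}

new_gait_dataset <- function(trials, channels, subjects, version = "1.0") {
  structure(list(trials = trials, channels = channels,
                 subjects = subjects, version = version),
            class = "gait_dataset")
}

#' @export
print.gait_dataset <- function(x, ...) {
  n_tr <- nrow(dplyr::distinct(x$trials, .data$subject_id, .data$trial_id))
  cat(sprintf(
    "<gait_dataset> %d subjects, %d trials, %d channels (format %s)\n",
    nrow(x$subjects), n_tr, nrow(x$channels), x$version))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.gait_dataset <- function(x, ...) x$trials
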