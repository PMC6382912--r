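# Preprocessing chain from raw gait trials to model-ready samples:
# zero-phase Butterworth filtering, stride segmentation by a vertical
# force threshold, body-weight normalization of forces, 101-point time
# normalization, z-transform and min-max scaling to [-1, 1].

#' Detect foot-ground contact from a vertical force series
#'
#' Contact is the span where the vertical ground reaction force reaches the
#' threshold.  Indices are 1-based and half-open: the returned interval is
#' `[start, end)` with `start` the first sample at or above the threshold
#' and `end` one past the last such sample.
#'
#' @param vertical_grf numeric series in Newtons.
#' @param threshold force threshold in Newtons (default 10).
#' @return Integer vector `c(start, end)`.
#' @export
detect_contact <- function(vertical_grf, threshold = 10) {
  if (length(vertical_grf) == 0) abort("empty series")
  assert_scalar_number(threshold, "threshold", positive = TRUE)
  hit <- which(vertical_grf >= threshold)
  if (length(hit) == 0) {
    abort("no sample reaches the contact threshold",
          class = "gaitlrp_no_contact")
  }
  c(hit[1L], hit[length(hit)] + 1L)
}

butter_coefs <- function(cutoff, sampling_rate, order = 2) {
  if (cutoff >= sampling_rate / 2) {
    abort("`cutoff` must be below the Nyquist frequency")
  }
  bf <- signal::butter(order, cutoff / (sampling_rate / 2), type = "low")
  list(b = bf$b, a = bf$a)
}

# One causal IIR pass with y-history initial conditions chosen so that a
# constant input passes through exactly (unit DC gain, no startup
# transient).  Uses stats::filter for the heavy lifting.
iir_pass <- function(b, a, x) {
  n <- length(x)
  x_ext <- c(rep(x[1L], length(b) - 1L), x)
  v <- stats::filter(x_ext, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[length(b):length(x_ext)]
  y <- stats::filter(v, -a[-1L], method = "recursive",
                     init = rep(x[1L], length(a) - 1L))
  as.numeric(y)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Second-order Butterworth filter applied forward and backward (zero
#' phase, squared magnitude response).  Edges are handled by odd-reflection
#' padding plus steady-state initial conditions, so constant signals are
#' reproduced exactly and startup transients decay inside the padding.
#'
#' @param series numeric series.
#' @param cutoff cut-off frequency in Hz (must be below Nyquist).
#' @param sampling_rate sampling rate in Hz.
#' @param order filter order per pass (default 2).
#' @return Filtered series of the same length.
#' @export
butterworth_lowpass <- function(series, cutoff, sampling_rate, order = 2) {
  co <- butter_coefs(cutoff, sampling_rate, order)
  n <- length(series)
  if (n < 2) abort("series too short to filter")
  # several filter time constants, so startup transients die in the padding
  pad <- min(n - 1L, as.integer(ceiling(6 * sampling_rate / cutoff)))
  pad_front <- 2 * series[1L] - series[(pad + 1L):2L]
  pad_back <- 2 * series[n] - series[(n - 1L):(n - pad)]
  x <- c(pad_front, series, pad_back)
  y <- iir_pass(co$b, co$a, x)
  y <- rev(iir_pass(co$b, co$a, rev(y)))
  y[(pad + 1L):(pad + n)]
}

#' Normalize forces to body-weight units
#'
#' @param grf_series force series in Newtons.
#' @param body_weight body mass in kg.
#' @param g gravitational acceleration in m/s^2.
#' @return Series in units of body weight (BW).
#' @export
normalize_bodyweight <- function(grf_series, body_weight, g = GRAVITY) {
  assert_scalar_number(body_weight, "body_weight", positive = TRUE)
  grf_series / (body_weight * g)
}

#' Resample a series to a fixed number of points
#'
#' Linear interpolation onto an equidistant grid spanning the input,
#' endpoints preserved.  Applied to each variable's stride window this
#' yields the standard 101-point (0-100% stride) representation.
#'
#' @param series numeric series (length >= 2).
#' @param n_points output length (default 101).
#' @return Numeric vector of length `n_points`.
#' @export
time_normalize <- function(series, n_points = 101) {
  n <- length(series)
  if (n < 2) abort("need at least 2 samples to time-normalize")
  approx(x = seq(0, 1, length.out = n), y = series,
         xout = seq(0, 1, length.out = n_points))$y
}

#' z-transform with population standard deviation
#'
#' Standardizes values to mean 0 and standard deviation 1 (divide-by-N
#' convention).  When `center`/`scale` are supplied they are reused, which
#' is how parameters fitted on a training split are applied to held-out
#' data.  A zero standard deviation is flagged degenerate and the values
#' are only centered.
#'
#' @param x numeric vector.
#' @param center,scale optional precomputed mean and standard deviation.
#' @return List with `values`, `center`, `scale`, `degenerate`.
#' @export
z_transform <- function(x, center = NULL, scale = NULL) {
  center <- center %||% mean(x)
  scale <- scale %||% sd_pop(x)
  degenerate <- !is.finite(scale) || scale == 0
  values <- if (degenerate) x - center else (x - center) / scale
  list(values = values, center = center, scale = scale,
       degenerate = degenerate)
}

#' Min-max scaling to [-1, 1], fitted per component
#'
#' `x' = 2 (x - min) / (max - min) - 1` with the minimum and maximum fitted
#' per column (input component) on the provided matrix, or reused from a
#' previous fit.  Held-out values may fall outside [-1, 1] and are not
#' clipped.  Constant components map to 0 and are flagged.
#'
#' @param x numeric matrix (rows = samples, columns = components).
#' @param state optional list with `min` and `max` from a previous fit.
#' @return List with `values` (matrix), `min`, `max`, `degenerate`.
#' @export
scale_minmax <- function(x, state = NULL) {
  x <- as.matrix(x)
  if (is.null(state)) {
    state <- list(min = apply(x, 2, min), max = apply(x, 2, max))
  }
  rng <- state$max - state$min
  degenerate <- rng == 0
  scl <- ifelse(degenerate, 1, rng)
  values <- sweep(x, 2, state$min, "-")
  values <- sweep(values, 2, scl, "/") * 2 - 1
  values[, degenerate] <- 0
  list(values = values, min = state$min, max = state$max,
       degenerate = degenerate)
}

select_variable_channels <- function(channels, variable_set) {
  if (length(variable_set) == 1 && variable_set %in% c("grf", "lbjax", "all")) {
    keep <- switch(variable_set,
                   grf = channels$kind == "kinetic",
                   lbjax = channels$kind == "kinematic",
                   all = rep(TRUE, nrow(channels)))
    channels[keep, ]
  } else {
    missing <- setdiff(variable_set, channels$channel)
    if (length(missing)) {
      abort(sprintf("unknown channels: %s", paste(missing, collapse = ", ")))
    }
    channels[match(variable_set, channels$channel), ]
  }
}

#' Trial-level preprocessing (split-independent stage)
#'
#' Runs the deterministic part of the processing chain - zero-phase
#' Butterworth filtering, stride segmentation, body-weight normalization
#' and 101-point time normalization - for every trial.  The result feeds
#' [build_samples()]/[run_experiment()], which add the split-dependent
#' normalization; computing it once and passing it as the `core` argument
#' avoids re-filtering when several experiments share a dataset.
#'
#' @inheritParams build_samples
#' @param kinematic_cutoff,kinetic_cutoff low-pass cut-offs in Hz.
#' @param g gravitational acceleration for body-weight units.
#' @return A list with the trials-by-channels-by-time array `x`, trial
#'   metadata, and the ordered channel table.
#' @export
preprocess_trials <- function(dataset, variable_set = "grf", n_points = 101,
                              contact_threshold = 10,
                              kinematic_cutoff = 12, kinetic_cutoff = 50,
                              g = GRAVITY) {
  stopifnot(inherits(dataset, "gait_dataset"))
  chans <- select_variable_channels(dataset$channels, variable_set)
  vert <- dataset$channels[dataset$channels$component == "vert", ]
  r_vert <- vert$channel[vert$side == "right"]
  l_vert <- vert$channel[vert$side == "left"]
  if (length(r_vert) != 1 || length(l_vert) != 1) {
    abort("dataset must contain one right and one left vertical GRF channel")
  }
  rate_of <- stats::setNames(dataset$channels$sampling_rate,
                             dataset$channels$channel)
  kind_of <- stats::setNames(dataset$channels$kind, dataset$channels$channel)
  bw_of <- stats::setNames(dataset$subjects$body_weight,
                           dataset$subjects$subject_id)

  tr <- dplyr::arrange(dataset$trials, .data$subject_id, .data$trial_id,
                       .data$channel, .data$sample_index)
  key <- paste(tr$subject_id, tr$trial_id, sep = "\r")
  series_key <- paste(key, tr$channel, sep = "\r")
  series <- split(tr$value, factor(series_key, levels = unique(series_key)))
  series_meta <- do.call(rbind, strsplit(names(series), "\r", fixed = TRUE))
  trial_key <- paste(series_meta[, 1], series_meta[, 2], sep = "\r")
  trials <- unique(trial_key)

  n_ch <- nrow(chans)
  x <- array(NA_real_, dim = c(length(trials), n_ch, n_points))
  meta <- vector("list", length(trials))
  needed <- unique(c(chans$channel, r_vert, l_vert))
  for (i in seq_along(trials)) {
    sel <- which(trial_key == trials[i])
    ch_names <- series_meta[sel, 3]
    sid <- as.integer(series_meta[sel[1], 1])
    tid <- as.integer(series_meta[sel[1], 2])
    miss <- setdiff(needed, ch_names)
    if (length(miss)) {
      abort(sprintf("trial (%d, %d) is missing channel(s): %s",
                    sid, tid, paste(miss, collapse = ", ")))
    }
    raw <- stats::setNames(series[sel], ch_names)
    filt <- lapply(needed, function(ch) {
      cutoff <- if (kind_of[[ch]] == "kinetic") kinetic_cutoff else kinematic_cutoff
      butterworth_lowpass(raw[[ch]], cutoff, rate_of[[ch]])
    })
    names(filt) <- needed
    rc <- detect_contact(filt[[r_vert]], contact_threshold)
    lc <- detect_contact(filt[[l_vert]], contact_threshold)
    # stride window in seconds: right heel strike to left toe off
    w0 <- (rc[1L] - 1L) / rate_of[[r_vert]]
    w1 <- (lc[2L] - 2L) / rate_of[[l_vert]]
    if (w1 <= w0) abort(sprintf("degenerate stride window in trial (%d, %d)",
                                sid, tid))
    grid <- seq(w0, w1, length.out = n_points)
    bw <- bw_of[[as.character(sid)]]
    for (j in seq_len(n_ch)) {
      ch <- chans$channel[j]
      v <- filt[[ch]]
      if (kind_of[[ch]] == "kinetic") {
        if (is.null(bw) || is.na(bw)) {
          abort(sprintf("missing body weight for subject %d", sid))
        }
        v <- normalize_bodyweight(v, bw, g)
      }
      t_ch <- (seq_along(v) - 1L) / rate_of[[ch]]
      x[i, j, ] <- approx(t_ch, v, xout = grid, rule = 2)$y
    }
    meta[[i]] <- tibble::tibble(subject_id = sid, trial_id = tid)
  }
  list(x = x, meta = dplyr::bind_rows(meta), channels = chans,
       n_points = n_points)
}

# Stage 2: split-dependent normalization.  Kinematic channels are
# z-transformed per trial over their own 101 points; kinetic channels use
# mean/sd pooled over the fitting-split trials.  Min-max scaling is fitted
# per input component (channel x time) on the fitting split.
normalize_samples <- function(core, fitting_idx) {
  x <- core$x
  n <- dim(x)[1]; n_ch <- dim(x)[2]; n_t <- dim(x)[3]
  kinetic_center <- kinetic_scale <- stats::setNames(
    rep(NA_real_, n_ch), core$channels$channel)
  degenerate <- character(0)
  for (j in seq_len(n_ch)) {
    if (core$channels$kind[j] == "kinematic") {
      for (i in seq_len(n)) {
        zt <- z_transform(x[i, j, ])
        x[i, j, ] <- zt$values
        if (zt$degenerate) degenerate <- c(degenerate, core$channels$channel[j])
      }
    } else {
      pool <- x[fitting_idx, j, ]
      ctr <- mean(pool)
      scl <- sd_pop(pool)
      if (!is.finite(scl) || scl == 0) {
        degenerate <- c(degenerate, core$channels$channel[j])
        scl <- 1
      }
      kinetic_center[j] <- ctr
      kinetic_scale[j] <- scl
      x[, j, ] <- (x[, j, ] - ctr) / scl
    }
  }
  # Flatten to row-concatenated channel-by-time vectors: component
  # (channel j, time t) lives at column (j - 1) * n_t + t.
  flat <- matrix(NA_real_, nrow = n, ncol = n_ch * n_t)
  for (j in seq_len(n_ch)) {
    flat[, (j - 1L) * n_t + seq_len(n_t)] <- x[, j, ]
  }
  mm <- scale_minmax(flat[fitting_idx, , drop = FALSE])
  scaled <- scale_minmax(flat, state = mm)
  state <- structure(list(
    kinetic_center = kinetic_center[core$channels$kind == "kinetic"],
    kinetic_scale = kinetic_scale[core$channels$kind == "kinetic"],
    minmax = list(min = mm$min, max = mm$max, degenerate = mm$degenerate),
    degenerate_channels = unique(degenerate),
    channels = core$channels,
    n_points = n_t
  ), class = "normalization_state")
  list(x = scaled$values, state = state)
}

#' Build model-ready samples from raw trials
#'
#' Runs the full processing chain: zero-phase Butterworth filtering (12 Hz
#' for kinematic, 50 Hz for kinetic channels), stride segmentation by the
#' 10 N vertical-force threshold (right heel strike to left toe off),
#' body-weight normalization of forces, 101-point time normalization,
#' z-transform (per trial for kinematic channels, pooled over the fitting
#' split for kinetic ones) and per-component min-max scaling to [-1, 1]
#' fitted on the fitting split only.  Held-out samples are transformed with
#' the fitted parameters and may fall outside [-1, 1].
#'
#' @param dataset a `gait_dataset`.
#' @param variable_set `"grf"`, `"lbjax"`, `"all"`, or a character vector
#'   of channel names.
#' @param fitting data frame with `subject_id`, `trial_id` naming the
#'   trials the normalization parameters are fitted on (default: all).
#' @param n_points points per normalized stride (default 101).
#' @param contact_threshold vertical force contact threshold in Newtons.
#' @return A `gait_samples` object: a samples-by-components matrix `x`
#'   (components ordered channel by channel, 101 time points each), trial
#'   metadata, the ordered channel table and the fitted
#'   `normalization_state`.
#' @export
build_samples <- function(dataset, variable_set = "grf", fitting = NULL,
                          n_points = 101, contact_threshold = 10) {
  core <- preprocess_trials(dataset, variable_set, n_points,
                            contact_threshold)
  finalize_samples(core, fitting)
}

finalize_samples <- function(core, fitting = NULL) {
  fitting_idx <- fitting_indices(core$meta, fitting)
  norm <- normalize_samples(core, fitting_idx)
  new_gait_samples(norm$x, core$meta, core$channels, norm$state,
                   core$n_points, fitting_idx)
}

fitting_indices <- function(meta, fitting) {
  if (is.null(fitting)) return(seq_len(nrow(meta)))
  stopifnot(all(c("subject_id", "trial_id") %in% names(fitting)))
  idx <- which(paste(meta$subject_id, meta$trial_id) %in%
                 paste(fitting$subject_id, fitting$trial_id))
  if (length(idx) == 0) abort("fitting split matches no trials")
  idx
}

new_gait_samples <- function(x, meta, channels, state, n_points, fitting_idx) {
  structure(list(
    x = x,
    subject_id = meta$subject_id,
    trial_id = meta$trial_id,
    subject = factor(meta$subject_id),
    channels = channels,
    n_points = n_points,
    norm_state = state,
    fitting_idx = fitting_idx
  ), class = "gait_samples")
}

#' @export
print.gait_samples <- function(x, ...) {
  cat(sprintf("<gait_samples> %d samples x (%d channels x %d points), %d subjects\n",
              nrow(x$x), nrow(x$channels), x$n_points, nlevels(x$subject)))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.gait_samples <- function(x, ...) {
  n_t <- x$n_points
  tibble::tibble(
    subject_id = rep(x$subject_id, each = ncol(x$x)),
    trial_id = rep(x$trial_id, each = ncol(x$x)),
    channel = rep(rep(x$channels$channel, each = n_t), times = nrow(x$x)),
    t = rep(rep(seq_len(n_t) - 1L, times = nrow(x$channels)), times = nrow(x$x)),
    value = as.vector(t(x$x))
  )
}

# Subset samples by row index, keeping metadata aligned.
samples_subset <- function(samples, idx) {
  out <- samples
  out$x <- samples$x[idx, , drop = FALSE]
  out$subject_id <- samples$subject_id[idx]
  out$trial_id <- samples$trial_id[idx]
  out$subject <- factor(samples$subject_id[idx],
                        levels = levels(samples$subject))
  out$fitting_idx <- NULL
  out
}
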