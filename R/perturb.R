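# Random-order input perturbation and the area-over-perturbation-curve
# (AOPC) robustness summary.  For every test sample a random order of its
# input components is drawn; at each step the next component is perturbed
# (perturbations accumulate), the whole test set is re-evaluated, and the
# accuracy drop relative to step 0 is aggregated into the AOPC.

#' Noise specification for perturbation runs
#'
#' Types: `"gaussian"` adds mean-zero noise with standard deviation
#' `sigma`; `"salt_minus"`/`"salt_plus"` replace the component by the
#' global minimum/maximum of the scaled training inputs (-1/+1 by
#' construction of the scaling); `"pepper"` sets it to 0; `"shot"`
#' multiplies it by a Poisson(1) draw.
#'
#' @param type noise type.
#' @param sigma gaussian standard deviation (> 0).
#' @param v_min,v_max replacement values for salt noise.
#' @param shot_rate Poisson rate for shot noise.
#' @return A `noise_spec`.
#' @export
noise_spec <- function(type = c("gaussian", "salt_minus", "pepper",
                                "salt_plus", "shot"),
                       sigma = 1, v_min = -1, v_max = 1, shot_rate = 1) {
  type <- match.arg(type)
  if (type == "gaussian" && sigma <= 0) abort("`sigma` must be > 0")
  structure(list(type = type, sigma = sigma, v_min = v_min, v_max = v_max,
                 shot_rate = shot_rate),
            class = "noise_spec")
}

noise_label <- function(noise) {
  if (noise$type == "gaussian") sprintf("gaussian sigma=%g", noise$sigma)
  else noise$type
}

#' Random perturbation order for one sample
#'
#' @param n_components number of input components.
#' @return Uniformly random permutation of `1:n_components`; the order is
#'   drawn once per sample and repetition and then fixed across steps.
#' @export
perturbation_order <- function(n_components) {
  sample.int(n_components)
}

#' Perturb selected components of a sample matrix
#'
#' @param x samples matrix (modified copy returned).
#' @param components one component index per row of `x`.
#' @param noise a [noise_spec()].
#' @return The matrix with, per row, the selected component perturbed.
#' @export
apply_perturbation <- function(x, components, noise) {
  stopifnot(length(components) == nrow(x))
  ij <- cbind(seq_len(nrow(x)), components)
  x[ij] <- switch(noise$type,
    gaussian = x[ij] + rnorm(nrow(x), 0, noise$sigma),
    salt_minus = noise$v_min,
    pepper = 0,
    salt_plus = noise$v_max,
    shot = x[ij] * stats::rpois(nrow(x), noise$shot_rate),
    abort(sprintf("unknown noise type '%s'", noise$type)))
  x
}

#' Accuracy under stepwise random-order perturbation
#'
#' Runs `repetitions` independent perturbation experiments: in each, every
#' test sample gets a fresh random component order, and over `steps`
#' consecutive steps the next component of each sample is perturbed (all
#' samples simultaneously) and test accuracy is re-evaluated.
#'
#' @param model a `network_model`.
#' @param samples test samples (`gait_samples` or matrix).
#' @param truth labels (taken from `gait_samples` if omitted).
#' @param noise a [noise_spec()].
#' @param steps number of perturbation steps L (default 50).
#' @param repetitions independent repetitions (default 10).
#' @param seed RNG seed.
#' @return A `perturbation_curves` tibble: `repetition`, `step` (0..L) and
#'   `accuracy` in percent; step 0 is the unperturbed accuracy.
#' @export
perturbation_curve <- function(model, samples, truth = NULL,
                               noise = noise_spec("gaussian", 1),
                               steps = 50, repetitions = 10, seed = 1) {
  if (inherits(samples, "gait_samples")) {
    truth <- truth %||% samples$subject_id
    samples <- samples$x
  }
  stopifnot(!is.null(truth), nrow(samples) == length(truth))
  p <- ncol(samples)
  if (steps > p) abort("more steps than input components")
  rows <- vector("list", repetitions)
  withr::with_seed(seed, {
    for (rep_i in seq_len(repetitions)) {
      orders <- t(vapply(seq_len(nrow(samples)), function(i) {
        perturbation_order(p)
      }, integer(p)))
      x <- samples
      acc <- numeric(steps + 1)
      acc[1] <- accuracy(predict(model, x), truth)
      for (s in seq_len(steps)) {
        x <- apply_perturbation(x, orders[, s], noise)
        acc[s + 1] <- accuracy(predict(model, x), truth)
      }
      rows[[rep_i]] <- tibble::tibble(repetition = rep_i, step = 0:steps,
                                      accuracy = acc)
    }
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("perturbation_curves", class(out)),
            noise = noise, model_label = model$spec$label)
}

#' Area over the perturbation curve
#'
#' `AOPC = (1 / (L + 1)) * sum_{k=0}^{L} (a_0 - a_k)` in accuracy
#' percentage points.  Higher values mean higher sensitivity to noise
#' (lower robustness).
#'
#' @param curve numeric accuracy vector `a_0..a_L`, or a
#'   `perturbation_curves` tibble (one AOPC per repetition, averaged).
#' @return A single AOPC value.
#' @export
aopc <- function(curve) {
  if (inherits(curve, "perturbation_curves") || is.data.frame(curve)) {
    per_rep <- curve |>
      dplyr::group_by(.data$repetition) |>
      dplyr::summarise(aopc = aopc(.data$accuracy[order(.data$step)]),
                       .groups = "drop")
    return(mean(per_rep$aopc))
  }
  if (length(curve) == 0) abort("empty perturbation curve")
  mean(curve[1] - curve)
}

#' AOPC of an experiment's models under one noise type
#'
#' Evaluates the perturbation protocol on every cross-validation fold's
#' test set with that fold's trained model, and aggregates the AOPC over
#' all repetition-by-fold runs as mean and (population) standard
#' deviation.
#'
#' @param experiment a `gait_experiment`.
#' @param noise a [noise_spec()].
#' @param steps,repetitions,seed see [perturbation_curve()].
#' @param folds fold indices to evaluate (default: all).
#' @return An `aopc_result` tibble with one row per fold and repetition,
#'   plus `mean_aopc`/`sd_aopc` attributes.
#' @export
experiment_aopc <- function(experiment, noise = noise_spec("gaussian", 1),
                            steps = 50, repetitions = 10, seed = 1,
                            folds = NULL) {
  stopifnot(inherits(experiment, "gait_experiment"))
  folds <- folds %||% seq_along(experiment$models)
  rows <- vector("list", length(folds))
  for (fi in seq_along(folds)) {
    f <- folds[fi]
    curves <- perturbation_curve(experiment$models[[f]],
                                 experiment$tests[[f]],
                                 noise = noise, steps = steps,
                                 repetitions = repetitions,
                                 seed = child_seed(seed, 505L, f))
    per_rep <- curves |>
      dplyr::group_by(.data$repetition) |>
      dplyr::summarise(aopc = aopc(.data$accuracy[order(.data$step)]),
                       .groups = "drop")
    per_rep$fold <- f
    rows[[fi]] <- per_rep
  }
  out <- dplyr::bind_rows(rows)[, c("fold", "repetition", "aopc")]
  structure(out, class = c("aopc_result", class(out)),
            noise = noise, model_label = experiment$spec$label,
            mean_aopc = mean(out$aopc), sd_aopc = sd_pop(out$aopc))
}

#' @exportS3Method generics::glance
glance.aopc_result <- function(x, ...) {
  tibble::tibble(model = attr(x, "model_label"),
                 noise = noise_label(attr(x, "noise")),
                 mean_aopc = attr(x, "mean_aopc"),
                 sd_aopc = attr(x, "sd_aopc"),
                 n_runs = nrow(x))
}
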