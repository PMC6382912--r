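# Reliability of relevance attributions: a coefficient of variation of the
# per-component relevance values across a subject's test trials (gathered
# over all cross-validation splits).  Low values mean the model attributes
# relevance to the same gait features for every trial of a subject.

#' Explain every test sample of an experiment
#'
#' Runs LRP on each trial exactly once, as a test sample of its
#' cross-validation fold with that fold's trained model, explaining the
#' true class.
#'
#' @param experiment a `gait_experiment`.
#' @param epsilon LRP stabilizer.
#' @return An `experiment_relevance` object: the relevance matrix (trials
#'   by components) plus aligned subject/trial/fold metadata.
#' @export
explain_experiment <- function(experiment, epsilon = 1e-9) {
  stopifnot(inherits(experiment, "gait_experiment"))
  mats <- list(); sids <- list(); tids <- list(); folds <- list()
  for (f in seq_along(experiment$models)) {
    te <- experiment$tests[[f]]
    mats[[f]] <- explain_samples(experiment$models[[f]], te,
                                 class_c = "true", epsilon = epsilon)
    sids[[f]] <- te$subject_id
    tids[[f]] <- te$trial_id
    folds[[f]] <- rep(f, nrow(te$x))
  }
  structure(list(
    relevance = do.call(rbind, mats),
    subject_id = unlist(sids),
    trial_id = unlist(tids),
    fold = unlist(folds),
    channels = experiment$tests[[1]]$channels,
    n_points = experiment$tests[[1]]$n_points,
    model_label = experiment$spec$label,
    variable_set = experiment$variable_set
  ), class = "experiment_relevance")
}

#' Gather one subject's relevance maps
#'
#' @param relevance an `experiment_relevance`.
#' @param subject subject id.
#' @return Matrix with one row per test trial of the subject (collected
#'   across all folds) and one column per input component.
#' @export
collect_subject_relevances <- function(relevance, subject) {
  stopifnot(inherits(relevance, "experiment_relevance"))
  idx <- which(relevance$subject_id == subject)
  if (length(idx) == 0) {
    abort(sprintf("subject %s has no explained trials", subject))
  }
  m <- relevance$relevance[idx, , drop = FALSE]
  rownames(m) <- relevance$trial_id[idx]
  attr(m, "fold") <- relevance$fold[idx]
  m
}

#' Coefficient of variation of relevance values
#'
#' Per input component the (population) standard deviation of the
#' relevance values over trials is computed; the CV is the mean of these
#' standard deviations normalised by the root mean square of the
#' mean-over-trials relevance signal.  The measure is invariant to global
#' rescaling of the maps and grows when attributions flip sign between
#' trials.
#'
#' @param mat trials-by-components relevance matrix (>= 2 trials).
#' @return A single nonnegative CV; `NaN` (with a warning) if the mean
#'   relevance signal is identically zero.
#' @export
relevance_cv <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) abort("need at least 2 trials to compute a CV")
  mu <- colMeans(mat)
  sigma <- sqrt(colMeans(mat^2) - mu^2)
  sigma <- pmax(sigma, 0)  # guard tiny negative round-off
  rms <- sqrt(mean(mu^2))
  if (rms == 0) {
    warn("mean relevance signal is identically zero; CV undefined")
    return(NaN)
  }
  mean(sigma) / rms
}

#' Reliability report over subjects
#'
#' @param relevance an `experiment_relevance` (or list of them).
#' @return A `reliability_report` tibble with one row per model: per-subject
#'   CVs aggregated as mean and (population) standard deviation, plus the
#'   per-subject values in a list column.
#' @export
reliability_report <- function(relevance) {
  if (inherits(relevance, "experiment_relevance")) relevance <- list(relevance)
  rows <- purrr::map(relevance, function(rel) {
    subjects <- sort(unique(rel$subject_id))
    cvs <- vapply(subjects, function(s) {
      relevance_cv(collect_subject_relevances(rel, s))
    }, numeric(1))
    tibble::tibble(
      model = rel$model_label,
      variable_set = rel$variable_set,
      mean_cv = mean(cvs),
      sd_cv = sd_pop(cvs),
      n_subjects = length(subjects),
      subject_cv = list(stats::setNames(cvs, subjects))
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("reliability_report", class(out)))
}
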