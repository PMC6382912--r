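# Dataset readers/writers and result report formatting.

DATASET_VERSIONS <- c("1.0")

validate_gait_dataset <- function(x) {
  need <- c("subject_id", "trial_id", "channel", "sample_index", "value")
  miss <- setdiff(need, names(x$trials))
  if (length(miss)) {
    abort(sprintf("trials table is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (!all(c("channel", "kind", "sampling_rate") %in% names(x$channels))) {
    abort("channels table must have channel, kind, sampling_rate")
  }
  if (!all(c("subject_id", "body_weight") %in% names(x$subjects))) {
    abort("subjects table must have subject_id and body_weight")
  }
  if (is.null(x$version) || !x$version %in% DATASET_VERSIONS) {
    abort(sprintf("unknown dataset format version '%s'", x$version %||% "<none>"))
  }
  unknown <- setdiff(unique(x$trials$channel), x$channels$channel)
  if (length(unknown)) {
    abort(sprintf("trials reference unknown channel(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  orphan <- setdiff(unique(x$trials$subject_id), x$subjects$subject_id)
  if (length(orphan)) {
    abort(sprintf("trials reference unknown subject(s): %s",
                  paste(orphan, collapse = ", ")))
  }
  if (any(x$channels$kind == "kinetic") && anyNA(x$subjects$body_weight)) {
    abort("body_weight is required for every subject when kinetic channels are present")
  }
  invisible(x)
}

#' Write / read a gait dataset
#'
#' Two on-disk forms share one schema (trials, channel metadata, subjects,
#' format version): `"csv"` writes a directory of RFC-4180 CSV files plus
#' a `meta.csv` carrying the version, and `"container"` writes a single
#' serialized file whose round trip is bit-exact.
#'
#' @param dataset a `gait_dataset`.
#' @param path directory (csv) or file (container).
#' @param format `"csv"` or `"container"` (inferred from `path` on read:
#'   directories are csv).
#' @return `read_gait_dataset` returns a validated `gait_dataset`.
#' @export
write_gait_dataset <- function(dataset, path, format = c("csv", "container")) {
  format <- match.arg(format)
  validate_gait_dataset(dataset)
  if (format == "container") {
    saveRDS(dataset, path)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(dataset$trials, file.path(path, "trials.csv"),
                     row.names = FALSE)
    utils::write.csv(dataset$channels, file.path(path, "channels.csv"),
                     row.names = FALSE)
    utils::write.csv(dataset$subjects, file.path(path, "subjects.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(key = "version", value = dataset$version),
                     file.path(path, "meta.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_gait_dataset
#' @export
read_gait_dataset <- function(path, format = NULL) {
  format <- format %||% if (dir.exists(path)) "csv" else "container"
  if (format == "container") {
    out <- readRDS(path)
    if (!inherits(out, "gait_dataset")) abort("not a gait dataset container")
  } else {
    files <- file.path(path, c("trials.csv", "channels.csv", "subjects.csv",
                               "meta.csv"))
    if (!all(file.exists(files))) {
      abort("csv dataset directory must contain trials.csv, channels.csv, subjects.csv and meta.csv")
    }
    read1 <- function(f) tibble::as_tibble(utils::read.csv(f))
    meta <- utils::read.csv(files[4], colClasses = "character")
    out <- new_gait_dataset(
      trials = read1(files[1]),
      channels = read1(files[2]),
      subjects = read1(files[3]),
      version = as.character(meta$value[meta$key == "version"][1])
    )
  }
  validate_gait_dataset(out)
  out
}

round_half_up <- function(x, digits) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

format_pair <- function(mean, sd, digits) {
  sprintf("%.*f (%.*f)", digits, round_half_up(mean, digits),
          digits, round_half_up(sd, digits))
}

#' Write a mean (sd) result report
#'
#' Formats result tables the way classification and robustness summaries
#' are conventionally printed: one cell per model and condition holding
#' `"mean (sd)"`, rounded to one decimal for accuracies/AOPC and two for
#' CVs.  A machine-readable twin with full precision is written next to
#' the formatted file (suffix `_full.csv`).
#'
#' @param result tibble with a `model` column, a condition column
#'   (`variable_set` or `noise`) and `mean_*`/`sd_*` columns (e.g. the
#'   output of `glance()` on experiments, AOPC results or reliability
#'   reports, row-bound).
#' @param layout `"accuracy"`, `"aopc"` or `"cv"` (sets the rounding).
#' @param path output CSV path.
#' @return The formatted tibble, invisibly.
#' @export
write_report <- function(result, layout = c("accuracy", "aopc", "cv"), path) {
  layout <- match.arg(layout)
  digits <- if (layout == "cv") 2L else 1L
  mean_col <- grep("^mean_", names(result), value = TRUE)[1]
  sd_col <- grep("^sd_", names(result), value = TRUE)[1]
  if (is.na(mean_col) || is.na(sd_col)) {
    abort("`result` must contain mean_* and sd_* columns")
  }
  cond_col <- intersect(c("variable_set", "noise"), names(result))[1]
  result$cell <- format_pair(result[[mean_col]], result[[sd_col]], digits)
  if (!is.na(cond_col)) {
    wide <- tidyr::pivot_wider(
      result[, c("model", cond_col, "cell")],
      names_from = dplyr::all_of(cond_col), values_from = "cell")
  } else {
    wide <- result[, c("model", "cell")]
  }
  utils::write.csv(wide, path, row.names = FALSE)
  keep <- setdiff(names(result)[!vapply(result, is.list, logical(1))], "cell")
  full <- result[, keep]
  utils::write.csv(full, sub("\\.csv$", "_full.csv", path), row.names = FALSE)
  invisible(wide)
}
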