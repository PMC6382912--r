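# Relevance-colored gait plots.  Gait curves are drawn per channel with
# line segments colored through a symmetric diverging palette: black for
# irrelevant inputs (R near 0), warm hues for relevance supporting the
# explained class, cold hues for contradicting inputs.

relevance_palette <- function() {
  c("#00FFFF", "#0066FF", "#000000", "#FF3300", "#FFFF00")
}

#' Plot gait curves colored by input relevance
#'
#' @param samples a `gait_samples` (for the curve values) or a
#'   channels-by-time matrix.
#' @param map a `relevance_map` aligned with the sample.
#' @param index row of `samples` to plot when it is a `gait_samples`.
#' @param mark_maxima circle the highest `|R|` per body side (channels are
#'   assigned to sides by their `_r_`/`_l_` name infix).
#' @param stance optional list with `right`/`left` stance windows in %
#'   stride, shaded behind kinematic channels.
#' @return A ggplot object.
#' @export
plot_relevance <- function(samples, map, index = 1, mark_maxima = TRUE,
                           stance = NULL) {
  stopifnot(inherits(map, "relevance_map"))
  vals <- if (inherits(samples, "gait_samples")) {
    t(matrix(samples$x[index, ], nrow = samples$n_points))
  } else {
    as.matrix(samples)
  }
  R <- map$relevance
  if (!all(dim(vals) == dim(R))) {
    abort("sample values and relevance map have mismatched shapes")
  }
  n_t <- ncol(R)
  df <- tibble::tibble(
    channel = factor(rep(rownames(R), each = n_t), levels = rownames(R)),
    t = rep(seq_len(n_t) - 1L, times = nrow(R)),
    value = as.vector(t(vals)),
    relevance = as.vector(t(R))
  )
  lim <- max(abs(df$relevance), 1e-12)  # display scale only
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(color = .data$relevance,
                                    group = .data$channel),
                       linewidth = 0.7) +
    ggplot2::scale_color_gradientn(colors = relevance_palette(),
                                   limits = c(-lim, lim)) +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "% stride", y = NULL, color = "relevance",
                  title = sprintf("%s, class %s", map$model_label,
                                  map$class_c)) +
    ggplot2::theme_minimal()
  if (!is.null(stance)) {
    shade <- dplyr::bind_rows(purrr::imap(stance, function(w, side) {
      tibble::tibble(xmin = w[1], xmax = w[2], side = side)
    }))
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax),
      ymin = -Inf, ymax = Inf, alpha = 0.08, inherit.aes = FALSE)
  }
  if (mark_maxima) {
    df$side <- ifelse(grepl("_r_", df$channel), "right",
                      ifelse(grepl("_l_", df$channel), "left", "central"))
    marks <- df |>
      dplyr::group_by(.data$side) |>
      dplyr::slice_max(abs(.data$relevance), n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    p <- p + ggplot2::geom_point(data = marks, shape = 21, size = 3,
                                 color = "red", fill = NA, stroke = 1)
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.relevance_map <- function(object, ...) {
  df <- tidy(object)
  lim <- max(abs(df$relevance), 1e-12)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$relevance,
                                   color = .data$relevance)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::scale_color_gradientn(colors = relevance_palette(),
                                   limits = c(-lim, lim)) +
    ggplot2::facet_wrap(~channel) +
    ggplot2::labs(x = "% stride", y = "relevance",
                  title = sprintf("%s, class %s", object$model_label,
                                  object$class_c)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.perturbation_curves <- function(object, ...) {
  df <- object |>
    dplyr::group_by(.data$step) |>
    dplyr::summarise(accuracy = mean(.data$accuracy), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "perturbation step", y = "accuracy [%]",
                  title = sprintf("%s under %s", attr(object, "model_label"),
                                  noise_label(attr(object, "noise")))) +
    ggplot2::theme_minimal()
}
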