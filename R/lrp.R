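# Layer-Wise Relevance Propagation.  The prediction f_c(x) (pre-softmax
# score of the explained class) is redistributed backwards through the
# layer sequence: affine and convolutional layers split each output
# neuron's relevance R_j across its inputs in proportion to their forward
# contributions z_ij = x_i w_ij (the bias acting as a constant always-on
# neuron), elementwise nonlinearities pass relevance through unchanged,
# and flatten layers only remap indices.  Summing input relevances and
# bias relevances recovers f_c(x) (conservation).

relevance_factor <- function(z, R, epsilon) {
  # R_j / (z_j + eps * sign(z_j)), with the convention sign(0) = +1;
  # outputs holding no relevance contribute nothing regardless of z_j.
  denom <- z + epsilon * ifelse(z >= 0, 1, -1)
  f <- numeric(length(z))
  nz <- R != 0
  if (any(nz & denom == 0)) {
    abort("degenerate denominator z_j = 0 in relevance propagation; use a positive epsilon",
          class = "gaitlrp_degenerate_denominator")
  }
  f[nz] <- R[nz] / denom[nz]
  f
}

propagate_affine <- function(layer, a_in, R_out, epsilon) {
  z <- as.vector(crossprod(layer$W, a_in)) + layer$b
  f <- relevance_factor(z, R_out, epsilon)
  list(R_in = a_in * as.vector(layer$W %*% f),
       R_bias = sum(layer$b * f))
}

propagate_conv <- function(layer, a_in, R_out, epsilon) {
  P <- conv_patches(layer, a_in)
  Z <- crossprod(P, layer$Wf)
  Z <- sweep(Z, 2, layer$b, "+")
  n_pos <- nrow(Z)
  R_mat <- matrix(R_out, nrow = n_pos)
  f <- matrix(relevance_factor(as.vector(Z), as.vector(R_mat), epsilon),
              nrow = n_pos)
  # relevance flowing to patch element e at position p:
  #   P[e, p] * sum_m Wf[e, m] * f[p, m]
  Rpatch <- P * (layer$Wf %*% t(f))
  d <- dim(a_in)
  wp <- d[2] + 2L * layer$pad_w
  flat <- numeric(d[1] * wp * d[3])
  acc <- rowsum(as.vector(Rpatch), group = as.vector(layer$idx))
  flat[as.integer(rownames(acc))] <- acc
  arr <- array(flat, dim = c(d[1], wp, d[3]))
  R_in <- array(arr[, layer$pad_w + seq_len(d[2]), , drop = FALSE], dim = d)
  list(R_in = R_in, R_bias = sum(sweep(f, 2, layer$b, "*")))
}

#' Explain one prediction with Layer-Wise Relevance Propagation
#'
#' Decomposes the pre-softmax score of the explained class into one
#' relevance value per input component (channel by time point).  Positive
#' relevance supports the explained class, negative relevance contradicts
#' it, near-zero relevance marks inputs without influence.  By default the
#' explained class is the sample's true label when `x` is a
#' `gait_samples`, otherwise the predicted class.
#'
#' @param model a `network_model`.
#' @param x one sample: a numeric vector of length `channels * time`, or a
#'   `gait_samples` together with `index`.
#' @param class_c class to explain (label or index); see default above.
#' @param epsilon stabilizer added to the denominators `z_j` (sign
#'   matched).  `0` gives exact conservation but fails loudly on zero
#'   denominators.
#' @param index row of `x` to explain when `x` is a `gait_samples`.
#' @return A `relevance_map`: relevance matrix (channels x time), bias
#'   relevance per layer, the explained class and `f_c(x)`.
#' @export
lrp_explain <- function(model, x, class_c = NULL, epsilon = 1e-9,
                        index = NULL) {
  channels <- NULL
  meta <- NULL
  if (inherits(x, "gait_samples")) {
    index <- index %||% 1L
    channels <- x$channels$channel
    meta <- list(subject_id = x$subject_id[index],
                 trial_id = x$trial_id[index])
    class_c <- class_c %||% as.character(x$subject_id[index])
    x <- x$x[index, ]
  }
  if (length(x) != model$n_inputs) {
    abort(sprintf("sample has %d components, model expects %d",
                  length(x), model$n_inputs))
  }
  fw <- nn_forward_cached(model, x)
  if (is.null(class_c)) class_c <- model$classes[which.max(fw$scores)]
  ci <- if (is.numeric(class_c)) as.integer(class_c) else
    match(as.character(class_c), model$classes)
  if (is.na(ci) || ci < 1 || ci > length(fw$scores)) {
    abort("explained class not found in the model's classes")
  }
  f_c <- fw$scores[ci]
  # output-layer relevance: f_c(x) at the explained class, 0 elsewhere
  R <- numeric(length(fw$scores))
  R[ci] <- f_c
  bias_relevance <- numeric(0)
  for (li in rev(seq_along(model$layers))) {
    layer <- model$layers[[li]]
    if (layer$type == "softmax") next  # LRP runs on pre-softmax scores
    a_in <- fw$caches[[li]]
    if (layer$type == "relu") {
      # elementwise nonlinearity: relevance passes through unchanged
      next
    } else if (layer$type == "flatten") {
      R <- array(R, dim = dim(a_in))
    } else if (layer$type == "affine") {
      pr <- propagate_affine(layer, a_in, R, epsilon)
      R <- pr$R_in
      bias_relevance <- c(pr$R_bias, bias_relevance)
    } else if (layer$type == "conv") {
      pr <- propagate_conv(layer, a_in, R, epsilon)
      R <- pr$R_in
      bias_relevance <- c(pr$R_bias, bias_relevance)
    }
  }
  if (!is.null(dim(R))) {
    # conv-input grid (channels, time, 1) back to the channels x time matrix
    R <- matrix(R[, , 1], nrow = dim(R)[1])
  } else {
    R <- t(matrix(R, nrow = model$spec$n_time))
  }
  rownames(R) <- channels %||% paste0("ch", seq_len(nrow(R)))
  structure(list(
    relevance = R,
    bias_relevance = bias_relevance,
    class_c = model$classes[ci],
    f_c = f_c,
    epsilon = epsilon,
    model_label = model$spec$label,
    meta = meta
  ), class = "relevance_map")
}

#' @export
print.relevance_map <- function(x, ...) {
  cat(sprintf(
    "<relevance_map> class %s, f_c = %.4f, sum(R) + sum(R_bias) = %.4f\n",
    x$class_c, x$f_c, sum(x$relevance) + sum(x$bias_relevance)))
  invisible(x)
}

#' Conservation error of a relevance map
#'
#' Relative deviation of `sum(R_i) + sum(R_bias)` from `f_c(x)`.
#'
#' @param map a `relevance_map`.
#' @return Absolute error divided by `max(|f_c|, 1e-12)`.
#' @export
conservation_error <- function(map) {
  abs(sum(map$relevance) + sum(map$bias_relevance) - map$f_c) /
    max(abs(map$f_c), 1e-12)
}

#' @exportS3Method generics::tidy
tidy.relevance_map <- function(x, ...) {
  tibble::tibble(
    channel = rep(rownames(x$relevance), each = ncol(x$relevance)),
    t = rep(seq_len(ncol(x$relevance)) - 1L, times = nrow(x$relevance)),
    relevance = as.vector(t(x$relevance))
  )
}

#' Explain many samples at once
#'
#' @param model a `network_model`.
#' @param samples a `gait_samples` (or matrix).
#' @param class_c `"true"` (default, requires `gait_samples`),
#'   `"predicted"`, or a fixed label.
#' @param epsilon stabilizer, see [lrp_explain()].
#' @return A samples-by-components matrix of relevance values, with the
#'   explained `f_c` as attribute `"f_c"`.
#' @export
explain_samples <- function(model, samples, class_c = "true",
                            epsilon = 1e-9) {
  x <- if (inherits(samples, "gait_samples")) samples$x else samples
  n <- nrow(x)
  out <- matrix(NA_real_, n, ncol(x))
  f_c <- numeric(n)
  for (i in seq_len(n)) {
    cc <- if (identical(class_c, "true")) {
      as.character(samples$subject_id[i])
    } else if (identical(class_c, "predicted")) NULL else class_c
    map <- lrp_explain(model, x[i, ], class_c = cc, epsilon = epsilon)
    out[i, ] <- as.vector(t(map$relevance))
    f_c[i] <- map$f_c
  }
  attr(out, "f_c") <- f_c
  out
}
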