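# Model zoo: the classifier family as explicit layer sequences.  Fully
# connected families consume row-concatenated channel-by-time vectors;
# convolutional families consume the channel x time grid directly.

MLP_WIDTHS <- c(64L, 128L, 256L, 512L, 1024L)

#' Specify a classifier architecture
#'
#' Families: `"linear_sgd"` (single affine layer + softmax, trained by
#' SGD), `"linear_svm"` (one-vs-rest linear SVM, represented as a single
#' affine layer for prediction and LRP), `"mlp"` (fully connected with
#' ReLU; `n_layers` affine layers in total, 64-1024 neurons per hidden
#' layer) and `"cnn"` (one to three convolutional layers with ReLU, topped
#' off by one affine layer to the classes).
#'
#' The two convolutional presets are documented approximations, not exact
#' reproductions of any published architecture: `"cnn_a"` is one
#' convolutional layer with a full-channel C x 3 filter (stride 1, 32
#' feature maps); `"cnn_c3"` stacks three convolutional layers (C x 3,
#' then 1 x 3 filters at time stride 2, 32 maps each).
#'
#' @param family model family.
#' @param n_classes number of classes.
#' @param n_channels,n_time input grid dimensions (channels x time).
#' @param n_layers,width MLP depth (2 or 3 affine layers) and hidden width.
#' @param preset CNN preset name, `"cnn_a"` or `"cnn_c3"`.
#' @param n_conv_layers,input_filter,n_maps,conv_stride explicit CNN
#'   configuration overriding the preset: number of convolutional layers
#'   (1-3), input-layer filter `c(height, width)`, feature maps per layer
#'   and the time stride of layers after the first.
#' @return A `model_spec`.
#' @export
model_spec <- function(family = c("linear_sgd", "linear_svm", "mlp", "cnn"),
                       n_classes, n_channels, n_time = 101,
                       n_layers = 3, width = 256,
                       preset = c("cnn_a", "cnn_c3"),
                       n_conv_layers = NULL, input_filter = NULL,
                       n_maps = 32, conv_stride = 2) {
  family <- match.arg(family)
  stopifnot(n_classes >= 2, n_channels >= 1, n_time >= 1)
  spec <- list(family = family, n_classes = as.integer(n_classes),
               n_channels = as.integer(n_channels),
               n_time = as.integer(n_time))
  if (family == "mlp") {
    if (!n_layers %in% c(2L, 3L)) abort("`n_layers` must be 2 or 3")
    if (!width %in% MLP_WIDTHS) {
      abort(sprintf("`width` must be one of %s",
                    paste(MLP_WIDTHS, collapse = ", ")))
    }
    spec$n_layers <- as.integer(n_layers)
    spec$width <- as.integer(width)
    spec$label <- sprintf("MLP (%d, %d)", n_layers, width)
  } else if (family == "cnn") {
    if (is.null(n_conv_layers)) {
      preset <- match.arg(preset)
      spec$preset <- preset
      if (preset == "cnn_a") {
        spec$n_conv_layers <- 1L
        spec$input_filter <- c(n_channels, 3L)
        spec$conv_stride <- 1L
      } else {
        spec$n_conv_layers <- 3L
        spec$input_filter <- c(n_channels, 3L)
        spec$conv_stride <- 2L
      }
      spec$n_maps <- 32L
      spec$label <- toupper(sub("cnn_", "CNN-", preset))
    } else {
      if (!n_conv_layers %in% 1:3) abort("`n_conv_layers` must be 1, 2 or 3")
      stopifnot(length(input_filter) == 2, input_filter[1] <= n_channels)
      spec$n_conv_layers <- as.integer(n_conv_layers)
      spec$input_filter <- as.integer(input_filter)
      spec$n_maps <- as.integer(n_maps)
      spec$conv_stride <- as.integer(conv_stride)
      spec$label <- sprintf("CNN (%dx%dx%d)", n_conv_layers,
                            input_filter[1], input_filter[2])
    }
  } else {
    spec$label <- if (family == "linear_sgd") "Linear (SGD)" else "Linear (SVM)"
  }
  structure(spec, class = "model_spec")
}

init_weights <- function(n_in, n_out) {
  # mean-zero normal with sd = m^(-1/2), m = inputs per output neuron
  matrix(rnorm(n_in * n_out, 0, 1 / sqrt(n_in)), n_in, n_out)
}

#' Build an initialized network from a specification
#'
#' Weights are drawn from a mean-zero normal distribution with standard
#' deviation `m^(-1/2)` where `m` is the number of inputs to each output
#' neuron of the layer; biases start at zero.  Deterministic given
#' `init_seed`.  (`linear_svm` models are produced by
#' [train_linear_svm()], not by this builder.)
#'
#' @param spec a [model_spec()].
#' @param init_seed integer seed for the weight draw.
#' @param classes optional character vector of class labels.
#' @return A `network_model`.
#' @export
build_model <- function(spec, init_seed = 1, classes = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$family == "linear_svm") {
    abort("linear_svm models are fitted with train_linear_svm()")
  }
  n_in <- spec$n_channels * spec$n_time
  withr::with_seed(init_seed, {
    layers <- list()
    if (spec$family == "linear_sgd") {
      layers <- list(new_affine_layer(init_weights(n_in, spec$n_classes),
                                      rep(0, spec$n_classes)),
                     new_softmax_layer())
    } else if (spec$family == "mlp") {
      dims <- c(n_in, rep(spec$width, spec$n_layers - 1L), spec$n_classes)
      for (l in seq_len(spec$n_layers)) {
        layers[[length(layers) + 1L]] <-
          new_affine_layer(init_weights(dims[l], dims[l + 1L]),
                           rep(0, dims[l + 1L]))
        if (l < spec$n_layers) layers[[length(layers) + 1L]] <- new_relu_layer()
      }
      layers[[length(layers) + 1L]] <- new_softmax_layer()
    } else {
      shape <- c(spec$n_channels, spec$n_time, 1L)
      for (l in seq_len(spec$n_conv_layers)) {
        filt <- if (l == 1L) spec$input_filter else c(1L, 3L)
        stride <- if (l == 1L) c(1L, 1L) else c(1L, spec$conv_stride)
        m_in <- filt[1] * filt[2] * shape[3]
        W <- array(rnorm(m_in * spec$n_maps, 0, 1 / sqrt(m_in)),
                   dim = c(filt[1], filt[2], shape[3], spec$n_maps))
        lay <- new_conv_layer(W, rep(0, spec$n_maps), in_shape = shape,
                              stride = stride, pad_w = 1L)
        layers[[length(layers) + 1L]] <- lay
        layers[[length(layers) + 1L]] <- new_relu_layer()
        shape <- lay$out_shape
      }
      layers[[length(layers) + 1L]] <- new_flatten_layer(shape)
      layers[[length(layers) + 1L]] <-
        new_affine_layer(init_weights(prod(shape), spec$n_classes),
                         rep(0, spec$n_classes))
      layers[[length(layers) + 1L]] <- new_softmax_layer()
    }
    new_network_model(layers, spec, classes, init_seed)
  })
}

new_network_model <- function(layers, spec, classes = NULL, init_seed = NA) {
  types <- vapply(layers, function(l) l$type, character(1))
  if (sum(types == "softmax") != 1L || types[length(types)] != "softmax") {
    abort("a network must end in exactly one softmax layer")
  }
  structure(list(
    layers = layers,
    spec = spec,
    n_inputs = spec$n_channels * spec$n_time,
    classes = classes %||% as.character(seq_len(spec$n_classes)),
    has_conv = any(types == "conv"),
    init_seed = init_seed
  ), class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("<network_model> %s: %d classes, input %d x %d\n",
              x$spec$label, x$spec$n_classes, x$spec$n_channels,
              x$spec$n_time))
  for (l in x$layers) {
    desc <- switch(l$type,
      affine = sprintf("affine %d -> %d", nrow(l$W), ncol(l$W)),
      conv = sprintf("conv %dx%dx%d -> %d maps (stride %d,%d)",
                     dim(l$W)[1], dim(l$W)[2], dim(l$W)[3], dim(l$W)[4],
                     l$stride[1], l$stride[2]),
      l$type)
    cat("  -", desc, "\n")
  }
  invisible(x)
}

# Forward pass for one flat sample, caching every layer's input (needed by
# both the gradient and the relevance backward passes).
nn_forward_cached <- function(model, x) {
  a <- x
  caches <- vector("list", length(model$layers))
  scores <- NULL
  for (li in seq_along(model$layers)) {
    layer <- model$layers[[li]]
    if (layer$type == "conv" && is.null(dim(a))) {
      a <- flat_to_grid(a, model$spec$n_channels, model$spec$n_time)
    }
    caches[[li]] <- a
    if (layer$type == "softmax") scores <- a
    a <- layer_forward(layer, a)
  }
  list(scores = as.vector(scores), probs = as.vector(a), caches = caches)
}

#' Evaluate a model on samples
#'
#' @param model a `network_model`.
#' @param x numeric matrix (samples by components) or a `gait_samples`.
#' @return List with `scores` (pre-softmax, samples x classes) and `probs`
#'   (post-softmax).
#' @export
nn_forward <- function(model, x) {
  if (inherits(x, "gait_samples")) x <- x$x
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$n_inputs) {
    abort(sprintf("input has %d components, model expects %d",
                  ncol(x), model$n_inputs))
  }
  if (!model$has_conv) {
    a <- x
    for (layer in model$layers) {
      a <- switch(layer$type,
        affine = sweep(a %*% layer$W, 2, layer$b, "+"),
        relu = pmax(a, 0),
        softmax = { scores <- a; softmax_rows(a) },
        abort("unexpected layer in dense model"))
    }
    list(scores = scores, probs = a)
  } else {
    out <- t(vapply(seq_len(nrow(x)), function(i) {
      nn_forward_cached(model, x[i, ])$scores
    }, numeric(model$spec$n_classes)))
    list(scores = out, probs = softmax_rows(out))
  }
}

#' Predict class labels
#'
#' Argmax over pre-softmax scores; ties broken by the lowest class index.
#'
#' @param object a `network_model`.
#' @param x samples matrix or `gait_samples`.
#' @param ... unused.
#' @return Character vector of predicted class labels.
#' @export
predict.network_model <- function(object, x, ...) {
  scores <- nn_forward(object, x)$scores
  object$classes[max.col(scores, ties.method = "first")]
}

#' Classification accuracy in percent
#'
#' @param predictions,truth vectors of equal length.
#' @return `100 * correct / total`.
#' @export
accuracy <- function(predictions, truth) {
  if (length(predictions) == 0) abort("empty prediction set")
  stopifnot(length(predictions) == length(truth))
  100 * mean(as.character(predictions) == as.character(truth))
}

#' Save / load a model container
#'
#' The container holds the spec, every layer's parameter arrays and the
#' init seed; a load after save is bit-exact.
#'
#' @param model a `network_model`.
#' @param path file path.
#' @return `load_model` returns the `network_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "network_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "network_model"))
  model
}

#' @exportS3Method generics::tidy
tidy.network_model <- function(x, ...) {
  rows <- purrr::imap(x$layers, function(l, i) {
    tibble::tibble(
      layer = i,
      type = l$type,
      n_parameters = switch(l$type,
                            affine = length(l$W) + length(l$b),
                            conv = length(l$W) + length(l$b),
                            0L),
      output_units = switch(l$type,
                            affine = ncol(l$W),
                            conv = prod(l$out_shape),
                            NA_integer_)
    )
  })
  dplyr::bind_rows(rows)
}
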