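# Training: mini-batch SGD under the staged learning-rate schedule,
# one-vs-rest linear SVM fitting, subject-stratified fold plans and the
# cross-validated experiment driver.

#' SGD training configuration
#'
#' Defaults follow the reference schedule: up to 30000 iterations of
#' mini-batches of 5 training samples drawn with replacement, learning rate
#' 5e-3 lowered to 1e-3 and then 5e-4 after every 10000 iterations.
#' Validation accuracy is evaluated every `eval_every` iterations; a
#' learning-rate stage ends early once `patience` consecutive evaluations
#' fail to improve the stage's best validation accuracy by at least
#' `min_delta` percentage points.  The returned model carries the weights
#' of the best validation evaluation seen during training.
#'
#' @param max_iterations total iteration budget.
#' @param batch_size samples per mini-batch.
#' @param learning_rates one rate per stage.
#' @param stage_iterations iterations per learning-rate stage.
#' @param eval_every,patience,min_delta early-stopping controls.
#' @param seed RNG seed for batch sampling.
#' @return A `train_config` list.
#' @export
train_config <- function(max_iterations = 30000, batch_size = 5,
                         learning_rates = c(5e-3, 1e-3, 5e-4),
                         stage_iterations = 10000, eval_every = 250,
                         patience = 8, min_delta = 0.1, seed = 1) {
  structure(list(max_iterations = as.integer(max_iterations),
                 batch_size = as.integer(batch_size),
                 learning_rates = learning_rates,
                 stage_iterations = as.integer(stage_iterations),
                 eval_every = as.integer(eval_every),
                 patience = as.integer(patience),
                 min_delta = min_delta, seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given iteration
#' @param config a [train_config()].
#' @param iteration iteration number (1-based).
#' @return The stage learning rate.
#' @export
learning_rate_at <- function(config, iteration) {
  stage <- min((iteration - 1L) %/% config$stage_iterations + 1L,
               length(config$learning_rates))
  config$learning_rates[stage]
}

#' Upper bound on passes over the training set
#'
#' @param iterations,batch_size,n_train SGD bookkeeping quantities.
#' @return `floor(iterations * batch_size / n_train)`.
#' @export
epoch_bound <- function(iterations = 30000, batch_size = 5, n_train = 912) {
  floor(iterations * batch_size / n_train)
}

#' Subject-stratified fold plan
#'
#' Assigns every (subject, trial) to one of `k` folds so that each
#' subject's trials are spread as evenly as possible (per-subject fold
#' counts differ by at most one).  Each cross-validation round uses one
#' fold for testing, the next for validation and the remaining `k - 2` for
#' training, so every sample is tested exactly once.
#'
#' @param data a `gait_dataset`, `gait_samples`, or data frame with
#'   `subject_id` and `trial_id`.
#' @param k number of folds (>= 3).
#' @param seed RNG seed.
#' @return A `fold_plan` tibble with columns `subject_id`, `trial_id`,
#'   `fold`.
#' @export
make_folds <- function(data, k = 10, seed = 1) {
  if (k < 3) abort("`k` must be >= 3 (train/validation/test roles)")
  meta <- if (inherits(data, "gait_dataset")) {
    dplyr::distinct(data$trials, .data$subject_id, .data$trial_id)
  } else if (inherits(data, "gait_samples")) {
    tibble::tibble(subject_id = data$subject_id, trial_id = data$trial_id)
  } else {
    dplyr::distinct(tibble::as_tibble(data), .data$subject_id, .data$trial_id)
  }
  plan <- meta |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(df, key) {
      with_child_seed(seed, 303L, key$subject_id[1], expr = {
        m <- nrow(df)
        start <- sample.int(k, 1)
        fold <- ((seq_len(m) - 1L + start) %% k) + 1L
        df$fold <- fold[sample.int(m)]
      })
      df
    }) |>
    dplyr::ungroup()
  structure(plan, class = c("fold_plan", class(plan)), k = as.integer(k),
            seed = as.integer(seed))
}

fold_roles <- function(plan, round) {
  k <- attr(plan, "k")
  stopifnot(round >= 1, round <= k)
  test <- round
  validation <- round %% k + 1L
  list(test = test, validation = validation,
       train = setdiff(seq_len(k), c(test, validation)))
}

match_plan <- function(samples, plan) {
  plan$fold[match(paste(samples$subject_id, samples$trial_id),
                  paste(plan$subject_id, plan$trial_id))]
}

clone_params <- function(model) {
  lapply(model$layers, function(l) {
    if (l$type %in% c("affine", "conv")) list(W = l$W, b = l$b) else NULL
  })
}

restore_params <- function(model, params) {
  for (i in seq_along(params)) {
    if (!is.null(params[[i]])) {
      model$layers[[i]]$W <- params[[i]]$W
      model$layers[[i]]$b <- params[[i]]$b
    }
  }
  model
}

# Predict labels from bare affine parameter lists (dense ReLU stack);
# used during training so evaluations see the in-place-updated weights.
dense_predict_labels <- function(Wl, bl, X, classes) {
  a <- X
  for (i in seq_along(Wl)) {
    a <- sweep(a %*% Wl[[i]], 2, bl[[i]], "+")
    if (i < length(Wl)) a <- pmax(a, 0)
  }
  classes[max.col(a, ties.method = "first")]
}

sgd_step_general <- function(model, xb, y_idx, lr) {
  n <- nrow(xb)
  grads <- vector("list", length(model$layers))
  loss <- 0
  for (s in seq_len(n)) {
    fw <- nn_forward_cached(model, xb[s, ])
    p <- fw$probs
    loss <- loss - log(max(p[y_idx[s]], 1e-300)) / n
    grad <- p
    grad[y_idx[s]] <- grad[y_idx[s]] - 1
    grad <- grad / n
    for (li in rev(seq_along(model$layers))) {
      layer <- model$layers[[li]]
      if (layer$type == "softmax") next
      bk <- layer_backward(layer, fw$caches[[li]], grad)
      grad <- bk$grad_in
      if (!is.null(bk$dW)) {
        if (is.null(grads[[li]])) {
          grads[[li]] <- list(dW = bk$dW, db = bk$db)
        } else {
          grads[[li]]$dW <- grads[[li]]$dW + bk$dW
          grads[[li]]$db <- grads[[li]]$db + bk$db
        }
      }
    }
  }
  for (li in seq_along(grads)) {
    if (!is.null(grads[[li]])) {
      model$layers[[li]]$W <- model$layers[[li]]$W - lr * grads[[li]]$dW
      model$layers[[li]]$b <- model$layers[[li]]$b - lr * grads[[li]]$db
    }
  }
  list(model = model, loss = loss)
}

#' Train a network with mini-batch SGD
#'
#' Minimizes cross-entropy on the softmax outputs under the staged
#' learning-rate schedule of the supplied [train_config()], with per-stage
#' early stopping on validation accuracy.  The returned model carries the
#' parameters of the best validation evaluation (or the final parameters
#' if no validation set is given).
#'
#' @param model an initialized `network_model`.
#' @param x,y training samples (matrix or `gait_samples`) and labels.
#' @param x_val,y_val optional validation set, required for early stopping.
#' @param config a [train_config()].
#' @return List with `model` (trained) and `log` (tibble: iteration,
#'   learning rate, training loss, validation accuracy).
#' @export
train_sgd <- function(model, x, y, x_val = NULL, y_val = NULL,
                      config = train_config()) {
  if (inherits(x, "gait_samples")) { y <- x$subject_id; x <- x$x }
  if (inherits(x_val, "gait_samples")) { y_val <- x_val$subject_id; x_val <- x_val$x }
  y_idx <- match(as.character(y), model$classes)
  if (anyNA(y_idx)) abort("training labels outside the model's classes")
  if (model$has_conv) {
    train_sgd_conv(model, x, y_idx, x_val, y_val, config)
  } else {
    train_sgd_dense(model, x, y_idx, x_val, y_val, config)
  }
}

# Dense path: blocks of iterations run in the fused compiled kernel, with
# validation checks (logging, early stopping, best-weight snapshots)
# between blocks.
train_sgd_dense <- function(model, x, y_idx, x_val, y_val, config) {
  aff <- which(vapply(model$layers, function(l) l$type == "affine",
                      logical(1)))
  Wl <- lapply(model$layers[aff], function(l) l$W + 0)  # private copies
  bl <- lapply(model$layers[aff], function(l) l$b + 0)
  n_stages <- length(config$learning_rates)
  log_rows <- list()
  best <- list(acc = -Inf, W = NULL, b = NULL)
  withr::with_seed(config$seed, {
    it <- 0L
    stage <- 1L
    stage_best <- -Inf
    stale <- 0L
    while (it < config$max_iterations) {
      stage_now <- min(it %/% config$stage_iterations + 1L, n_stages)
      if (stage_now != stage) { stage <- stage_now; stage_best <- -Inf; stale <- 0L }
      lr <- config$learning_rates[stage]
      block_end <- min(it + config$eval_every,
                       stage * config$stage_iterations,
                       config$max_iterations)
      loss <- sgd_dense_block(Wl, bl, x, y_idx, model$spec$n_classes,
                              block_end - it, lr, config$batch_size)
      it <- block_end
      if (is.na(loss) || !is.finite(loss)) {
        abort("SGD diverged (non-finite loss)", class = "gaitlrp_divergence")
      }
      if (!is.null(x_val)) {
        va <- accuracy(dense_predict_labels(Wl, bl, x_val, model$classes),
                       y_val)
        log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
          iteration = it, stage = stage, learning_rate = lr,
          train_loss = loss, validation_accuracy = va)
        if (va > best$acc) {
          best$acc <- va
          best$W <- lapply(Wl, function(w) w + 0)
          best$b <- lapply(bl, function(b) b + 0)
        }
        if (va > stage_best + config$min_delta) {
          stage_best <- va
          stale <- 0L
        } else {
          stale <- stale + 1L
          if (stale >= config$patience) {
            # stage converged: jump to the next learning-rate stage
            if (stage >= n_stages) break
            it <- stage * config$stage_iterations
            stage <- stage + 1L
            stage_best <- -Inf
            stale <- 0L
          }
        }
      }
    }
  })
  if (!is.null(best$W)) { Wl <- best$W; bl <- best$b }
  for (i in seq_along(aff)) {
    model$layers[[aff[i]]]$W <- Wl[[i]]
    model$layers[[aff[i]]]$b <- bl[[i]]
  }
  list(model = model, log = bind_log(log_rows))
}

bind_log <- function(log_rows) {
  if (length(log_rows)) dplyr::bind_rows(log_rows) else
    tibble::tibble(iteration = integer(), stage = integer(),
                   learning_rate = numeric(), train_loss = numeric(),
                   validation_accuracy = numeric())
}

# Convolutional path: per-sample forward/backward in R.
train_sgd_conv <- function(model, x, y_idx, x_val, y_val, config) {
  n <- nrow(x)
  n_stages <- length(config$learning_rates)
  log_rows <- list()
  best <- list(acc = -Inf, params = NULL)
  withr::with_seed(config$seed, {
    it <- 0L
    stage <- 1L
    stage_best <- -Inf
    stale <- 0L
    while (it < config$max_iterations) {
      it <- it + 1L
      stage_now <- min((it - 1L) %/% config$stage_iterations + 1L, n_stages)
      if (stage_now != stage) { stage <- stage_now; stage_best <- -Inf; stale <- 0L }
      lr <- config$learning_rates[stage]
      bi <- sample.int(n, config$batch_size, replace = TRUE)
      st <- sgd_step_general(model, x[bi, , drop = FALSE], y_idx[bi], lr)
      model <- st$model
      if (!is.finite(st$loss)) {
        abort("SGD diverged (non-finite loss)", class = "gaitlrp_divergence")
      }
      if (!is.null(x_val) && it %% config$eval_every == 0L) {
        va <- accuracy(predict(model, x_val), y_val)
        log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
          iteration = it, stage = stage, learning_rate = lr,
          train_loss = st$loss, validation_accuracy = va)
        if (va > best$acc) { best$acc <- va; best$params <- clone_params(model) }
        if (va > stage_best + config$min_delta) {
          stage_best <- va
          stale <- 0L
        } else {
          stale <- stale + 1L
          if (stale >= config$patience) {
            if (stage >= n_stages) break
            it <- stage * config$stage_iterations
            stage <- stage + 1L
            stage_best <- -Inf
            stale <- 0L
          }
        }
      }
    }
  })
  if (!is.null(best$params)) model <- restore_params(model, best$params)
  list(model = model, log = bind_log(log_rows))
}

#' Fit a one-vs-rest linear SVM as a network model
#'
#' Trains one binary linear soft-margin SVM (hinge loss, regularisation
#' parameter `C`) per class and assembles the per-class decision functions
#' `(w_c, b_c)` into a single affine layer, so the fitted classifier can be
#' used by [nn_forward()], [predict.network_model()] and [lrp_explain()]
#' exactly like the neural models.
#'
#' @param x training samples (matrix or `gait_samples`).
#' @param y class labels (ignored when `x` is a `gait_samples`).
#' @param C regularisation parameter (default 0.1).
#' @param classes optional fixed class ordering.
#' @return A `network_model` with a single affine layer and softmax.
#' @export
train_linear_svm <- function(x, y = NULL, C = 0.1, classes = NULL) {
  n_ch <- 1L
  if (inherits(x, "gait_samples")) {
    y <- x$subject_id
    n_ch <- nrow(x$channels)
    x <- x$x
  }
  y <- as.character(y)
  classes <- classes %||% sort(unique(y))
  if (length(unique(y)) < 2) abort("need at least 2 classes to fit an SVM")
  p <- ncol(x)
  W <- matrix(0, p, length(classes))
  b <- numeric(length(classes))
  for (ci in seq_along(classes)) {
    yb <- factor(ifelse(y == classes[ci], "pos", "neg"),
                 levels = c("pos", "neg"))
    fit <- e1071::svm(x, yb, kernel = "linear", cost = C, scale = FALSE)
    w <- as.vector(t(fit$coefs) %*% fit$SV)
    rho <- fit$rho
    # e1071 orients decision values towards whichever class it saw first;
    # flip so that the "pos" (own-class) side is positive
    s <- if (fit$levels[fit$labels[1]] == "pos") 1 else -1
    W[, ci] <- s * w
    b[ci] <- -s * rho
  }
  spec <- model_spec("linear_svm", n_classes = length(classes),
                     n_channels = n_ch, n_time = p %/% n_ch)
  new_network_model(
    list(new_affine_layer(W, b), new_softmax_layer()),
    spec, classes = classes, init_seed = NA)
}

#' Run a cross-validated classification experiment
#'
#' For each cross-validation round the normalization parameters are
#' refitted on that round's training folds only (no leakage into
#' validation or test data), a fresh model is initialized and trained, and
#' accuracy is measured on the round's test fold.  The aggregate is the
#' mean and (population) standard deviation of the per-fold test
#' accuracies, in percent.
#'
#' @param dataset a `gait_dataset`.
#' @param spec a [model_spec()] (`n_classes`/`n_channels` are taken from
#'   the data).
#' @param plan a [make_folds()] plan.
#' @param config a [train_config()]; ignored for `linear_svm`.
#' @param variable_set passed to [build_samples()].
#' @param svm_C regularisation parameter for `linear_svm`.
#' @param verbose print per-fold progress.
#' @param core optional cached result of [preprocess_trials()] for this
#'   dataset and variable set.
#' @return A `gait_experiment` with per-fold accuracies, the trained
#'   per-fold models and the per-fold test samples.
#' @export
run_experiment <- function(dataset, spec, plan, config = train_config(),
                           variable_set = "grf", svm_C = 0.1,
                           verbose = FALSE, core = NULL) {
  stopifnot(inherits(dataset, "gait_dataset"), inherits(plan, "fold_plan"))
  k <- attr(plan, "k")
  core <- core %||% preprocess_trials(dataset, variable_set)
  n_ch <- nrow(core$channels)
  spec <- update_spec_shape(spec, n_classes = length(unique(plan$subject_id)),
                            n_channels = n_ch, n_time = core$n_points)
  models <- vector("list", k)
  tests <- vector("list", k)
  logs <- vector("list", k)
  results <- vector("list", k)
  classes <- as.character(sort(unique(plan$subject_id)))
  for (r in seq_len(k)) {
    roles <- fold_roles(plan, r)
    fold_of <- match_plan(core$meta, plan)
    train_pairs <- plan[plan$fold %in% roles$train, c("subject_id", "trial_id")]
    samples <- finalize_samples(core, fitting = train_pairs)
    idx_train <- which(fold_of %in% roles$train)
    idx_val <- which(fold_of == roles$validation)
    idx_test <- which(fold_of == roles$test)
    tr <- samples_subset(samples, idx_train)
    va <- samples_subset(samples, idx_val)
    te <- samples_subset(samples, idx_test)
    if (spec$family == "linear_svm") {
      model <- train_linear_svm(tr$x, tr$subject_id, C = svm_C,
                                classes = classes)
      model$spec <- update_spec_shape(model$spec, spec$n_classes, n_ch,
                                      core$n_points)
      model$n_inputs <- n_ch * core$n_points
      logs[[r]] <- NULL
    } else {
      model <- build_model(spec, init_seed = child_seed(config$seed, 404L, r),
                           classes = classes)
      fit <- train_sgd(model, tr, x_val = va, config = config)
      model <- fit$model
      logs[[r]] <- fit$log
    }
    acc <- accuracy(predict(model, te), te$subject_id)
    if (verbose) {
      message(sprintf("fold %d/%d: test accuracy %.1f%%", r, k, acc))
    }
    models[[r]] <- model
    tests[[r]] <- te
    results[[r]] <- tibble::tibble(fold = r, accuracy = acc,
                                   n_test = nrow(te$x))
  }
  res <- dplyr::bind_rows(results)
  structure(list(
    spec = spec, plan = plan, config = config, variable_set = variable_set,
    results = res, models = models, tests = tests, logs = logs,
    classes = classes,
    mean_accuracy = mean(res$accuracy),
    sd_accuracy = sd_pop(res$accuracy)
  ), class = "gait_experiment")
}

update_spec_shape <- function(spec, n_classes, n_channels, n_time) {
  args <- list(family = spec$family, n_classes = n_classes,
               n_channels = n_channels, n_time = n_time)
  if (spec$family == "mlp") {
    args$n_layers <- spec$n_layers; args$width <- spec$width
  } else if (spec$family == "cnn") {
    if (!is.null(spec$preset)) {
      args$preset <- spec$preset
    } else {
      args$n_conv_layers <- spec$n_conv_layers
      args$input_filter <- spec$input_filter
      args$n_maps <- spec$n_maps
      args$conv_stride <- spec$conv_stride
    }
  }
  do.call(model_spec, args)
}

#' @export
print.gait_experiment <- function(x, ...) {
  cat(sprintf("<gait_experiment> %s on '%s': %.1f (%.1f) %% over %d folds\n",
              x$spec$label, x$variable_set, x$mean_accuracy, x$sd_accuracy,
              nrow(x$results)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gait_experiment <- function(x, ...) x$results

#' @exportS3Method generics::glance
glance.gait_experiment <- function(x, ...) {
  tibble::tibble(model = x$spec$label, variable_set = x$variable_set,
                 mean_accuracy = x$mean_accuracy,
                 sd_accuracy = x$sd_accuracy, k = nrow(x$results))
}
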