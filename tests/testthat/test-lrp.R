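linear_model <- function(W, b, classes = NULL) {
  spec <- model_spec("linear_sgd", n_classes = ncol(W), n_channels = 1,
                     n_time = nrow(W))
  gaitlrp:::new_network_model(
    list(gaitlrp:::new_affine_layer(W, b), gaitlrp:::new_softmax_layer()),
    spec, classes = classes)
}

test_that("output-layer relevance initializes to f_c at the explained class", {
  W <- diag(3)  # scores equal the input
  m <- linear_model(W, rep(0, 3))
  x <- c(2, -1, 0.5)
  m1 <- lrp_explain(m, x, class_c = 1, epsilon = 0)
  expect_equal(m1$f_c, 2)
  m3 <- lrp_explain(m, x, class_c = 3, epsilon = 0)
  expect_equal(m3$f_c, 0.5)
  expect_error(lrp_explain(m, x, class_c = 7), "class")
})

test_that("a single affine layer collapses to componentwise x * w plus bias relevance", {
  # closed form: x = (1, 2), w = (0.5, -1), b = 0.25
  W <- matrix(c(0.5, -1), 2, 1)
  m <- linear_model(cbind(W, 0), c(0.25, 0))
  map <- lrp_explain(m, c(1, 2), class_c = 1, epsilon = 0)
  expect_equal(as.vector(map$relevance), c(0.5, -2))
  expect_equal(map$bias_relevance, 0.25)
  expect_equal(sum(map$relevance) + map$bias_relevance, map$f_c)
  expect_equal(map$f_c, -1.25)

  # zero input: everything lands on the bias
  map0 <- lrp_explain(m, c(0, 0), class_c = 1, epsilon = 0)
  expect_equal(as.vector(map0$relevance), c(0, 0))
  expect_equal(map0$bias_relevance, map0$f_c)

  # general multi-class collapse: R_i = x_i w_ic, exactly
  set.seed(3)
  Wm <- matrix(rnorm(606 * 5), 606, 5)
  bm <- rnorm(5)
  spec <- model_spec("linear_sgd", 5, 6, 101)
  mm <- gaitlrp:::new_network_model(
    list(gaitlrp:::new_affine_layer(Wm, bm), gaitlrp:::new_softmax_layer()),
    spec)
  x <- rnorm(606)
  for (cc in c(1, 4)) {
    map <- lrp_explain(mm, x, class_c = cc, epsilon = 0)
    expect_identical(as.vector(t(map$relevance)), x * Wm[, cc])
    expect_identical(map$bias_relevance, bm[cc])
  }
})

test_that("affine propagation conserves relevance including the bias neuron", {
  set.seed(11)
  layer <- gaitlrp:::new_affine_layer(matrix(rnorm(15), 5, 3), rnorm(3))
  x <- rnorm(5)
  R_out <- rnorm(3)
  pr <- gaitlrp:::propagate_affine(layer, x, R_out, epsilon = 0)
  expect_equal(sum(pr$R_in) + pr$R_bias, sum(R_out), tolerance = 1e-9)
  # epsilon = 0 with a vanishing denominator fails loudly
  z0 <- gaitlrp:::new_affine_layer(matrix(0, 2, 1), 0)
  expect_error(gaitlrp:::propagate_affine(z0, c(1, 1), 1, epsilon = 0),
               class = "gaitlrp_degenerate_denominator")
  # with a stabilizer the same case is finite
  pr0 <- gaitlrp:::propagate_affine(z0, c(1, 1), 1, epsilon = 1e-9)
  expect_true(all(is.finite(pr0$R_in)))
})

test_that("elementwise nonlinearities pass relevance through unchanged", {
  # with all hidden pre-activations positive, a ReLU is the identity in the
  # forward pass; its relevance rule must then leave the explanation of the
  # ReLU and no-ReLU networks identical
  set.seed(13)
  W1 <- matrix(abs(rnorm(8 * 4)), 8, 4)
  b1 <- rep(1, 4)
  W2 <- matrix(rnorm(4 * 3), 4, 3)
  b2 <- rnorm(3)
  spec <- model_spec("mlp", n_classes = 3, n_channels = 1, n_time = 8,
                     n_layers = 2, width = 64)
  with_relu <- gaitlrp:::new_network_model(
    list(gaitlrp:::new_affine_layer(W1, b1), gaitlrp:::new_relu_layer(),
         gaitlrp:::new_affine_layer(W2, b2), gaitlrp:::new_softmax_layer()),
    spec)
  without_relu <- gaitlrp:::new_network_model(
    list(gaitlrp:::new_affine_layer(W1, b1),
         gaitlrp:::new_affine_layer(W2, b2), gaitlrp:::new_softmax_layer()),
    spec)
  x <- abs(rnorm(8))
  r1 <- lrp_explain(with_relu, x, class_c = 2, epsilon = 0)
  r2 <- lrp_explain(without_relu, x, class_c = 2, epsilon = 0)
  expect_equal(r1$relevance, r2$relevance)
  expect_equal(r1$bias_relevance, r2$bias_relevance)
  expect_lt(conservation_error(r1), 1e-10)
})

test_that("conv propagation equals affine propagation on the unrolled form", {
  set.seed(21)
  for (i in 1:20) {
    h <- sample(2:5, 1); w <- sample(6:12, 1); d <- sample(1:3, 1)
    fh <- sample(seq_len(h), 1); fw <- 3
    maps <- sample(2:4, 1)
    sw <- sample(1:2, 1)
    layer <- random_conv_layer(h, w, d, fh, fw, maps, stride = c(1L, sw))
    a <- array(rnorm(h * w * d), dim = c(h, w, d))
    R_out <- array(rnorm(prod(layer$out_shape)), dim = layer$out_shape)
    pr_conv <- gaitlrp:::propagate_conv(layer, a, R_out, epsilon = 1e-9)
    dense <- unroll_conv(layer)
    dl <- gaitlrp:::new_affine_layer(dense$W, dense$b)
    pr_aff <- gaitlrp:::propagate_affine(dl, pad_grid_flat(layer, a),
                                         as.vector(R_out), epsilon = 1e-9)
    R_aff <- array(pr_aff$R_in,
                   dim = c(h, w + 2L * layer$pad_w, d))
    R_aff <- R_aff[, layer$pad_w + seq_len(w), , drop = FALSE]
    expect_equal(as.vector(pr_conv$R_in), as.vector(R_aff),
                 tolerance = 1e-9)
    expect_equal(pr_conv$R_bias, pr_aff$R_bias, tolerance = 1e-9)
  }
})

test_that("relevance conservation holds through deep and convolutional models", {
  set.seed(5)
  specs <- list(
    model_spec("mlp", 8, 6, n_layers = 3, width = 64),
    model_spec("mlp", 8, 6, n_layers = 3, width = 256),
    model_spec("cnn", 8, 6, preset = "cnn_a"),
    model_spec("cnn", 8, 6, preset = "cnn_c3")
  )
  for (spec in specs) {
    m <- build_model(spec, 17)
    for (rep in 1:3) {
      x <- rnorm(606)
      cc <- sample(8, 1)
      map <- lrp_explain(m, x, class_c = cc, epsilon = 1e-9)
      expect_lt(conservation_error(map), 1e-6)
      map0 <- lrp_explain(m, x, class_c = cc, epsilon = 0)
      expect_lt(conservation_error(map0), 1e-10)
    }
  }
})

test_that("explanations run on pre-softmax scores: shifting all scores preserves sign structure", {
  set.seed(9)
  W <- matrix(rnorm(20), 10, 2)
  b <- rnorm(2)
  x <- rnorm(10)
  m1 <- linear_model(W, b)
  m2 <- linear_model(W, b + 5)  # same decision, shifted scores
  r1 <- lrp_explain(m1, x, class_c = 1, epsilon = 0)
  r2 <- lrp_explain(m2, x, class_c = 1, epsilon = 0)
  # input relevances are identical (the shift lands on the bias neuron)
  expect_equal(r1$relevance, r2$relevance)
  expect_equal(r2$bias_relevance - r1$bias_relevance, 5)
})

test_that("gait samples are explained for their true class by default", {
  smp <- small_samples()
  m <- train_linear_svm(smp)
  map <- lrp_explain(m, smp, index = 5)
  expect_equal(map$class_c, as.character(smp$subject_id[5]))
  expect_equal(dim(map$relevance), c(6L, 101L))
  expect_equal(rownames(map$relevance), smp$channels$channel)
  expect_lt(conservation_error(map), 1e-6)
  df <- tidy(map)
  expect_equal(nrow(df), 606)
  rel <- explain_samples(m, smp)
  expect_equal(dim(rel), dim(smp$x))
  expect_equal(rel[5, ], as.vector(t(map$relevance)))
})
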