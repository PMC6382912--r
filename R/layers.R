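# Layer primitives.  Every model is an explicit ordered layer sequence
# (affine / convolution / ReLU / flatten / softmax) so that the relevance
# backward pass can address each layer's contributions z_ij directly.

new_affine_layer <- function(W, b) {
  stopifnot(is.matrix(W), length(b) == ncol(W))
  list(type = "affine", W = W, b = as.numeric(b))
}

new_relu_layer <- function() list(type = "relu")

new_flatten_layer <- function(in_shape) {
  list(type = "flatten", in_shape = in_shape)
}

new_softmax_layer <- function() list(type = "softmax")

# Convolution over (channel, time) grids with full-depth filters, zero
# padding along time only (channel alignment is preserved so relevance maps
# stay on the 101-point grid).  The im2col index matrix is precomputed:
# column p holds the flat indices (into the time-padded input array) of the
# patch feeding output position p.
new_conv_layer <- function(W, b, in_shape, stride = c(1L, 1L), pad_w = 1L) {
  stopifnot(length(dim(W)) == 4)
  fh <- dim(W)[1]; fw <- dim(W)[2]; d_in <- dim(W)[3]; maps <- dim(W)[4]
  h <- in_shape[1]; w <- in_shape[2]
  stopifnot(d_in == in_shape[3], fh <= h, length(b) == maps)
  wp <- w + 2L * pad_w
  oh <- (h - fh) %/% stride[1] + 1L
  ow <- (wp - fw) %/% stride[2] + 1L
  # flat offsets of one patch within the padded (h, wp, d) array
  patch_off <- as.vector(outer(
    outer(seq_len(fh) - 1L, (seq_len(fw) - 1L) * h, "+"),
    (seq_len(d_in) - 1L) * h * wp, "+"))
  base <- as.vector(outer((seq_len(oh) - 1L) * stride[1],
                          (seq_len(ow) - 1L) * stride[2] * h, "+")) + 1L
  idx <- outer(patch_off, base, "+")  # patch_len x n_pos
  list(type = "conv", W = W, b = as.numeric(b),
       Wf = matrix(W, ncol = maps),
       in_shape = as.integer(in_shape), stride = as.integer(stride),
       pad_w = as.integer(pad_w), idx = idx,
       out_shape = c(oh, ow, maps))
}

pad_time <- function(a, pad_w) {
  if (pad_w == 0L) return(a)
  d <- dim(a)
  out <- array(0, dim = c(d[1], d[2] + 2L * pad_w, d[3]))
  out[, pad_w + seq_len(d[2]), ] <- a
  out
}

conv_patches <- function(layer, a) {
  ap <- pad_time(a, layer$pad_w)
  matrix(ap[layer$idx], nrow = nrow(layer$idx))
}

flat_to_grid <- function(x, n_channels, n_time) {
  # flat input is row-concatenated channel-by-time; grid is (h = channel,
  # w = time, d = 1)
  array(t(matrix(x, nrow = n_time)), dim = c(n_channels, n_time, 1L))
}

softmax_rows <- function(s) {
  if (is.null(dim(s))) s <- matrix(s, nrow = 1)
  e <- exp(s - apply(s, 1, max))
  e / rowSums(e)
}

# ---- single-sample forward (with caches, used by training on conv models
# ---- and by LRP on everything)

layer_forward <- function(layer, a) {
  switch(layer$type,
    affine = as.vector(crossprod(layer$W, a)) + layer$b,
    relu = { a[a < 0] <- 0; a },
    flatten = as.vector(a),
    conv = {
      P <- conv_patches(layer, a)
      Z <- crossprod(P, layer$Wf)
      Z <- sweep(Z, 2, layer$b, "+")
      array(Z, dim = layer$out_shape)
    },
    softmax = as.vector(softmax_rows(a)),
    abort(sprintf("unknown layer type '%s'", layer$type))
  )
}

# ---- single-sample backward for gradients (cross-entropy training)

layer_backward <- function(layer, a_in, grad_out) {
  switch(layer$type,
    affine = list(
      grad_in = as.vector(layer$W %*% grad_out),
      dW = outer(a_in, grad_out),
      db = grad_out),
    relu = list(grad_in = grad_out * (a_in > 0)),
    flatten = list(grad_in = array(grad_out, dim = dim(a_in))),
    conv = {
      P <- conv_patches(layer, a_in)
      dZ <- matrix(grad_out, ncol = layer$out_shape[3])
      dW <- array(P %*% dZ, dim = dim(layer$W))
      db <- colSums(dZ)
      dP <- layer$Wf %*% t(dZ)
      d <- dim(a_in)
      wp <- d[2] + 2L * layer$pad_w
      dxp <- numeric(d[1] * wp * d[3])
      acc <- rowsum(as.vector(dP), group = as.vector(layer$idx))
      dxp[as.integer(rownames(acc))] <- acc
      dxp <- array(dxp, dim = c(d[1], wp, d[3]))
      grad_in <- dxp[, layer$pad_w + seq_len(d[2]), , drop = FALSE]
      list(grad_in = array(grad_in, dim = d), dW = dW, db = db)
    },
    abort(sprintf("no backward for layer type '%s'", layer$type))
  )
}
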