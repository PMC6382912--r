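# Independent oracles used by the relevance-propagation tests.

# Unroll a convolution layer into its dense affine form over the
# time-padded input: column (m - 1) * n_pos + p of the dense weight matrix
# holds filter m's weights scattered to the input positions feeding output
# position p.  Built by direct index arithmetic, independent of the conv
# forward/backward implementation it checks.
unroll_conv <- function(layer) {
  n_pos <- ncol(layer$idx)
  maps <- dim(layer$W)[4]
  wp <- layer$in_shape[2] + 2L * layer$pad_w
  in_len <- layer$in_shape[1] * wp * layer$in_shape[3]
  Wf <- matrix(layer$W, ncol = maps)
  Wd <- matrix(0, in_len, n_pos * maps)
  for (m in seq_len(maps)) {
    for (p in seq_len(n_pos)) {
      Wd[layer$idx[, p], (m - 1L) * n_pos + p] <- Wf[, m]
    }
  }
  list(W = Wd, b = rep(layer$b, each = n_pos))
}

pad_grid_flat <- function(layer, a) {
  as.vector(gaitlrp:::pad_time(a, layer$pad_w))
}

random_conv_layer <- function(h, w, d, fh, fw, maps, stride = c(1L, 1L),
                              pad_w = 1L) {
  W <- array(rnorm(fh * fw * d * maps), dim = c(fh, fw, d, maps))
  gaitlrp:::new_conv_layer(W, rnorm(maps), in_shape = c(h, w, d),
                           stride = stride, pad_w = pad_w)
}

# squared second-order Butterworth amplitude response (bidirectional pass)
butter2_bidir_gain <- function(f, cutoff) {
  1 / (1 + (f / cutoff)^4)
}
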