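# Internal helpers shared across modules.

#' @importFrom rlang abort warn %||%
#' @importFrom stats rnorm runif sd approx predict
NULL

# Derive a reproducible child seed from a root seed and integer ids.
# Generation order must not matter, so every subject/trial gets its own
# stream keyed by (seed, ids) rather than consuming a global stream.
child_seed <- function(seed, ...) {
  ids <- c(...)
  h <- as.double(seed %% 2147483647L)
  for (id in ids) {
    h <- (h * 48271 + as.double(id) * 16807 + 11) %% 2147483647
  }
  as.integer(h %% 2147483647) + 1L
}

with_child_seed <- function(seed, ..., expr) {
  withr::with_seed(child_seed(seed, ...), expr)
}

# Population (divide-by-N) standard deviation, the convention used by the
# z-transform and all reported spreads in this package.
sd_pop <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

# cos^2 bump with compact support: smooth, zero (with zero slope) outside
# |u - center| >= halfwidth.  The building block of all synthetic waveforms.
cos2_bump <- function(u, center, halfwidth) {
  d <- (u - center) / halfwidth
  out <- numeric(length(u))
  inside <- is.finite(d) & abs(d) < 1
  out[inside] <- cos(pi * d[inside] / 2)^2
  out
}
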