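#' Dilated convolution of a signal
#'
#' Centered cross-correlation with zero padding, with the kernel taps spaced
#' `d` samples apart: `out[i] = sum_n in[i + d*n] * k[n]`, `n` running over
#' centered kernel offsets. With `d = 1` this is ordinary (same-size)
#' convolution as deep-learning frameworks define it; larger `d` enlarges
#' the field of view without extra parameters. Equivalent to ordinary
#' convolution with the kernel zero-inflated by a factor `d`.
#'
#' @param signal Numeric vector or matrix.
#' @param kernel Numeric vector (for 1-D signals) or matrix with odd
#'   dimensions, not larger than the signal.
#' @param d Dilation rate (integer >= 1).
#' @return Grid of the same shape as `signal`.
#' @examples
#' apply_dilated_conv(c(0, 0, 1, 0, 0), c(1, 1, 1), d = 2)  # 1 0 1 0 1
#' @export
apply_dilated_conv <- function(signal, kernel, d = 1L) {
  d <- as.integer(d)
  if (d < 1L) abort("`d` must be >= 1")
  if (length(kernel) == 0L) abort("`kernel` must be non-empty")
  one_d <- is.null(dim(signal))
  x <- if (one_d) matrix(signal, ncol = 1) else as.matrix(signal)
  k <- if (is.null(dim(kernel))) matrix(kernel, ncol = 1) else as.matrix(kernel)
  if (one_d && !is.null(dim(kernel)) && ncol(kernel) > 1L)
    abort("1-D signal needs a 1-D kernel")
  if (nrow(k) %% 2L == 0L || ncol(k) %% 2L == 0L)
    abort("kernel dimensions must be odd (centered indexing)")
  if (nrow(k) > nrow(x) || ncol(k) > ncol(x))
    abort("kernel must not be larger than the signal")
  xc <- array(x, dim = c(nrow(x), ncol(x), 1))
  w <- matrix(as.vector(k), ncol = 1)      # row index i + kh*j, one channel
  out <- conv2d_fw(xc, w, 0, nrow(k), ncol(k), d)[, , 1]
  if (one_d) as.vector(out) else out
}

relu <- function(x) { x[x < 0] <- 0; x }
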