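#' Reference implementations of segmentation-network layer operations
#'
#' Pure-function, CPU reference versions of the layer primitives used by
#' segmentation/classification networks for particle picking: valid
#' multi-channel 2D convolution, ReLU, cross-channel local response
#' normalization, max pooling, and atrous (dilated) convolution together
#' with its receptive-field arithmetic. They exist to pin down the exact
#' arithmetic of each operation; there is no training and no learned
#' weights.
#'
#' Multi-channel inputs are 3D arrays indexed `[channel, row, col]`
#' (M x H x W); kernels are `[channel, k, l]` (M x K x K).
#'
#' @name netmath
NULL

#' Valid multi-channel 2D convolution
#'
#' Computes `Y[i, j] = sum_m sum_k sum_l W[m, k, l] * X[m, i + k - 1, j + l - 1]`
#' over the valid region only (no padding), collapsing channels; the output
#' is a `(H - K + 1) x (W - K + 1)` matrix.
#'
#' @param X 3D numeric array, `M x H x W`.
#' @param W 3D numeric array, `M x K x K`.
#' @return Numeric matrix.
#' @export
conv2d <- function(X, W) {
  X <- as_tensor3(X, "X")
  W <- as_tensor3(W, "W")
  dX <- dim(X); dW <- dim(W)
  if (dX[1] != dW[1]) abort_shape("channel counts of X and W differ")
  if (dW[2] != dW[3]) abort_shape("kernel must be square (M x K x K)")
  K <- dW[2]
  ho <- dX[2] - K + 1L; wo <- dX[3] - K + 1L
  if (ho < 1L || wo < 1L) abort_shape("input smaller than kernel")
  Y <- matrix(0, ho, wo)
  for (m in seq_len(dX[1])) {
    for (k in seq_len(K)) {
      for (l in seq_len(K)) {
        Y <- Y + W[m, k, l] * X[m, k:(k + ho - 1L), l:(l + wo - 1L)]
      }
    }
  }
  Y
}

#' Rectified linear unit
#'
#' Elementwise `max(0, x)`: negative inputs map to 0, positive inputs pass
#' through unchanged.
#'
#' @param X Numeric vector, matrix or array.
#' @return Object of the same shape.
#' @export
relu <- function(X) {
  check_finite(X, "relu input")
  pmax(X, 0)
}

#' Cross-channel local response normalization
#'
#' Divides each value of channel `i` by `(1 + a * sum(X_j^2))^b`, the sum
#' running over the channel window `i - I/2 ... i + I/2` (clipped at the
#' channel boundaries). Defaults follow common practice: scaling parameter
#' `a = 1e-4`, exponent `b = 0.75`.
#'
#' @param X 3D numeric array, `M x H x W`.
#' @param a Scaling parameter (>= 0).
#' @param b Exponent parameter (> 0).
#' @param I Channel window size (even, >= 0); the window spans `I/2`
#'   channels to each side.
#' @return Array of the same shape as `X`.
#' @export
local_response_norm <- function(X, a = 1e-4, b = 0.75, I = 2) {
  X <- as_tensor3(X, "X")
  if (a < 0) abort_validation("`a` must be >= 0")
  if (b <= 0) abort_validation("`b` must be > 0")
  if (I < 0 || I %% 2 != 0) abort_validation("`I` must be even and >= 0")
  M <- dim(X)[1]
  sq <- X^2
  out <- X
  half <- I %/% 2
  for (i in seq_len(M)) {
    win <- max(1L, i - half):min(M, i + half)
    ssum <- apply(sq[win, , , drop = FALSE], c(2, 3), sum)
    out[i, , ] <- X[i, , ] / (1 + a * ssum)^b
  }
  out
}

#' Max pooling
#'
#' Downsamples a matrix by taking the maximum over `L x L` windows placed at
#' the given stride; partial windows at the bottom/right edges are included.
#'
#' @param X Numeric matrix.
#' @param L Pooling window side (>= 1).
#' @param stride Step between window origins (>= 1; defaults to `L`).
#' @return Numeric matrix of `ceiling(H / stride) x ceiling(W / stride)`.
#' @export
max_pool <- function(X, L, stride = L) {
  if (!is.matrix(X)) abort_shape("X must be a matrix")
  if (L < 1 || stride < 1) abort_validation("L and stride must be >= 1")
  if (L > nrow(X) || L > ncol(X)) abort_shape("pooling window exceeds raster")
  ys <- seq(1L, nrow(X), by = stride)
  xs <- seq(1L, ncol(X), by = stride)
  out <- matrix(0, length(ys), length(xs))
  for (a in seq_along(ys)) {
    rows <- ys[a]:min(ys[a] + L - 1L, nrow(X))
    for (b in seq_along(xs)) {
      cols <- xs[b]:min(xs[b] + L - 1L, ncol(X))
      out[a, b] <- max(X[rows, cols])
    }
  }
  out
}

#' Atrous (dilated) valid convolution
#'
#' Convolution whose kernel taps are spaced `rate` pixels apart ("holes"),
#' enlarging the field of view without additional parameters. With
#' `rate = 1` this is exactly [conv2d()]. The effective footprint side is
#' `K + (K - 1) * (rate - 1)` and the output covers the valid region only.
#'
#' @param X 3D numeric array, `M x H x W`.
#' @param W 3D numeric array, `M x K x K`.
#' @param rate Integer atrous rate `s >= 1`.
#' @return Numeric matrix.
#' @export
atrous_conv2d <- function(X, W, rate = 1) {
  X <- as_tensor3(X, "X")
  W <- as_tensor3(W, "W")
  if (rate < 1 || rate != round(rate)) abort_validation("rate must be an integer >= 1")
  dX <- dim(X); dW <- dim(W)
  if (dX[1] != dW[1]) abort_shape("channel counts of X and W differ")
  if (dW[2] != dW[3]) abort_shape("kernel must be square (M x K x K)")
  K <- dW[2]
  eff <- effective_field_of_view(K, rate)
  ho <- dX[2] - eff + 1L; wo <- dX[3] - eff + 1L
  if (ho < 1L || wo < 1L) abort_shape("atrous footprint exceeds input")
  Y <- matrix(0, ho, wo)
  for (m in seq_len(dX[1])) {
    for (k in seq_len(K)) {
      ro <- (k - 1L) * rate + 1L
      for (l in seq_len(K)) {
        co <- (l - 1L) * rate + 1L
        Y <- Y + W[m, k, l] * X[m, ro:(ro + ho - 1L), co:(co + wo - 1L)]
      }
    }
  }
  Y
}

#' Effective field of view of an atrous kernel
#'
#' Side length, in pixels, of the receptive field of a `K x K` kernel with
#' atrous rate `rate`: `K + (K - 1) * (rate - 1)`. A 3x3 kernel at rate 2
#' sees the same 5x5 field as a dense 5x5 kernel.
#'
#' @param K Kernel side (>= 1).
#' @param rate Atrous rate (>= 1).
#' @return Integer side length in pixels.
#' @export
effective_field_of_view <- function(K, rate) {
  if (K < 1 || rate < 1) abort_validation("K and rate must be >= 1")
  as.integer(K + (K - 1) * (rate - 1))
}

#' Number of free parameters of a (possibly atrous) kernel
#'
#' Always `K^2` per channel regardless of the atrous rate: the inserted
#' holes are structural zeros, not parameters.
#'
#' @param K Kernel side (>= 1).
#' @return Integer count.
#' @export
kernel_parameter_count <- function(K) {
  if (K < 1) abort_validation("K must be >= 1")
  as.integer(K^2)
}

#' Zero-insert a kernel to its atrous footprint
#'
#' Expands an `M x K x K` kernel to the dense
#' `M x eff x eff` kernel (eff = [effective_field_of_view()]) whose taps at
#' spacing `rate` carry the original weights and whose remaining entries are
#' zero. `atrous_conv2d(X, W, rate)` equals `conv2d(X, zero_insert_kernel(W,
#' rate))` — useful as a constructive cross-check.
#'
#' @param W 3D numeric array, `M x K x K`.
#' @param rate Atrous rate (>= 1).
#' @return 3D array `M x eff x eff`.
#' @export
zero_insert_kernel <- function(W, rate) {
  W <- as_tensor3(W, "W")
  K <- dim(W)[2]
  eff <- effective_field_of_view(K, rate)
  out <- array(0, c(dim(W)[1], eff, eff))
  taps <- (seq_len(K) - 1L) * rate + 1L
  out[, taps, taps] <- W
  out
}

as_tensor3 <- function(X, what) {
  if (is.matrix(X)) X <- array(X, c(1L, dim(X)))
  if (!is.array(X) || length(dim(X)) != 3L) {
    abort_shape(sprintf("`%s` must be a 3D array (channels x H x W)", what))
  }
  check_finite(X, what)
  X
}
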