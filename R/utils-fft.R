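# FFT bookkeeping shared by the simulator and the analyzers.
# Frequencies are in cycles per micron; index k of an n-point axis of
# physical length L maps to q = k'/L with k' = k for k <= n/2 and
# k' = k - n otherwise (standard DFT ordering).

.fft_freq <- function(n, L) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k / L
}

# 1-based array index of harmonic k (may be negative) on an n-point axis
.harmonic_index <- function(k, n) {
  (k %% n) + 1L
}

# 3D array of decay rates 4*pi^2 * q^t D q over the full DFT grid
.rate_array <- function(tensor, dims, fov_um) {
  qx <- .fft_freq(dims[1], fov_um[1])
  qy <- .fft_freq(dims[2], fov_um[2])
  qz <- .fft_freq(dims[3], fov_um[3])
  qx2 <- array(qx^2, dims)
  qy2 <- array(rep(qy^2, each = dims[1]), dims)
  qz2 <- array(rep(qz^2, each = dims[1] * dims[2]), dims)
  qxy <- array(outer(qx, qy), dims)
  qxz <- array(qx, dims) * array(rep(qz, each = dims[1] * dims[2]), dims)
  qyz <- array(rep(qy, each = dims[1]), dims) *
    array(rep(qz, each = dims[1] * dims[2]), dims)
  4 * pi^2 * (tensor$dxx * qx2 + tensor$dyy * qy2 + tensor$dzz * qz2 +
              2 * tensor$dxy * qxy + 2 * tensor$dxz * qxz +
              2 * tensor$dyz * qyz)
}

# |q|^2 over the DFT grid (for noise-floor masks)
.qsq_array <- function(dims, fov_um) {
  qx <- .fft_freq(dims[1], fov_um[1])
  qy <- .fft_freq(dims[2], fov_um[2])
  qz <- .fft_freq(dims[3], fov_um[3])
  array(qx^2, dims) +
    array(rep(qy^2, each = dims[1]), dims) +
    array(rep(qz^2, each = dims[1] * dims[2]), dims)
}

#' Analytic decay rate of a spatial-frequency mode
#'
#' Under free anisotropic diffusion, the Fourier mode at spatial frequency
#' `q = (u, v, w)` (cycles/um) decays as `exp(-k t)` with
#' `k = 4 pi^2 q^T D q`.
#'
#' @param q Length-3 frequency vector, cycles/um (length-2 for a 2D tensor).
#' @param tensor A `diffusion_tensor` or `diffusion_tensor_2d`.
#' @return Decay rate k, 1/s.
#' @examples
#' decay_rate(c(0.1, 0, 0), diffusion_tensor(10, 5, 2))
#' @export
decay_rate <- function(q, tensor) {
  m <- as.matrix(tensor)
  stopifnot(length(q) == nrow(m))
  4 * pi^2 * drop(t(q) %*% m %*% q)
}

# shift an array along one axis by +1 (towards higher index) or -1,
# with "mirror" (zero-gradient ghost) or "wrap" (periodic) boundaries.
# shift = +1 returns a with a[i] := a[i+1].
.shift3 <- function(a, axis, shift, boundary = c("mirror", "wrap")) {
  boundary <- match.arg(boundary)
  n <- dim(a)[axis]
  idx <- seq_len(n) + shift
  if (boundary == "wrap") {
    idx <- ((idx - 1L) %% n) + 1L
  } else {
    idx[idx < 1L] <- 1L
    idx[idx > n] <- n
  }
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}
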