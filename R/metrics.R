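#' Stokes-Einstein diffusivity prediction
#'
#' `D = kB T / (6 pi eta r)` for a sphere of hydrodynamic radius `r` in a
#' solution of viscosity `eta` at absolute temperature `T`, converted to
#' um^2/s. The Boltzmann constant is fixed at its exact 2019 SI value.
#'
#' @param temperature_K Absolute temperature, K.
#' @param viscosity_Pa_s Dynamic viscosity, Pa s.
#' @param hydrodynamic_radius_m Hydrodynamic radius, m.
#' @return Diffusivity, um^2/s.
#' @examples
#' stokes_einstein(293.15, 1e-3, 1e-9)   # ~214.7 um^2/s
#' @export
stokes_einstein <- function(temperature_K, viscosity_Pa_s,
                            hydrodynamic_radius_m) {
  .check_scalar_pos(temperature_K, "temperature_K")
  .check_scalar_pos(viscosity_Pa_s, "viscosity_Pa_s")
  .check_scalar_pos(hydrodynamic_radius_m, "hydrodynamic_radius_m")
  d_m2s <- .kB * temperature_K /
    (6 * pi * viscosity_Pa_s * hydrodynamic_radius_m)
  d_m2s * 1e12
}

# separable Gaussian blur with replicated edges
.gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_idx <- function(n) pmin(pmax(seq(1 - r, n + r), 1L), n)
  blur1 <- function(mat) {   # along rows (dim 1)
    n <- nrow(mat)
    padded <- mat[pad_idx(n), , drop = FALSE]
    out <- matrix(0, n, ncol(mat))
    for (j in seq_along(k)) {
      out <- out + k[j] * padded[j:(j + n - 1L), , drop = FALSE]
    }
    out
  }
  t(blur1(t(blur1(m))))
}

#' Structure-tensor coherency of an image
#'
#' Quantifies how aligned the local image gradients (e.g. fiber edges)
#' are: the Gaussian-windowed structure tensor of the gradients is
#' evaluated per pixel, and the coherency
#' `(lambda_max - lambda_min) / (lambda_max + lambda_min)` is averaged
#' over the image. 0 means no predominant orientation (fibers randomly
#' distributed); 1 means perfectly parallel structure. Invariant to
#' affine intensity rescaling.
#'
#' @param image 2D numeric matrix, at least 16 x 16 pixels.
#' @param window_sigma_px Gaussian window scale, pixels (default 6: a wide
#'   window keeps the orientation statistic stable on weakly structured
#'   images).
#' @return Mean coherency in \[0, 1\].
#' @export
structure_coherency <- function(image, window_sigma_px = 6) {
  if (!is.matrix(image) || nrow(image) < 16L || ncol(image) < 16L) {
    .stop_validation("image must be a matrix of at least 16 x 16 pixels")
  }
  .check_finite(image, "image")
  if (sd(image) == 0) {
    .stop_validation("constant image has no defined orientation",
                     class = "liftfrap_undefined_input")
  }
  n <- nrow(image); m <- ncol(image)
  gx <- (image[c(2:n, n), ] - image[c(1, 1:(n - 1)), ]) / 2
  gy <- (image[, c(2:m, m)] - image[, c(1, 1:(m - 1))]) / 2
  jxx <- .gauss_blur(gx * gx, window_sigma_px)
  jyy <- .gauss_blur(gy * gy, window_sigma_px)
  jxy <- .gauss_blur(gx * gy, window_sigma_px)
  tr <- jxx + jyy
  valid <- tr > 1e-12 * max(tr)
  coh <- sqrt((jxx - jyy)^2 + 4 * jxy^2)[valid] / tr[valid]
  mean(pmin(coh, 1))
}

#' Tissue water content
#'
#' `(w_wet - w_dry) / w_wet * 100`, percent.
#'
#' @param w_wet Wet weight (> 0, any unit).
#' @param w_dry Dry weight, same unit, with `0 < w_dry <= w_wet`.
#' @return Water content, percent in \[0, 100).
#' @examples
#' water_content(100, 40)   # 60
#' @export
water_content <- function(w_wet, w_dry) {
  .check_scalar_pos(w_wet, "w_wet")
  .check_scalar_pos(w_dry, "w_dry")
  if (w_dry > w_wet) .stop_validation("w_dry must not exceed w_wet")
  (w_wet - w_dry) / w_wet * 100
}
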