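#' 2D spatial-Fourier FRAP analysis of a single-plane image series
#'
#' Classical invasive 2D pipeline: the averaged prebleach image is
#' SUBTRACTED from each postbleach frame (unlike the 3D pipeline, which
#' divides — the two normalizations are preserved as the respective
#' methods define them), the difference images are transformed with a 2D
#' spatial Fourier transform, per-mode phase-projected coefficients are
#' fitted as `A exp(-k t)`, and the in-plane tensor follows from weighted linear
#' least squares on `k(q) = 4 pi^2 (dxx u^2 + 2 dxy uv + dyy v^2)`.
#'
#' @param series An [image_series_2d()] with >= 1 prebleach and >= 4
#'   postbleach frames.
#' @param n_harm Maximum harmonic index per axis.
#' @param q_max Frequency cutoff, cycles/um; default `0.6 / bleach side`
#'   when known from metadata, else derived from the conventional bleach
#'   square (side 1/8 of the image).
#' @param noise_floor_mult Noise-floor multiplier, as in the 3D pipeline.
#' @return A `frap2d_fit`: `tensor` (`diffusion_tensor_2d`), `lambda`
#'   (principal diffusivities, ascending), `fa` (via [fa_from_2d()]),
#'   per-mode tibble.
#' @export
analyze_frap2d <- function(series, n_harm = 4, q_max = NULL,
                           noise_floor_mult = 5) {
  stopifnot(inherits(series, "image_series_2d"))
  d <- dim(series$data)
  if (series$n_prebleach < 1L) {
    .stop_validation("need at least one prebleach frame")
  }
  nt_post <- d[3] - series$n_prebleach
  if (nt_post < 4L) .stop_validation("need >= 4 postbleach frames")
  L <- d[1:2] * series$pixel_um
  if (is.null(q_max)) {
    ext <- series$metadata$bleach_extent_um
    q_max <- if (!is.null(ext)) 0.6 / max(ext) else 0.6 / (max(L) / 8)
  }

  pre <- array(0, d[1:2])
  for (i in seq_len(series$n_prebleach)) pre <- pre + series$data[, , i]
  pre <- pre / series$n_prebleach

  harm <- seq_len(n_harm)
  pairs <- tidyr::expand_grid(n = harm, m = harm)
  modes <- dplyr::bind_rows(
    tibble::tibble(kx = harm, ky = 0L, direction = "x"),
    tibble::tibble(kx = 0L, ky = harm, direction = "y"),
    tibble::tibble(kx = pairs$n, ky = pairs$m, direction = "xy"))
  modes <- dplyr::mutate(modes, u = .data$kx / L[1], v = .data$ky / L[2],
                         q_mag = sqrt(.data$u^2 + .data$v^2))
  modes <- dplyr::filter(modes, .data$q_mag > 0, .data$q_mag <= q_max)
  X2 <- 4 * pi^2 * cbind(dxx = modes$u^2, dyy = modes$v^2,
                         dxy = 2 * modes$u * modes$v)
  if (nrow(modes) < 3L || qr(X2)$rank < 3L) {
    .stop_validation("fewer than 3 independent quadratic directions in band")
  }

  ii <- cbind(.harmonic_index(modes$kx, d[1]), .harmonic_index(modes$ky, d[2]))
  lin <- ii[, 1] + d[1] * (ii[, 2] - 1L)
  qx <- .fft_freq(d[1], L[1]); qy <- .fft_freq(d[2], L[2])
  hi_mask <- outer(qx^2, qy^2, "+") > (2 * q_max)^2
  coef_mat <- matrix(0i, nrow(modes), nt_post)
  noise_rms <- NA_real_
  for (j in seq_len(nt_post)) {
    fh <- fft(series$data[, , series$n_prebleach + j] - pre)
    coef_mat[, j] <- fh[lin]
    if (j == 1L) noise_rms <- sqrt(mean(Mod(fh[hi_mask])^2))
  }
  c0 <- Mod(coef_mat[, 1])
  floor_abs <- noise_floor_mult * noise_rms
  modes$c0 <- c0
  modes$floor_rel <- ifelse(c0 > 0, floor_abs / c0, Inf)
  modes$used <- c0 > floor_abs & c0 > 0
  time_s <- (seq_len(nt_post) - 1) * series$frame_interval_s
  fits <- purrr::map(seq_len(nrow(modes)), function(i) {
    if (!modes$used[i]) {
      return(list(k = NA_real_, k_se = NA_real_, r2 = NA_real_,
                  n_pts = 0L, converged = FALSE))
    }
    fit_mode_decay(Re(coef_mat[i, ] * Conj(coef_mat[i, 1])) / c0[i]^2,
                   time_s, modes$floor_rel[i])
  })
  modes$k <- purrr::map_dbl(fits, "k")
  modes$k_se <- purrr::map_dbl(fits, "k_se")
  modes$r2 <- purrr::map_dbl(fits, "r2")
  modes$n_pts <- purrr::map_int(fits, ~ as.integer(.x$n_pts))
  modes$used <- modes$used & purrr::map_lgl(fits, "converged")

  mt <- modes[modes$used & is.finite(modes$k), , drop = FALSE]
  if (nrow(mt) < 3L) {
    .stop_validation("fewer than 3 usable modes", class = "liftfrap_rank_deficient")
  }
  X <- 4 * pi^2 * cbind(dxx = mt$u^2, dyy = mt$v^2, dxy = 2 * mt$u * mt$v)
  wts <- 1 / mt$k_se^2
  if (any(!is.finite(wts)) || any(wts <= 0)) wts <- rep(1, nrow(mt))
  fit <- stats::lm.wfit(X, mt$k, wts)
  beta <- fit$coefficients
  tensor <- diffusion_tensor_2d(beta[["dxx"]], beta[["dyy"]], beta[["dxy"]])
  lam <- principal_diffusivities_2d(tensor)
  fa <- tryCatch(fa_from_2d(max(lam[1], 0), max(lam[2], 0)),
                 error = function(e) NA_real_)
  structure(list(tensor = tensor, lambda = lam, fa = fa, modes = modes,
                 time_s = time_s, n_modes_used = nrow(mt),
                 config = list(n_harm = n_harm, q_max = q_max)),
            class = "frap2d_fit")
}

#' @export
print.frap2d_fit <- function(x, ...) {
  cat("<frap2d_fit> in-plane FRAP tensor estimate\n")
  print(x$tensor)
  cat(sprintf("  lambda = (%.4g, %.4g), FA (lambda3 := lambda2) = %.4f\n",
              x$lambda[1], x$lambda[2], x$fa))
  invisible(x)
}

#' @export
tidy.frap2d_fit <- function(x, ...) {
  tibble::tibble(component = c("dxx", "dyy", "dxy"),
                 estimate = c(x$tensor$dxx, x$tensor$dyy, x$tensor$dxy))
}

#' @export
glance.frap2d_fit <- function(x, ...) {
  tibble::tibble(lambda1 = x$lambda[1], lambda2 = x$lambda[2], fa = x$fa,
                 n_modes = x$n_modes_used,
                 median_r2 = median(x$modes$r2[x$modes$used], na.rm = TRUE))
}
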