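#' Normalize a FRAP volume series by its prebleach record
#'
#' Divides each postbleach volume voxelwise by the time-averaged
#' prebleach volume, removing static illumination patterns so the
#' background is ~1 away from the bleach region. Voxels whose prebleach
#' intensity falls below `floor_frac` of the median are masked and
#' in-filled with the local (3x3x3) median before division.
#'
#' @param series A [volume_series()] with >= 1 prebleach volume.
#' @param floor_frac Prebleach floor as a fraction of the median.
#' @return A normalized `volume_series` containing only the postbleach
#'   volumes (`n_prebleach = 0`, `normalized = TRUE`).
#' @export
normalize_series <- function(series, floor_frac = 0.01) {
  stopifnot(is_volume_series(series))
  if (series$n_prebleach < 1L) {
    .stop_validation("need at least one prebleach volume to normalize")
  }
  d <- dim(series$data)
  pre_idx <- seq_len(series$n_prebleach)
  ref <- array(0, d[1:3])
  for (i in pre_idx) ref <- ref + series$data[, , , i]
  ref <- ref / length(pre_idx)
  med <- median(ref)
  if (!is.finite(med) || med <= 0) {
    .stop_validation("prebleach volumes are dark; cannot normalize")
  }
  low <- ref < floor_frac * med
  if (any(low)) {
    idx <- which(low, arr.ind = TRUE)
    filled <- ref
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, ]
      nb <- ref[max(1, i[1] - 1):min(d[1], i[1] + 1),
                max(1, i[2] - 1):min(d[2], i[2] + 1),
                max(1, i[3] - 1):min(d[3], i[3] + 1)]
      nb <- nb[nb >= floor_frac * med]
      filled[i[1], i[2], i[3]] <- if (length(nb)) median(nb) else med
    }
    ref <- filled
  }
  post_idx <- (series$n_prebleach + 1L):d[4]
  out <- array(0, c(d[1:3], length(post_idx)))
  for (j in seq_along(post_idx)) {
    out[, , , j] <- series$data[, , , post_idx[j]] / ref
  }
  res <- volume_series(out, series$voxel_um, series$frame_interval_s,
                       n_prebleach = 0,
                       bleach_duration_s = series$bleach_duration_s,
                       metadata = series$metadata)
  res$normalized <- TRUE
  res
}

#' Select spatial-frequency modes for tensor fitting
#'
#' Returns the low-order axis modes `(n/Lx, 0, 0)`, `(0, n/Ly, 0)`,
#' `(0, 0, n/Lz)` and pairwise diagonal-plane modes `(n/Lx, m/Ly, 0)`
#' etc. for harmonic indices `n, m` in `1..n_harm`, excluding `q = 0`
#' and any mode with `|q| > q_max`. The default band keeps modes inside
#' the high-power region of the bleach-box spectrum
#' (`q_max = 0.6 / bleach extent`).
#'
#' @param fov_um Length-3 field of view, um.
#' @param n_harm Maximum harmonic index per axis.
#' @param q_max Frequency-magnitude cutoff, cycles/um.
#' @param both_signs Also include mirrored diagonal modes
#'   `(n/Lx, -m/Ly, 0)` etc. (better conditioning for off-diagonal
#'   components; the positive quadrant alone already identifies them).
#' @return A tibble with columns `kx, ky, kz` (harmonic indices), `u, v,
#'   w` (cycles/um) and `direction`.
#' @export
select_frequencies <- function(fov_um, n_harm = 4, q_max = 0.06,
                               both_signs = FALSE) {
  if (length(fov_um) != 3L || any(fov_um <= 0)) {
    .stop_validation("fov_um must be three positive lengths")
  }
  stopifnot(n_harm >= 1)
  harm <- seq_len(n_harm)
  axis_modes <- dplyr::bind_rows(
    tibble::tibble(kx = harm, ky = 0L, kz = 0L, direction = "x"),
    tibble::tibble(kx = 0L, ky = harm, kz = 0L, direction = "y"),
    tibble::tibble(kx = 0L, ky = 0L, kz = harm, direction = "z"))
  pairs <- tidyr::expand_grid(n = harm, m = harm)
  signs <- if (both_signs) c(1L, -1L) else 1L
  diag_modes <- dplyr::bind_rows(lapply(signs, function(s) dplyr::bind_rows(
    tibble::tibble(kx = pairs$n, ky = s * pairs$m, kz = 0L, direction = "xy"),
    tibble::tibble(kx = pairs$n, ky = 0L, kz = s * pairs$m, direction = "xz"),
    tibble::tibble(kx = 0L, ky = pairs$n, kz = s * pairs$m, direction = "yz"))))
  modes <- dplyr::bind_rows(axis_modes, diag_modes)
  modes <- dplyr::mutate(modes,
                         u = .data$kx / fov_um[1],
                         v = .data$ky / fov_um[2],
                         w = .data$kz / fov_um[3],
                         q_mag = sqrt(.data$u^2 + .data$v^2 + .data$w^2))
  modes <- dplyr::filter(modes, .data$q_mag > 0, .data$q_mag <= q_max)
  X <- .tensor_design(modes)
  if (nrow(modes) < 6L || qr(X)$rank < 6L) {
    .stop_validation(paste0(
      "fewer than 6 independent quadratic directions survive the band ",
      "filter; increase q_max or n_harm"))
  }
  modes[, c("kx", "ky", "kz", "u", "v", "w", "q_mag", "direction")]
}

# design matrix of k(q) = 4 pi^2 (dxx u^2 + dyy v^2 + dzz w^2
#                                 + 2 dxy uv + 2 dxz uw + 2 dyz vw)
.tensor_design <- function(modes) {
  4 * pi^2 * cbind(dxx = modes$u^2, dyy = modes$v^2, dzz = modes$w^2,
                   dxy = 2 * modes$u * modes$v,
                   dxz = 2 * modes$u * modes$w,
                   dyz = 2 * modes$v * modes$w)
}

#' Extract normalized frequency-mode time series
#'
#' Per-volume 3D discrete Fourier transform of `(normalized volume - 1)`.
#' Under free diffusion each complex coefficient decays as
#' `C(t) = C(0) exp(-k t)` with a time-constant phase, so the series is
#' reduced to the real projection onto the first postbleach coefficient's
#' phase, divided by its magnitude: `Re(C(t) conj(C0)) / |C0|^2`. This
#' starts at 1 by construction, is as robust to sub-voxel bleach-center
#' offsets as the plain modulus (an offset is a pure per-mode phase), and
#' unlike the modulus carries no positive noise bias near the floor.
#' Modes whose first-frame magnitude falls below the noise floor
#' (estimated from coefficients with `|q| > 2 q_max`) are flagged
#' unusable.
#'
#' @param series A normalized `volume_series` (see [normalize_series()]).
#' @param modes Mode table from [select_frequencies()].
#' @param noise_floor_mult Noise floor = this multiple of the RMS
#'   high-frequency coefficient magnitude in the first postbleach volume.
#' @return The `modes` tibble with list-column `coeffs` (normalized
#'   magnitude time series), columns `c0` (first-frame magnitude),
#'   `floor_rel` (noise floor relative to `c0`) and `used`; the time
#'   vector is attached as attribute `time_s`.
#' @export
extract_mode_series <- function(series, modes, noise_floor_mult = 5) {
  stopifnot(is_volume_series(series))
  if (!isTRUE(series$normalized)) {
    .stop_validation("series must be normalized first (normalize_series)")
  }
  d <- dim(series$data)
  nt <- d[4]
  if (nt < 4L) .stop_validation("need >= 4 postbleach volumes")
  fov <- .fov_um(series)
  ii <- cbind(.harmonic_index(modes$kx, d[1]),
              .harmonic_index(modes$ky, d[2]),
              .harmonic_index(modes$kz, d[3]))
  lin <- ii[, 1] + d[1] * (ii[, 2] - 1L) + d[1] * d[2] * (ii[, 3] - 1L)
  q_max <- max(modes$q_mag)
  hi_mask <- .qsq_array(d[1:3], fov) > (2 * q_max)^2
  coef_mat <- matrix(0i, nrow(modes), nt)
  noise_rms <- NA_real_
  for (j in seq_len(nt)) {
    fh <- fft(series$data[, , , j] - 1)
    coef_mat[, j] <- fh[lin]
    if (j == 1L) noise_rms <- sqrt(mean(Mod(fh[hi_mask])^2))
  }
  c0 <- Mod(coef_mat[, 1])
  floor_abs <- noise_floor_mult * noise_rms
  used <- c0 > floor_abs & c0 > 0
  out <- modes
  out$c0 <- c0
  out$floor_rel <- ifelse(c0 > 0, floor_abs / c0, Inf)
  out$used <- used
  out$coeffs <- lapply(seq_len(nrow(modes)), function(i) {
    if (c0[i] > 0) Re(coef_mat[i, ] * Conj(coef_mat[i, 1])) / c0[i]^2
    else rep(NA_real_, nt)
  })
  attr(out, "time_s") <- (seq_len(nt) - 1) * series$frame_interval_s
  attr(out, "noise_floor_abs") <- floor_abs
  out
}

#' Fit a single-mode exponential decay
#'
#' Nonlinear least-squares fit of `C/C0 = A exp(-k t)` with `A` free near
#' 1. The fit is truncated at the first time point whose magnitude drops
#' below the per-mode noise floor.
#'
#' @param coeffs Normalized coefficient magnitudes (starts at 1).
#' @param time_s Time points, s (same length).
#' @param floor_rel Relative noise floor; points below it are dropped
#'   from the first crossing onwards.
#' @return A list: `k` (1/s), `k_se`, `r2`, `n_pts`, `converged`.
#' @export
fit_mode_decay <- function(coeffs, time_s, floor_rel = 0) {
  stopifnot(length(coeffs) == length(time_s))
  below <- which(coeffs < floor_rel)
  n_use <- if (length(below)) min(below) - 1L else length(coeffs)
  if (n_use < 4L) {
    return(list(k = NA_real_, k_se = NA_real_, r2 = NA_real_,
                n_pts = n_use, converged = FALSE))
  }
  y <- coeffs[seq_len(n_use)]
  t <- time_s[seq_len(n_use)]
  if (sd(y) < 1e-12) {
    return(list(k = 0, k_se = 0, r2 = 1, n_pts = n_use, converged = TRUE))
  }
  # log-linear slope as starting value
  ypos <- pmax(y, 1e-12)
  k0 <- max(1e-8, -coef(stats::lm(log(ypos) ~ t))[[2]])
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-k * t),
                      start = list(A = 1, k = k0),
                      lower = c(A = 0, k = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(k = NA_real_, k_se = NA_real_, r2 = NA_real_,
                n_pts = n_use, converged = FALSE))
  }
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit)))[["k"]], error = function(e) NA_real_)
  res <- y - stats::predict(fit)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else 1
  list(k = unname(est[["k"]]), k_se = se, r2 = r2, n_pts = n_use,
       converged = TRUE)
}

#' Assemble the diffusion tensor from fitted mode decay rates
#'
#' Weighted linear least squares on
#' `k(q) = 4 pi^2 (dxx u^2 + dyy v^2 + dzz w^2 + 2 dxy uv + 2 dxz uw +
#' 2 dyz vw)` with weights `1/k_se^2` (unweighted fallback when any
#' standard error is degenerate).
#'
#' @param modes Tibble with columns `u, v, w, k, k_se, used`.
#' @return A list: `tensor` (`diffusion_tensor`), `cov` (6x6 parameter
#'   covariance), `se` (component standard errors), `n_modes`.
#' @export
assemble_tensor <- function(modes) {
  mt <- modes[modes$used & is.finite(modes$k), , drop = FALSE]
  if (nrow(mt) < 6L) {
    .stop_validation(sprintf(
      "only %d usable modes; >= 6 independent directions required",
      nrow(mt)), class = "liftfrap_rank_deficient")
  }
  X <- .tensor_design(mt)
  qrX <- qr(X)
  if (qrX$rank < 6L) {
    miss <- colnames(X)[setdiff(seq_len(6L), qrX$pivot[seq_len(qrX$rank)])]
    .stop_validation(paste0(
      "rank-deficient mode set; unidentified components: ",
      paste(miss, collapse = ", ")), class = "liftfrap_rank_deficient")
  }
  wts <- 1 / mt$k_se^2
  if (any(!is.finite(wts)) || any(wts <= 0)) wts <- rep(1, nrow(mt))
  fit <- stats::lm.wfit(X, mt$k, wts)
  beta <- fit$coefficients
  dof <- max(1L, nrow(mt) - 6L)
  sigma2 <- sum(wts * fit$residuals^2) / dof
  xtwx_inv <- chol2inv(chol(crossprod(X, wts * X)))
  covb <- sigma2 * xtwx_inv
  dimnames(covb) <- list(names(beta), names(beta))
  tensor <- diffusion_tensor(max(beta[["dxx"]], 0), max(beta[["dyy"]], 0),
                             max(beta[["dzz"]], 0),
                             beta[["dxy"]], beta[["dxz"]], beta[["dyz"]])
  list(tensor = tensor, raw = beta, cov = covb,
       se = sqrt(pmax(diag(covb), 0)), n_modes = nrow(mt))
}

#' Full 3D FRAP tensor analysis pipeline
#'
#' Runs normalize -> select modes -> extract -> per-mode decay fits ->
#' weighted tensor assembly -> eigendecomposition and fractional
#' anisotropy. Time origin is the first postbleach volume, which makes
#' the estimator agnostic to diffusion occurring during the bleach pulse.
#'
#' @param series A [volume_series()] with >= 1 prebleach and >= 4
#'   postbleach volumes (or an already-normalized series).
#' @param n_harm Maximum harmonic index per axis.
#' @param q_max Frequency cutoff, cycles/um; default `0.6 / bleach
#'   extent` when the bleach extent is known (10 um -> 0.06), else 0.06.
#' @param both_signs Include mirrored diagonal modes (see
#'   [select_frequencies()]).
#' @param noise_floor_mult Noise-floor multiplier (see
#'   [extract_mode_series()]).
#' @param method `"two_stage"` (per-mode fits then linear assembly,
#'   default) or `"joint"` (refine by jointly fitting all mode series
#'   with a shared tensor, initialized at the two-stage solution).
#' @return A `frap_fit` object: tensor, covariance, eigensystem, FA,
#'   mean diffusivity, per-mode tibble, diagnostics.
#' @examples
#' cfg <- sim_config(diffusion_tensor(20, 10, 5), grid = c(32, 32, 16),
#'                   n_prebleach = 2, n_postbleach = 20,
#'                   noise = NULL, n_bleach_substeps = 2)
#' fit <- analyze_frap3d(simulate_liftfrap(cfg), n_harm = 2)
#' glance(fit)
#' @export
analyze_frap3d <- function(series, n_harm = 4, q_max = NULL,
                           both_signs = FALSE, noise_floor_mult = 5,
                           method = c("two_stage", "joint")) {
  method <- match.arg(method)
  stopifnot(is_volume_series(series))
  stage <- function(name, expr) {
    tryCatch(expr, liftfrap_too_fast = function(e) rlang::abort(
      conditionMessage(e), class = c("liftfrap_too_fast", "liftfrap_error")),
      error = function(e) rlang::abort(
        sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
        class = class(e), parent = e))
  }
  if (is.null(q_max)) {
    ext <- series$metadata$bleach_extent_um
    q_max <- if (!is.null(ext)) 0.6 / max(ext) else 0.06
  }
  norm <- if (isTRUE(series$normalized)) series else
    stage("normalize", normalize_series(series))
  fov <- .fov_um(norm)
  modes <- stage("select_frequencies",
                 select_frequencies(fov, n_harm = n_harm, q_max = q_max,
                                    both_signs = both_signs))
  modes <- stage("extract_mode_series",
                 extract_mode_series(norm, modes,
                                     noise_floor_mult = noise_floor_mult))
  time_s <- attr(modes, "time_s")
  fits <- purrr::map(seq_len(nrow(modes)), function(i) {
    if (!modes$used[i]) {
      return(list(k = NA_real_, k_se = NA_real_, r2 = NA_real_,
                  n_pts = 0L, converged = FALSE))
    }
    fit_mode_decay(modes$coeffs[[i]], time_s, modes$floor_rel[i])
  })
  modes$k <- purrr::map_dbl(fits, "k")
  modes$k_se <- purrr::map_dbl(fits, "k_se")
  modes$r2 <- purrr::map_dbl(fits, "r2")
  modes$n_pts <- purrr::map_int(fits, ~ as.integer(.x$n_pts))
  modes$used <- modes$used & purrr::map_lgl(fits, "converged")

  # frame-rate limit diagnostic: the recovery outran the acquisition if
  # even the slowest-decaying selected mode fell below the noise floor
  # within 3 volumes (fast high harmonics dropping out early is expected
  # and merely shrinks the usable mode set)
  npts_used <- modes$n_pts[modes$c0 > attr(modes, "noise_floor_abs")]
  if (!length(npts_used)) {
    rlang::abort("no selected mode rises above the noise floor",
                 class = c("liftfrap_rank_deficient", "liftfrap_error"))
  }
  if (max(npts_used) < 4) {
    rlang::abort(paste0(
      "diffusion too fast for frame rate: most selected modes decay ",
      "below the noise floor within 3 volumes; increase the volume rate ",
      "or restrict to lower-frequency modes"),
      class = c("liftfrap_too_fast", "liftfrap_error"))
  }

  asm <- assemble_tensor(modes)
  if (method == "joint") {
    asm <- .joint_refine(modes, time_s, asm)
  }
  es <- eigendecompose(asm$tensor)
  fa <- tryCatch(fractional_anisotropy(es$values),
                 error = function(e) fractional_anisotropy(es$values,
                                                           clip_spd = TRUE))
  structure(list(
    tensor = asm$tensor, raw_components = asm$raw, cov = asm$cov,
    se = asm$se, eigensystem = es, fa = fa,
    mean_diffusivity = mean_diffusivity(asm$tensor),
    modes = modes[, setdiff(names(modes), "coeffs")],
    mode_series = modes$coeffs, time_s = time_s,
    n_modes_used = asm$n_modes,
    noise_floor_abs = attr(modes, "noise_floor_abs"),
    config = list(n_harm = n_harm, q_max = q_max, both_signs = both_signs,
                  noise_floor_mult = noise_floor_mult, method = method),
    series_metadata = series$metadata),
    class = "frap_fit")
}

# joint refinement: minimize the summed squared residuals of all usable
# mode series over the six tensor components (amplitudes profiled out)
.joint_refine <- function(modes, time_s, asm) {
  use <- which(modes$used & is.finite(modes$k))
  X <- .tensor_design(modes[use, , drop = FALSE])
  obj <- function(beta) {
    k <- pmax(drop(X %*% beta), 0)
    tot <- 0
    for (ii in seq_along(use)) {
      i <- use[ii]
      n <- modes$n_pts[i]
      y <- modes$coeffs[[i]][seq_len(n)]
      e <- exp(-k[ii] * time_s[seq_len(n)])
      a <- sum(y * e) / sum(e^2)
      tot <- tot + sum((y - a * e)^2)
    }
    tot
  }
  beta0 <- asm$raw
  opt <- stats::optim(beta0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  beta <- setNames(opt$par, names(beta0))
  asm$raw <- beta
  asm$tensor <- suppressWarnings(
    diffusion_tensor(max(beta[["dxx"]], 0), max(beta[["dyy"]], 0),
                     max(beta[["dzz"]], 0),
                     beta[["dxy"]], beta[["dxz"]], beta[["dyz"]]))
  asm
}

#' @export
print.frap_fit <- function(x, ...) {
  cat("<frap_fit> 3D FRAP tensor estimate\n")
  print(x$tensor)
  cat(sprintf("  %d modes used, noise floor %.3g\n",
              x$n_modes_used, x$noise_floor_abs))
  invisible(x)
}

#' @export
tidy.frap_fit <- function(x, ...) {
  tibble::tibble(
    component = c("dxx", "dyy", "dzz", "dxy", "dxz", "dyz"),
    estimate = c(x$tensor$dxx, x$tensor$dyy, x$tensor$dzz,
                 x$tensor$dxy, x$tensor$dxz, x$tensor$dyz),
    std.error = unname(x$se))
}

#' @export
glance.frap_fit <- function(x, ...) {
  tibble::tibble(
    lambda1 = x$eigensystem$values[1],
    lambda2 = x$eigensystem$values[2],
    lambda3 = x$eigensystem$values[3],
    fa = x$fa, mean_diffusivity = x$mean_diffusivity,
    n_modes = x$n_modes_used,
    median_r2 = median(x$modes$r2[x$modes$used], na.rm = TRUE),
    is_spd = x$tensor$is_spd)
}

#' @export
augment.frap_fit <- function(x, ...) {
  md <- x$modes
  md$fitted_k <- drop(.tensor_design(md) %*% x$raw_components)
  md
}
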