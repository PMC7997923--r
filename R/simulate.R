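#' Bleach pulse specification
#'
#' The photobleached region is a box (default the central 10 um cube of
#' the field of view) with error-function-smoothed edges: the profile is
#' the product of per-axis boxes convolved with a Gaussian of width
#' `edge_sigma_um`. `depth` is the fraction of fluorescence removed at the
#' plateau.
#'
#' @param center_um Length-3 box center, um; `NULL` means the FOV center.
#' @param extent_um Length-3 box side lengths, um.
#' @param edge_sigma_um Edge smoothing scale, um; 0 gives a hard box.
#' @param depth Fraction of fluorescence removed at the center, in (0, 1].
#' @return A `bleach_spec` list.
#' @export
bleach_spec <- function(center_um = NULL, extent_um = c(10, 10, 10),
                        edge_sigma_um = 0.5, depth = 0.8) {
  if (length(extent_um) == 1L) extent_um <- rep(extent_um, 3)
  if (any(!is.finite(extent_um)) || any(extent_um <= 0)) {
    .stop_validation("extent_um must be positive")
  }
  .check_scalar_pos(edge_sigma_um, "edge_sigma_um", strict = FALSE)
  if (!is.finite(depth) || depth < 0 || depth > 1) {
    .stop_validation("depth must be in [0, 1]")
  }
  structure(list(center_um = center_um, extent_um = as.numeric(extent_um),
                 edge_sigma_um = edge_sigma_um, depth = depth),
            class = "bleach_spec")
}

#' Camera noise specification
#'
#' Shot noise is modeled as Poisson counting with `photon_scale` expected
#' photons per voxel at unit prebleach intensity; `read_sigma` is additive
#' Gaussian read noise and `offset` a constant camera baseline, both in
#' the same (normalized) intensity units. With intensity `I`, the recorded
#' value is `Pois(photon_scale * I)/photon_scale + N(0, read_sigma) +
#' offset`, so the per-voxel variance is approximately
#' `mean/photon_scale + read_sigma^2`.
#'
#' @param photon_scale Expected photons at prebleach intensity 1.0;
#'   `Inf` disables shot noise.
#' @param read_sigma Additive Gaussian sd, intensity units.
#' @param offset Constant baseline, intensity units.
#' @return A `noise_spec` list. `noise_off()` is shorthand for no noise.
#' @export
noise_spec <- function(photon_scale = 1000, read_sigma = 0.01, offset = 0) {
  if (any(!is.finite(c(read_sigma, offset))) || read_sigma < 0 || offset < 0 ||
      (is.finite(photon_scale) && photon_scale <= 0)) {
    .stop_validation("noise parameters must be non-negative")
  }
  structure(list(photon_scale = photon_scale, read_sigma = read_sigma,
                 offset = offset), class = "noise_spec")
}

#' @rdname noise_spec
#' @export
noise_off <- function() noise_spec(photon_scale = Inf, read_sigma = 0, offset = 0)

.apply_noise <- function(field, noise) {
  if (is.null(noise)) return(field)
  out <- field
  if (is.finite(noise$photon_scale)) {
    lam <- pmax(noise$photon_scale * out, 0)
    out <- array(rpois(length(lam), lam), dim(out)) / noise$photon_scale
  }
  if (noise$read_sigma > 0) {
    out <- out + array(rnorm(length(out), 0, noise$read_sigma), dim(out))
  }
  out + noise$offset
}

#' Virtual FRAP experiment configuration
#'
#' Defaults mirror a light-sheet volumetric FRAP acquisition: a 76 um
#' cubic field of view imaged at 8 volumes/s (10 s of prebleach volumes),
#' a 10 um central bleach cube applied over 1 s, and up to 80 postbleach
#' volumes. The full-resolution grid is 192 x 192 x 64 (x, y, z); the
#' default here is a 64 x 64 x 32 grid that preserves the physical
#' geometry at lower cost.
#'
#' @param tensor Ground-truth `diffusion_tensor`, um^2/s.
#' @param fov_um Length-3 field of view, um.
#' @param grid Length-3 voxel counts `(nx, ny, nz)`; each >= 8.
#' @param volume_rate_hz Volumes per second.
#' @param n_prebleach,n_postbleach Volume counts.
#' @param bleach A [bleach_spec()].
#' @param bleach_duration_s Bleach pulse duration, s.
#' @param n_bleach_substeps Number of bleach/diffusion interleaving
#'   substeps across the pulse (diffusion proceeds during bleaching).
#' @param noise A [noise_spec()], or `NULL` for a noiseless run.
#' @param illumination Optional multiplicative illumination field: either
#'   a 3D array matching `grid` or a function `(x, y, z) -> intensity`
#'   of voxel-center coordinates in um.
#' @param seed Integer seed; mandatory when `noise` is stochastic.
#' @return A `sim_config` list.
#' @export
sim_config <- function(tensor,
                       fov_um = c(76, 76, 76),
                       grid = c(64, 64, 32),
                       volume_rate_hz = 8,
                       n_prebleach = 80,
                       n_postbleach = 80,
                       bleach = bleach_spec(),
                       bleach_duration_s = 1,
                       n_bleach_substeps = 8,
                       noise = noise_spec(),
                       illumination = NULL,
                       seed = NULL) {
  tensor <- as_diffusion_tensor(as.matrix(tensor))
  if (length(fov_um) != 3L || any(fov_um <= 0)) {
    .stop_validation("fov_um must be three positive lengths")
  }
  grid <- as.integer(grid)
  if (length(grid) != 3L || any(grid < 8L)) {
    .stop_validation("grid must have >= 8 voxels per axis")
  }
  .check_scalar_pos(volume_rate_hz, "volume_rate_hz")
  .check_scalar_pos(bleach_duration_s, "bleach_duration_s", strict = FALSE)
  stopifnot(inherits(bleach, "bleach_spec"))
  if (!is.null(noise)) stopifnot(inherits(noise, "noise_spec"))
  stochastic <- !is.null(noise) &&
    (is.finite(noise$photon_scale) || noise$read_sigma > 0)
  if (stochastic && is.null(seed)) {
    .stop_validation("seed is mandatory for a stochastic simulation")
  }
  center <- bleach$center_um %||% (fov_um / 2)
  if (any(center - bleach$extent_um / 2 < 0) ||
      any(center + bleach$extent_um / 2 > fov_um)) {
    .stop_validation("bleach box extends outside the field of view")
  }
  structure(list(tensor = tensor, fov_um = as.numeric(fov_um), grid = grid,
                 volume_rate_hz = volume_rate_hz,
                 n_prebleach = as.integer(n_prebleach),
                 n_postbleach = as.integer(n_postbleach),
                 bleach = bleach, bleach_duration_s = bleach_duration_s,
                 n_bleach_substeps = as.integer(n_bleach_substeps),
                 noise = noise, illumination = illumination,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_config")
}

#' Propagate a concentration field under anisotropic diffusion (spectral)
#'
#' Exact periodic-domain propagator: every Fourier mode `q = (u, v, w)`
#' (cycles/um) is multiplied by `exp(-4 pi^2 q^T D q dt)`. The spatial
#' mean (q = 0 mode) is conserved exactly and the field stays real.
#'
#' @param field 3D numeric array.
#' @param tensor A `diffusion_tensor`.
#' @param dt_s Time step, s (>= 0).
#' @param fov_um Length-3 physical extent of the array, um.
#' @return The propagated 3D array.
#' @export
spectral_propagate <- function(field, tensor, dt_s, fov_um) {
  if (!all(is.finite(field))) .stop_validation("field must be finite")
  if (!is.finite(dt_s) || dt_s < 0) .stop_validation("dt_s must be >= 0")
  if (dt_s == 0) return(field)
  tensor <- as_diffusion_tensor(as.matrix(tensor))
  dims <- dim(field)
  rates <- .rate_array(tensor, dims, fov_um)
  fh <- fft(field) * exp(-rates * dt_s)
  Re(fft(fh, inverse = TRUE)) / length(field)
}

# smoothed box profile along one axis: box of side e centered at c,
# convolved with a Gaussian of sd sigma; hard box when sigma = 0
.box_profile <- function(x, center, extent, sigma) {
  lo <- center - extent / 2
  hi <- center + extent / 2
  if (sigma <= 0) return(as.numeric(x >= lo & x <= hi))
  pnorm((x - lo) / sigma) - pnorm((x - hi) / sigma)
}

#' Apply a photobleaching pulse to a concentration field
#'
#' Multiplies the field by `1 - depth * B(x)` where `B` is the smoothed
#' 3D box profile of the bleach region (1 on the plateau, 0 far outside).
#'
#' @param field 3D numeric array.
#' @param bleach A [bleach_spec()].
#' @param fov_um Length-3 physical extent, um.
#' @return The bleached field.
#' @export
apply_bleach <- function(field, bleach, fov_um) {
  stopifnot(inherits(bleach, "bleach_spec"))
  if (bleach$depth == 0) return(field)
  dims <- dim(field)
  center <- bleach$center_um %||% (fov_um / 2)
  h <- fov_um / dims
  bx <- .box_profile((seq_len(dims[1]) - 0.5) * h[1], center[1],
                     bleach$extent_um[1], bleach$edge_sigma_um)
  by <- .box_profile((seq_len(dims[2]) - 0.5) * h[2], center[2],
                     bleach$extent_um[2], bleach$edge_sigma_um)
  bz <- .box_profile((seq_len(dims[3]) - 0.5) * h[3], center[3],
                     bleach$extent_um[3], bleach$edge_sigma_um)
  B <- array(bx, dims) * array(rep(by, each = dims[1]), dims) *
    array(rep(bz, each = dims[1] * dims[2]), dims)
  field * (1 - bleach$depth * B)
}

.illumination_field <- function(config) {
  dims <- config$grid
  illum <- config$illumination
  if (is.null(illum)) return(array(1, dims))
  if (is.function(illum)) {
    h <- config$fov_um / dims
    x <- (seq_len(dims[1]) - 0.5) * h[1]
    y <- (seq_len(dims[2]) - 0.5) * h[2]
    z <- (seq_len(dims[3]) - 0.5) * h[3]
    g <- expand.grid(x = x, y = y, z = z)
    return(array(illum(g$x, g$y, g$z), dims))
  }
  if (!identical(dim(illum), as.integer(dims))) {
    .stop_validation("illumination array must match the grid")
  }
  illum
}

#' Simulate a full volumetric FRAP experiment
#'
#' Virtual microscope: records prebleach volumes of the (uniform or
#' patterned) fluorescence field, applies the bleach pulse in
#' `n_bleach_substeps` bleach/diffusion interleaving substeps across
#' `bleach_duration_s` (diffusion proceeds while bleaching), then records
#' postbleach volumes at the volume rate, propagating the concentration
#' with the exact spectral propagator between frames. Noise is applied
#' independently per recorded volume. The run is fully reproducible from
#' the config seed, and the ground-truth tensor is stored in the metadata.
#'
#' @param config A [sim_config()].
#' @return A [volume_series()] with `metadata$truth_tensor` and
#'   `metadata$config`.
#' @export
simulate_liftfrap <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  dims <- config$grid
  illum <- .illumination_field(config)
  dt_frame <- 1 / config$volume_rate_hz

  nt <- config$n_prebleach + config$n_postbleach
  data <- array(0, c(dims, nt))

  conc <- array(1, dims)
  for (i in seq_len(config$n_prebleach)) {
    data[, , , i] <- .apply_noise(illum * conc, config$noise)
  }

  # bleach with diffusion during the pulse: per-substep depth compounds
  # to the configured total depth at the plateau
  n_sub <- max(1L, config$n_bleach_substeps)
  if (config$bleach$depth > 0 && config$bleach_duration_s > 0) {
    sub_depth <- 1 - (1 - config$bleach$depth)^(1 / n_sub)
    sub_spec <- config$bleach
    sub_spec$depth <- sub_depth
    dt_sub <- config$bleach_duration_s / n_sub
    for (s in seq_len(n_sub)) {
      conc <- apply_bleach(conc, sub_spec, config$fov_um)
      conc <- spectral_propagate(conc, config$tensor, dt_sub, config$fov_um)
    }
  } else if (config$bleach$depth > 0) {
    conc <- apply_bleach(conc, config$bleach, config$fov_um)
  }

  for (j in seq_len(config$n_postbleach)) {
    if (j > 1) {
      conc <- spectral_propagate(conc, config$tensor, dt_frame, config$fov_um)
    }
    data[, , , config$n_prebleach + j] <- .apply_noise(illum * conc,
                                                       config$noise)
  }

  volume_series(data,
                voxel_um = config$fov_um / dims,
                frame_interval_s = dt_frame,
                n_prebleach = config$n_prebleach,
                bleach_duration_s = config$bleach_duration_s,
                metadata = list(truth_tensor = config$tensor,
                                config = config, seed = config$seed,
                                bleach_extent_um = config$bleach$extent_um))
}

#' Simulate a single-plane 2D FRAP experiment
#'
#' 2D analogue of [simulate_liftfrap()] for purely in-plane dynamics:
#' square field of view, centered square bleach region (default side
#' 1/8 of the image side), exact 2D spectral propagation between frames.
#'
#' @param tensor2d A `diffusion_tensor_2d`.
#' @param n_px Image side, pixels.
#' @param pixel_um Pixel size, um.
#' @param frame_interval_s Frame interval, s.
#' @param n_prebleach,n_postbleach Frame counts.
#' @param bleach_side_frac Bleach square side as a fraction of the image
#'   side.
#' @param depth Bleach depth in (0, 1].
#' @param edge_sigma_um Bleach edge smoothing, um.
#' @param noise A [noise_spec()] or `NULL`.
#' @param seed Integer seed (mandatory when noise is stochastic).
#' @return An [image_series_2d()] with the truth tensor in metadata.
#' @export
simulate_frap2d <- function(tensor2d, n_px = 128, pixel_um = 2,
                            frame_interval_s = 0.355,
                            n_prebleach = 5, n_postbleach = 200,
                            bleach_side_frac = 1 / 8, depth = 0.8,
                            edge_sigma_um = NULL, noise = NULL,
                            seed = NULL) {
  stopifnot(inherits(tensor2d, "diffusion_tensor_2d"))
  stochastic <- !is.null(noise) &&
    (is.finite(noise$photon_scale) || noise$read_sigma > 0)
  if (stochastic && is.null(seed)) {
    .stop_validation("seed is mandatory for a stochastic simulation")
  }
  if (!is.null(seed)) set.seed(seed)
  L <- n_px * pixel_um
  if (is.null(edge_sigma_um)) edge_sigma_um <- pixel_um
  # embed as an nx x ny x 1 pseudo-volume and reuse the 3D machinery
  t3 <- suppressWarnings(
    diffusion_tensor(tensor2d$dxx, tensor2d$dyy, 0, dxy = tensor2d$dxy))
  fov3 <- c(L, L, 1)
  dims3 <- c(n_px, n_px, 1L)
  bl <- bleach_spec(center_um = c(L / 2, L / 2, 0.5),
                    extent_um = c(L * bleach_side_frac,
                                  L * bleach_side_frac, 1),
                    edge_sigma_um = edge_sigma_um, depth = depth)
  conc <- array(1, dims3)
  nt <- n_prebleach + n_postbleach
  data <- array(0, c(n_px, n_px, nt))
  for (i in seq_len(n_prebleach)) {
    data[, , i] <- .apply_noise(conc, noise)[, , 1]
  }
  conc <- apply_bleach(conc, bl, fov3)
  for (j in seq_len(n_postbleach)) {
    if (j > 1) conc <- spectral_propagate(conc, t3, frame_interval_s, fov3)
    data[, , n_prebleach + j] <- .apply_noise(conc, noise)[, , 1]
  }
  image_series_2d(data, pixel_um = pixel_um,
                  frame_interval_s = frame_interval_s,
                  n_prebleach = n_prebleach,
                  metadata = list(truth_tensor = tensor2d, seed = seed,
                                  bleach_extent_um = L * bleach_side_frac))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
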