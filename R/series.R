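#' Construct a FRAP volume time series
#'
#' Container for a 4D fluorescence record: a stack of 3D volumes acquired
#' at a uniform frame interval, with physical calibration and acquisition
#' metadata. The data array is stored `(x, y, z, t)` with x fastest
#' (column-major R layout).
#'
#' @param data 4D numeric array, dim `(nx, ny, nz, nt)`.
#' @param voxel_um Length-3 voxel size `(x, y, z)`, um.
#' @param frame_interval_s Time between successive volumes, s.
#' @param n_prebleach Number of leading prebleach volumes.
#' @param bleach_duration_s Duration of the bleaching pulse, s.
#' @param metadata Free-form list (may carry the ground-truth tensor and
#'   the simulation config for synthetic series).
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(data, voxel_um, frame_interval_s, n_prebleach,
                          bleach_duration_s = 0, metadata = list()) {
  if (!is.array(data) || length(dim(data)) != 4L) {
    .stop_validation("data must be a 4D array (x, y, z, t)")
  }
  if (length(voxel_um) != 3L || any(!is.finite(voxel_um)) || any(voxel_um <= 0)) {
    .stop_validation("voxel_um must be three positive values")
  }
  .check_scalar_pos(frame_interval_s, "frame_interval_s")
  if (!is.finite(n_prebleach) || n_prebleach < 0 || n_prebleach >= dim(data)[4]) {
    .stop_validation("n_prebleach must be in [0, nt)")
  }
  structure(list(data = data, voxel_um = as.numeric(voxel_um),
                 frame_interval_s = frame_interval_s,
                 n_prebleach = as.integer(n_prebleach),
                 bleach_duration_s = bleach_duration_s,
                 normalized = FALSE, metadata = metadata),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<volume_series> %d x %d x %d voxels, %d volumes (%d prebleach)\n",
    d[1], d[2], d[3], d[4], x$n_prebleach))
  cat(sprintf("  voxel %.3g x %.3g x %.3g um, frame interval %.4g s%s\n",
              x$voxel_um[1], x$voxel_um[2], x$voxel_um[3],
              x$frame_interval_s,
              if (isTRUE(x$normalized)) ", normalized" else ""))
  invisible(x)
}

#' @rdname volume_series
#' @param x Object to test.
#' @export
is_volume_series <- function(x) inherits(x, "volume_series")

# field of view, um, per axis
.fov_um <- function(series) {
  dim(series$data)[1:3] * series$voxel_um
}

# postbleach volumes as a list of 3D arrays (t = 0 at first postbleach)
.postbleach_volumes <- function(series) {
  nt <- dim(series$data)[4]
  idx <- (series$n_prebleach + 1L):nt
  lapply(idx, function(i) series$data[, , , i])
}

#' Construct a single-plane FRAP image series
#'
#' 2D analogue of [volume_series()]: a time series of single-plane images
#' with pixel calibration, as produced by a confocal 2D FRAP experiment.
#' Data layout is `(x, y, t)`.
#'
#' @param data 3D numeric array, dim `(nx, ny, nt)`.
#' @param pixel_um Pixel size, um (isotropic in-plane).
#' @param frame_interval_s Time between frames, s.
#' @param n_prebleach Number of leading prebleach frames.
#' @param metadata Free-form list.
#' @return An object of class `image_series_2d`.
#' @export
image_series_2d <- function(data, pixel_um, frame_interval_s, n_prebleach,
                            metadata = list()) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    .stop_validation("data must be a 3D array (x, y, t)")
  }
  .check_scalar_pos(pixel_um, "pixel_um")
  .check_scalar_pos(frame_interval_s, "frame_interval_s")
  if (!is.finite(n_prebleach) || n_prebleach < 0 || n_prebleach >= dim(data)[3]) {
    .stop_validation("n_prebleach must be in [0, nt)")
  }
  structure(list(data = data, pixel_um = pixel_um,
                 frame_interval_s = frame_interval_s,
                 n_prebleach = as.integer(n_prebleach),
                 metadata = metadata),
            class = "image_series_2d")
}

#' @export
print.image_series_2d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_series_2d> %d x %d px, %d frames (%d prebleach), %.3g um/px, %.4g s/frame\n",
    d[1], d[2], d[3], x$n_prebleach, x$pixel_um, x$frame_interval_s))
  invisible(x)
}

#' Extract one z-plane of a volume series as a 2D image series
#'
#' Emulates the invasive single-plane measurement on a 3D experiment:
#' the selected plane is carried over with its in-plane calibration and
#' prebleach bookkeeping so it can be fed to [analyze_frap2d()].
#'
#' @param series A `volume_series`.
#' @param z Plane index (default: center plane).
#' @return An `image_series_2d`.
#' @export
extract_plane <- function(series, z = NULL) {
  stopifnot(is_volume_series(series))
  d <- dim(series$data)
  if (is.null(z)) z <- ceiling(d[3] / 2)
  if (z < 1 || z > d[3]) .stop_validation("z outside the stack")
  if (abs(series$voxel_um[1] - series$voxel_um[2]) >
      1e-9 * series$voxel_um[1]) {
    .stop_validation("in-plane voxel size must be isotropic for a 2D series")
  }
  image_series_2d(series$data[, , z, ], pixel_um = series$voxel_um[1],
                  frame_interval_s = series$frame_interval_s,
                  n_prebleach = series$n_prebleach,
                  metadata = c(series$metadata, list(source_plane_z = z)))
}
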