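.sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

.schema_version <- "1.0.0"

#' Write a volume series to a multi-page TIFF with a JSON sidecar
#'
#' Pages are stored as 32-bit samples affinely scaled to the intensity
#' range recorded in the sidecar (relative quantization error below
#' 2^-32), ordered z-within-t; calibration, acquisition metadata and
#' (for synthetic series) the ground-truth tensor go to a sidecar JSON
#' next to the TIFF.
#'
#' @param series A [volume_series()].
#' @param path Output TIFF path (`.tif`); the sidecar replaces the
#'   extension with `.json`.
#' @return `path`, invisibly.
#' @export
write_volume_series <- function(series, path) {
  stopifnot(is_volume_series(series))
  d <- dim(series$data)
  rng <- range(series$data)
  span <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
  pages <- vector("list", d[3] * d[4])
  p <- 0L
  for (ti in seq_len(d[4])) {
    for (zi in seq_len(d[3])) {
      p <- p + 1L
      pages[[p]] <- t((series$data[, , zi, ti] - rng[1]) / span)  # rows = y
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(
    schema_version = .schema_version,
    intensity_range = rng,
    dims = d, voxel_um = series$voxel_um,
    frame_interval_s = series$frame_interval_s,
    n_prebleach = series$n_prebleach,
    bleach_duration_s = series$bleach_duration_s,
    normalized = isTRUE(series$normalized),
    page_order = "z_within_t")
  if (!is.null(series$metadata$truth_tensor)) {
    meta$truth_tensor <- tensor_to_list(series$metadata$truth_tensor)
  }
  if (!is.null(series$metadata$seed)) meta$seed <- series$metadata$seed
  if (!is.null(series$metadata$bleach_extent_um)) {
    meta$bleach_extent_um <- series$metadata$bleach_extent_um
  }
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a volume series from a multi-page TIFF
#'
#' Reads a TIFF stack written by [write_volume_series()] (or any
#' consistent multi-page stack plus calibration). Calibration is taken
#' from the sidecar JSON when present; explicit arguments override the
#' sidecar (a conflict is reported as a message). Integer TIFFs are
#' converted to floating point with their full range preserved.
#'
#' @param path TIFF path.
#' @param voxel_um,frame_interval_s,n_prebleach,bleach_duration_s
#'   Calibration overrides; required when no sidecar carries them.
#' @param nz Number of z-planes per time point; required when the
#'   sidecar is absent.
#' @return A [volume_series()].
#' @export
read_volume_series <- function(path, voxel_um = NULL,
                               frame_interval_s = NULL, n_prebleach = NULL,
                               bleach_duration_s = NULL, nz = NULL) {
  side <- .sidecar_path(path)
  meta0 <- if (file.exists(side)) jsonlite::read_json(side,
                                                      simplifyVector = TRUE)
           else list()
  scaled <- !is.null(meta0$intensity_range)
  # our own files are range-scaled; foreign integer TIFFs are read as
  # raw counts so the full range is preserved without clipping
  pages <- tiff::readTIFF(path, all = TRUE, as.is = !scaled)
  if (!length(pages)) .stop_validation("empty TIFF stack")
  dims <- lapply(pages, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
    .stop_validation("inconsistent page sizes in TIFF stack")
  }
  meta <- meta0
  pick <- function(flag, field, what) {
    stored <- meta[[field]]
    if (!is.null(flag)) {
      if (!is.null(stored) && !isTRUE(all.equal(as.numeric(flag),
                                                as.numeric(stored)))) {
        rlang::inform(sprintf(
          "%s: argument (%s) overrides sidecar value (%s)", what,
          paste(flag, collapse = ","), paste(stored, collapse = ",")))
      }
      return(flag)
    }
    if (is.null(stored)) {
      .stop_validation(sprintf("missing calibration: %s (no sidecar value and no argument)", what))
    }
    stored
  }
  voxel_um <- as.numeric(pick(voxel_um, "voxel_um", "voxel_um"))
  frame_interval_s <- as.numeric(pick(frame_interval_s, "frame_interval_s",
                                      "frame_interval_s"))
  n_prebleach <- as.integer(pick(n_prebleach, "n_prebleach", "n_prebleach"))
  bleach_duration_s <- as.numeric(
    if (!is.null(bleach_duration_s)) bleach_duration_s
    else meta$bleach_duration_s %||% 0)
  nz <- as.integer(if (!is.null(nz)) nz else
    if (!is.null(meta$dims)) meta$dims[3] else
      .stop_validation("missing calibration: nz (planes per volume)"))
  n_pages <- length(pages)
  if (n_pages %% nz != 0L) {
    .stop_validation("page count is not a multiple of nz")
  }
  nt <- n_pages %/% nz
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  data <- array(0, c(nx, ny, nz, nt))
  p <- 0L
  for (ti in seq_len(nt)) {
    for (zi in seq_len(nz)) {
      p <- p + 1L
      data[, , zi, ti] <- t(pages[[p]])
    }
  }
  if (scaled) {
    rng <- as.numeric(meta$intensity_range)
    span <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
    data <- rng[1] + data * span
  }
  md <- list()
  if (!is.null(meta$truth_tensor)) {
    tt <- meta$truth_tensor
    md$truth_tensor <- suppressWarnings(
      diffusion_tensor(tt$dxx, tt$dyy, tt$dzz, tt$dxy, tt$dxz, tt$dyz))
  }
  if (!is.null(meta$bleach_extent_um)) {
    md$bleach_extent_um <- meta$bleach_extent_um
  }
  out <- volume_series(data, voxel_um, frame_interval_s, n_prebleach,
                       bleach_duration_s, metadata = md)
  out$normalized <- isTRUE(meta$normalized)
  out
}

#' Write a FRAP fit result to JSON + CSV
#'
#' Writes `<prefix>.json` (schema-versioned tensor serialization with
#' eigenvalues, FA and mean diffusivity, plus a provenance block),
#' `<prefix>_modes.csv` (the per-mode table) and `<prefix>.log` (a
#' human-readable summary).
#'
#' @param fit A `frap_fit` from [analyze_frap3d()].
#' @param prefix Output path prefix.
#' @param frame `"lab"` or `"sample"` tag for the tensor frame.
#' @return Named list of the files written, invisibly.
#' @export
write_frap_results <- function(fit, prefix, frame = "lab") {
  stopifnot(inherits(fit, "frap_fit"))
  json_path <- paste0(prefix, ".json")
  csv_path <- paste0(prefix, "_modes.csv")
  log_path <- paste0(prefix, ".log")
  payload <- list(
    schema_version = .schema_version,
    tensor = tensor_to_list(fit$tensor, frame = frame),
    component_se = as.list(setNames(fit$se, names(fit$raw_components))),
    n_modes_used = fit$n_modes_used,
    noise_floor = fit$noise_floor_abs,
    provenance = list(
      package_version = as.character(packageVersion("liftfrap")),
      config = fit$config,
      config_hash = rlang::hash(fit$config),
      seed = fit$series_metadata$seed))
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  write.csv(fit$modes, csv_path, row.names = FALSE)
  lines <- c(
    "FRAP 3D tensor analysis result",
    sprintf("package liftfrap %s", packageVersion("liftfrap")),
    sprintf("modes used: %d", fit$n_modes_used),
    sprintf("tensor (um^2/s): dxx=%.5g dyy=%.5g dzz=%.5g dxy=%.5g dxz=%.5g dyz=%.5g",
            fit$tensor$dxx, fit$tensor$dyy, fit$tensor$dzz,
            fit$tensor$dxy, fit$tensor$dxz, fit$tensor$dyz),
    sprintf("eigenvalues: %s", paste(signif(fit$eigensystem$values, 6),
                                     collapse = ", ")),
    sprintf("FA = %.5f, mean diffusivity = %.5g", fit$fa,
            fit$mean_diffusivity))
  writeLines(lines, log_path)
  invisible(list(json = json_path, modes_csv = csv_path, log = log_path))
}

#' Read back a result JSON written by [write_frap_results()]
#'
#' @param json_path Path to the `.json` result file.
#' @return The parsed list with `tensor` as a `diffusion_tensor`.
#' @export
read_frap_results <- function(json_path) {
  payload <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  tt <- payload$tensor
  payload$tensor_object <- suppressWarnings(
    diffusion_tensor(tt$dxx, tt$dyy, tt$dzz, tt$dxy, tt$dxz, tt$dyz))
  payload
}
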