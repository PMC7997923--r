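#' Plot per-mode recovery curves of a 3D FRAP fit
#'
#' Normalized frequency-domain magnitudes `C/C0` against time for the
#' fitted modes, with the fitted exponential decays overlaid.
#'
#' @param object A `frap_fit`.
#' @param max_modes Plot at most this many modes (lowest `|q|` first).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.frap_fit <- function(object, max_modes = 9, ...) {
  md <- object$modes
  keep <- order(md$q_mag)[seq_len(min(max_modes, nrow(md)))]
  df <- purrr::map_dfr(keep, function(i) {
    y <- object$mode_series[[i]]
    n <- md$n_pts[i]
    tibble::tibble(
      mode = sprintf("q=(%.3g,%.3g,%.3g)", md$u[i], md$v[i], md$w[i]),
      t = object$time_s, y = y,
      fitted = if (md$used[i] && is.finite(md$k[i]))
        exp(-md$k[i] * object$time_s) else NA_real_,
      in_fit = seq_along(y) <= n)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(alpha = .data$in_fit), size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red",
                       na.rm = TRUE) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.25),
                                guide = "none") +
    ggplot2::facet_wrap(~mode, scales = "free_y") +
    ggplot2::labs(x = "time after bleach (s)",
                  y = expression(tilde(C) / tilde(C)[0])) +
    ggplot2::theme_bw()
}

#' Plot fitted decay rates against the quadratic-form prediction
#'
#' Diagnostic for tensor assembly: each fitted per-mode rate `k` against
#' the rate implied by the assembled tensor, `4 pi^2 q^T D q`.
#'
#' @param fit A `frap_fit`.
#' @return A ggplot object.
#' @export
plot_rate_fit <- function(fit) {
  stopifnot(inherits(fit, "frap_fit"))
  df <- augment(fit)
  df <- df[df$used, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fitted_k, y = .data$k)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$k - .data$k_se, ymax = .data$k + .data$k_se,
      colour = .data$direction)) +
    ggplot2::labs(x = expression(4 * pi^2 * q^T * D * q ~ (s^-1)),
                  y = expression(fitted ~ k ~ (s^-1)),
                  colour = "direction") +
    ggplot2::theme_bw()
}

#' Plot a benchmark sweep
#'
#' Median relative eigenvalue error against ground-truth diffusivity,
#' one line per noise level.
#'
#' @param object A `frap_benchmark` from [benchmark_recovery()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.frap_benchmark <- function(object, ...) {
  df <- object |>
    dplyr::group_by(.data$photon_scale, .data$diffusivity) |>
    dplyr::summarise(median_rel_err = median(.data$mean_lambda_rel_err,
                                             na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$diffusivity,
                                   y = .data$median_rel_err,
                                   colour = factor(.data$photon_scale))) +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"),
                        linetype = 2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "ground-truth diffusivity (um^2/s)",
                  y = "median relative eigenvalue error",
                  colour = "photons/voxel") +
    ggplot2::theme_bw()
}

#' Plot axis concentration profiles
#'
#' @param profiles Tibble from [concentration_profiles()].
#' @return A ggplot object.
#' @export
plot_profiles <- function(profiles) {
  ggplot2::ggplot(profiles, ggplot2::aes(x = .data$distance_um,
                                         y = .data$concentration,
                                         colour = .data$axis)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from source center (um)",
                  y = "normalized concentration") +
    ggplot2::theme_bw()
}
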