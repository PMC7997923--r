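test_that("prebleach normalization removes illumination structure", {
  tn <- diffusion_tensor(5, 5, 5)

  # postbleach identical to prebleach -> unit field
  cfg <- sim_config(tn, grid = c(16, 16, 16), n_prebleach = 2,
                    n_postbleach = 5, bleach = bleach_spec(depth = 0),
                    noise = NULL)
  norm <- normalize_series(simulate_liftfrap(cfg))
  expect_equal(max(abs(norm$data - 1)), 0, tolerance = 1e-12)
  expect_equal(dim(norm$data)[4], 5)
  expect_true(norm$normalized)

  # multiplicative pattern divides out exactly in the noiseless limit
  cfg2 <- sim_config(tn, grid = c(16, 16, 16), n_prebleach = 2,
                     n_postbleach = 5, noise = NULL,
                     illumination = function(x, y, z) 1 + 0.4 * cos(y / 9))
  vs2 <- simulate_liftfrap(cfg2)
  cfg3 <- sim_config(tn, grid = c(16, 16, 16), n_prebleach = 2,
                     n_postbleach = 5, noise = NULL)
  vs3 <- simulate_liftfrap(cfg3)
  expect_equal(normalize_series(vs2)$data, normalize_series(vs3)$data,
               tolerance = 1e-12)

  # with shot noise the background away from the bleach box sits at 1
  cfg4 <- sim_config(tn, grid = c(32, 32, 32), n_prebleach = 8,
                     n_postbleach = 4, noise = noise_spec(), seed = 31)
  norm4 <- normalize_series(simulate_liftfrap(cfg4))
  shell <- norm4$data[c(1:6, 27:32), c(1:6, 27:32), c(1:6, 27:32), 1]
  expect_equal(mean(shell), 1, tolerance = 0.01)

  dark <- volume_series(array(0, c(8, 8, 8, 4)), c(1, 1, 1), 0.1, 2)
  expect_error(normalize_series(dark), class = "liftfrap_validation_error")
})

test_that("mode selection spans the band with the documented geometry", {
  modes <- select_frequencies(c(76, 76, 76), n_harm = 4, q_max = 0.06)
  expect_equal(min(modes$q_mag), 1 / 76, tolerance = 1e-12)
  expect_true(all(modes$q_mag <= 0.06))
  expect_false(any(modes$kx == 0 & modes$ky == 0 & modes$kz == 0))

  # minimum solvable set: 3 axis + 3 diagonal-plane directions
  m1 <- select_frequencies(c(76, 76, 76), n_harm = 1, q_max = 0.06)
  expect_equal(nrow(m1), 6)
  expect_setequal(m1$direction, c("x", "y", "z", "xy", "xz", "yz"))

  expect_error(select_frequencies(c(76, 76, 76), n_harm = 1, q_max = 0.015),
               class = "liftfrap_validation_error")
})

test_that("extracted mode series follow the spectral decay law", {
  tn <- diffusion_tensor(20, 10, 5, dxy = 2, dyz = 1)
  cfg <- small_sim_config(tn)
  norm <- normalize_series(simulate_liftfrap(cfg))
  modes <- select_frequencies(.fov <- dim(norm$data)[1:3] * norm$voxel_um,
                              n_harm = 2)
  ext <- extract_mode_series(norm, modes)
  ts <- attr(ext, "time_s")
  expect_equal(ts[1], 0)
  worst <- 0
  for (i in seq_len(nrow(ext))) {
    expect_equal(ext$coeffs[[i]][1], 1)
    pred <- exp(-decay_rate(c(ext$u[i], ext$v[i], ext$w[i]), tn) * ts)
    n <- sum(pred > ext$floor_rel[i])
    worst <- max(worst, max(abs(ext$coeffs[[i]][1:n] - pred[1:n])))
  }
  expect_lt(worst, 1e-3)

  # static sample: all modes stay at 1
  cfg0 <- small_sim_config(diffusion_tensor(0, 0, 0))
  norm0 <- normalize_series(simulate_liftfrap(cfg0))
  ext0 <- extract_mode_series(norm0, modes)
  for (i in seq_len(nrow(ext0))) {
    expect_equal(ext0$coeffs[[i]], rep(1, length(ts)), tolerance = 1e-9)
  }
})

test_that("single-mode decay fitting is exact on clean data and calibrated under noise", {
  t <- (0:39) / 8
  fit <- fit_mode_decay(exp(-0.5 * t), t)
  expect_equal(fit$k, 0.5, tolerance = 1e-6)
  expect_true(fit$converged)

  fit0 <- fit_mode_decay(rep(1, 40), t)
  expect_equal(fit0$k, 0)

  # Monte-Carlo coverage: k within 3 SE of truth in >= 95% of replicates
  set.seed(77)
  hits <- 0
  for (r in 1:500) {
    y <- exp(-0.5 * t) + rnorm(40, 0, 0.02)
    f <- fit_mode_decay(y, t)
    if (f$converged && abs(f$k - 0.5) <= 3 * f$k_se) hits <- hits + 1
  }
  expect_gte(hits / 500, 0.95)

  short <- fit_mode_decay(c(1, 0.5, 0.1), c(0, 1, 2))
  expect_false(short$converged)
})

test_that("tensor assembly solves the quadratic-form system exactly", {
  D <- matrix(c(10, 2, 1, 2, 5, 0.5, 1, 0.5, 2), 3, 3)
  tn <- as_diffusion_tensor(D)
  expect_equal(decay_rate(c(0.1, 0.1, 0), tn), 4 * pi^2 * 0.19,
               tolerance = 1e-12)

  modes <- select_frequencies(c(76, 76, 76), n_harm = 2)
  modes$k <- vapply(seq_len(nrow(modes)), function(i)
    decay_rate(c(modes$u[i], modes$v[i], modes$w[i]), tn), 0)
  modes$k_se <- 1e-4
  modes$used <- TRUE
  asm <- assemble_tensor(modes)
  expect_equal(unname(as.matrix(asm$tensor)), D, tolerance = 1e-10)

  # isotropic rates give vanishing off-diagonals
  iso <- diffusion_tensor(7, 7, 7)
  modes$k <- vapply(seq_len(nrow(modes)), function(i)
    decay_rate(c(modes$u[i], modes$v[i], modes$w[i]), iso), 0)
  asm2 <- assemble_tensor(modes)
  expect_lt(max(abs(c(asm2$tensor$dxy, asm2$tensor$dxz, asm2$tensor$dyz))),
            1e-10)

  # axis-only modes cannot identify the off-diagonals
  ax <- modes[modes$direction %in% c("x", "y", "z"), ]
  err <- expect_error(assemble_tensor(ax), class = "liftfrap_rank_deficient")
  expect_match(conditionMessage(err), "dxy|dxz|dyz")
})

test_that("the full pipeline recovers a noiseless anisotropic tensor", {
  truth <- diffusion_tensor(20, 10, 5)
  fit <- analyze_frap3d(simulate_liftfrap(small_sim_config(truth)),
                        n_harm = 2)
  expect_lt(abs(fit$tensor$dxx - 20) / 20, 0.01)
  expect_lt(abs(fit$tensor$dyy - 10) / 10, 0.01)
  expect_lt(abs(fit$tensor$dzz - 5) / 5, 0.01)
  expect_lt(max(abs(c(fit$tensor$dxy, fit$tensor$dxz, fit$tensor$dyz))), 0.05)

  td <- tidy(fit)
  expect_equal(nrow(td), 6)
  gl <- glance(fit)
  expect_equal(gl$lambda1, 20, tolerance = 0.01)
  expect_equal(gl$fa, fractional_anisotropy(20, 10, 5), tolerance = 0.02)
})

test_that("recovery error shrinks as more volumes are recorded", {
  # noiseless series are recovered at solver precision regardless of
  # length; with shot noise, longer records must reduce the error
  truth <- diffusion_tensor(12, 6, 3, dxy = 1)
  cfg0 <- sim_config(truth, grid = c(32, 32, 16), n_prebleach = 2,
                     n_postbleach = 20, noise = NULL)
  err0 <- max(abs(as.matrix(analyze_frap3d(simulate_liftfrap(cfg0),
                                           n_harm = 2)$tensor) -
                    as.matrix(truth)))
  expect_lt(err0, 1e-3)

  err_at <- function(vs, nt) {
    short <- vs
    short$data <- vs$data[, , , seq_len(vs$n_prebleach + nt), drop = FALSE]
    fit <- analyze_frap3d(short, n_harm = 2)
    max(abs(as.matrix(fit$tensor) - as.matrix(truth)))
  }
  med <- sapply(c(20, 40, 80), function(nt) {
    median(vapply(1:5, function(seed) {
      # bright imaging so the reduced test grid keeps all modes usable
      cfg <- sim_config(truth, grid = c(32, 32, 16), n_prebleach = 4,
                        n_postbleach = 80,
                        noise = noise_spec(photon_scale = 1e4,
                                           read_sigma = 0.002), seed = seed)
      err_at(simulate_liftfrap(cfg), nt)
    }, 0))
  })
  expect_true(all(diff(med) < 0))
})

test_that("relabeling the volume axes permutes the recovered tensor", {
  truth <- diffusion_tensor(18, 9, 4, dxy = 2, dxz = 1, dyz = 0.5)
  cfg <- sim_config(truth, grid = c(32, 32, 32), n_prebleach = 2,
                    n_postbleach = 30, noise = NULL)
  vs <- simulate_liftfrap(cfg)
  fit <- analyze_frap3d(vs, n_harm = 2)

  swapped <- vs
  swapped$data <- aperm(vs$data, c(2, 1, 3, 4))
  fit_sw <- analyze_frap3d(swapped, n_harm = 2)
  expect_equal(fit_sw$tensor$dxx, fit$tensor$dyy, tolerance = 1e-6)
  expect_equal(fit_sw$tensor$dyy, fit$tensor$dxx, tolerance = 1e-6)
  expect_equal(fit_sw$tensor$dxy, fit$tensor$dxy, tolerance = 1e-6)
  expect_equal(fit_sw$tensor$dxz, fit$tensor$dyz, tolerance = 1e-6)
  expect_equal(fit_sw$tensor$dyz, fit$tensor$dxz, tolerance = 1e-6)
})

test_that("recovery outrunning the frame rate raises a dedicated diagnostic", {
  cfg <- sim_config(diffusion_tensor(400, 400, 400), grid = c(32, 32, 16),
                    n_prebleach = 4, n_postbleach = 20,
                    bleach_duration_s = 0.2, seed = 1)
  expect_error(analyze_frap3d(simulate_liftfrap(cfg)),
               class = "liftfrap_too_fast")
})

test_that("the joint refinement agrees with the two-stage solution on clean data", {
  truth <- diffusion_tensor(15, 8, 4, dxy = 1.5)
  vs <- simulate_liftfrap(small_sim_config(truth))
  fit2 <- analyze_frap3d(vs, n_harm = 2)
  fitj <- analyze_frap3d(vs, n_harm = 2, method = "joint")
  expect_equal(as.matrix(fitj$tensor), as.matrix(fit2$tensor),
               tolerance = 0.01)
})
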