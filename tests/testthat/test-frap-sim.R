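test_that("spectral propagator decays single modes at the analytic rate and conserves the mean", {
  dims <- c(16, 16, 16)
  fov <- c(10, 10, 10)
  tn <- diffusion_tensor(10, 1, 1)

  f <- array(runif(prod(dims)), dims)
  expect_identical(spectral_propagate(f, tn, 0, fov), f)
  expect_lt(abs(mean(spectral_propagate(f, tn, 0.7, fov)) - mean(f)), 1e-12)

  # pure mode q = (0.1, 0, 0) cycles/um with dxx = 10 over 1 s
  x <- (seq_len(dims[1]) - 0.5) * fov[1] / dims[1]
  mode <- array(cos(2 * pi * 0.1 * x), dims)
  prop <- spectral_propagate(mode, tn, 1, fov)
  expect_equal(max(prop) / max(mode), exp(-4 * pi^2 * 0.1), tolerance = 1e-6)
  expect_lt(max(abs(Im(fft(prop)[1, 1, 1]))), 1e-10)

  bad <- f; bad[1] <- NA
  expect_error(spectral_propagate(bad, tn, 0.1, fov),
               class = "liftfrap_validation_error")
})

test_that("bleach profiles remove the configured fraction of fluorescence", {
  dims <- c(32, 32, 32)
  fov <- c(76, 76, 76)
  f <- array(1, dims)

  expect_identical(apply_bleach(f, bleach_spec(depth = 0), fov), f)

  hard <- apply_bleach(f, bleach_spec(extent_um = c(10, 10, 10),
                                      edge_sigma_um = 0, depth = 1), fov)
  h <- fov / dims
  centers <- (seq_len(dims[1]) - 0.5) * h[1]
  inside <- abs(centers - 38) <= 5
  expect_true(all(hard[inside, inside, inside] == 0))
  expect_true(all(hard[!inside, , ] == 1))

  # smooth edges resolved by the grid: removed mass ~ depth * box volume
  dims2 <- c(64, 64, 64)
  f2 <- array(1, dims2)
  h2 <- fov / dims2
  sm <- apply_bleach(f2, bleach_spec(extent_um = c(10, 10, 10),
                                     edge_sigma_um = 1.5, depth = 0.8), fov)
  removed <- sum(f2 - sm) * prod(h2)
  expect_equal(removed, 0.8 * 1000, tolerance = 0.02)
})

test_that("the virtual microscope is conservative, reproducible and noise-faithful", {
  tn <- diffusion_tensor(15, 8, 4)

  # no bleach, no noise: every volume equals the prebleach field
  cfg0 <- sim_config(tn, grid = c(16, 16, 16), n_prebleach = 2,
                     n_postbleach = 5, bleach = bleach_spec(depth = 0),
                     noise = NULL)
  vs0 <- simulate_liftfrap(cfg0)
  for (i in 2:7) expect_equal(vs0$data[, , , i], vs0$data[, , , 1])

  # noiseless: total fluorescence constant across postbleach volumes
  cfg1 <- small_sim_config(tn)
  vs1 <- simulate_liftfrap(cfg1)
  totals <- apply(vs1$data[, , , 3:32], 4, sum)
  expect_lt(diff(range(totals)) / totals[1], 1e-12)

  # determinism: same config + seed => bit-identical series
  cfg2 <- small_sim_config(tn, noise = noise_spec(), seed = 99)
  expect_identical(simulate_liftfrap(cfg2)$data, simulate_liftfrap(cfg2)$data)

  # prebleach variance ~ mean/photon_scale + read_sigma^2
  cfg3 <- sim_config(tn, grid = c(64, 64, 32), n_prebleach = 1,
                     n_postbleach = 1,
                     noise = noise_spec(photon_scale = 500,
                                        read_sigma = 0.02), seed = 5)
  pre <- simulate_liftfrap(cfg3)$data[, , , 1]
  expect_gt(length(pre), 1e5)
  expect_equal(var(as.vector(pre)), mean(pre) / 500 + 0.02^2,
               tolerance = 0.05)

  # seed required for stochastic runs; bleach must stay inside the FOV
  expect_error(small_sim_config(tn, noise = noise_spec()),
               class = "liftfrap_validation_error")
  expect_error(sim_config(tn, bleach = bleach_spec(center_um = c(2, 38, 38)),
                          noise = NULL),
               class = "liftfrap_validation_error")
})

test_that("simulated recovery matches the finite-difference oracle voxelwise", {
  tn <- diffusion_tensor(20, 10, 5, dxy = 2)
  cfg <- sim_config(tn, grid = c(32, 32, 32), n_prebleach = 1,
                    n_postbleach = 20, noise = NULL)
  vs <- simulate_liftfrap(cfg)
  post1 <- vs$data[, , , 2]
  dom <- pde_domain(c(32, 32, 32), vs$voxel_um, tn, initial_field = post1,
                    boundary = "periodic")
  worst <- 0
  for (j in c(5, 10, 20)) {
    fd <- fd_diffuse(dom, duration_s = (j - 1) * vs$frame_interval_s)
    sim_vol <- vs$data[, , , 1 + j]
    scale <- max(abs(fd - mean(fd)))
    worst <- max(worst, max(abs(sim_vol - fd)) / scale)
  }
  expect_lt(worst, 0.01)
})

test_that("illumination patterns multiply the recorded volumes", {
  tn <- diffusion_tensor(5, 5, 5)
  cfg <- sim_config(tn, grid = c(16, 16, 16), n_prebleach = 1,
                    n_postbleach = 4, noise = NULL,
                    illumination = function(x, y, z) 1 + 0.3 * sin(x / 10))
  vs <- simulate_liftfrap(cfg)
  h <- 76 / 16
  expected <- 1 + 0.3 * sin(((1:16) - 0.5) * h / 10)
  expect_equal(vs$data[, 1, 1, 1], expected, tolerance = 1e-12)
})
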