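test_that("zero-flux diffusion conserves mass over long runs and rejects unstable steps", {
  set.seed(4)
  tn <- diffusion_tensor(6, 3, 1.5, dxy = 0.8, dyz = 0.4)
  init <- array(runif(12^3), c(12, 12, 12))
  dom <- pde_domain(c(12, 12, 12), 1, tn, initial_field = init)
  dt <- fd_max_dt(tn, 1) * 0.9
  out <- fd_diffuse(dom, duration_s = 1000 * dt, dt_s = dt)
  expect_lt(abs(sum(out) / sum(init) - 1), 1e-6)

  err <- expect_error(fd_diffuse(dom, 1, dt_s = fd_max_dt(tn, 1) * 2),
                      class = "liftfrap_unstable_dt")
  expect_match(conditionMessage(err), "maximum stable dt")
})

test_that("isotropic spreading matches the free-space Gaussian variance 2Dt", {
  tn <- diffusion_tensor(5, 5, 5)
  n <- 48
  init <- array(0, c(n, n, n))
  init[24:25, 24:25, 24:25] <- 1
  dom <- pde_domain(c(n, n, n), 1, tn, initial_field = init)
  out <- fd_diffuse(dom, duration_s = 2)
  x <- (1:n) - 24.5
  marg <- apply(out, 1, sum)
  v <- sum(marg * x^2) / sum(marg)
  # initial two-voxel bump contributes var 1/4 + discrete correction
  expect_equal(v, 2 * 5 * 2, tolerance = 0.02)
})

test_that("a held source fills the domain monotonically", {
  tn <- diffusion_tensor(4, 2, 1)
  n <- 16
  mask <- array(FALSE, c(n, n, n))
  mask[8:9, 8:9, 8:9] <- TRUE
  dom <- pde_domain(c(n, n, n), 1, tn, source_mask = mask, source_value = 1)
  out <- fd_diffuse(dom, duration_s = 3, snapshot_every = 20)
  snaps <- attr(out, "snapshots")
  for (i in seq_len(length(snaps) - 1)) {
    expect_true(all(snaps[[i + 1]] - snaps[[i]] > -1e-12))
  }
  expect_true(all(out >= 0 & out <= 1 + 1e-12))
})

test_that("periodic finite differences reproduce the analytic mode decay rates", {
  set.seed(12)
  tn <- random_spd_tensor(c(2, 8))
  n <- 32
  init <- array(0, c(n, n, n)); init[13:20, 13:20, 13:20] <- 1
  dom <- pde_domain(c(n, n, n), 1, tn, initial_field = init,
                    boundary = "periodic")
  out <- fd_diffuse(dom, duration_s = 2, snapshot_every = 10)
  snaps <- attr(out, "snapshots")
  ts <- attr(out, "snapshot_times_s")
  for (k in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0))) {
    idx <- (k %% n) + 1
    amp <- vapply(snaps, function(s) Mod(fft(s)[idx[1], idx[2], idx[3]]), 0)
    kfit <- -coef(stats::lm(log(amp) ~ ts))[[2]]
    expect_equal(kfit, decay_rate(k / n, tn), tolerance = 0.02)
  }
})

test_that("axis concentration profiles are normalized and reflect anisotropy", {
  # isotropic: the three half-axis profiles coincide
  tn_iso <- diffusion_tensor(5, 5, 5)
  n <- 33
  mask <- array(FALSE, c(n, n, n)); mask[17, 17, 17] <- TRUE
  dom <- pde_domain(c(n, n, n), 1, tn_iso, source_mask = mask)
  out <- fd_diffuse(dom, duration_s = 4)
  prof <- concentration_profiles(out, 1, origin = c(17, 17, 17))
  expect_equal(prof$concentration[prof$distance_um == 0], rep(1, 3))
  px <- prof$concentration[prof$axis == "x"]
  py <- prof$concentration[prof$axis == "y"]
  pz <- prof$concentration[prof$axis == "z"]
  expect_equal(px, py, tolerance = 0.01)
  expect_equal(px, pz, tolerance = 0.01)

  # strong x-anisotropy: x profile dominates at equal radius
  tn_ani <- diffusion_tensor(19, 5.5, 5.5)
  dom2 <- pde_domain(c(n, n, n), 1, tn_ani, source_mask = mask)
  out2 <- fd_diffuse(dom2, duration_s = 4)
  prof2 <- concentration_profiles(out2, 1, origin = c(17, 17, 17))
  p2x <- prof2$concentration[prof2$axis == "x"]
  p2y <- prof2$concentration[prof2$axis == "y"]
  p2z <- prof2$concentration[prof2$axis == "z"]
  r <- 2:10
  expect_true(all(p2x[r] > p2y[r]))
  expect_true(all(p2x[r] > p2z[r]))

  zero <- array(0, c(17, 17, 17))
  expect_error(concentration_profiles(zero, 1),
               class = "liftfrap_validation_error")
})
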