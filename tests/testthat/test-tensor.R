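test_that("eigendecomposition recovers diagonal tensors and matches an independent characteristic-polynomial oracle", {
  es <- eigendecompose(diffusion_tensor(10, 5, 2))
  expect_equal(es$values, c(10, 5, 2))
  expect_equal(abs(es$vectors), diag(3), tolerance = 1e-12)

  m <- matrix(c(10, 2, 1, 2, 5, 0.5, 1, 0.5, 2), 3, 3)
  es2 <- eigendecompose(as_diffusion_tensor(m))
  expect_equal(es2$values, char_poly_eigenvalues(m), tolerance = 1e-8)

  # deterministic sign convention
  for (j in 1:3) {
    i <- which.max(abs(es2$vectors[, j]))
    expect_gt(es2$vectors[i, j], 0)
  }
  expect_error(eigendecompose(matrix(c(1, NA, 0, NA, 1, 0, 0, 0, 1), 3, 3)),
               class = "liftfrap_validation_error")
})

test_that("eigendecompose/reconstruct is an identity for random SPD tensors", {
  set.seed(101)
  worst <- 0
  for (i in 1:1000) {
    tn <- random_spd_tensor()
    es <- eigendecompose(tn)
    rec <- es$vectors %*% diag(es$values) %*% t(es$vectors)
    worst <- max(worst, max(abs(rec - as.matrix(tn))) / max(abs(as.matrix(tn))))
    expect_lt(max(abs(crossprod(es$vectors) - diag(3))), 1e-10)
  }
  expect_lt(worst, 1e-8)
})

test_that("fractional anisotropy satisfies the defining identities and bounds", {
  for (d in c(0.5, 1, 20)) expect_equal(fractional_anisotropy(d, d, d), 0)
  expect_equal(fractional_anisotropy(1, 0, 0), 1)
  expect_equal(fractional_anisotropy(2, 1, 1), sqrt(2) / sqrt(12),
               tolerance = 1e-12)
  expect_error(fractional_anisotropy(0, 0, 0),
               class = "liftfrap_undefined_input")
  expect_error(fractional_anisotropy(1, -0.1, 0.5),
               class = "liftfrap_validation_error")
  expect_equal(fractional_anisotropy(1, -0.1, 0.5, clip_spd = TRUE),
               fractional_anisotropy(1, 0, 0.5))
  # strictly increasing in the elongation of one axis
  eps <- seq(0.01, 2, length.out = 40)
  fa <- vapply(eps, function(e) fractional_anisotropy(1 + e, 1, 1), 0)
  expect_true(all(diff(fa) > 0))
  expect_true(all(fa >= 0 & fa <= 1))
})

test_that("tensor rotation conjugates the matrix and preserves invariants", {
  tn <- diffusion_tensor(10, 5, 2, dxy = 1)
  expect_equal(as.matrix(rotate_tensor(tn, diag(3))), as.matrix(tn))

  # quarter turn about z permutes the x/y diagonal entries
  rot <- rotate_tensor(diffusion_tensor(3, 7, 2),
                       rotation_about_axis("z", pi / 2))
  expect_equal(c(rot$dxx, rot$dyy, rot$dzz), c(7, 3, 2), tolerance = 1e-12)

  expect_error(rotate_tensor(tn, diag(c(1, 1, 2))),
               class = "liftfrap_validation_error")
  expect_error(rotate_tensor(tn, diag(c(1, 1, -1))),  # improper (det = -1)
               class = "liftfrap_validation_error")

  set.seed(7)
  for (i in 1:300) {
    tn_i <- random_spd_tensor()
    rot_i <- rotate_tensor(tn_i, random_rotation())
    expect_lt(max(abs(eigendecompose(rot_i)$values -
                        eigendecompose(tn_i)$values)), 1e-9)
    expect_lt(abs(fractional_anisotropy(rot_i) -
                    fractional_anisotropy(tn_i)), 1e-9)
  }
})

test_that("mean diffusivity is the diagonal average and a rotation invariant", {
  expect_equal(mean_diffusivity(diffusion_tensor(10, 5, 2)), 17 / 3)
  expect_equal(mean_diffusivity(diffusion_tensor(4, 4, 4)), 4)
  set.seed(21)
  tn <- random_spd_tensor()
  expect_equal(mean_diffusivity(rotate_tensor(tn, random_rotation())),
               mean_diffusivity(tn), tolerance = 1e-12)
})

test_that("indefinite tensors are flagged, kept raw by default, and clipped on request", {
  m <- diag(c(5, 3, 1)); m[1, 2] <- m[2, 1] <- 4.5   # smallest eigenvalue < 0
  expect_warning(tn <- as_diffusion_tensor(m), "negative eigenvalue")
  expect_false(tn$is_spd)
  expect_equal(unname(as.matrix(tn)), m)  # raw estimate preserved
  expect_error(fractional_anisotropy(tn), class = "liftfrap_validation_error")

  tn_clip <- as_diffusion_tensor(m, clip_spd = TRUE)
  expect_true(tn_clip$is_spd)
  expect_gte(min(eigendecompose(tn_clip)$values), -1e-12)
})

test_that("tensor serialization carries components, eigensystem and derived scalars", {
  tn <- diffusion_tensor(10, 5, 2, dxy = 1, dxz = 0.5, dyz = 0.25)
  ser <- tensor_to_list(tn, frame = "sample")
  expect_equal(ser$units, "um^2/s")
  expect_equal(ser$frame, "sample")
  expect_equal(ser$dxy, 1)
  expect_equal(ser$eigenvalues, eigendecompose(tn)$values)
  expect_equal(ser$fa, fractional_anisotropy(tn))
  expect_equal(ser$mean_diffusivity, 17 / 3)
  expect_length(ser$eigenvectors, 3)
})

test_that("tidy and glance summarise tensors as tibbles", {
  tn <- diffusion_tensor(10, 5, 2)
  td <- tidy(tn)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$estimate[td$component == "dzz"], 2)
  gl <- glance(tn)
  expect_equal(gl$lambda1, 10)
  expect_true(gl$is_spd)
})
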