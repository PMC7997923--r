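#' Construct a 3D diffusion tensor
#'
#' Represents the symmetric 3x3 diffusion tensor `D` of anisotropic
#' Fickian diffusion by its six unique components, in um^2/s. Diagonal
#' components are axis diffusivities; off-diagonal components couple axes.
#' Symmetry is structural: only six numbers are stored and the
#' reconstructed matrix is exactly equal to its transpose.
#'
#' The tensor need not be positive semi-definite: noisy per-mode fits can
#' produce a slightly negative smallest eigenvalue. Such tensors are kept
#' as-is and flagged with `is_spd = FALSE` (with a warning) so the raw
#' estimate is preserved; `clip_spd = TRUE` instead projects negative
#' eigenvalues to zero.
#'
#' @param dxx,dyy,dzz Diagonal components, um^2/s. Must be non-negative.
#' @param dxy,dxz,dyz Off-diagonal components, um^2/s.
#' @param clip_spd If `TRUE`, eigenvalues below zero are clipped to zero
#'   and the tensor is rebuilt from the clipped eigensystem.
#' @return An object of class `diffusion_tensor` (list with the six
#'   components and an `is_spd` flag).
#' @examples
#' diffusion_tensor(10, 5, 2)
#' diffusion_tensor(10, 5, 2, dxy = 1.5)
#' @export
diffusion_tensor <- function(dxx, dyy, dzz, dxy = 0, dxz = 0, dyz = 0,
                             clip_spd = FALSE) {
  comp <- c(dxx = dxx, dyy = dyy, dzz = dzz, dxy = dxy, dxz = dxz, dyz = dyz)
  .check_finite(comp, "diffusion tensor components")
  if (any(comp[c("dxx", "dyy", "dzz")] < 0)) {
    .stop_validation("diagonal diffusivities must be >= 0")
  }
  out <- structure(as.list(comp), class = "diffusion_tensor")
  ev <- eigen(as.matrix(out), symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-9 * sum(comp[c("dxx", "dyy", "dzz")])
  out$is_spd <- all(ev >= -tol)
  if (!out$is_spd) {
    if (clip_spd) {
      es <- eigen(as.matrix(out), symmetric = TRUE)
      lam <- pmax(es$values, 0)
      m <- es$vectors %*% diag(lam) %*% t(es$vectors)
      out$dxx <- m[1, 1]; out$dyy <- m[2, 2]; out$dzz <- m[3, 3]
      out$dxy <- m[1, 2]; out$dxz <- m[1, 3]; out$dyz <- m[2, 3]
      out$is_spd <- TRUE
    } else {
      rlang::warn("diffusion tensor has a negative eigenvalue; is_spd = FALSE")
    }
  }
  out
}

#' Coerce a diffusion tensor to / from a 3x3 matrix
#'
#' @param x A `diffusion_tensor`, or for [as_diffusion_tensor()] a symmetric
#'   3x3 numeric matrix.
#' @param ... Unused.
#' @return `as.matrix()` returns the symmetric 3x3 matrix;
#'   `as_diffusion_tensor()` the `diffusion_tensor`.
#' @export
as.matrix.diffusion_tensor <- function(x, ...) {
  matrix(c(x$dxx, x$dxy, x$dxz,
           x$dxy, x$dyy, x$dyz,
           x$dxz, x$dyz, x$dzz), 3, 3,
         dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
}

#' @rdname as.matrix.diffusion_tensor
#' @param clip_spd Passed to [diffusion_tensor()].
#' @export
as_diffusion_tensor <- function(x, clip_spd = FALSE) {
  if (inherits(x, "diffusion_tensor")) return(x)
  stopifnot(is.matrix(x), all(dim(x) == c(3L, 3L)))
  .check_finite(x, "tensor matrix")
  if (max(abs(x - t(x))) > 1e-8 * max(1, max(abs(x)))) {
    .stop_validation("matrix is not symmetric")
  }
  x <- (x + t(x)) / 2
  diffusion_tensor(x[1, 1], x[2, 2], x[3, 3],
                   x[1, 2], x[1, 3], x[2, 3], clip_spd = clip_spd)
}

#' @export
print.diffusion_tensor <- function(x, digits = 4, ...) {
  cat("<diffusion_tensor> (um^2/s)\n")
  print(round(as.matrix(x), digits))
  es <- eigendecompose(x)
  cat(sprintf("lambda = (%s), FA = %.4f, MD = %.4g, is_spd = %s\n",
              paste(signif(es$values, digits), collapse = ", "),
              tryCatch(fractional_anisotropy(es$values),
                       error = function(e) NA_real_),
              mean_diffusivity(x), x$is_spd))
  invisible(x)
}

#' Eigendecomposition of a diffusion tensor
#'
#' Returns the principal diffusivities (eigenvalues, descending:
#' `lambda1 >= lambda2 >= lambda3`) and the principal directions as an
#' orthonormal matrix with a deterministic sign convention: the
#' largest-magnitude entry of each eigenvector is made positive.
#'
#' @param tensor A `diffusion_tensor` or symmetric 3x3 matrix.
#' @return A list of class `eigen_system`: `values` (length 3, descending,
#'   um^2/s) and `vectors` (3x3, columns are unit eigenvectors e1, e2, e3).
#' @examples
#' eigendecompose(diffusion_tensor(10, 5, 2))
#' @export
eigendecompose <- function(tensor) {
  m <- as.matrix(as_diffusion_tensor(tensor))
  .check_finite(m, "tensor")
  es <- eigen(m, symmetric = TRUE)   # base eigen: descending for symmetric
  v <- es$vectors
  for (j in 1:3) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  structure(list(values = es$values, vectors = v), class = "eigen_system")
}

#' @export
print.eigen_system <- function(x, ...) {
  cat("<eigen_system> lambda =", signif(x$values, 5), "\n")
  print(signif(x$vectors, 4))
  invisible(x)
}

#' Diffusion fractional anisotropy
#'
#' Scalar in \[0, 1\] quantifying how direction-dependent diffusion is:
#' \deqn{FA = \sqrt{(\lambda_1-\lambda_2)^2 + (\lambda_1-\lambda_3)^2 +
#'   (\lambda_2-\lambda_3)^2} / \sqrt{2(\lambda_1^2+\lambda_2^2+\lambda_3^2)}}
#' A value of 0 indicates pure isotropic diffusion; 1 indicates pure
#' unidirectional diffusion.
#'
#' @param lambda1 First principal diffusivity, or a length-3 vector of all
#'   three, or a `diffusion_tensor` / `eigen_system`.
#' @param lambda2,lambda3 Remaining principal diffusivities when `lambda1`
#'   is scalar.
#' @param clip_spd If the input is a tensor with negative eigenvalues,
#'   clip them to zero before evaluating; otherwise negative input is an
#'   error (the definition presumes diffusivities).
#' @return FA, dimensionless in \[0, 1\].
#' @examples
#' fractional_anisotropy(1, 1, 1)   # 0
#' fractional_anisotropy(1, 0, 0)   # 1
#' fractional_anisotropy(2, 1, 1)   # sqrt(2)/sqrt(12)
#' @export
fractional_anisotropy <- function(lambda1, lambda2 = NULL, lambda3 = NULL,
                                  clip_spd = FALSE) {
  if (inherits(lambda1, "diffusion_tensor")) {
    lam <- eigendecompose(lambda1)$values
  } else if (inherits(lambda1, "eigen_system")) {
    lam <- lambda1$values
  } else if (is.null(lambda2)) {
    lam <- lambda1
  } else {
    lam <- c(lambda1, lambda2, lambda3)
  }
  if (length(lam) != 3L) .stop_validation("need three principal diffusivities")
  .check_finite(lam, "principal diffusivities")
  if (any(lam < 0)) {
    if (clip_spd) lam <- pmax(lam, 0)
    else .stop_validation("negative principal diffusivity; FA is defined for diffusivities >= 0 (use clip_spd = TRUE to clip)")
  }
  if (all(lam == 0)) {
    .stop_validation("FA undefined for all-zero diffusivities",
                     class = "liftfrap_undefined_input")
  }
  fa <- sqrt((lam[1] - lam[2])^2 + (lam[1] - lam[3])^2 + (lam[2] - lam[3])^2) /
    sqrt(2 * sum(lam^2))
  min(max(fa, 0), 1)
}

#' Mean diffusivity
#'
#' Average of the diagonal tensor components, `(dxx + dyy + dzz)/3`
#' (one third of the trace; rotation invariant).
#'
#' @param tensor A `diffusion_tensor` or symmetric 3x3 matrix.
#' @return Mean diffusivity, um^2/s.
#' @export
mean_diffusivity <- function(tensor) {
  tensor <- as_diffusion_tensor(tensor)
  (tensor$dxx + tensor$dyy + tensor$dzz) / 3
}

#' Rotate a diffusion tensor into another coordinate frame
#'
#' Applies `D' = R D R^T` for a proper rotation matrix `R`, e.g. to present
#' a lab-frame tensor in a sample (tissue) coordinate system. Eigenvalues,
#' FA and mean diffusivity are invariant.
#'
#' @param tensor A `diffusion_tensor` or symmetric 3x3 matrix.
#' @param R 3x3 rotation matrix: orthonormal with `det(R) = +1` (to 1e-8).
#' @return The rotated `diffusion_tensor`.
#' @examples
#' Rz <- rotation_about_axis("z", pi / 2)
#' rotate_tensor(diffusion_tensor(10, 5, 2), Rz)
#' @export
rotate_tensor <- function(tensor, R) {
  tensor <- as_diffusion_tensor(tensor)
  if (!is.matrix(R) || !all(dim(R) == c(3L, 3L)) || !all(is.finite(R))) {
    .stop_validation("R must be a finite 3x3 matrix")
  }
  if (max(abs(crossprod(R) - diag(3))) > 1e-8 || abs(det(R) - 1) > 1e-8) {
    .stop_validation("R is not a proper rotation (orthonormal, det = +1)")
  }
  m <- R %*% as.matrix(tensor) %*% t(R)
  suppressWarnings(as_diffusion_tensor((m + t(m)) / 2))
}

#' Elementary and random rotation matrices
#'
#' `rotation_about_axis()` returns the right-handed rotation by `angle`
#' radians about a coordinate axis. `random_rotation()` draws a rotation
#' uniformly (Haar) via QR decomposition of a Gaussian matrix.
#'
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param angle Rotation angle, radians.
#' @return A 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis = c("x", "y", "z"), angle) {
  axis <- match.arg(axis)
  c_ <- cos(angle); s <- sin(angle)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, s, 0, -s, c_), 3, 3),
    y = matrix(c(c_, 0, -s, 0, 1, 0, s, 0, c_), 3, 3),
    z = matrix(c(c_, s, 0, -s, c_, 0, 0, 0, 1), 3, 3))
}

#' @rdname rotation_about_axis
#' @export
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

#' Construct a 2D diffusion tensor
#'
#' Symmetric 2x2 in-plane diffusion tensor, um^2/s, as recovered by
#' single-plane FRAP analysis.
#'
#' @param dxx,dyy,dxy Components, um^2/s.
#' @return An object of class `diffusion_tensor_2d`.
#' @export
diffusion_tensor_2d <- function(dxx, dyy, dxy = 0) {
  comp <- c(dxx = dxx, dyy = dyy, dxy = dxy)
  .check_finite(comp, "2D diffusion tensor components")
  structure(as.list(comp), class = "diffusion_tensor_2d")
}

#' @export
as.matrix.diffusion_tensor_2d <- function(x, ...) {
  matrix(c(x$dxx, x$dxy, x$dxy, x$dyy), 2, 2,
         dimnames = list(c("x", "y"), c("x", "y")))
}

#' @export
print.diffusion_tensor_2d <- function(x, digits = 4, ...) {
  cat("<diffusion_tensor_2d> (um^2/s)\n")
  print(round(as.matrix(x), digits))
  invisible(x)
}

#' Principal diffusivities of a 2D tensor
#'
#' @param tensor A `diffusion_tensor_2d`.
#' @return Numeric length-2, sorted ascending (`lambda1 <= lambda2`).
#' @export
principal_diffusivities_2d <- function(tensor) {
  stopifnot(inherits(tensor, "diffusion_tensor_2d"))
  sort(eigen(as.matrix(tensor), symmetric = TRUE, only.values = TRUE)$values)
}

#' Fractional anisotropy from 2D principal diffusivities
#'
#' Estimates the 3D FA from an in-plane measurement by assuming the
#' unobserved third principal diffusivity equals the larger in-plane
#' one (`lambda3 := lambda2`), then evaluating the 3D FA definition on
#' `(lambda1, lambda2, lambda2)`.
#'
#' @param lambda1,lambda2 In-plane principal diffusivities with
#'   `0 <= lambda1 <= lambda2`, not both zero.
#' @return FA, dimensionless.
#' @examples
#' fa_from_2d(1, 2)   # 1/3
#' @export
fa_from_2d <- function(lambda1, lambda2) {
  .check_finite(c(lambda1, lambda2), "principal diffusivities")
  if (lambda1 < 0 || lambda2 < 0) {
    .stop_validation("principal diffusivities must be >= 0")
  }
  if (lambda1 > lambda2) {
    .stop_validation("expected lambda1 <= lambda2 (2D values sorted ascending)")
  }
  fractional_anisotropy(lambda1, lambda2, lambda2)
}

#' Serialize a diffusion tensor (with derived scalars) to a list
#'
#' Flat representation used by [write_frap_results()]: the six components,
#' eigenvalues, eigenvectors, FA, mean diffusivity, units and frame tag.
#'
#' @param tensor A `diffusion_tensor`.
#' @param frame `"lab"` or `"sample"`.
#' @return A named list, JSON-ready.
#' @export
tensor_to_list <- function(tensor, frame = c("lab", "sample")) {
  frame <- match.arg(frame)
  tensor <- as_diffusion_tensor(tensor)
  es <- eigendecompose(tensor)
  fa <- tryCatch(fractional_anisotropy(es$values), error = function(e) NA_real_)
  list(dxx = tensor$dxx, dyy = tensor$dyy, dzz = tensor$dzz,
       dxy = tensor$dxy, dxz = tensor$dxz, dyz = tensor$dyz,
       eigenvalues = es$values,
       eigenvectors = lapply(1:3, function(j) es$vectors[, j]),
       fa = fa, mean_diffusivity = mean_diffusivity(tensor),
       is_spd = tensor$is_spd, units = "um^2/s", frame = frame)
}

#' @export
tidy.diffusion_tensor <- function(x, ...) {
  tibble::tibble(
    component = c("dxx", "dyy", "dzz", "dxy", "dxz", "dyz"),
    estimate = c(x$dxx, x$dyy, x$dzz, x$dxy, x$dxz, x$dyz))
}

#' @export
glance.diffusion_tensor <- function(x, ...) {
  es <- eigendecompose(x)
  tibble::tibble(
    lambda1 = es$values[1], lambda2 = es$values[2], lambda3 = es$values[3],
    fa = tryCatch(fractional_anisotropy(es$values),
                  error = function(e) NA_real_),
    mean_diffusivity = mean_diffusivity(x),
    is_spd = x$is_spd)
}
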