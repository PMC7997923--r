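# shared fixtures: everything is generated in code under fixed seeds

# random SPD tensor with eigenvalues drawn uniformly from lambda_range
random_spd_tensor <- function(lambda_range = c(2, 12)) {
  lam <- sort(runif(3, lambda_range[1], lambda_range[2]), decreasing = TRUE)
  R <- random_rotation()
  rotate_tensor(as_diffusion_tensor(diag(lam)), R)
}

# small, fast simulation config for unit tests
small_sim_config <- function(tensor, noise = NULL, seed = NULL, ...) {
  sim_config(tensor, grid = c(32, 32, 16), n_prebleach = 2,
             n_postbleach = 30, noise = noise, seed = seed, ...)
}

# independent eigenvalue oracle: roots of the characteristic polynomial
# det(M - lambda I) via polyroot, no call into eigen()
char_poly_eigenvalues <- function(m) {
  tr <- sum(diag(m))
  c2 <- (tr^2 - sum(m * m)) / 2   # sum of principal 2x2 minors (symmetric m)
  dt <- det(m)
  # lambda^3 - tr lambda^2 + c2 lambda - det = 0
  roots <- polyroot(c(-dt, c2, -tr, 1))
  sort(Re(roots), decreasing = TRUE)
}
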