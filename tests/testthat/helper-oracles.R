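# Independent oracles used across the test files. These deliberately avoid
# the code paths they check.

# Incompressible strain energy as a function of (lambda1, lambda2) with
# lambda3 = 1/(lambda1 lambda2), through the exported energy functions.
energy_2d <- function(l1, l2, params) {
  st <- stretch_state(l1, l2, 1 / (l1 * l2))
  strain_energy(st, params)
}

# Principal Cauchy stress difference sigma_i - sigma_3 by central finite
# differences of the energy: sigma_1 - sigma_3 = lambda_1 dW/dlambda_1 at
# fixed lambda_2 (incompressibility absorbed into lambda_3).
fd_stress_diff <- function(l1, l2, params, h = 1e-6) {
  d1 <- (energy_2d(l1 + h, l2, params) - energy_2d(l1 - h, l2, params)) / (2 * h)
  d2 <- (energy_2d(l1, l2 + h, params) - energy_2d(l1, l2 - h, params)) / (2 * h)
  c(l1 * d1, l2 * d2)
}

# Uniaxial nominal stress by brute-force energy minimization over the
# transverse stretch (independent of the equilibrium solver): minimizes
# W(lam_ax, x) over x and differentiates the minimized energy numerically.
minimized_energy <- function(lam_ax, params, axis = 1L) {
  obj <- function(x) {
    if (axis == 1L) energy_2d(lam_ax, x, params)
    else energy_2d(x, lam_ax, params)
  }
  stats::optimize(obj, c(0.2, 2), tol = 1e-12)$objective
}

oracle_uniaxial_nominal <- function(lam_ax, params, axis = 1L, h = 1e-5) {
  # P = dW_min/dlambda (nominal stress conjugate to the axial stretch)
  (minimized_energy(lam_ax + h, params, axis) -
     minimized_energy(lam_ax - h, params, axis)) / (2 * h)
}

# Loop-coded uniform-grid second-order finite-difference helicity oracle.
oracle_helicity <- function(x, y, z, u, v, w) {
  nx <- length(x); ny <- length(y); nz <- length(z)
  hx <- x[2] - x[1]; hy <- y[2] - y[1]; hz <- z[2] - z[1]
  d <- function(f, axis, i, j, k) {
    n <- switch(axis, nx, ny, nz)
    h <- switch(axis, hx, hy, hz)
    idx <- switch(axis, i, j, k)
    at <- function(m) switch(axis, f[m, j, k], f[i, m, k], f[i, j, m])
    if (idx == 1) (-3 * at(1) + 4 * at(2) - at(3)) / (2 * h)
    else if (idx == n) (3 * at(n) - 4 * at(n - 1) + at(n - 2)) / (2 * h)
    else (at(idx + 1) - at(idx - 1)) / (2 * h)
  }
  he <- array(NA_real_, c(nx, ny, nz))
  for (i in seq_len(nx)) for (j in seq_len(ny)) for (k in seq_len(nz)) {
    wx <- d(w, 2, i, j, k) - d(v, 3, i, j, k)
    wy <- d(u, 3, i, j, k) - d(w, 1, i, j, k)
    wz <- d(v, 1, i, j, k) - d(u, 2, i, j, k)
    he[i, j, k] <- u[i, j, k] * wx + v[i, j, k] * wy + w[i, j, k] * wz
  }
  he
}

# Random incompressible stretch states (moderate deformations).
random_incompressible_states <- function(n, seed = 4L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    l1 <- exp(runif(1, -0.3, 0.3))
    l2 <- exp(runif(1, -0.3, 0.3))
    c(l1, l2)
  })
}

silicone <- reference_material("silicone")
porcine <- reference_material("porcine")
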