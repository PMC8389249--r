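test_that("inlet waveform satisfies its defining constraints", {
  wf <- make_inlet_waveform()
  ts <- 0.37
  fwd <- integrate(wf$q, 0, ts, rel.tol = 1e-12, subdivisions = 500L)$value
  expect_equal(fwd, 60, tolerance = 1e-9)
  # forward lobe is positive exactly on [0, ts)
  expect_true(all(wf$q(seq(1e-6, ts - 1e-6, length.out = 500)) > 0))
  expect_equal(wf$q(ts), 0, tolerance = 1e-12)
  # minimum equals -10% of the peak (attained mid-backflow)
  expect_equal(min(wf$q(seq(0, 1, 1e-5))), -0.1 * wf$q_max, tolerance = 1e-9)
  expect_equal(max(wf$q(seq(0, 1, 1e-5))), wf$q_max, tolerance = 1e-6)
  # no backflow lobe -> nonnegative everywhere
  wf0 <- make_inlet_waveform(backflow_fraction = 0)
  expect_true(all(wf0$q(seq(0, 1, 1e-4)) >= 0))
  expect_error(make_inlet_waveform(systolic_fraction = 0.99,
                                   backflow_duration = 0.5), "infeasible")
})

test_that("waveform series tiles periodically", {
  wf <- make_inlet_waveform()
  s1 <- gen_waveform_series(wf, n_cycles = 1L, dt = 1e-3)
  s5 <- gen_waveform_series(wf, n_cycles = 5L, dt = 1e-3)
  expect_equal(s5$q[seq_len(nrow(s1))], s1$q)
  net1 <- sum(s1$q[-1] + s1$q[-nrow(s1)]) / 2 * 1e-3
  net5 <- sum(s5$q[-1] + s5$q[-nrow(s5)]) / 2 * 1e-3
  expect_equal(net5, 5 * net1, tolerance = 1e-9)
  # halving dt reproduces the shared samples exactly
  fine <- gen_waveform_series(wf, n_cycles = 1L, dt = 5e-4)
  expect_equal(fine$q[seq(1, nrow(fine), by = 2)], s1$q)
  expect_error(gen_waveform_series(wf, dt = 3e-4), "divide")
})

test_that("peak timing is exact for canonical pulses", {
  t <- seq(0, 1, by = 5e-3)
  tri <- pmax(0, 1 - abs(t - 0.18) / 0.1)
  expect_equal(peak_time(t, tri), 0.18, tolerance = 1e-12)
  t2 <- seq(0, 1, 1e-4)
  expect_equal(peak_time(t2, sin(2 * pi * t2)), 0.25, tolerance = 1e-6)
  wf <- make_inlet_waveform()
  expect_equal(peak_time(wf$samples$t, wf$samples$q), 0.37 / 2,
               tolerance = 1e-6)
  expect_error(peak_time(t2, rep(1, length(t2))), "constant")
})

test_that("Poiseuille flow has zero helicity", {
  f <- gen_velocity_field("poiseuille", params = list(u_mean = 0.3, R = 0.015),
                          grid = list(n = c(33L, 33L, 7L), half_width = 0.016,
                                      length_z = 0.05))
  he <- helicity(f)$values
  expect_lt(max(abs(he), na.rm = TRUE), 1e-12)
})

test_that("solid-body rotation with axial drift has helicity 2*omega*w", {
  f <- gen_velocity_field("solid_rotation_axial",
                          params = list(omega = 4, w0 = 0.6),
                          grid = list(n = c(17L, 19L, 7L), half_width = 0.02,
                                      length_z = 0.05))
  he <- helicity(f)$values
  expect_lt(max(abs(he - 2 * 4 * 0.6)), 1e-10)
})

test_that("helicity matches an independently coded finite-difference oracle", {
  n <- 13L
  x <- seq(0, 1, length.out = n)
  X <- array(rep(x, n * n), c(n, n, n))
  Y <- aperm(X, c(2, 1, 3)); Z <- aperm(X, c(3, 2, 1))
  u <- sin(2 * pi * Y) * cos(pi * Z)
  v <- cos(2 * pi * X) * sin(pi * Z)
  w <- sin(pi * X) * sin(pi * Y)
  fld <- velocity_field(x, x, x, u, v, w)
  expect_equal(helicity(fld)$values, oracle_helicity(x, x, x, u, v, w),
               tolerance = 1e-12)
})

test_that("helicity converges at second order on a smooth field", {
  err <- vapply(c(17L, 33L, 65L), function(n) {
    x <- seq(0, 1, length.out = n)
    X <- array(rep(x, n * n), c(n, n, n))
    Y <- aperm(X, c(2, 1, 3)); Z <- aperm(X, c(3, 2, 1))
    u <- sin(2 * pi * Y) * cos(pi * Z)
    v <- cos(2 * pi * X) * sin(pi * Z)
    w <- sin(pi * X) * sin(pi * Y)
    he <- helicity(velocity_field(x, x, x, u, v, w))$values
    wx <- pi * sin(pi * X) * cos(pi * Y) - pi * cos(2 * pi * X) * cos(pi * Z)
    wy <- -pi * sin(2 * pi * Y) * sin(pi * Z) - pi * cos(pi * X) * sin(pi * Y)
    wz <- -2 * pi * sin(2 * pi * X) * sin(pi * Z) -
      2 * pi * cos(2 * pi * Y) * cos(pi * Z)
    max(abs(he - (u * wx + v * wy + w * wz)))
  }, numeric(1))
  expect_gt(err[1] / err[2], 3)
  expect_gt(err[2] / err[3], 3)
})

test_that("kinetic energy matches closed forms and scales quadratically", {
  n <- 21L
  x <- seq(-0.02, 0.02, length.out = n)
  z <- seq(0, 0.05, length.out = 5L)
  dims <- c(n, n, 5L)
  one <- array(1 / sqrt(3), dims)
  f <- velocity_field(x, x, z, one, one, one)
  ke <- kinetic_energy(f, fluid_properties(density = 1025))
  expect_equal(ke$mean_density, 512.5, tolerance = 1e-12)
  zero <- velocity_field(x, x, z, 0 * one, 0 * one, 0 * one)
  expect_equal(kinetic_energy(zero)$total, 0)
  # quadratic scaling is exact
  f3 <- velocity_field(x, x, z, 3 * one, 3 * one, 3 * one)
  expect_equal(kinetic_energy(f3)$total, 9 * ke$total, tolerance = 1e-14)
  # Poiseuille: mean density (2/3) rho ubar^2 on a resolved grid
  fp <- gen_velocity_field("poiseuille", params = list(u_mean = 0.3, R = 0.015),
                           grid = list(n = c(81L, 81L, 5L), half_width = 0.016,
                                       length_z = 0.05))
  kep <- kinetic_energy(fp)
  expect_equal(kep$mean_density, 2 / 3 * 1025 * 0.3^2, tolerance = 5e-3)
})

test_that("normalized profiles behave for uniform, Poiseuille and sheared flow", {
  n <- 41L
  x <- seq(-0.02, 0.02, length.out = n)
  z <- seq(0, 0.05, length.out = 5L)
  dims <- c(n, n, 5L)
  unif <- velocity_field(x, x, z, array(0, dims), array(0, dims),
                         array(0.4, dims))
  pu <- normalized_profile(unif)
  expect_equal(pu$profile$u_norm, rep(1, n), tolerance = 1e-12)
  expect_equal(pu$peak_ratio, 1, tolerance = 1e-12)

  fp <- gen_velocity_field("poiseuille", params = list(u_mean = 0.3, R = 0.015),
                           grid = list(n = c(81L, 81L, 5L), half_width = 0.016,
                                       length_z = 0.05))
  pp <- normalized_profile(fp)
  expect_equal(pp$peak_ratio, 2, tolerance = 2e-2)

  # skewed flow: uniform + linear shear; trapezoid mean is exact
  X <- array(rep(x, n), c(n, n))
  w <- array(0.4, dims) + array(rep(5 * X, 5L), dims)
  sk <- velocity_field(x, x, z, array(0, dims), array(0, dims), w)
  ps <- normalized_profile(sk)
  expect_equal(ps$U_bar, 0.4, tolerance = 1e-8)
  expect_error(normalized_profile(
    velocity_field(x, x, z, array(0, dims), array(0, dims), array(0.4, dims),
                   mask = array(FALSE, dims))), "mask")
})
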