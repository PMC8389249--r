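test_that("curve averaging is the identity on one curve and linear in stress", {
  g <- seq(0.05, 1, length.out = 20)
  c1 <- equibiaxial_response(silicone, g)
  expect_equal(average_curves(list(c1))$stress, c1$stress)
  c3 <- stress_strain_curve(g, 3 * c1$stress, mode = "equibiaxial")
  avg <- average_curves(list(c1, c3), g)
  expect_equal(avg$stress, 2 * c1$stress, tolerance = 1e-12)
  expect_error(average_curves(list(c1,
    stress_strain_curve(g, c1$stress, mode = "uniaxial-circumferential"))),
    "mixed")
  expect_error(average_curves(list(c1), seq(0, 2, 0.1)), "span")
})

test_that("averaging noisy replicates recovers the generator curve", {
  curves <- gen_mechanical_tests(silicone, "equibiaxial",
                                 noise = noise_spec(0.02, seed = 1, 5))
  truth <- attr(curves, "truth")
  avg <- average_curves(curves)
  # direct recomputation oracle: interpolate-and-mean done by hand
  S <- vapply(curves, function(cv)
    approx(cv$strain, cv$stress, xout = truth$strain)$y,
    numeric(nrow(truth)))
  expect_equal(avg$stress, rowMeans(S), tolerance = 1e-12)
  # with sd 0.02 and 5 replicates the standard error is 0.894%; require
  # every point within 3 standard errors and 1% on average
  rel <- abs(avg$stress / truth$stress - 1)
  expect_lt(max(rel), 3 * 0.02 / sqrt(5))
  expect_lt(mean(rel), 0.01)
})

test_that("Ogden fit recovers generating parameters from noise-free data", {
  g <- seq(0.02, 1, length.out = 50)
  crv <- equibiaxial_response(silicone, g)
  fit <- fit_ogden(crv)
  expect_true(fit$converged)
  expect_equal(fit$params$mu, 1.73e-1, tolerance = 1e-3)
  expect_equal(fit$params$alpha, 4.39, tolerance = 1e-3)
  expect_lt(fit$residual, 1e-10)
  # doubling all stresses doubles mu and leaves alpha unchanged
  dbl <- fit_ogden(stress_strain_curve(g, 2 * crv$stress,
                                       mode = "equibiaxial"))
  expect_equal(dbl$params$mu, 2 * fit$params$mu, tolerance = 1e-6)
  expect_equal(dbl$params$alpha, fit$params$alpha, tolerance = 1e-6)
  expect_error(fit_ogden(stress_strain_curve(g, rep(0, 50),
                                             mode = "equibiaxial")),
               "degenerate")
})

test_that("Ogden fit is robust to multiplicative noise (Monte Carlo)", {
  g <- seq(0.02, 1, length.out = 30)
  truth <- equibiaxial_response(silicone, g)
  set.seed(11)
  errs <- replicate(100, {
    noisy <- stress_strain_curve(g, truth$stress * rlnorm(30, 0, 0.02),
                                 mode = "equibiaxial")
    fit <- fit_ogden(noisy, n_starts = 4L)
    c(abs(fit$params$mu / 0.173 - 1), abs(fit$params$alpha / 4.39 - 1))
  })
  expect_lt(median(errs[1, ]), 0.05)
  expect_lt(median(errs[2, ]), 0.05)
})

test_that("HGO fit recovers generating parameters with kappa, theta fixed", {
  g <- seq(0.02, 1, length.out = 40)
  circ <- uniaxial_response(porcine, g, "circumferential")
  long <- uniaxial_response(porcine, g, "longitudinal")
  fit <- fit_hgo(circ, long, fixed = list(kappa = 0.25, theta = 27))
  expect_true(fit$converged)
  expect_setequal(fit$fixed_params, c("kappa", "theta"))
  expect_equal(fit$params$C, 2.89e-2, tolerance = 1e-3)
  expect_equal(fit$params$k1, 1.20e-1, tolerance = 1e-3)
  expect_equal(fit$params$k2, 0.4, tolerance = 1e-3)
  expect_lt(fit$residual, 1e-8)
})

test_that("HGO fit drives k1 to zero on isotropic data", {
  iso <- hgo_params(C = 0.0289, k1 = 0, k2 = 0.4, kappa = 0.25, theta = 27)
  g <- seq(0.05, 1, length.out = 25)
  circ <- uniaxial_response(iso, g, "circumferential")
  long <- uniaxial_response(iso, g, "longitudinal")
  fit <- fit_hgo(circ, long, fixed = list(kappa = 0.25, theta = 27),
                 n_starts = 8L)
  expect_lt(fit$params$k1, 1e-4)
})

test_that("freeing all five HGO parameters can only lower the residual", {
  g <- seq(0.05, 1, length.out = 15)
  circ <- uniaxial_response(porcine, g, "circumferential")
  long <- uniaxial_response(porcine, g, "longitudinal")
  fixed <- fit_hgo(circ, long, fixed = list(kappa = 0.25, theta = 27),
                   n_starts = 4L)
  expect_warning(
    free <- fit_hgo(circ, long, fixed = list(), n_starts = 4L),
    "identifiable")
  expect_lte(free$residual, fixed$residual + 1e-12)
  expect_true(isTRUE(free$identifiability_warning))
})

test_that("fits are deterministic and more starts never hurt", {
  g <- seq(0.02, 1, length.out = 30)
  crv <- equibiaxial_response(silicone, g)
  f1 <- fit_ogden(crv)
  f2 <- fit_ogden(crv)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$residual, f2$residual)
  few <- fit_ogden(crv, n_starts = 4L)
  many <- fit_ogden(crv, n_starts = 16L)
  expect_lte(many$residual, few$residual + 1e-15)
})

test_that("fit results serialize to JSON with parameters and provenance", {
  g <- seq(0.02, 1, length.out = 20)
  fit <- fit_ogden(equibiaxial_response(silicone, g))
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path, seed = 7)
  obj <- jsonlite::read_json(path)
  expect_equal(obj$model, "ogden_params")
  expect_equal(obj$params$mu, fit$params$mu, tolerance = 1e-12)
  expect_equal(obj$seed, 7)
})
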