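#' Noise specification for synthetic mechanical tests
#'
#' Multiplicative lognormal noise applied to generated stress curves, a
#' stand-in for sample-to-sample spread in mechanical testing (errors scale
#' with load).
#'
#' @param multiplicative_sd Standard deviation of the lognormal multiplier
#'   (log scale), default 0.02.
#' @param seed Integer RNG seed.
#' @param n_replicates Number of replicate samples.
#' @return An object of class `"noise_spec"`.
#' @export
noise_spec <- function(multiplicative_sd = 0.02, seed = 1L,
                       n_replicates = 1L) {
  stopifnot(multiplicative_sd >= 0, n_replicates >= 1)
  structure(list(multiplicative_sd = multiplicative_sd,
                 seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates)),
            class = "noise_spec")
}

#' Generate synthetic mechanical-test curves
#'
#' Evaluates the exact forward stress response of a material on a uniform
#' strain grid and multiplies each replicate pointwise by lognormal noise,
#' emulating replicate tensile or biaxial test samples. Deformations up to
#' 100% engineering strain match the test protocol; replicate counts of 5
#' (biaxial) and 4 (uniaxial) mirror the experimental sample counts.
#'
#' @param material A `material_params` object.
#' @param mode `"uniaxial-circumferential"`, `"uniaxial-longitudinal"` or
#'   `"equibiaxial"`.
#' @param strain_max Largest engineering strain, default 1 (100%).
#' @param n_points Grid points, default 50.
#' @param noise A [noise_spec()]; `multiplicative_sd = 0` reproduces the
#'   forward model in every replicate.
#' @return List of [stress_strain_curve()] objects (one per replicate) with
#'   attribute `"truth"` holding the noise-free curve.
#' @examples
#' curves <- gen_mechanical_tests(reference_material("silicone"),
#'                                "equibiaxial", noise = noise_spec(0.02, 7, 5))
#' @export
gen_mechanical_tests <- function(material,
                                 mode = c("equibiaxial",
                                          "uniaxial-circumferential",
                                          "uniaxial-longitudinal"),
                                 strain_max = 1.0, n_points = 50L,
                                 noise = noise_spec()) {
  mode <- match.arg(mode)
  stopifnot(inherits(noise, "noise_spec"), strain_max > 0, n_points >= 3L)
  # start just off zero so every point is informative for fitting
  grid <- seq(strain_max / n_points, strain_max, length.out = n_points)
  truth <- switch(mode,
    "equibiaxial" = equibiaxial_response(material, grid, label = "truth"),
    "uniaxial-circumferential" =
      uniaxial_response(material, grid, "circumferential", label = "truth"),
    "uniaxial-longitudinal" =
      uniaxial_response(material, grid, "longitudinal", label = "truth"))
  out <- withr_seed(noise$seed, {
    lapply(seq_len(noise$n_replicates), function(i) {
      fac <- if (noise$multiplicative_sd > 0)
        stats::rlnorm(n_points, meanlog = 0, sdlog = noise$multiplicative_sd)
      else rep(1, n_points)
      stress_strain_curve(grid, truth$stress * fac, mode = mode,
                          label = sprintf("replicate-%d", i))
    })
  })
  attr(out, "truth") <- truth
  out
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards so generators are pure functions of the seed.
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate analytic velocity fields
#'
#' Exact evaluation of reference flows on a rectilinear grid, used as test
#' substrates for the flow metrics:
#' * `"poiseuille"`: axial parabolic pipe flow `w = 2 u_mean (1 - r^2/R^2)`
#'   inside a circular mask of radius `R` about the z axis.
#' * `"solid_rotation_axial"`: solid-body rotation at angular rate `omega`
#'   about z superposed on uniform axial velocity `w0` (helicity
#'   `2 omega w0` everywhere).
#' * `"superposition"`: pointwise sum of two generated fields on the same
#'   grid (mask = intersection).
#'
#' @param kind Field kind; see Details.
#' @param params Named list of parameters: `u_mean`, `R` (poiseuille);
#'   `omega`, `w0`, optional `R` (solid rotation); `a`, `b` (superposition:
#'   two `velocity_field` objects).
#' @param grid List with `n` (nodes per axis, length 3) and `half_width`
#'   (m) for the x-y extent and `length_z` (m); or explicit `x`, `y`, `z`
#'   vectors.
#' @return A [velocity_field()].
#' @export
gen_velocity_field <- function(kind = c("poiseuille", "solid_rotation_axial",
                                        "superposition"),
                               params = list(),
                               grid = list(n = c(33L, 33L, 9L),
                                           half_width = 0.02,
                                           length_z = 0.05)) {
  kind <- match.arg(kind)
  if (kind == "superposition") {
    a <- params$a; b <- params$b
    stopifnot(inherits(a, "velocity_field"), inherits(b, "velocity_field"))
    if (!isTRUE(all.equal(a$x, b$x)) || !isTRUE(all.equal(a$y, b$y)) ||
        !isTRUE(all.equal(a$z, b$z)))
      stop("superposed fields must share a grid")
    return(velocity_field(a$x, a$y, a$z, a$u + b$u, a$v + b$v, a$w + b$w,
                          mask = a$mask & b$mask, time = a$time))
  }
  if (!is.null(grid$x)) {
    x <- grid$x; y <- grid$y; z <- grid$z
  } else {
    x <- seq(-grid$half_width, grid$half_width, length.out = grid$n[1L])
    y <- seq(-grid$half_width, grid$half_width, length.out = grid$n[2L])
    z <- seq(0, grid$length_z, length.out = grid$n[3L])
  }
  dims <- c(length(x), length(y), length(z))
  X <- array(rep(x, times = dims[2L] * dims[3L]), dims)
  Y <- array(rep(rep(y, each = dims[1L]), times = dims[3L]), dims)
  r2 <- X^2 + Y^2
  zero <- array(0, dims)
  if (kind == "poiseuille") {
    u_mean <- params$u_mean %||% 0.2
    R <- params$R %||% (0.95 * max(abs(x)))
    w <- 2 * u_mean * pmax(1 - r2 / R^2, 0)
    dim(w) <- dims
    mask <- array(r2 <= R^2, dims)
    return(velocity_field(x, y, z, zero, zero, w, mask = mask))
  }
  # solid_rotation_axial
  omega <- params$omega %||% 1
  w0 <- params$w0 %||% 0
  u <- -omega * Y
  v <- omega * X
  w <- array(w0, dims)
  mask <- if (!is.null(params$R)) array(r2 <= params$R^2, dims) else NULL
  velocity_field(x, y, z, u, v, w, mask = mask)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
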