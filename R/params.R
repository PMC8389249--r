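#' Constitutive parameters for the one-term Ogden model
#'
#' Constructs a validated parameter set for the one-term (reduced-polynomial
#' normalization) Ogden hyperelastic model,
#' \deqn{W = \frac{2\mu}{\alpha^2}\left(\lambda_1^\alpha + \lambda_2^\alpha +
#'   \lambda_3^\alpha - 3\right) + \frac{1}{D}(J - 1)^2,}
#' where \eqn{\mu} is the small-strain shear modulus, \eqn{\alpha} the
#' strain-hardening exponent and \eqn{D} a compressibility parameter. With
#' this normalization \eqn{\mu} equals the shear modulus of the
#' linearized material for any \eqn{\alpha}.
#'
#' @param mu Shear-like modulus (MPa), must be positive.
#' @param alpha Strain-hardening exponent (dimensionless), must be nonzero.
#' @param D Compressibility parameter (MPa^-1), must be positive. Carried for
#'   completeness; it does not enter incompressible (J = 1) responses.
#' @return An object of class `c("ogden_params", "material_params")`.
#' @examples
#' silicone <- ogden_params(mu = 0.173, alpha = 4.39, D = 1.193)
#' @export
ogden_params <- function(mu, alpha, D = 1) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(D), length(D) == 1L, is.finite(D))
  if (mu <= 0) stop("'mu' must be positive (MPa)")
  if (alpha == 0) stop("'alpha' must be nonzero")
  if (D <= 0) stop("'D' must be positive (MPa^-1)")
  structure(list(mu = mu, alpha = alpha, D = D),
            class = c("ogden_params", "material_params"))
}

#' Constitutive parameters for the Holzapfel-Gasser-Ogden (HGO) model
#'
#' Constructs a validated parameter set for the fiber-reinforced anisotropic
#' hyperelastic model of arterial tissue: an isotropic neo-Hookean matrix plus
#' `n_families` dispersed collagen-fiber families with exponential stiffening,
#' \deqn{W = C(I_1 - 3) + \frac{1}{D}\left(\frac{J^2-1}{2} - \ln J\right) +
#'   \frac{k_1}{2 k_2}\sum_{a=1}^{N}\left\{\exp\left[k_2\langle \bar E_a
#'   \rangle^2\right] - 1\right\},}
#' \deqn{\bar E_a = \kappa (I_1 - 3) + (1 - 3\kappa)(I_{4(aa)} - 1).}
#' The Macaulay bracket \eqn{\langle x \rangle = \max(x, 0)} switches fibers
#' off in compression. The two fiber families lie in the
#' circumferential-longitudinal sheet plane at \eqn{\pm\theta} about the
#' circumferential axis.
#'
#' @param C Matrix stiffness (MPa); the matrix small-strain shear modulus is
#'   `2 * C`. Must be positive.
#' @param k1 Fiber stiffness (MPa), nonnegative.
#' @param k2 Fiber uncrimping exponent (dimensionless), positive.
#' @param kappa Fiber-dispersion parameter in `[0, 1/3]`; 0 is perfectly
#'   aligned fibers, 1/3 is an isotropic fiber distribution.
#' @param theta Mean fiber angle from the circumferential axis (degrees), in
#'   `[0, 90]`.
#' @param D Compressibility parameter (MPa^-1), positive; does not enter
#'   incompressible responses.
#' @param n_families Number of fiber bundles; only the symmetric two-family
#'   arrangement is supported.
#' @return An object of class `c("hgo_params", "material_params")`.
#' @examples
#' porcine <- hgo_params(C = 0.0289, k1 = 0.12, k2 = 0.4,
#'                       kappa = 0.25, theta = 27, D = 0.7)
#' @export
hgo_params <- function(C, k1, k2, kappa, theta, D = 1, n_families = 2L) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  stopifnot(num1(C), num1(k1), num1(k2), num1(kappa), num1(theta), num1(D))
  if (C <= 0) stop("'C' must be positive (MPa)")
  if (k1 < 0) stop("'k1' must be nonnegative (MPa)")
  if (k2 <= 0) stop("'k2' must be positive")
  if (kappa < 0 || kappa > 1 / 3) stop("'kappa' must lie in [0, 1/3]")
  if (theta < 0 || theta > 90) stop("'theta' must lie in [0, 90] degrees")
  if (D <= 0) stop("'D' must be positive (MPa^-1)")
  if (n_families != 2L) stop("only two symmetric fiber families are supported")
  structure(list(C = C, k1 = k1, k2 = k2, kappa = kappa, theta = theta,
                 D = D, n_families = 2L),
            class = c("hgo_params", "material_params"))
}

#' @export
print.ogden_params <- function(x, ...) {
  cat("One-term Ogden hyperelastic material\n")
  cat(sprintf("  mu    = %.6g MPa (small-strain shear modulus)\n", x$mu))
  cat(sprintf("  alpha = %.6g\n", x$alpha))
  cat(sprintf("  D     = %.6g MPa^-1\n", x$D))
  invisible(x)
}

#' @export
print.hgo_params <- function(x, ...) {
  cat("Holzapfel-Gasser-Ogden fiber-reinforced material\n")
  cat(sprintf("  C     = %.6g MPa (matrix; shear modulus 2C = %.6g MPa)\n",
              x$C, 2 * x$C))
  cat(sprintf("  k1    = %.6g MPa, k2 = %.6g\n", x$k1, x$k2))
  cat(sprintf("  kappa = %.6g, theta = %.6g deg (2 families at +/-theta)\n",
              x$kappa, x$theta))
  cat(sprintf("  D     = %.6g MPa^-1\n", x$D))
  invisible(x)
}

#' Table of published calibrated materials
#'
#' Returns the calibrated parameter sets for the PROCHIMA Cristal Rubber
#' silicone (Ogden) and the porcine aortic tissue (HGO) used as the default
#' phantom wall materials.
#'
#' @param which `"silicone"` (Ogden) or `"porcine"` (HGO).
#' @return A `material_params` object.
#' @export
reference_material <- function(which = c("silicone", "porcine")) {
  which <- match.arg(which)
  switch(which,
         silicone = ogden_params(mu = 1.73e-1, alpha = 4.39, D = 1.193),
         porcine  = hgo_params(C = 2.89e-2, k1 = 1.20e-1, k2 = 0.4,
                               kappa = 0.25, theta = 27, D = 0.7))
}

#' Read and write material parameter files
#'
#' Flat key-value files in Debian-control (DCF) format. Keys: `model`
#' (`ogden` or `hgo`) plus the parameter names of [ogden_params()] /
#' [hgo_params()] (`theta_deg` is accepted as an alias for `theta`).
#' Units are MPa for moduli, MPa^-1 for `D`, degrees for `theta`.
#'
#' @param path File path.
#' @return `read_material()` returns a `material_params` object;
#'   `write_material()` returns `path` invisibly.
#' @export
read_material <- function(path) {
  if (!file.exists(path)) stop("material file not found: ", path)
  rec <- as.list(as.data.frame(read.dcf(path), stringsAsFactors = FALSE))
  names(rec) <- tolower(names(rec))
  if (is.null(rec$model)) stop("material file must declare 'model: ogden|hgo'")
  num <- function(key, default = NULL) {
    if (is.null(rec[[key]])) {
      if (is.null(default)) stop("missing key '", key, "' in ", path)
      return(default)
    }
    as.numeric(rec[[key]])
  }
  model <- tolower(trimws(rec$model))
  if (model == "ogden") {
    ogden_params(mu = num("mu"), alpha = num("alpha"), D = num("d", 1))
  } else if (model == "hgo") {
    theta <- if (!is.null(rec$theta_deg)) as.numeric(rec$theta_deg) else num("theta")
    hgo_params(C = num("c"), k1 = num("k1"), k2 = num("k2"),
               kappa = num("kappa"), theta = theta, D = num("d", 1))
  } else {
    stop("unknown model '", model, "' (expected 'ogden' or 'hgo')")
  }
}

#' @rdname read_material
#' @param params A `material_params` object to serialize.
#' @export
write_material <- function(params, path) {
  stopifnot(inherits(params, "material_params"))
  if (inherits(params, "ogden_params")) {
    m <- cbind(model = "ogden", mu = params$mu, alpha = params$alpha,
               D = params$D)
  } else {
    m <- cbind(model = "hgo", C = params$C, k1 = params$k1, k2 = params$k2,
               kappa = params$kappa, theta_deg = params$theta, D = params$D)
  }
  write.dcf(m, path)
  invisible(path)
}
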