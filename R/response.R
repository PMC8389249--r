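#' Stress-strain curve container
#'
#' One mechanical test record: an engineering-strain grid and the matching
#' nominal (first Piola-Kirchhoff) stress grid, with the test mode.
#'
#' @param strain Engineering strain grid (dimensionless, >= 0, strictly
#'   increasing).
#' @param stress Nominal stress grid (MPa, same length).
#' @param mode One of `"uniaxial-circumferential"`, `"uniaxial-longitudinal"`,
#'   `"equibiaxial"`.
#' @param label Free-text sample identifier.
#' @return A data.frame of class `"stress_strain_curve"` with columns
#'   `strain`, `stress` and attributes `mode`, `label`.
#' @export
stress_strain_curve <- function(strain, stress,
                                mode = c("uniaxial-circumferential",
                                         "uniaxial-longitudinal",
                                         "equibiaxial"),
                                label = "") {
  mode <- match.arg(mode)
  strain <- as.numeric(strain)
  stress <- as.numeric(stress)
  if (length(strain) != length(stress))
    stop("'strain' and 'stress' must have the same length")
  if (length(strain) < 3L) stop("a curve needs at least 3 points")
  if (any(!is.finite(strain)) || any(!is.finite(stress)))
    stop("non-finite values in curve")
  if (strain[1] < 0) stop("strains must be nonnegative")
  if (any(diff(strain) <= 0)) stop("'strain' must be strictly increasing")
  out <- data.frame(strain = strain, stress = stress)
  attr(out, "mode") <- mode
  attr(out, "label") <- label
  class(out) <- c("stress_strain_curve", "data.frame")
  out
}

curve_mode <- function(curve) attr(curve, "mode")

#' @export
print.stress_strain_curve <- function(x, ...) {
  cat(sprintf("Stress-strain curve [%s]%s: %d points, strain %.3g..%.3g, max stress %.4g MPa\n",
              attr(x, "mode"),
              if (nzchar(attr(x, "label"))) paste0(" '", attr(x, "label"), "'") else "",
              nrow(x), min(x$strain), max(x$strain), max(x$stress)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Transverse equilibrium for uniaxial loading of an incompressible material.
#
# Loading along principal axis `axis` with stretch lam_ax; the two transverse
# stretches are reduced to one unknown x through J = 1 and found from zero
# transverse Cauchy stress. For anisotropic materials the two transverse
# stretches differ; the in-sheet transverse axis is the other of (circ, long)
# and the radial axis is 3.
#
# Returns the 3 x n stretch matrix. Vectorized damped Newton with a uniroot
# fallback; residual tolerance 1e-10 relative to the material stress scale.
solve_uniaxial_kinematics <- function(lambda_ax, params, axis = 1L,
                                      tol = 1e-10, max_iter = 60L) {
  n <- length(lambda_ax)
  trans <- if (axis == 1L) 2L else 1L     # in-sheet transverse axis
  build <- function(x) {
    lam <- matrix(0, 3L, n)
    lam[axis, ] <- lambda_ax
    lam[trans, ] <- x
    lam[3L, ] <- 1 / (lambda_ax * x)
    lam
  }
  # residual: sigma_trans - sigma_radial = t_trans - t_3
  g <- function(x) {
    t <- principal_extra_stress(build(x), params)
    t[trans, ] - t[3L, ]
  }
  scale_ref <- if (inherits(params, "ogden_params")) params$mu else 2 * params$C
  gtol <- tol * scale_ref + 1e-14

  x <- 1 / sqrt(lambda_ax)                # isotropic guess
  for (it in seq_len(max_iter)) {
    gx <- g(x)
    if (all(abs(gx) <= gtol)) break
    h <- 1e-7 * x
    dg <- (g(x + h) - g(x - h)) / (2 * h)
    step <- gx / dg
    step[!is.finite(step)] <- 0
    # damp: cap the relative step to keep x positive and stable
    step <- sign(step) * pmin(abs(step), 0.2 * x)
    x <- x - step
  }
  bad <- abs(g(x)) > gtol
  if (any(bad)) {
    g1 <- function(xx, la) {
      lam <- numeric(3L)
      lam[axis] <- la; lam[trans] <- xx; lam[3L] <- 1 / (la * xx)
      t <- principal_extra_stress(lam, params)
      t[trans] - t[3L]
    }
    for (i in which(bad)) {
      la <- lambda_ax[i]
      lo <- 1e-3; hi <- max(2, 2 / sqrt(la))
      flo <- g1(lo, la); fhi <- g1(hi, la)
      if (flo * fhi > 0)
        stop("transverse-equilibrium solver failed to bracket a root at ",
             "axial stretch ", format(la), " (residuals ", format(flo), ", ",
             format(fhi), ")")
      x[i] <- uniroot(g1, c(lo, hi), la = la, tol = 1e-14)$root
    }
    if (any(abs(g(x)) > 10 * gtol))
      stop("transverse-equilibrium solver did not reach the requested ",
           "residual tolerance ", format(tol), " (max residual ",
           format(max(abs(g(x)))), " MPa)")
  }
  build(x)
}

#' Uniaxial nominal-stress response
#'
#' Exact incompressible uniaxial response of a hyperelastic material along
#' the circumferential or longitudinal axis. For each engineering strain
#' `eps` the axial stretch is `1 + eps`; the transverse stretches are found
#' by enforcing incompressibility and zero transverse Cauchy stress (they
#' are unequal for fiber-reinforced materials). The returned stress is
#' nominal: `P = sigma / lambda`.
#'
#' @param material An [ogden_params()] or [hgo_params()] object. For HGO the
#'   fiber families lie at `+/-theta` in the circumferential-longitudinal
#'   plane.
#' @param strain_grid Engineering strains, nonnegative and strictly
#'   increasing.
#' @param loading_axis `"circumferential"` or `"longitudinal"`.
#' @param label Curve label.
#' @return A [stress_strain_curve()].
#' @examples
#' uniaxial_response(reference_material("silicone"), seq(0, 1, 0.1))
#' @export
uniaxial_response <- function(material, strain_grid,
                              loading_axis = c("circumferential",
                                               "longitudinal"),
                              label = "") {
  loading_axis <- match.arg(loading_axis)
  strain_grid <- as.numeric(strain_grid)
  if (any(strain_grid < 0)) stop("strains must be nonnegative")
  if (any(diff(strain_grid) <= 0)) stop("strains must be strictly increasing")
  axis <- if (loading_axis == "circumferential") 1L else 2L
  lam_ax <- 1 + strain_grid
  pos <- lam_ax > 1
  P <- numeric(length(lam_ax))
  if (any(pos)) {
    lam <- solve_uniaxial_kinematics(lam_ax[pos], material, axis = axis)
    t <- principal_extra_stress(lam, material)
    sigma <- t[axis, ] - t[3L, ]          # radial traction-free
    P[pos] <- sigma / lam_ax[pos]
  }
  stress_strain_curve(strain_grid, P,
                      mode = paste0("uniaxial-", loading_axis), label = label)
}

#' Equibiaxial nominal-stress response
#'
#' Exact incompressible equibiaxial response: in-plane stretches
#' `lambda1 = lambda2 = 1 + eps`, thickness stretch `(1 + eps)^-2`, zero
#' traction through the thickness. For isotropic materials the two in-plane
#' nominal stresses are equal and that value is returned; for HGO the two
#' directions differ unless `theta = 45` degrees and the mean of the
#' circumferential and longitudinal nominal stresses is returned, with both
#' available in attribute `"by_axis"`.
#'
#' @inheritParams uniaxial_response
#' @return A [stress_strain_curve()] with mode `"equibiaxial"`.
#' @examples
#' equibiaxial_response(reference_material("silicone"), seq(0, 1, 0.1))
#' @export
equibiaxial_response <- function(material, strain_grid, label = "") {
  strain_grid <- as.numeric(strain_grid)
  if (any(strain_grid < 0)) stop("strains must be nonnegative")
  if (any(diff(strain_grid) <= 0)) stop("strains must be strictly increasing")
  lam <- 1 + strain_grid
  lam3 <- lam^-2
  t <- principal_extra_stress(rbind(lam, lam, lam3), material)
  P1 <- (t[1L, ] - t[3L, ]) / lam
  P2 <- (t[2L, ] - t[3L, ]) / lam
  out <- stress_strain_curve(strain_grid, (P1 + P2) / 2,
                             mode = "equibiaxial", label = label)
  attr(out, "by_axis") <- cbind(circumferential = P1, longitudinal = P2)
  out
}

#' Closed-form Ogden uniaxial and equibiaxial nominal stress
#'
#' Reference closed forms for the incompressible one-term Ogden model:
#' uniaxial Cauchy stress `(2 mu / alpha)(lambda^alpha - lambda^(-alpha/2))`
#' and equibiaxial `(2 mu / alpha)(lambda^alpha - lambda^(-2 alpha))`,
#' converted to nominal by dividing by `lambda`.
#'
#' @param params An [ogden_params()].
#' @param strain Engineering strain(s).
#' @param mode `"uniaxial"` or `"equibiaxial"`.
#' @return Nominal stress (MPa).
#' @export
ogden_nominal_closed_form <- function(params, strain,
                                      mode = c("uniaxial", "equibiaxial")) {
  mode <- match.arg(mode)
  lam <- 1 + strain
  a <- params$alpha
  sig <- switch(mode,
                uniaxial    = 2 * params$mu / a * (lam^a - lam^(-a / 2)),
                equibiaxial = 2 * params$mu / a * (lam^a - lam^(-2 * a)))
  sig / lam
}
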