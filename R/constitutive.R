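#' Principal stretch state
#'
#' A homogeneous deformation described by its principal stretches and the
#' volumetric ratio `J`. For incompressible states `J = 1` and
#' `lambda1 * lambda2 * lambda3 = 1` to machine precision.
#'
#' @param lambda1,lambda2,lambda3 Principal stretches (> 0).
#' @param J Volumetric ratio; defaults to `lambda1 * lambda2 * lambda3`.
#' @param incompressible If `TRUE` (default) the product of the stretches is
#'   required to equal `J = 1` within `1e-12`.
#' @return An object of class `"stretch_state"`.
#' @export
stretch_state <- function(lambda1, lambda2, lambda3,
                          J = lambda1 * lambda2 * lambda3,
                          incompressible = TRUE) {
  lam <- c(lambda1, lambda2, lambda3)
  if (!all(is.finite(lam)) || any(lam <= 0))
    stop("principal stretches must be positive and finite")
  if (!is.finite(J) || J <= 0) stop("'J' must be positive")
  if (incompressible) {
    if (abs(prod(lam) - J) > 1e-12 || abs(J - 1) > 1e-12)
      stop("incompressible state requires lambda1*lambda2*lambda3 = J = 1 ",
           "(got product ", format(prod(lam), digits = 15), ")")
  }
  structure(list(lambda = lam, J = J, incompressible = incompressible),
            class = "stretch_state")
}

#' Uniaxial incompressible stretch state
#'
#' Convenience constructor: stretch `lambda` along one axis with the equal
#' transverse contraction `lambda^(-1/2)` that isotropic incompressible
#' materials select.
#'
#' @param lambda Axial stretch (> 0).
#' @return A `"stretch_state"`.
#' @export
uniaxial_state <- function(lambda) {
  stretch_state(lambda, 1 / sqrt(lambda), 1 / sqrt(lambda))
}

#' Equibiaxial incompressible stretch state
#'
#' @param lambda In-plane stretch applied along the first two axes; the third
#'   takes `lambda^-2` by incompressibility.
#' @return A `"stretch_state"`.
#' @export
equibiaxial_state <- function(lambda) {
  stretch_state(lambda, lambda, lambda^-2)
}

# Deviatoric principal stretches lam_i * J^(-1/3); identical to lam at J = 1.
deviatoric_stretches <- function(state) {
  state$lambda * state$J^(-1 / 3)
}

#' Deformation invariants for fiber-reinforced materials
#'
#' Computes the first deviatoric invariant `I1`, the squared fiber stretch
#' `I4` of each fiber family, and the dispersed fiber-strain measure
#' `E_bar = kappa (I1 - 3) + (1 - 3 kappa)(I4 - 1)` that drives the HGO
#' fiber term.
#'
#' @param state A [stretch_state()].
#' @param fiber_directions Matrix with one unit reference direction per row,
#'   expressed in the principal-stretch frame.
#' @param kappa Fiber-dispersion parameter in `[0, 1/3]`.
#' @return List with elements `I1`, `I4` (one per family), `E_bar`.
#' @export
deformation_invariants <- function(state, fiber_directions, kappa) {
  stopifnot(inherits(state, "stretch_state"))
  fiber_directions <- rbind(fiber_directions)
  if (ncol(fiber_directions) != 3L)
    stop("fiber directions must have three components")
  nrm <- sqrt(rowSums(fiber_directions^2))
  if (any(abs(nrm - 1) > 1e-8))
    stop("fiber directions must be unit vectors")
  lam <- deviatoric_stretches(state)
  I1 <- sum(lam^2)
  I4 <- as.numeric(fiber_directions^2 %*% lam^2)
  E_bar <- kappa * (I1 - 3) + (1 - 3 * kappa) * (I4 - 1)
  list(I1 = I1, I4 = I4, E_bar = E_bar)
}

#' Fiber reference directions for two symmetric families
#'
#' Unit vectors at `+/-theta` from the circumferential axis in the
#' circumferential-longitudinal sheet plane. Axis order of the returned
#' vectors is (circumferential, longitudinal, radial).
#'
#' @param theta_deg Mean fiber angle in degrees.
#' @return A 2 x 3 matrix, one direction per row.
#' @export
fiber_directions <- function(theta_deg) {
  th <- theta_deg * pi / 180
  rbind(c(cos(th),  sin(th), 0),
        c(cos(th), -sin(th), 0))
}

#' Ogden strain-energy density
#'
#' Evaluates `W = (2 mu / alpha^2) (lam1^alpha + lam2^alpha + lam3^alpha - 3)
#' + (1/D) (J - 1)^2` at a principal stretch state, using the deviatoric
#' stretches in the isochoric term. Units MPa.
#'
#' @param state A [stretch_state()].
#' @param params An [ogden_params()] object.
#' @return Strain-energy density (MPa).
#' @examples
#' ogden_energy(uniaxial_state(1.5), ogden_params(0.173, 4.39))
#' @export
ogden_energy <- function(state, params) {
  stopifnot(inherits(state, "stretch_state"), inherits(params, "ogden_params"))
  lam <- deviatoric_stretches(state)
  a <- params$alpha
  2 * params$mu / a^2 * (sum(lam^a) - 3) + (state$J - 1)^2 / params$D
}

#' Holzapfel-Gasser-Ogden strain-energy density
#'
#' Evaluates the three-term HGO energy (isotropic matrix, volumetric term,
#' exponential dispersed-fiber term) at a principal stretch state. The
#' Macaulay bracket applied to `E_bar` makes each fiber family contribute
#' only when its strain measure is tensile.
#'
#' @param state A [stretch_state()].
#' @param params An [hgo_params()] object.
#' @param directions Optional 2 x 3 matrix of unit fiber directions in the
#'   principal frame; defaults to [fiber_directions()] at `params$theta`.
#' @return Strain-energy density (MPa).
#' @examples
#' p <- reference_material("porcine")
#' hgo_energy(equibiaxial_state(1.2), p)
#' @export
hgo_energy <- function(state, params, directions = NULL) {
  stopifnot(inherits(state, "stretch_state"), inherits(params, "hgo_params"))
  if (is.null(directions)) directions <- fiber_directions(params$theta)
  inv <- deformation_invariants(state, directions, params$kappa)
  E <- pmax(inv$E_bar, 0)
  J <- state$J
  W_iso <- params$C * (inv$I1 - 3)
  W_vol <- ((J^2 - 1) / 2 - log(J)) / params$D
  W_fib <- params$k1 / (2 * params$k2) * sum(exp(params$k2 * E^2) - 1)
  W_iso + W_vol + W_fib
}

#' Strain-energy density (generic)
#'
#' Dispatches to [ogden_energy()] or [hgo_energy()] on the material class.
#'
#' @param state A [stretch_state()].
#' @param params A `material_params` object.
#' @param ... Passed on to the model-specific method.
#' @return Strain-energy density (MPa).
#' @export
strain_energy <- function(state, params, ...) {
  if (inherits(params, "ogden_params")) return(ogden_energy(state, params))
  if (inherits(params, "hgo_params")) return(hgo_energy(state, params, ...))
  stop("unsupported material class: ", paste(class(params), collapse = "/"))
}

# ---------------------------------------------------------------------------
# Principal Cauchy stresses (incompressible, up to the pressure Lagrange
# multiplier). Returns the "extra" stress t_i = lam_i dW/dlam_i so that
# sigma_i = t_i - p; only differences t_i - t_j are physical.
#
# lam: 3 x n matrix of principal stretches (columns are states, J = 1).
# Axis convention for HGO: 1 = circumferential, 2 = longitudinal, 3 = radial,
# with the fiber families in the 1-2 plane.
principal_extra_stress <- function(lam, params) {
  lam <- matrix(lam, nrow = 3L)
  if (inherits(params, "ogden_params")) {
    a <- params$alpha
    return(2 * params$mu / a * lam^a)
  }
  if (!inherits(params, "hgo_params"))
    stop("unsupported material class")
  th <- params$theta * pi / 180
  a2 <- c(cos(th)^2, sin(th)^2, 0)        # squared direction cosines
  I1 <- colSums(lam^2)
  I4 <- colSums(lam^2 * a2)               # identical for the +/- families
  E <- params$kappa * (I1 - 3) + (1 - 3 * params$kappa) * (I4 - 1)
  E <- pmax(E, 0)
  g <- params$k1 * exp(params$k2 * E^2) * E     # dW_fib/dE_bar per family
  W1 <- params$C + 2 * g * params$kappa         # both families through I1
  W4 <- g * (1 - 3 * params$kappa)              # per family
  t_iso <- 2 * rep(W1, each = 3L) * lam^2
  t_fib <- 2 * 2 * rep(W4, each = 3L) * lam^2 * a2   # two identical families
  t_iso + t_fib
}
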