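#' Structured-grid velocity field
#'
#' A velocity snapshot on a rectilinear grid: coordinate vectors per axis
#' (m), three velocity component arrays (m/s) of dimension
#' `c(length(x), length(y), length(z))`, and an optional in-domain mask.
#'
#' @param x,y,z Strictly increasing coordinate vectors (m).
#' @param u,v,w Velocity component arrays (m/s), dim `c(nx, ny, nz)`.
#' @param mask Logical array of the same dimension; `FALSE` nodes are
#'   excluded from all statistics. Default: all in-domain.
#' @param time Snapshot time (s).
#' @return An object of class `"velocity_field"`.
#' @export
velocity_field <- function(x, y, z, u, v, w, mask = NULL, time = 0) {
  dims <- c(length(x), length(y), length(z))
  if (any(dims < 2L)) stop("each axis needs at least 2 nodes")
  for (co in list(x, y, z))
    if (any(diff(co) <= 0)) stop("coordinates must be strictly increasing")
  for (comp in list(u, v, w))
    if (!identical(dim(comp), as.integer(dims)))
      stop("velocity arrays must have dim c(nx, ny, nz) = c(",
           paste(dims, collapse = ", "), ")")
  if (is.null(mask)) mask <- array(TRUE, dims)
  if (!identical(dim(mask), as.integer(dims)))
    stop("mask must conform to the grid")
  structure(list(x = x, y = y, z = z, u = u, v = v, w = w,
                 mask = mask, time = time),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("Velocity field %d x %d x %d (%d masked-in nodes), t = %g s\n",
              length(x$x), length(x$y), length(x$z), sum(x$mask), x$time))
  invisible(x)
}

# Second-order partial derivative of a 3D array along one axis of a
# rectilinear grid: three-point centered stencil in the interior (exact for
# quadratics, also on nonuniform spacing) and one-sided three-point
# second-order stencils at the two boundaries.
fd_partial <- function(f, coords, axis) {
  n <- length(coords)
  if (n < 3L) stop("need at least 3 nodes per axis for derivatives")
  if (min(diff(coords)) <= 0) stop("degenerate grid spacing")
  perm <- switch(axis, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L),
                 `3` = c(3L, 1L, 2L))
  fa <- aperm(f, perm)
  d <- dim(fa)
  m <- matrix(fa, nrow = d[1L])
  out <- matrix(0, nrow = d[1L], ncol = ncol(m))
  h1 <- coords[2:(n - 1)] - coords[1:(n - 2)]
  h2 <- coords[3:n] - coords[2:(n - 1)]
  # interior weights for nonuniform centered differences
  wm <- -h2 / (h1 * (h1 + h2))
  wc <- (h2 - h1) / (h1 * h2)
  wp <- h1 / (h2 * (h1 + h2))
  out[2:(n - 1), ] <- wm * m[1:(n - 2), ] + wc * m[2:(n - 1), ] +
    wp * m[3:n, ]
  # one-sided second-order ends
  a <- coords[2] - coords[1]; b <- coords[3] - coords[1]
  out[1L, ] <- (-(a + b) / (a * b)) * m[1L, ] +
    (b / (a * (b - a))) * m[2L, ] + (-a / (b * (b - a))) * m[3L, ]
  a <- coords[n] - coords[n - 1]; b <- coords[n] - coords[n - 2]
  out[n, ] <- ((a + b) / (a * b)) * m[n, ] +
    (-b / (a * (b - a))) * m[n - 1L, ] + (a / (b * (b - a))) * m[n - 2L, ]
  aperm(array(out, d), order(perm))
}

#' Vorticity of a gridded velocity field
#'
#' Curl by second-order finite differences (centered in the interior,
#' one-sided at boundaries).
#'
#' @param field A [velocity_field()].
#' @return List of arrays `wx`, `wy`, `wz` (1/s).
#' @export
vorticity <- function(field) {
  stopifnot(inherits(field, "velocity_field"))
  dudy <- fd_partial(field$u, field$y, 2L)
  dudz <- fd_partial(field$u, field$z, 3L)
  dvdx <- fd_partial(field$v, field$x, 1L)
  dvdz <- fd_partial(field$v, field$z, 3L)
  dwdx <- fd_partial(field$w, field$x, 1L)
  dwdy <- fd_partial(field$w, field$y, 2L)
  list(wx = dwdy - dvdz, wy = dudz - dwdx, wz = dvdx - dudy)
}

#' Helicity field
#'
#' Node-wise helicity `He = v . (curl v)` (m/s^2), the scalar product of
#' velocity and vorticity; a marker of helical (swirling) flow.
#'
#' @param field A [velocity_field()].
#' @return An object of class `"helicity_field"`: list with array `values`
#'   (NA outside the mask) and the grid coordinates.
#' @examples
#' f <- gen_velocity_field("solid_rotation_axial",
#'                         params = list(omega = 3, w0 = 0.5))
#' range(helicity(f)$values, na.rm = TRUE)   # 2 * omega * w0 inside
#' @export
helicity <- function(field) {
  om <- vorticity(field)
  he <- field$u * om$wx + field$v * om$wy + field$w * om$wz
  he[!field$mask] <- NA_real_
  structure(list(values = he, x = field$x, y = field$y, z = field$z,
                 time = field$time),
            class = "helicity_field")
}

# Trapezoidal quadrature weights for a coordinate vector.
trapezoid_weights <- function(coords) {
  n <- length(coords)
  w <- numeric(n)
  d <- diff(coords)
  w[1L] <- d[1L] / 2
  w[n] <- d[n - 1L] / 2
  if (n > 2L) w[2:(n - 1)] <- (d[1:(n - 2)] + d[2:(n - 1)]) / 2
  w
}

node_volume_weights <- function(field) {
  wx <- trapezoid_weights(field$x)
  wy <- trapezoid_weights(field$y)
  wz <- trapezoid_weights(field$z)
  outer(outer(wx, wy), wz)
}

#' Kinetic energy of a velocity field
#'
#' Node-wise kinetic-energy density `rho |u|^2 / 2` integrated over the
#' masked domain with trapezoidal volume weights.
#'
#' @param field A [velocity_field()].
#' @param fluid A [fluid_properties()] object.
#' @return List with `mean_density` (volume-weighted mean, J/m^3), `total`
#'   (volume integral, J) and `volume` (masked volume, m^3).
#' @export
kinetic_energy <- function(field, fluid = fluid_properties()) {
  stopifnot(inherits(field, "velocity_field"),
            inherits(fluid, "fluid_properties"))
  if (!any(field$mask)) stop("mask excludes every node")
  e <- fluid$density * (field$u^2 + field$v^2 + field$w^2) / 2
  w <- node_volume_weights(field)
  w[!field$mask] <- 0
  vol <- sum(w)
  total <- sum(w * e)
  list(mean_density = total / vol, total = total, volume = vol)
}

#' Normalized axial-velocity profile on a cross-section
#'
#' Extracts the axial (z) velocity on the grid plane nearest
#' `section_z`, computes the area-averaged axial velocity `U_bar` over the
#' masked section, and returns the profile along the line `y = line_y`
#' normalized by `U_bar`, together with the section peak ratio
#' `u_max / U_bar`.
#'
#' @param field A [velocity_field()].
#' @param section_z Axial position of the section (m); nearest grid plane
#'   is used.
#' @param line_y Transverse position of the profile line (m); nearest grid
#'   line is used.
#' @return List with `profile` (data.frame `x`, `u_norm`), `U_bar` (m/s),
#'   `u_max` (m/s), `peak_ratio`, and the snapped `z` and `y`.
#' @export
normalized_profile <- function(field, section_z = NULL, line_y = NULL) {
  stopifnot(inherits(field, "velocity_field"))
  if (is.null(section_z)) section_z <- stats::median(field$z)
  if (is.null(line_y)) line_y <- stats::median(field$y)
  k <- which.min(abs(field$z - section_z))
  uz <- field$w[, , k]
  mk <- field$mask[, , k]
  if (!any(mk)) stop("section does not intersect the mask")
  wx <- trapezoid_weights(field$x)
  wy <- trapezoid_weights(field$y)
  wa <- outer(wx, wy)
  wa[!mk] <- 0
  U_bar <- sum(wa * uz) / sum(wa)
  if (U_bar == 0) stop("zero mean axial velocity on the section")
  j <- which.min(abs(field$y - line_y))
  sel <- mk[, j]
  if (!any(sel)) stop("profile line does not intersect the mask")
  prof <- data.frame(x = field$x[sel], u_norm = uz[sel, j] / U_bar)
  u_max <- max(uz[mk])
  list(profile = prof, U_bar = U_bar, u_max = u_max,
       peak_ratio = u_max / U_bar, z = field$z[k], y = field$y[j])
}
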