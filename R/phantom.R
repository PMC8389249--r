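#' Unit conversion constants
#'
#' Fixed conversion used throughout: 1 mmHg = 133.322 Pa = 1.33322e-4 MPa.
#' @format Length-one numeric.
#' @export
MMHG_TO_MPA <- 1.33322e-4

#' Phantom tube specification
#'
#' Geometry, material and pressure reference of the straight cylindrical
#' pipe used to select the phantom wall thickness.
#'
#' @param length Pipe length (mm).
#' @param inner_diameter Inner diameter (mm).
#' @param wall_thickness Wall thickness (mm).
#' @param material A `material_params` object ([ogden_params()] or
#'   [hgo_params()]). For HGO the fiber families lie in the hoop-axial
#'   surface at `+/-theta` from the hoop direction.
#' @param axial_stretch Fixed axial stretch (default 1: axially constrained
#'   tube, no end effects).
#' @param p0 Reference pressure (mmHg) at which the geometry is stress-free
#'   in `"stress-free-at-p0"` mode (default 80).
#' @param pressure_reference_mode `"stress-free-at-p0"`: the given geometry
#'   is unstressed at `p0` and only pressure in excess of `p0` loads the
#'   wall. `"stress-free-at-zero"`: the geometry is unstressed at zero
#'   absolute pressure.
#' @return An object of class `"tube_spec"`.
#' @examples
#' tube_spec(50, 30, 2.5, reference_material("silicone"))
#' @export
tube_spec <- function(length, inner_diameter, wall_thickness, material,
                      axial_stretch = 1, p0 = 80,
                      pressure_reference_mode = c("stress-free-at-p0",
                                                  "stress-free-at-zero")) {
  pressure_reference_mode <- match.arg(pressure_reference_mode)
  stopifnot(length > 0, inner_diameter > 0, wall_thickness > 0,
            axial_stretch > 0, p0 >= 0)
  if (!inherits(material, "material_params"))
    stop("'material' must be an ogden_params or hgo_params object")
  structure(list(length = length, inner_diameter = inner_diameter,
                 wall_thickness = wall_thickness, material = material,
                 axial_stretch = axial_stretch, p0 = p0,
                 pressure_reference_mode = pressure_reference_mode),
            class = "tube_spec")
}

#' @export
print.tube_spec <- function(x, ...) {
  cat(sprintf("Tube: L = %g mm, Di = %g mm, wall = %g mm, lambda_z = %g, %s (p0 = %g mmHg)\n",
              x$length, x$inner_diameter, x$wall_thickness, x$axial_stretch,
              x$pressure_reference_mode, x$p0))
  print(x$material)
  invisible(x)
}

#' Reference inner volume of the tube
#'
#' `pi * (inner_diameter / 2)^2 * length`, in mm^3.
#'
#' @param tube A [tube_spec()].
#' @return Volume (mm^3).
#' @examples
#' reference_volume(tube_spec(50, 30, 2.5, reference_material("silicone")))
#' @export
reference_volume <- function(tube) {
  stopifnot(inherits(tube, "tube_spec"))
  pi * (tube$inner_diameter / 2)^2 * tube$length
}

# Hoop-radial Cauchy stress difference (sigma_theta - sigma_r) at hoop
# stretch lam_t and fixed axial stretch lam_z, incompressible (MPa).
# Material axes: 1 = hoop, 2 = axial, 3 = radial.
hoop_radial_stress_diff <- function(lam_t, lam_z, material) {
  lam <- rbind(lam_t, rep(lam_z, length(lam_t)), 1 / (lam_t * lam_z))
  t <- principal_extra_stress(lam, material)
  t[1L, ] - t[3L, ]
}

# Internal pressure (MPa) that holds the tube open with deformed inner
# radius ri (mm), by integrating (sigma_theta - sigma_r)/r through the wall.
# Incompressible mapping r(R) = sqrt(ri^2 + (R^2 - Ri^2)/lam_z).
inflation_pressure <- function(ri, Ri, Ro, lam_z, material,
                               rel_tol = 1e-9) {
  integrand <- function(R) {
    r2 <- ri^2 + (R^2 - Ri^2) / lam_z
    r <- sqrt(r2)
    lam_t <- r / R
    hoop_radial_stress_diff(lam_t, lam_z, material) * R / (lam_z * r2)
  }
  stats::integrate(integrand, Ri, Ro, rel.tol = rel_tol, abs.tol = 0,
                   subdivisions = 256L)$value
}

#' Static inflation of the thick-walled tube
#'
#' Solves the incompressible axisymmetric finite-deformation inflation
#' problem at fixed axial stretch: the deformed inner radius is the root of
#' the wall-equilibrium integral
#' \deqn{p = \int_{r_i}^{r_o} \frac{\sigma_{\theta\theta} - \sigma_{rr}}{r}
#'   \, dr}
#' with zero external traction, found by bracketed root-finding to 1e-10
#' relative. In `"stress-free-at-p0"` mode the effective load is
#' `pressure - p0`.
#'
#' @param tube A [tube_spec()].
#' @param pressure Internal pressure(s), mmHg.
#' @return A data.frame with columns `pressure` (mmHg), `inner_radius` (mm),
#'   `inner_volume` (mm^3).
#' @examples
#' tb <- tube_spec(50, 30, 2.5, reference_material("silicone"))
#' inflate(tb, c(80, 100, 120))
#' @export
inflate <- function(tube, pressure) {
  stopifnot(inherits(tube, "tube_spec"))
  if (any(pressure < 0)) stop("pressure must be nonnegative (mmHg)")
  dp_mmHg <- if (tube$pressure_reference_mode == "stress-free-at-p0")
    pressure - tube$p0 else pressure
  Ri <- tube$inner_diameter / 2
  Ro <- Ri + tube$wall_thickness
  lz <- tube$axial_stretch
  ri <- vapply(dp_mmHg, function(dp) {
    dp_MPa <- dp * MMHG_TO_MPA
    if (abs(dp_MPa) < 1e-16) return(Ri)
    f <- function(r) inflation_pressure(r, Ri, Ro, lz, tube$material) - dp_MPa
    if (dp_MPa > 0) { lo <- Ri; hi <- Ri * 1.05 } else { hi <- Ri; lo <- Ri * 0.95 }
    for (k in 1:60) {
      if (dp_MPa > 0 && f(hi) > 0) break
      if (dp_MPa < 0 && f(lo) < 0) break
      if (dp_MPa > 0) hi <- Ri + (hi - Ri) * 1.6 else lo <- Ri - (Ri - lo) * 1.6
      if (hi > 50 * Ri || lo < 1e-3 * Ri)
        stop("inflation root not bracketable at ", format(dp + tube$p0),
             " mmHg: the wall is too soft for this load")
    }
    uniroot(f, c(lo, hi), tol = 1e-10 * Ri)$root
  }, numeric(1))
  data.frame(pressure = pressure, inner_radius = ri,
             inner_volume = pi * ri^2 * tube$length * lz)
}

#' Compliance and distensibility of the tube
#'
#' Inflates the tube over a pressure grid from `p_lo` to `p_hi` and
#' computes the compliance `C = (V(p_hi) - V(p_lo)) / (p_hi - p_lo)` and
#' the wall distensibility `AD = C / V0`, with `V0` the reference inner
#' volume.
#'
#' @param tube A [tube_spec()].
#' @param p_lo,p_hi Pressure interval (mmHg), default 80 to 120.
#' @param n_pressures Number of pressure samples stored in the result.
#' @return An object of class `"inflation_result"`: list with `pressures`,
#'   `inner_radius`, `inner_volume`, `V0` (mm^3), `compliance`
#'   (mm^3/mmHg), `distensibility` (mmHg^-1) and `distensibility_x1e3`.
#' @examples
#' tb <- tube_spec(50, 30, 2.5, reference_material("silicone"))
#' compliance_and_distensibility(tb)
#' @export
compliance_and_distensibility <- function(tube, p_lo = 80, p_hi = 120,
                                          n_pressures = 5L) {
  stopifnot(p_hi > p_lo)
  pr <- seq(p_lo, p_hi, length.out = max(2L, n_pressures))
  inf <- inflate(tube, pr)
  V0 <- reference_volume(tube)
  C <- (inf$inner_volume[nrow(inf)] - inf$inner_volume[1L]) / (p_hi - p_lo)
  structure(list(pressures = inf$pressure, inner_radius = inf$inner_radius,
                 inner_volume = inf$inner_volume, V0 = V0, compliance = C,
                 distensibility = C / V0,
                 distensibility_x1e3 = 1e3 * C / V0),
            class = "inflation_result")
}

#' @export
print.inflation_result <- function(x, ...) {
  cat(sprintf("Inflation %g -> %g mmHg: V0 = %.4g mm^3\n",
              min(x$pressures), max(x$pressures), x$V0))
  cat(sprintf("  compliance     C  = %.4g mm^3/mmHg\n", x$compliance))
  cat(sprintf("  distensibility AD = %.4g mmHg^-1  (%.3g x 10^-3 mmHg^-1)\n",
              x$distensibility, x$distensibility_x1e3))
  invisible(x)
}

#' Wall-thickness sweep for phantom design
#'
#' Computes the distensibility of the tube for each material over a grid of
#' wall thicknesses, reports the thicknesses whose `AD` lies inside the
#' physiological band for every material, and recommends the midpoint of
#' the intersection (rounded to 0.1 mm).
#'
#' @param tube_template A [tube_spec()] whose geometry (and pressure mode)
#'   is reused; its wall thickness and material are replaced per case.
#' @param materials Named list of `material_params` objects.
#' @param thicknesses Strictly increasing wall-thickness grid (mm), default
#'   1 to 4 mm.
#' @param band Length-2 distensibility band `[AD_lo, AD_hi]` in mmHg^-1;
#'   default `c(5, 9.1) * 1e-3`, the young-healthy aortic range on the
#'   10^-3 mmHg^-1 scale.
#' @param p_lo,p_hi Pressure interval (mmHg) for the compliance.
#' @return An object of class `"thickness_sweep"`: list with `table`
#'   (data.frame: material, thickness_mm, C_mm3_per_mmHg, AD_per_mmHg,
#'   AD_x1e3_per_mmHg, in_band), `admissible` (per-material thickness
#'   ranges), `intersection` (range or NULL) and `recommended_thickness`
#'   (mm or NA).
#' @export
thickness_sweep <- function(tube_template, materials,
                            thicknesses = seq(1, 4, by = 0.25),
                            band = c(5e-3, 9.1e-3),
                            p_lo = 80, p_hi = 120) {
  stopifnot(inherits(tube_template, "tube_spec"),
            length(band) == 2L, band[2L] >= band[1L])
  if (any(diff(thicknesses) <= 0))
    stop("'thicknesses' must be strictly increasing")
  if (inherits(materials, "material_params"))
    materials <- list(material = materials)
  if (is.null(names(materials)) || any(!nzchar(names(materials))))
    names(materials) <- paste0("material", seq_along(materials))
  rows <- list()
  for (nm in names(materials)) {
    for (s in thicknesses) {
      tb <- tube_template
      tb$wall_thickness <- s
      tb$material <- materials[[nm]]
      res <- compliance_and_distensibility(tb, p_lo = p_lo, p_hi = p_hi,
                                           n_pressures = 2L)
      rows[[length(rows) + 1L]] <- data.frame(
        material = nm, thickness_mm = s,
        C_mm3_per_mmHg = res$compliance,
        AD_per_mmHg = res$distensibility,
        AD_x1e3_per_mmHg = res$distensibility_x1e3,
        in_band = res$distensibility >= band[1L] &
                  res$distensibility <= band[2L])
    }
  }
  tab <- do.call(rbind, rows)
  admissible <- lapply(split(tab, tab$material), function(d) {
    ok <- d$thickness_mm[d$in_band]
    if (length(ok)) range(ok) else NULL
  })
  ranges <- Filter(Negate(is.null), admissible)
  intersection <- NULL
  if (length(ranges) == length(materials)) {
    lo <- max(vapply(ranges, `[`, numeric(1), 1L))
    hi <- min(vapply(ranges, `[`, numeric(1), 2L))
    if (lo <= hi) intersection <- c(lo, hi)
  }
  rec <- if (is.null(intersection)) NA_real_ else
    round(mean(intersection) * 10) / 10
  structure(list(table = tab, band = band, admissible = admissible,
                 intersection = intersection,
                 recommended_thickness = rec),
            class = "thickness_sweep")
}

#' @export
print.thickness_sweep <- function(x, ...) {
  cat(sprintf("Thickness sweep, band = [%g, %g] mmHg^-1\n",
              x$band[1L], x$band[2L]))
  print(x$table, row.names = FALSE)
  if (is.null(x$intersection)) {
    cat("  no thickness satisfies the band for every material\n")
  } else {
    cat(sprintf("  intersection: [%g, %g] mm; recommended s = %g mm\n",
                x$intersection[1L], x$intersection[2L],
                x$recommended_thickness))
  }
  invisible(x)
}
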