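#' Fluid properties
#'
#' Density and dynamic viscosity of the working fluid. Defaults are the
#' blood values used for the aortic simulations.
#'
#' @param density kg/m^3 (default 1025).
#' @param dynamic_viscosity Pa s (default 3.5e-3).
#' @return An object of class `"fluid_properties"`.
#' @export
fluid_properties <- function(density = 1025, dynamic_viscosity = 3.5e-3) {
  stopifnot(density > 0, dynamic_viscosity > 0)
  structure(list(density = density, dynamic_viscosity = dynamic_viscosity),
            class = "fluid_properties")
}

#' Pulsatile aortic-inlet flow waveform
#'
#' Builds the inlet boundary-condition waveform: a half-sine forward
#' (systolic) lobe over `[0, systolic_fraction * period]` whose amplitude
#' is solved so the forward-phase integral equals `stroke_volume`, followed
#' immediately by a negative half-sine backflow lobe of amplitude
#' `backflow_fraction * q_max` lasting `backflow_duration`, and zero flow
#' for the rest of the cycle (diastole).
#'
#' @param period Cardiac period (s), default 1 (heart rate 60 bpm).
#' @param systolic_fraction Fraction of the cycle with forward ejection,
#'   default 0.37.
#' @param backflow_fraction Backflow peak as a fraction of the forward peak,
#'   default 0.10.
#' @param stroke_volume Volume ejected in the forward phase (mL), default 60.
#' @param backflow_duration Duration of the backflow lobe (s), default 0.08.
#' @param n_samples Number of equally spaced samples stored over one period.
#' @return An object of class `"flow_waveform"`: list with the parameters,
#'   the solved peak flow `q_max` (mL/s), a vectorized evaluator `q(t)`
#'   (mL/s, periodic) and a data.frame `samples` with columns `t`, `q`.
#' @examples
#' wf <- make_inlet_waveform()
#' wf$q_max                      # 60 * pi / (2 * 0.37) mL/s
#' @export
make_inlet_waveform <- function(period = 1, systolic_fraction = 0.37,
                                backflow_fraction = 0.10, stroke_volume = 60,
                                backflow_duration = 0.08, n_samples = 1000L) {
  if (!(systolic_fraction > 0 && systolic_fraction < 1))
    stop("'systolic_fraction' must lie in (0, 1)")
  if (backflow_fraction < 0) stop("'backflow_fraction' must be nonnegative")
  if (backflow_duration < 0) stop("'backflow_duration' must be nonnegative")
  ts <- systolic_fraction * period
  if (ts + backflow_duration > period)
    stop("infeasible timing: systolic phase plus backflow exceeds the period")
  # forward half-sine integral q_max * 2 ts / pi = SV
  q_max <- stroke_volume * pi / (2 * ts)
  tb <- backflow_duration
  q <- function(t) {
    t <- t %% period
    out <- numeric(length(t))
    fwd <- t < ts
    out[fwd] <- q_max * sin(pi * t[fwd] / ts)
    if (tb > 0) {
      bwd <- t >= ts & t < ts + tb
      out[bwd] <- -backflow_fraction * q_max * sin(pi * (t[bwd] - ts) / tb)
    }
    out
  }
  tt <- seq(0, period, length.out = n_samples + 1L)[seq_len(n_samples)]
  structure(list(period = period, systolic_fraction = systolic_fraction,
                 backflow_fraction = backflow_fraction,
                 stroke_volume = stroke_volume,
                 backflow_duration = backflow_duration, q_max = q_max,
                 q = q, samples = data.frame(t = tt, q = q(tt))),
            class = "flow_waveform")
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf("Pulsatile inlet waveform: T = %g s, systole %g s, SV = %g mL\n",
              x$period, x$systolic_fraction * x$period, x$stroke_volume))
  cat(sprintf("  q_max = %.4g mL/s, backflow %g%% of peak over %g s\n",
              x$q_max, 100 * x$backflow_fraction, x$backflow_duration))
  invisible(x)
}

#' Tile a waveform over several cardiac cycles
#'
#' Samples the periodic waveform on a uniform time grid covering
#' `n_cycles` periods (the default five cycles is the usual settling length
#' for periodic aortic flow).
#'
#' @param waveform A [make_inlet_waveform()] object.
#' @param n_cycles Number of cycles, default 5.
#' @param dt Time step (s); must divide the period to within 1e-12.
#' @return data.frame with columns `t` (s) and `q` (mL/s), from 0 to
#'   `n_cycles * period` inclusive.
#' @export
gen_waveform_series <- function(waveform, n_cycles = 5L, dt = 1e-3) {
  stopifnot(inherits(waveform, "flow_waveform"), n_cycles >= 1, dt > 0)
  steps <- waveform$period / dt
  if (abs(steps - round(steps)) > 1e-12 * steps)
    stop("'dt' must divide the period exactly")
  t <- seq(0, n_cycles * waveform$period, by = dt)
  data.frame(t = t, q = waveform$q(t))
}

#' Time of peak from a sampled series
#'
#' Locates the maximum of a sampled time series with parabolic (three-point)
#' interpolation around the discrete maximum; ties are broken by the
#' earliest time, and a maximum at the first or last sample is returned
#' without interpolation.
#'
#' @param t Sample times (strictly increasing).
#' @param value Sampled values (same length, >= 3, non-constant).
#' @return Peak time (s).
#' @examples
#' t <- seq(0, 1, 1e-3)
#' peak_time(t, sin(2 * pi * t))   # 0.25
#' @export
peak_time <- function(t, value) {
  stopifnot(length(t) == length(value), length(t) >= 3L)
  if (any(diff(t) <= 0)) stop("'t' must be strictly increasing")
  if (diff(range(value)) == 0)
    stop("constant series has no defined peak time")
  i <- which.max(value)            # which.max returns the earliest maximum
  if (i == 1L || i == length(value)) return(t[i])
  y0 <- value[i - 1L]; y1 <- value[i]; y2 <- value[i + 1L]
  denom <- y0 - 2 * y1 + y2
  if (denom == 0) return(t[i])
  # parabola through three (possibly unevenly spaced) points
  t0 <- t[i - 1L]; t1 <- t[i]; t2 <- t[i + 1L]
  d1 <- (y1 - y0) / (t1 - t0)
  d2 <- (y2 - y1) / (t2 - t1)
  a <- (d2 - d1) / (t2 - t0)
  if (a == 0) return(t1)
  # vertex of the Newton-form parabola y = y0 + d1 (t-t0) + a (t-t0)(t-t1)
  tp <- (t0 + t1) / 2 - d1 / (2 * a)
  max(min(tp, t2), t0)
}

#' Export a waveform to CSV
#'
#' Writes columns `t_s`, `q_mL_per_s` for one period.
#'
#' @param waveform A `flow_waveform`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(waveform, path) {
  stopifnot(inherits(waveform, "flow_waveform"))
  df <- data.frame(t_s = waveform$samples$t, q_mL_per_s = waveform$samples$q)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
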