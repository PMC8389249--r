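#' Read stress-strain curves from CSV
#'
#' Reads a curve file with header `strain,stress_mpa`. Malformed rows are
#' reported with their line numbers; validation failures (missing header,
#' non-monotone strain, negative stress at zero strain) are errors, not
#' silent coercions.
#'
#' @param path CSV file path.
#' @param mode Curve mode to attach (the file format carries no mode).
#' @return A [stress_strain_curve()].
#' @export
read_curves <- function(path, mode = c("uniaxial-circumferential",
                                       "uniaxial-longitudinal",
                                       "equibiaxial")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("curve file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), ",")[[1L]]
  header <- tolower(gsub("\"", "", trimws(header)))
  if (length(header) < 2L || header[1L] != "strain" ||
      header[2L] != "stress_mpa")
    stop("expected header 'strain,stress_mpa' in ", path, " but found '",
         paste(header, collapse = ","), "'")
  raw <- utils::read.csv(path, colClasses = "character")
  strain <- suppressWarnings(as.numeric(raw[[1L]]))
  stress <- suppressWarnings(as.numeric(raw[[2L]]))
  bad <- which(!is.finite(strain) | !is.finite(stress))
  if (length(bad))
    stop("malformed numeric rows in ", path, " at line(s) ",
         paste(bad + 1L, collapse = ", "))
  if (any(strain == 0 & stress < 0))
    stop("negative stress at zero strain in ", path)
  stress_strain_curve(strain, stress, mode = mode, label = basename(path))
}

#' Write a stress-strain curve to CSV
#'
#' @param curve A [stress_strain_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curve, path) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  df <- data.frame(strain = curve$strain, stress_mpa = curve$stress)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a directory of replicate curve files
#'
#' Reads every `*.csv` in `dir` as one replicate (all with the same mode),
#' for multi-sample averaging.
#'
#' @param dir Directory path.
#' @inheritParams read_curves
#' @return List of curves.
#' @export
read_curve_dir <- function(dir, mode) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (!length(files)) stop("no .csv curve files in ", dir)
  lapply(files, read_curves, mode = mode)
}

#' Write a velocity field to CSV
#'
#' Long format with columns `x,y,z,u,v,w` (SI units), masked-in nodes only.
#'
#' @param field A [velocity_field()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path) {
  stopifnot(inherits(field, "velocity_field"))
  g <- expand.grid(x = field$x, y = field$y, z = field$z,
                   KEEP.OUT.ATTRS = FALSE)
  keep <- as.vector(field$mask)
  df <- data.frame(g[keep, ], u = as.vector(field$u)[keep],
                   v = as.vector(field$v)[keep],
                   w = as.vector(field$w)[keep])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a velocity field from CSV
#'
#' Inverse of [write_field_csv()]: reconstructs the rectilinear grid from
#' the unique coordinates; nodes absent from the file are masked out with
#' zero velocity.
#'
#' @param path CSV with header `x,y,z,u,v,w`.
#' @param time Snapshot time attached to the field (s).
#' @return A [velocity_field()].
#' @export
read_field_csv <- function(path, time = 0) {
  if (!file.exists(path)) stop("field file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("x", "y", "z", "u", "v", "w")
  if (!all(need %in% names(df)))
    stop("field file must have columns x,y,z,u,v,w")
  x <- sort(unique(df$x)); y <- sort(unique(df$y)); z <- sort(unique(df$z))
  dims <- c(length(x), length(y), length(z))
  ix <- match(df$x, x); iy <- match(df$y, y); iz <- match(df$z, z)
  idx <- cbind(ix, iy, iz)
  u <- array(0, dims); v <- array(0, dims); w <- array(0, dims)
  mask <- array(FALSE, dims)
  u[idx] <- df$u; v[idx] <- df$v; w[idx] <- df$w; mask[idx] <- TRUE
  velocity_field(x, y, z, u, v, w, mask = mask, time = time)
}

#' Read a pipeline run configuration
#'
#' DCF key-value file with the fields used by [run_pipeline()]; unknown
#' keys are rejected.
#'
#' @param path Config file path.
#' @return A named list (class `"run_config"`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  rec <- as.list(as.data.frame(read.dcf(path), stringsAsFactors = FALSE))
  known <- c("stages", "seed", "outdir", "length_mm", "diameter_mm",
             "thickness_mm", "thickness_sweep_mm", "p0_mmHg", "p_hi_mmHg",
             "band_per_mmHg", "silicone_file", "porcine_file",
             "strain_max", "n_points", "noise_sd", "field_file")
  unknown <- setdiff(names(rec), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  num_keys <- setdiff(known, c("stages", "outdir", "silicone_file",
                               "porcine_file", "field_file"))
  for (k in intersect(names(rec), num_keys)) {
    v <- suppressWarnings(as.numeric(strsplit(rec[[k]], "[ ,]+")[[1L]]))
    if (any(!is.finite(v))) stop("config key '", k, "' is not numeric")
    rec[[k]] <- v
  }
  if (!is.null(rec$stages))
    rec$stages <- strsplit(rec$stages, "[ ,]+")[[1L]]
  class(rec) <- "run_config"
  rec
}

#' Run the full phantom-design pipeline
#'
#' Orchestrates the stages in the order of the physical workflow:
#' `characterize` (generate or read mechanical-test curves and calibrate
#' both materials), `phantom` (wall-thickness sweep on the pressurized
#' pipe), `waveform` (inlet boundary condition) and `metrics` (flow
#' post-processing on a synthetic or supplied field). Deterministic given
#' the seed; each stage logs its inputs and outputs.
#'
#' @param config A named list or `"run_config"`; see [read_run_config()].
#'   Recognized fields (all optional): `stages` (character subset of
#'   `c("characterize", "phantom", "waveform", "metrics")`), `seed`,
#'   `outdir`, geometry/pressure keys (`length_mm`, `diameter_mm`,
#'   `thickness_sweep_mm`, `p0_mmHg`, `p_hi_mmHg`, `band_per_mmHg`),
#'   synthetic-data keys (`strain_max`, `n_points`, `noise_sd`) and
#'   `field_file`.
#' @return A result bundle (list) with one element per executed stage and
#'   a `log` character vector.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- function(key, default) config[[key]] %||% default
  stages <- cfg("stages", c("characterize", "phantom", "waveform", "metrics"))
  bad <- setdiff(stages, c("characterize", "phantom", "waveform", "metrics"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  seed <- as.integer(cfg("seed", 1L))
  outdir <- cfg("outdir", NULL)
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message("[pipeline] ", msg)
  }
  bundle <- list()
  stage <- "init"
  result <- try({
    if ("characterize" %in% stages) {
      stage <- "characterize"
      note("characterize: seed %d", seed)
      sil_true <- if (!is.null(config$silicone_file))
        read_material(config$silicone_file) else reference_material("silicone")
      por_true <- if (!is.null(config$porcine_file))
        read_material(config$porcine_file) else reference_material("porcine")
      sd <- cfg("noise_sd", 0.02)
      np <- as.integer(cfg("n_points", 50L))
      smax <- cfg("strain_max", 1.0)
      bi <- gen_mechanical_tests(sil_true, "equibiaxial", smax, np,
                                 noise_spec(sd, seed, 5L))
      ci <- gen_mechanical_tests(por_true, "uniaxial-circumferential", smax,
                                 np, noise_spec(sd, seed + 1L, 4L))
      lo <- gen_mechanical_tests(por_true, "uniaxial-longitudinal", smax,
                                 np, noise_spec(sd, seed + 2L, 4L))
      fit_sil <- fit_ogden(average_curves(bi), D = sil_true$D)
      fit_por <- fit_hgo(average_curves(ci), average_curves(lo),
                         fixed = list(kappa = por_true$kappa,
                                      theta = por_true$theta),
                         D = por_true$D)
      note("characterize: Ogden residual %.3g MPa, HGO residual %.3g MPa",
           fit_sil$residual, fit_por$residual)
      if (!is.null(outdir)) {
        write_fit_json(fit_sil, file.path(outdir, "fit_ogden.json"), seed)
        write_fit_json(fit_por, file.path(outdir, "fit_hgo.json"), seed)
      }
      bundle$characterize <- list(silicone = fit_sil, porcine = fit_por)
    }
    if ("phantom" %in% stages) {
      stage <- "phantom"
      mats <- if (!is.null(bundle$characterize))
        list(silicone = bundle$characterize$silicone$params,
             porcine = bundle$characterize$porcine$params)
      else list(silicone = reference_material("silicone"),
                porcine = reference_material("porcine"))
      tmpl <- tube_spec(length = cfg("length_mm", 50),
                        inner_diameter = cfg("diameter_mm", 30),
                        wall_thickness = 2.5, material = mats[[1L]],
                        p0 = cfg("p0_mmHg", 80))
      band <- cfg("band_per_mmHg", c(5e-3, 9.1e-3))
      sw <- thickness_sweep(tmpl, mats,
                            thicknesses = cfg("thickness_sweep_mm",
                                              seq(1, 4, by = 0.5)),
                            band = band,
                            p_lo = cfg("p0_mmHg", 80),
                            p_hi = cfg("p_hi_mmHg", 120))
      note("phantom: recommended thickness %s mm",
           format(sw$recommended_thickness))
      if (!is.null(outdir)) {
        utils::write.csv(sw$table, file.path(outdir, "thickness_sweep.csv"),
                         row.names = FALSE)
        jsonlite::write_json(
          list(band_per_mmHg = sw$band, admissible = sw$admissible,
               intersection = sw$intersection,
               recommended_thickness_mm = sw$recommended_thickness),
          file.path(outdir, "thickness_sweep.json"),
          auto_unbox = TRUE, digits = NA, null = "null")
      }
      bundle$phantom <- sw
    }
    if ("waveform" %in% stages) {
      stage <- "waveform"
      wf <- make_inlet_waveform()
      note("waveform: q_max %.4g mL/s, peak at %.4g s", wf$q_max,
           peak_time(wf$samples$t, wf$samples$q))
      if (!is.null(outdir))
        write_waveform_csv(wf, file.path(outdir, "waveform.csv"))
      bundle$waveform <- wf
    }
    if ("metrics" %in% stages) {
      stage <- "metrics"
      fld <- if (!is.null(config$field_file)) read_field_csv(config$field_file)
      else {
        pois <- gen_velocity_field("poiseuille",
                                   params = list(u_mean = 0.2, R = 0.015),
                                   grid = list(n = c(41L, 41L, 9L),
                                               half_width = 0.016,
                                               length_z = 0.05))
        rot <- gen_velocity_field("solid_rotation_axial",
                                  params = list(omega = 5, w0 = 0,
                                                R = 0.015),
                                  grid = list(n = c(41L, 41L, 9L),
                                              half_width = 0.016,
                                              length_z = 0.05))
        gen_velocity_field("superposition", params = list(a = pois, b = rot))
      }
      he <- helicity(fld)
      ke <- kinetic_energy(fld)
      pr <- normalized_profile(fld)
      note("metrics: mean KE density %.4g J/m^3, peak ratio %.3g",
           ke$mean_density, pr$peak_ratio)
      bundle$metrics <- list(helicity = he, kinetic_energy = ke,
                             profile = pr)
    }
    TRUE
  }, silent = TRUE)
  if (inherits(result, "try-error"))
    stop("pipeline stage '", stage, "' failed: ",
         attr(result, "condition")$message)
  bundle$log <- log
  bundle
}
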