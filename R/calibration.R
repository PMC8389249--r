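#' Average replicate stress-strain curves onto a common grid
#'
#' Linearly interpolates each replicate onto `common_grid` and takes the
#' pointwise mean, mirroring the use of averaged experimental curves for
#' calibration. All curves must share a mode and span the grid.
#'
#' @param curves List of [stress_strain_curve()] objects of one mode.
#' @param common_grid Strain grid for the average; defaults to the grid of
#'   the first curve.
#' @return A [stress_strain_curve()] labelled `"average"`.
#' @export
average_curves <- function(curves, common_grid = NULL) {
  if (inherits(curves, "stress_strain_curve")) curves <- list(curves)
  if (length(curves) < 1L) stop("need at least one curve")
  modes <- vapply(curves, curve_mode, character(1))
  if (length(unique(modes)) != 1L)
    stop("cannot average curves of mixed modes: ",
         paste(unique(modes), collapse = ", "))
  if (is.null(common_grid)) common_grid <- curves[[1L]]$strain
  for (cu in curves) {
    if (min(common_grid) < min(cu$strain) - 1e-12 ||
        max(common_grid) > max(cu$strain) + 1e-12)
      stop("common_grid extends beyond the span of curve '",
           attr(cu, "label"), "'")
  }
  mat <- vapply(curves,
                function(cu) approx(cu$strain, cu$stress, xout = common_grid,
                                    rule = 1)$y,
                numeric(length(common_grid)))
  stress_strain_curve(common_grid, rowMeans(matrix(mat, ncol = length(curves))),
                      mode = modes[1L], label = "average")
}

new_fit_result <- function(params, residual, n_starts, converged,
                           fixed_params = character(0), starts = NULL) {
  structure(list(params = params, residual = residual, n_starts = n_starts,
                 converged = converged, fixed_params = fixed_params,
                 starts = starts),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Constitutive fit (", class(x$params)[1L], ")\n", sep = "")
  print(x$params)
  cat(sprintf("  RMS residual = %.4g MPa over %d start(s); converged: %s\n",
              x$residual, x$n_starts, x$converged))
  if (length(x$fixed_params))
    cat("  held fixed:", paste(x$fixed_params, collapse = ", "), "\n")
  invisible(x)
}

rms <- function(x) sqrt(mean(x^2))

#' Fit the one-term Ogden model to a stress-strain curve
#'
#' Least-squares estimation of `(mu, alpha)` from a nominal-stress curve
#' (equibiaxial by design; uniaxial curves are accepted). The forward model
#' is the exact incompressible response; the objective is the unweighted sum
#' of squared nominal-stress residuals, minimized by bounded
#' Levenberg-Marquardt from a deterministic multi-start grid (log-spaced
#' `mu` in `[1e-3, 10]` MPa, `alpha` in `[0.5, 12]`).
#'
#' @param curve A [stress_strain_curve()].
#' @param initial_guess Optional `c(mu, alpha)` added to the start set.
#' @param n_starts Number of multi-start points (>= 8; rounded up to a full
#'   grid).
#' @param D Compressibility parameter carried into the returned
#'   [ogden_params()] (not fitted).
#' @return A `fit_result` with fields `params`, `residual` (RMS, MPa),
#'   `n_starts`, `converged`, `fixed_params`.
#' @examples
#' crv <- equibiaxial_response(reference_material("silicone"), seq(0.02, 1, length.out = 50))
#' fit_ogden(crv)$params
#' @export
fit_ogden <- function(curve, initial_guess = NULL, n_starts = 9L, D = 1) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  if (nrow(curve) < 3L) stop("need at least 3 points to fit")
  if (all(curve$stress == 0)) stop("degenerate data: all stresses are zero")
  mode <- if (curve_mode(curve) == "equibiaxial") "equibiaxial" else "uniaxial"

  resid_fun <- function(p) {
    prm <- list(mu = p[1L], alpha = p[2L])
    class(prm) <- c("ogden_params", "material_params")
    ogden_nominal_closed_form(prm, curve$strain, mode = mode) - curve$stress
  }
  n_side <- max(3L, ceiling(sqrt(n_starts)))
  starts <- expand.grid(
    mu = exp(seq(log(1e-3), log(10), length.out = n_side)),
    alpha = exp(seq(log(0.5), log(12), length.out = n_side)))
  if (!is.null(initial_guess))
    starts <- rbind(starts, data.frame(mu = initial_guess[1L],
                                       alpha = initial_guess[2L]))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(minpack.lm::nls.lm(
      par = as.numeric(starts[i, ]), fn = resid_fun,
      lower = c(1e-8, 0.05), upper = c(1e3, 30),
      control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                           maxiter = 500)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    r <- rms(fit$fvec)
    if (is.null(best) || r < best$r - 1e-15) best <- list(fit = fit, r = r)
  }
  if (is.null(best)) stop("all optimizer starts failed")
  p <- best$fit$par
  new_fit_result(ogden_params(mu = p[1L], alpha = p[2L], D = D),
                 residual = best$r, n_starts = nrow(starts),
                 converged = best$fit$info %in% 1:4)
}

#' Fit the HGO model to paired uniaxial curves
#'
#' Simultaneous least squares on a circumferential and a longitudinal
#' uniaxial nominal-stress curve using the exact incompressible
#' [uniaxial_response()] forward model. By default the weakly identifiable
#' dispersion `kappa` and fiber angle `theta` are held at supplied values
#' and `(C, k1, k2)` are free; freeing all five is supported but flagged,
#' since two uniaxial directions cannot separate `(kappa, theta)` from
#' `(k1, k2)`.
#'
#' @param circ,long [stress_strain_curve()] objects for the circumferential
#'   and longitudinal direction.
#' @param fixed Named list of parameters to hold fixed; may contain `kappa`
#'   and/or `theta` (degrees). Default holds both (required unless
#'   explicitly freed with `fixed = list()`).
#' @param initial_guess Optional named vector added to the start set.
#' @param n_starts Multi-start count (>= 16 by default; rounded up to a
#'   full grid over log-spaced `C`, `k1`, `k2`).
#' @param D Compressibility parameter carried through (not fitted).
#' @return A `fit_result`; `fixed_params` records what was held.
#' @export
fit_hgo <- function(circ, long, fixed = list(kappa = 0.25, theta = 27),
                    initial_guess = NULL, n_starts = 16L, D = 1) {
  stopifnot(inherits(circ, "stress_strain_curve"),
            inherits(long, "stress_strain_curve"))
  if (curve_mode(circ) != "uniaxial-circumferential")
    stop("'circ' must have mode uniaxial-circumferential")
  if (curve_mode(long) != "uniaxial-longitudinal")
    stop("'long' must have mode uniaxial-longitudinal")
  fixed_names <- intersect(names(fixed), c("kappa", "theta"))
  free_disp <- setdiff(c("kappa", "theta"), fixed_names)
  if (length(free_disp))
    warning("freeing ", paste(free_disp, collapse = " and "),
            " with two uniaxial directions is weakly identifiable; ",
            "interpret those estimates with caution")

  make_params <- function(p) {
    kappa <- if ("kappa" %in% fixed_names) fixed$kappa else p[["kappa"]]
    theta <- if ("theta" %in% fixed_names) fixed$theta else p[["theta"]]
    prm <- list(C = p[["C"]], k1 = p[["k1"]], k2 = p[["k2"]],
                kappa = kappa, theta = theta, D = D, n_families = 2L)
    class(prm) <- c("hgo_params", "material_params")
    prm
  }
  resid_fun <- function(p) {
    prm <- make_params(p)
    pc <- uniaxial_response(prm, circ$strain, "circumferential")$stress
    pl <- uniaxial_response(prm, long$strain, "longitudinal")$stress
    c(pc - circ$stress, pl - long$stress)
  }

  n_C <- max(4L, ceiling(n_starts / 4))
  grid <- expand.grid(
    C = exp(seq(log(1e-3), log(1), length.out = n_C)),
    k1 = exp(seq(log(1e-3), log(1), length.out = 2L)),
    k2 = exp(seq(log(0.05), log(5), length.out = 2L)))
  free_names <- c("C", "k1", "k2", free_disp)
  if ("kappa" %in% free_disp) grid$kappa <- 1 / 6
  if ("theta" %in% free_disp) grid$theta <- 30
  lower <- c(C = 1e-8, k1 = 0, k2 = 1e-4, kappa = 0, theta = 0)[free_names]
  upper <- c(C = 10, k1 = 10, k2 = 50, kappa = 1 / 3, theta = 90)[free_names]
  starts <- grid[, free_names, drop = FALSE]
  if (!is.null(initial_guess))
    starts <- rbind(starts, as.data.frame(as.list(initial_guess))[, free_names])

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- unlist(starts[i, , drop = TRUE])
    fit <- try(minpack.lm::nls.lm(
      par = p0, fn = resid_fun, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                           maxiter = 300)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    r <- rms(fit$fvec)
    k2_i <- fit$par[["k2"]]
    if (is.null(best) || r < best$r - 1e-14 ||
        (abs(r - best$r) <= 1e-14 && k2_i < best$k2)) {
      best <- list(fit = fit, r = r, k2 = k2_i)
    }
  }
  if (is.null(best)) stop("all optimizer starts failed")
  p <- best$fit$par
  res <- new_fit_result(make_params(as.list(p)), residual = best$r,
                        n_starts = nrow(starts),
                        converged = best$fit$info %in% 1:4,
                        fixed_params = fixed_names)
  if (length(free_disp)) res$identifiability_warning <- TRUE
  res
}

#' Serialize a fit result to JSON
#'
#' @param fit A `fit_result`.
#' @param path Output path; if `NULL` the JSON string is returned.
#' @param seed Optional seed to record for provenance.
#' @return `path` invisibly, or a JSON string.
#' @export
write_fit_json <- function(fit, path = NULL, seed = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  pl <- unclass(fit$params)
  obj <- list(model = class(fit$params)[1L],
              params = pl[vapply(pl, is.numeric, logical(1))],
              residual_rms_mpa = fit$residual,
              n_starts = fit$n_starts,
              converged = fit$converged,
              fixed_params = fit$fixed_params,
              seed = seed)
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
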