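#' Exponential force-dependence law
#'
#' A single-exponential (Bell-type) dependence of a rate or speed on tension,
#' \deqn{y(F) = A \exp(F / F_s),}
#' where `amplitude` (A) is the unloaded value and `force_scale` (F_s, pN) is
#' the characteristic force. A negative `force_scale` encodes a quantity that
#' decreases with tension (e.g. the pause entrance rate); `force_scale = Inf`
#' encodes a force-independent (constant) quantity.
#'
#' @param amplitude Value at zero force (min^-1 for rates, um/min for speeds).
#'   Must be > 0.
#' @param force_scale Characteristic force (pN); any nonzero value, or `Inf`
#'   for a constant law.
#' @return An object of class `exp_law`.
#' @examples
#' k_en <- exp_law(19.4, -4.6)   # pause entrance rate, suppressed by tension
#' eval_law(k_en, 4)             # rate at 4 pN of tension
#' @export
exp_law <- function(amplitude, force_scale) {
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L,
            is.numeric(force_scale), length(force_scale) == 1L)
  if (!is.finite(amplitude) || amplitude <= 0)
    stop("`amplitude` must be a positive finite number")
  if (is.na(force_scale) || force_scale == 0)
    stop("`force_scale` must be nonzero (use Inf for a constant law)")
  structure(list(amplitude = amplitude, force_scale = force_scale),
            class = "exp_law")
}

#' @export
print.exp_law <- function(x, ...) {
  if (is.infinite(x$force_scale)) {
    cat(sprintf("exponential law: %g (force-independent)\n", x$amplitude))
  } else {
    cat(sprintf("exponential law: %g * exp(F / %g pN)\n",
                x$amplitude, x$force_scale))
  }
  invisible(x)
}

# force range (pN) over which the underlying force-clamp measurements are valid
.FORCE_VALID_RANGE <- c(0.5, 18)

#' Evaluate an exponential force law
#'
#' @param law An [exp_law()].
#' @param force Tension (pN); vectorized.
#' @param check_range If `TRUE`, warn when any `|force|` lies outside the
#'   0.5--18 pN range over which the underlying measurements were made.
#'   Coupled simulations can transiently leave this range, so evaluation
#'   warns rather than fails.
#' @return `law$amplitude * exp(force / law$force_scale)`; strictly positive.
#' @export
eval_law <- function(law, force, check_range = FALSE) {
  stopifnot(inherits(law, "exp_law"), is.numeric(force), all(is.finite(force)))
  if (check_range &&
      any(abs(force) < .FORCE_VALID_RANGE[1] | abs(force) > .FORCE_VALID_RANGE[2]))
    warning(sprintf("force outside the %g-%g pN validity range of the kinetic laws",
                    .FORCE_VALID_RANGE[1], .FORCE_VALID_RANGE[2]))
  if (is.infinite(law$force_scale)) {
    rep(law$amplitude, length(force))
  } else {
    law$amplitude * exp(force / law$force_scale)
  }
}

#' Extrapolate a loaded speed measurement to zero force
#'
#' Given a speed measured at tension `force` and an exponential force
#' dependence with characteristic force `force_scale`, returns the intrinsic
#' unloaded speed `speed * exp(-force / force_scale)`, so that re-evaluating
#' `exp_law(unloaded, force_scale)` at `force` recovers the measurement
#' exactly.
#'
#' @param speed Measured speed (um/min), > 0; vectorized.
#' @param force Tension at which the speed was measured (pN); vectorized.
#' @param force_scale Characteristic force of the assumed law (pN).
#' @return Unloaded intrinsic speed(s) (um/min).
#' @export
extrapolate_unloaded <- function(speed, force, force_scale) {
  stopifnot(is.numeric(speed), is.numeric(force),
            is.numeric(force_scale), length(force_scale) == 1L,
            force_scale != 0)
  if (any(!is.finite(speed)) || any(speed <= 0))
    stop("`speed` must be positive and finite")
  if (is.infinite(force_scale)) return(speed + 0 * force)
  speed * exp(-force / force_scale)
}

#' Kinetic parameter set for microtubule growth models
#'
#' Bundles the exponential force laws used by the growth models. Defaults are
#' the fitted values from force-clamp measurements of single kinetochore-
#' attached microtubules:
#' growth-speed force sensitivity F_g = 8.4 pN (non-pausing model);
#' pause entrance k_EN0 = 19.4 min^-1, F_EN = -4.6 pN;
#' pause exit k_EX0 = 9.0 min^-1, F_EX = 14.1 pN;
#' run speed v_0 = 0.52 um/min, F_RUN = 14.8 pN.
#'
#' The trajectory-terminating laws (detachment, catastrophe, and a
#' force-independent interruption rate) were estimated in the original
#' force-clamp study and are not bundled here: they are `NULL` by default and
#' must be supplied (or termination explicitly disabled) before simulating.
#' [synthetic_termination_laws()] provides documented synthetic stand-ins.
#'
#' @param f_g Growth-speed force sensitivity (pN), used by the non-pausing
#'   model's speed law v_g = v_g0 * exp(F / f_g).
#' @param pause_entrance,pause_exit,run_speed [exp_law()] objects for the
#'   pausing model.
#' @param detachment,catastrophe,interruption Optional [exp_law()] objects for
#'   trajectory-terminating events (rates in min^-1); `interruption` is
#'   conventionally force-independent (`force_scale = Inf`).
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(f_g = 8.4,
                           pause_entrance = exp_law(19.4, -4.6),
                           pause_exit = exp_law(9.0, 14.1),
                           run_speed = exp_law(0.52, 14.8),
                           detachment = NULL,
                           catastrophe = NULL,
                           interruption = NULL) {
  stopifnot(is.numeric(f_g), length(f_g) == 1L, f_g != 0,
            inherits(pause_entrance, "exp_law"),
            inherits(pause_exit, "exp_law"),
            inherits(run_speed, "exp_law"))
  for (law in list(detachment, catastrophe, interruption))
    if (!is.null(law) && !inherits(law, "exp_law"))
      stop("termination laws must be exp_law objects or NULL")
  structure(list(f_g = f_g,
                 pause_entrance = pause_entrance,
                 pause_exit = pause_exit,
                 run_speed = run_speed,
                 detachment = detachment,
                 catastrophe = catastrophe,
                 interruption = interruption),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameter set (rates min^-1, speeds um/min, forces pN)\n")
  cat(sprintf("  growth speed sensitivity F_g = %g pN\n", x$f_g))
  cat(sprintf("  pause entrance: k_EN = %g * exp(F / %g)\n",
              x$pause_entrance$amplitude, x$pause_entrance$force_scale))
  cat(sprintf("  pause exit:     k_EX = %g * exp(F / %g)\n",
              x$pause_exit$amplitude, x$pause_exit$force_scale))
  cat(sprintf("  run speed:      v_RUN = %g * exp(F / %g)\n",
              x$run_speed$amplitude, x$run_speed$force_scale))
  for (nm in c("detachment", "catastrophe", "interruption")) {
    if (is.null(x[[nm]])) {
      cat(sprintf("  %s: not configured\n", nm))
    } else if (is.infinite(x[[nm]]$force_scale)) {
      cat(sprintf("  %s: %g min^-1 (force-independent)\n", nm,
                  x[[nm]]$amplitude))
    } else {
      cat(sprintf("  %s: %g * exp(F / %g)\n", nm,
                  x[[nm]]$amplitude, x[[nm]]$force_scale))
    }
  }
  invisible(x)
}

#' Write / read a kinetic parameter file
#'
#' Round-trips a [kinetic_params()] object through a YAML parameter file whose
#' keys mirror the standard parameter table (amplitudes in min^-1 or um/min,
#' force sensitivities in pN). Unconfigured termination laws are omitted.
#'
#' @param params A [kinetic_params()].
#' @param path File path.
#' @return `write_kinetic_params()` returns `path` invisibly;
#'   `read_kinetic_params()` returns a [kinetic_params()].
#' @export
write_kinetic_params <- function(params, path) {
  stopifnot(inherits(params, "kinetic_params"))
  x <- list(
    growth_speed_force_sensitivity_pN = params$f_g,
    unloaded_pause_entrance_rate_per_min = params$pause_entrance$amplitude,
    pause_entrance_force_sensitivity_pN = params$pause_entrance$force_scale,
    unloaded_pause_exit_rate_per_min = params$pause_exit$amplitude,
    pause_exit_force_sensitivity_pN = params$pause_exit$force_scale,
    unloaded_run_speed_um_per_min = params$run_speed$amplitude,
    run_speed_force_sensitivity_pN = params$run_speed$force_scale)
  for (nm in c("detachment", "catastrophe", "interruption")) {
    if (!is.null(params[[nm]])) {
      x[[paste0("unloaded_", nm, "_rate_per_min")]] <- params[[nm]]$amplitude
      x[[paste0(nm, "_force_sensitivity_pN")]] <-
        if (is.infinite(params[[nm]]$force_scale)) ".inf"
        else params[[nm]]$force_scale
    }
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_kinetic_params
#' @export
read_kinetic_params <- function(path) {
  x <- yaml::read_yaml(path)
  need <- c("growth_speed_force_sensitivity_pN",
            "unloaded_pause_entrance_rate_per_min",
            "pause_entrance_force_sensitivity_pN",
            "unloaded_pause_exit_rate_per_min",
            "pause_exit_force_sensitivity_pN",
            "unloaded_run_speed_um_per_min",
            "run_speed_force_sensitivity_pN")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("parameter file is missing keys: ", paste(missing, collapse = ", "))
  term <- lapply(c("detachment", "catastrophe", "interruption"), function(nm) {
    a <- x[[paste0("unloaded_", nm, "_rate_per_min")]]
    if (is.null(a)) return(NULL)
    fs <- x[[paste0(nm, "_force_sensitivity_pN")]]
    if (is.null(fs) || identical(fs, ".inf")) fs <- Inf
    exp_law(a, as.numeric(fs))
  })
  kinetic_params(
    f_g = x$growth_speed_force_sensitivity_pN,
    pause_entrance = exp_law(x$unloaded_pause_entrance_rate_per_min,
                             x$pause_entrance_force_sensitivity_pN),
    pause_exit = exp_law(x$unloaded_pause_exit_rate_per_min,
                         x$pause_exit_force_sensitivity_pN),
    run_speed = exp_law(x$unloaded_run_speed_um_per_min,
                        x$run_speed_force_sensitivity_pN),
    detachment = term[[1]], catastrophe = term[[2]], interruption = term[[3]])
}

#' Pool of intrinsic-speed measurements
#'
#' A collection of (speed, force) pairs from which per-microtubule intrinsic
#' unloaded speeds are drawn when simulating heterogeneous microtubules. The
#' pausing model draws from run-speed measurements; the non-pausing model
#' draws from whole-trace growth-speed measurements.
#'
#' @param speed Measured speeds (um/min), > 0.
#' @param force Tensions at which the speeds were measured (pN); must lie in
#'   the 0.5--18 pN validity range of the assay.
#' @return An object of class `speed_pool` (a data.frame with columns
#'   `speed_um_per_min`, `force_pN`).
#' @export
speed_pool <- function(speed, force) {
  stopifnot(is.numeric(speed), is.numeric(force),
            length(speed) == length(force), length(speed) >= 1L)
  if (any(!is.finite(speed)) || any(speed <= 0))
    stop("pool speeds must be positive and finite")
  if (any(force < .FORCE_VALID_RANGE[1] - 1e-9) ||
      any(force > .FORCE_VALID_RANGE[2] + 1e-9))
    stop(sprintf("pool forces must lie within the %g-%g pN validity range",
                 .FORCE_VALID_RANGE[1], .FORCE_VALID_RANGE[2]))
  structure(data.frame(speed_um_per_min = speed, force_pN = force),
            class = c("speed_pool", "data.frame"))
}

#' Read a speed pool from a two-column tabular file
#'
#' @param path CSV/TSV file with columns `speed_um_per_min` and `force_pN`.
#' @param delim Field delimiter; guessed from the extension by default.
#' @return A [speed_pool()].
#' @export
read_speed_pool <- function(path, delim = NULL) {
  df <- .read_delim_file(path, delim)
  for (k in c("speed_um_per_min", "force_pN"))
    if (is.null(df[[k]])) stop("speed pool file is missing column: ", k)
  speed_pool(df$speed_um_per_min, df$force_pN)
}

# cap on plausible unloaded run speeds: 30 nm/s = 1.8 um/min
.UNLOADED_SPEED_CAP <- 1.8

#' Draw intrinsic unloaded speeds from a measurement pool
#'
#' Draws (speed, force) pairs uniformly at random from the pool and
#' extrapolates each to zero force along an exponential law with the given
#' `force_scale`. Draws whose extrapolated unloaded speed exceeds
#' `max_unloaded` (default 1.8 um/min, i.e. 30 nm/s) are treated as outliers
#' and redrawn; set `max_unloaded = Inf` to disable the filter (as for
#' whole-trace growth-speed pools).
#'
#' @param pool A [speed_pool()].
#' @param force_scale Characteristic force of the extrapolation law (pN).
#' @param n Number of draws.
#' @param max_unloaded Outlier cutoff on the unloaded speed (um/min).
#' @param seed Optional integer seed for reproducible draws.
#' @return Numeric vector of `n` unloaded intrinsic speeds (um/min).
#' @export
sample_intrinsic_speed <- function(pool, force_scale, n = 1L,
                                   max_unloaded = .UNLOADED_SPEED_CAP,
                                   seed = NULL) {
  stopifnot(inherits(pool, "speed_pool"))
  if (!is.null(seed)) set.seed(seed)
  v0 <- extrapolate_unloaded(pool$speed_um_per_min, pool$force_pN, force_scale)
  keep <- which(v0 <= max_unloaded)
  if (!length(keep))
    stop("speed pool is empty after outlier filtering (all unloaded speeds > ",
         max_unloaded, " um/min)")
  v0[sample(keep, n, replace = TRUE)]
}
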