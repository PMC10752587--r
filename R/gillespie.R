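#' @keywords internal
#' @noRd
.law_consts <- function(law, per_second = TRUE) {
  if (is.null(law)) return(NULL)
  a <- law$amplitude
  if (per_second) a <- a / 60
  list(a = a, fs = law$force_scale)
}

#' @keywords internal
#' @noRd
.law_value <- function(cst, force) {
  if (is.infinite(cst$fs)) rep.int(cst$a, length(force))
  else cst$a * exp(force / cst$fs)
}

# Shared modified-Gillespie engine for one or more tips.
#
# All stochastic events (pause entrance/exit, detachment, catastrophe,
# interruption) are treated as independent Poisson processes whose rates are
# re-evaluated at the current forces; the force-dependent rates are only
# locally Poisson, so the waiting time drawn from the summed rates is capped
# at `dt_max` (and at the next output grid point). If the drawn waiting time
# exceeds the cap, the tips simply advance deterministically for the capped
# interval with no event. A terminating event on any tip ends the usable
# trace (the trajectory is censored there, not discarded).
#' @keywords internal
#' @noRd
.sim_engine <- function(x0, force_fun, params, model, v0,
                        duration, dt_max, grid_dt, termination) {
  nt <- length(x0)
  pausing <- model %in% c("pausing", "pausing_ergodic")
  kEN <- .law_consts(params$pause_entrance)
  kEX <- .law_consts(params$pause_exit)
  term <- list(detachment = .law_consts(params$detachment),
               catastrophe = .law_consts(params$catastrophe),
               interruption = .law_consts(params$interruption))
  if (termination) {
    term <- term[!vapply(term, is.null, logical(1))]
    if (!length(term))
      stop("no termination laws configured: supply detachment/catastrophe/",
           "interruption laws in `params`, or set `termination = FALSE`")
  } else {
    term <- list()
  }
  speed_fs <- if (pausing) params$run_speed$force_scale else params$f_g
  v0s <- v0 / 60                             # um/s at zero force
  ev_names <- c(if (pausing) "switch", names(term))
  n_ev <- length(ev_names)

  grid <- seq(0, duration, by = grid_dt)
  ng <- length(grid)
  X <- matrix(NA_real_, ng, nt)
  Fm <- matrix(NA_real_, ng, nt)
  M <- matrix(NA_integer_, ng, nt)
  ev_time <- numeric(0); ev_tip <- integer(0); ev_what <- character(0)

  x <- x0
  mode <- rep.int(1L, nt)                    # 1 = run/growing, 0 = pause
  t <- 0
  gi <- 1L
  f <- force_fun(x)
  X[1L, ] <- x; Fm[1L, ] <- f; M[1L, ] <- mode
  censor_time <- NA_real_
  cause <- "none"
  alive <- TRUE

  while (alive && gi < ng) {
    f <- force_fun(x)
    # per-tip event rates (per second), laid out tip-major
    lam <- numeric(nt * n_ev)
    if (n_ev > 0L) {
      k <- 1L
      if (pausing) {
        sw <- ifelse(mode == 1L, .law_value(kEN, f), .law_value(kEX, f))
        lam[seq.int(1L, by = n_ev, length.out = nt)] <- sw
        k <- 2L
      }
      for (tl in term) {
        lam[seq.int(k, by = n_ev, length.out = nt)] <- .law_value(tl, f)
        k <- k + 1L
      }
    }
    Rtot <- sum(lam)
    tau <- if (Rtot > 0) stats::rexp(1L, Rtot) else Inf
    cap <- min(dt_max, grid[gi + 1L] - t)
    v <- v0s * exp(f / speed_fs) * (mode == 1L)
    if (tau < cap) {
      x <- x + v * tau
      t <- t + tau
      idx <- sample.int(nt * n_ev, 1L, prob = lam)
      tip <- (idx - 1L) %/% n_ev + 1L
      what <- ev_names[(idx - 1L) %% n_ev + 1L]
      ev_time <- c(ev_time, t); ev_tip <- c(ev_tip, tip)
      if (identical(what, "switch")) {
        ev_what <- c(ev_what,
                     if (mode[tip] == 1L) "pause_entrance" else "pause_exit")
        mode[tip] <- 1L - mode[tip]
      } else {
        ev_what <- c(ev_what, what)
        alive <- FALSE
        censor_time <- t
        cause <- what
      }
    } else {
      x <- x + v * cap
      t <- t + cap
      if (t >= grid[gi + 1L] - 1e-12) {
        gi <- gi + 1L
        t <- grid[gi]
        X[gi, ] <- x; Fm[gi, ] <- force_fun(x); M[gi, ] <- mode
      }
    }
  }
  keep <- seq_len(gi)
  list(time = grid[keep],
       x = X[keep, , drop = FALSE],
       force = Fm[keep, , drop = FALSE],
       mode = M[keep, , drop = FALSE],
       events = data.frame(time = ev_time, tip = ev_tip, event = ev_what,
                           stringsAsFactors = FALSE),
       censor_time = censor_time,
       termination_cause = cause)
}

#' Simulate a single microtubule growing under constant force
#'
#' Runs the modified Gillespie scheme for one tip held at a constant tension.
#' Between events the tip advances deterministically at the current state's
#' speed (the run-speed law for pausing models, the growth-speed law for the
#' non-pausing model; zero while paused). Waiting times are drawn from the
#' exponential distribution of the summed active rates and capped at `dt_max`
#' so the force-dependent rates remain locally Poisson. Detachment,
#' catastrophe, or interruption ends the trajectory and records the cause.
#'
#' @param force Constant applied tension (pN). A warning is issued if it lies
#'   outside the 0.5--18 pN validity range of the kinetic laws.
#' @param params A [kinetic_params()].
#' @param model One of `"pausing"`, `"non_pausing"`, `"pausing_ergodic"`.
#' @param v0 Intrinsic unloaded speed (um/min): the run-speed amplitude for
#'   pausing models or growth-speed amplitude for the non-pausing model.
#'   Defaults to the run-speed law amplitude for `"pausing_ergodic"`;
#'   required otherwise (typically drawn via [sample_intrinsic_speed()]).
#' @param duration Simulated time (s).
#' @param dt_max Timestep cap (s); must be <= 1.
#' @param grid_dt Output grid spacing (s).
#' @param termination If `TRUE` (default), the termination laws in `params`
#'   are active and must be configured; set `FALSE` to disable termination
#'   explicitly.
#' @param seed Optional integer seed.
#' @return An object of class `mt_trajectory`: list with elements `time`,
#'   `x`, `force`, `mode` (matrices with one column), `events` (data.frame of
#'   time/tip/event), `censor_time` (`NA` if the trace survived), and
#'   `termination_cause`.
#' @export
simulate_single <- function(force, params = kinetic_params(),
                            model = c("pausing", "non_pausing", "pausing_ergodic"),
                            v0 = NULL, duration = 400, dt_max = 1, grid_dt = 1,
                            termination = TRUE, seed = NULL) {
  model <- match.arg(model)
  stopifnot(is.numeric(force), length(force) == 1L, is.finite(force),
            duration > 0, dt_max > 0, dt_max <= 1, grid_dt > 0)
  if (force < .FORCE_VALID_RANGE[1] || force > .FORCE_VALID_RANGE[2])
    warning(sprintf("constant force %g pN is outside the %g-%g pN validity range",
                    force, .FORCE_VALID_RANGE[1], .FORCE_VALID_RANGE[2]))
  v0 <- .resolve_v0(v0, model, params, n = 1L)
  if (!is.null(seed)) set.seed(seed)
  out <- .sim_engine(x0 = 0, force_fun = function(x) force, params = params,
                     model = model, v0 = v0, duration = duration,
                     dt_max = dt_max, grid_dt = grid_dt,
                     termination = termination)
  out$model <- model
  out$v0 <- v0
  out$applied_force <- force
  class(out) <- "mt_trajectory"
  out
}

#' @keywords internal
#' @noRd
.resolve_v0 <- function(v0, model, params, n) {
  if (is.null(v0)) {
    if (model == "pausing_ergodic") {
      v0 <- rep(params$run_speed$amplitude, n)
    } else {
      stop("`v0` (intrinsic unloaded speed, um/min) is required for the ",
           model, " model; draw it with sample_intrinsic_speed()")
    }
  }
  stopifnot(is.numeric(v0), length(v0) == n, all(is.finite(v0)), all(v0 > 0))
  v0
}

#' Simulate a coupled microtubule pair sharing an elastic load
#'
#' Both tips start side by side (`x1 = x2 = 0`), in run, each bearing half of
#' the total load. At every step the per-tip tensions are recomputed from the
#' tip positions via [partition_force()], all active event rates are
#' re-evaluated at the current forces, and one joint Gillespie clock runs over
#' the union of both tips' events (waiting times capped at `dt_max`). The
#' trajectory is recorded on the output grid; the first terminating event on
#' either tip censors the pair's usable trace at that time.
#'
#' @param coupler A [coupler_config()].
#' @param params A [kinetic_params()].
#' @param model Growth model variant (see [simulate_single()]). For
#'   `"pausing_ergodic"` both tips share the run-speed law amplitude;
#'   otherwise two intrinsic speeds must be supplied in `v0`.
#' @param v0 Numeric vector of 2 intrinsic unloaded speeds (um/min).
#' @param n_tips Number of coupled tips (default 2; the force partition
#'   generalizes to N tips).
#' @param duration,dt_max,grid_dt,termination,seed As in [simulate_single()].
#' @return An object of class `pair_trajectory`: list with `time`, `x`,
#'   `force`, `mode` (one column per tip), `events`, `censor_time`,
#'   `termination_cause`, plus the configuration used.
#' @examples
#' cfg <- coupler_config(kappa = 5, f_total = 8)
#' tr <- simulate_pair(cfg, v0 = c(0.4, 0.6), termination = FALSE,
#'                     duration = 100, seed = 1)
#' range(rowSums(tr$force))  # total load conserved at every step
#' @export
simulate_pair <- function(coupler, params = kinetic_params(),
                          model = c("pausing", "non_pausing", "pausing_ergodic"),
                          v0 = NULL, n_tips = 2L, duration = 400,
                          dt_max = 1, grid_dt = 1, termination = TRUE,
                          seed = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(coupler, "coupler_config"), n_tips >= 2L,
            duration > 0, dt_max > 0, dt_max <= 1, grid_dt > 0)
  v0 <- .resolve_v0(v0, model, params, n = n_tips)
  if (!is.null(seed)) set.seed(seed)
  kap <- coupler$kappa; ft <- coupler$f_total; fl <- coupler$force_floor
  force_fun <- function(x) {
    f <- ft / length(x) + kap * (mean(x) - x)
    if (!is.null(fl)) f <- pmax(f, fl)
    f
  }
  out <- .sim_engine(x0 = rep(0, n_tips), force_fun = force_fun,
                     params = params, model = model, v0 = v0,
                     duration = duration, dt_max = dt_max, grid_dt = grid_dt,
                     termination = termination)
  out$model <- model
  out$v0 <- v0
  out$coupler <- coupler
  class(out) <- "pair_trajectory"
  out
}

#' @export
print.pair_trajectory <- function(x, ...) {
  cat(sprintf("Coupled-pair trajectory (%s model): %d grid points, %s\n",
              x$model, length(x$time),
              if (is.na(x$censor_time)) "ran to completion"
              else sprintf("censored at %.1f s (%s)", x$censor_time,
                           x$termination_cause)))
  invisible(x)
}

#' @export
print.mt_trajectory <- function(x, ...) {
  cat(sprintf("Single-tip trajectory (%s model, %g pN): %d grid points, %s\n",
              x$model, x$applied_force, length(x$time),
              if (is.na(x$censor_time)) "ran to completion"
              else sprintf("censored at %.1f s (%s)", x$censor_time,
                           x$termination_cause)))
  invisible(x)
}

#' Run and pause dwell times of a simulated trajectory
#'
#' Extracts completed dwell times in the run and pause states from a
#' trajectory's event log. The initial run dwell (from time zero to the first
#' pause entrance) is included; the final, incomplete dwell is not.
#'
#' @param traj An `mt_trajectory` or `pair_trajectory`.
#' @param tip Which tip's dwells to extract (default 1).
#' @return List with numeric components `run` and `pause` (seconds).
#' @export
dwell_times <- function(traj, tip = 1L) {
  ev <- traj$events
  ev <- ev[ev$tip == tip & ev$event %in% c("pause_entrance", "pause_exit"), ]
  run <- numeric(0); pause <- numeric(0)
  t_prev <- 0
  for (i in seq_len(nrow(ev))) {
    if (ev$event[i] == "pause_entrance") run <- c(run, ev$time[i] - t_prev)
    else pause <- c(pause, ev$time[i] - t_prev)
    t_prev <- ev$time[i]
  }
  list(run = run, pause = pause)
}

#' Convert a simulated pair trajectory to a pair recording
#'
#' @param traj A `pair_trajectory`.
#' @param noise_sd Optional Gaussian position noise (um) added independently
#'   to each tip at each grid point (emulating measurement noise).
#' @param label Optional condition label (e.g. `"soft"` or `"stiff"`).
#' @param id Optional identifier.
#' @return A [pair_recording()].
#' @export
as_pair_recording <- function(traj, noise_sd = 0, label = NA_character_,
                              id = NA_character_) {
  stopifnot(inherits(traj, "pair_trajectory"))
  x1 <- traj$x[, 1]; x2 <- traj$x[, 2]
  if (noise_sd > 0) {
    x1 <- x1 + stats::rnorm(length(x1), 0, noise_sd)
    x2 <- x2 + stats::rnorm(length(x2), 0, noise_sd)
  }
  pair_recording(time = traj$time, x1 = x1, x2 = x2,
                 f1 = traj$force[, 1], f2 = traj$force[, 2],
                 censor_time = if (is.na(traj$censor_time)) max(traj$time)
                               else traj$censor_time,
                 censored = !is.na(traj$censor_time),
                 label = label, id = id)
}

#' Ensemble summary of simulated pair trajectories
#'
#' Computes, at each output grid time, the mean and SEM of the absolute tip
#' separation over all pairs whose trace is still usable (not yet censored),
#' mirroring the dual-trap ensemble statistics. SEM over fewer than two
#' surviving pairs is reported as missing.
#'
#' @param trajectories List of `pair_trajectory` objects (or
#'   [pair_recording()]s).
#' @return Data frame with columns `time`, `mean_sep`, `sem`, `n`.
#' @export
summarize_ensemble <- function(trajectories) {
  stopifnot(length(trajectories) >= 1L)
  series <- lapply(trajectories, function(tr) {
    if (inherits(tr, "pair_trajectory"))
      data.frame(time = tr$time, separation = abs(tr$x[, 1] - tr$x[, 2]))
    else separation_series(tr)
  })
  ensemble_mean_sem(series)
}
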