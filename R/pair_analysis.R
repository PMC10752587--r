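#' Dual-trap pair recording
#'
#' Paired tip positions versus time for two microtubules sharing a load,
#' measured (dual-trap assay) or simulated. The trace is usable on
#' `[0, censor_time]`: growth episodes end by detachment, catastrophe, or
#' other interruption, and subsequent samples (if any) are ignored by the
#' ensemble statistics.
#'
#' @param time Sample times (s), strictly increasing.
#' @param x1,x2 Tip positions (um).
#' @param f1,f2 Optional per-tip forces (pN).
#' @param censor_time End of the usable growth episode (s); defaults to the
#'   last sample time.
#' @param censored Logical: did the episode end by a terminating event
#'   (`TRUE`) rather than by the end of the observation window?
#' @param label Optional condition label (e.g. `"soft"`, `"stiff"`).
#' @param id Optional identifier.
#' @return An object of class `pair_recording`.
#' @export
pair_recording <- function(time, x1, x2, f1 = NULL, f2 = NULL,
                           censor_time = NULL, censored = FALSE,
                           label = NA_character_, id = NA_character_) {
  stopifnot(is.numeric(time), length(time) >= 1L, all(diff(time) > 0),
            length(x1) == length(time), length(x2) == length(time))
  if (is.null(censor_time)) censor_time <- time[length(time)]
  stopifnot(censor_time >= time[1])
  structure(list(time = time, x1 = x1, x2 = x2, f1 = f1, f2 = f2,
                 censor_time = censor_time, censored = censored,
                 label = label, id = id),
            class = "pair_recording")
}

#' @export
print.pair_recording <- function(x, ...) {
  cat(sprintf("Pair recording%s%s: %.1f s usable%s\n",
              if (is.na(x$id)) "" else paste0(" ", x$id),
              if (is.na(x$label)) "" else sprintf(" (%s)", x$label),
              x$censor_time,
              if (x$censored) " (ended by terminating event)" else ""))
  invisible(x)
}

#' Tip-separation series at 1-s intervals
#'
#' Computes the absolute tip separation |x1 - x2| at regular intervals
#' (default 1 s) over the usable part of the recording, using the nearest
#' sample within half a step of each requested time.
#'
#' @param pr A [pair_recording()].
#' @param dt Resampling interval (s), default 1.
#' @return Data frame with columns `time` and `separation` (um), carrying the
#'   censoring time and label as attributes.
#' @export
separation_series <- function(pr, dt = 1) {
  stopifnot(inherits(pr, "pair_recording"), dt > 0)
  t_max <- min(pr$censor_time, pr$time[length(pr$time)])
  tt <- seq(0, floor(t_max / dt) * dt, by = dt)
  # nearest-sample lookup within half a step
  lo <- pmax(findInterval(tt, pr$time), 1L)
  hi <- pmin(lo + 1L, length(pr$time))
  idx <- ifelse(abs(pr$time[lo] - tt) <= abs(pr$time[hi] - tt), lo, hi)
  near <- abs(pr$time[idx] - tt) <= dt / 2
  tt <- tt[near]; idx <- idx[near]
  structure(data.frame(time = tt,
                       separation = abs(pr$x1[idx] - pr$x2[idx])),
            censor_time = pr$censor_time, censored = pr$censored,
            label = pr$label, id = pr$id)
}

#' Ensemble mean and SEM of tip separation versus time
#'
#' At each grid time, averages the tip separation over the pairs whose trace
#' is still usable (i.e. extends to that time); the SEM is sd/sqrt(N_t) over
#' those pairs, reported as missing when fewer than two pairs survive.
#'
#' @param series_list List of separation series (from [separation_series()]
#'   or equivalent data.frames with `time` and `separation`).
#' @return Data frame with columns `time`, `mean_sep`, `sem`, `n`.
#' @export
ensemble_mean_sem <- function(series_list) {
  stopifnot(is.list(series_list), length(series_list) >= 1L)
  grid <- sort(unique(unlist(lapply(series_list, function(s) s$time))))
  M <- vapply(series_list, function(s) {
    v <- rep(NA_real_, length(grid))
    v[match(s$time, grid)] <- s$separation
    v
  }, numeric(length(grid)))
  M <- matrix(M, nrow = length(grid))
  n <- rowSums(!is.na(M))
  mean_sep <- ifelse(n > 0, rowMeans(M, na.rm = TRUE), NA_real_)
  sem <- vapply(seq_along(grid), function(i) {
    v <- M[i, !is.na(M[i, ])]
    if (length(v) >= 2L) stats::sd(v) / sqrt(length(v)) else NA_real_
  }, numeric(1))
  data.frame(time = grid, mean_sep = mean_sep, sem = sem, n = n)
}

#' Early tip-separation rate
#'
#' Slope of the least-squares line through the separation series over the
#' first `window` seconds (default 100 s), reported in um/min with a
#' standard error estimated from the fit residuals. (The damped iterative
#' fit used for nonlinear laws reduces to ordinary least squares for a
#' straight line.)
#'
#' @param series A separation series (data.frame with `time`, `separation`).
#' @param window Fit window (s), default 100.
#' @return List with `rate` (um/min), `se` (um/min), and `n_points`; both
#'   are `NA` if fewer than 2 points fall inside the window.
#' @export
separation_rate <- function(series, window = 100) {
  stopifnot(is.data.frame(series), window > 0)
  s <- series[series$time <= window, , drop = FALSE]
  if (nrow(s) < 2L)
    return(list(rate = NA_real_, se = NA_real_, n_points = nrow(s)))
  fit <- stats::lm(separation ~ time, data = s)
  slope <- stats::coef(fit)[["time"]]
  se <- if (nrow(s) >= 3L) {
    sxx <- sum((s$time - mean(s$time))^2)
    sqrt(sum(stats::residuals(fit)^2) / (nrow(s) - 2L) / sxx)
  } else NA_real_
  list(rate = slope * 60, se = se * 60, n_points = nrow(s))
}
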