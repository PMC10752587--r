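#' Force-clamp recording of a growing microtubule
#'
#' A uniformly sampled position-versus-time trace (nominally 200 Hz) of a
#' single microtubule tip held under constant tension.
#'
#' @param time Sample times (s), strictly increasing and uniformly spaced
#'   (within 1% tolerance).
#' @param position Tip positions (um).
#' @param force Constant applied tension (pN), or `NA` if unknown.
#' @param id Optional identifier.
#' @return An object of class `mt_recording`.
#' @export
recording <- function(time, position, force = NA_real_, id = NA_character_) {
  stopifnot(is.numeric(time), is.numeric(position),
            length(time) == length(position), length(time) >= 3L)
  dt <- diff(time)
  if (any(dt <= 0)) stop("`time` must be strictly increasing")
  if (max(dt) - min(dt) > 0.01 * stats::median(dt))
    stop("`time` must be uniformly sampled (within 1% tolerance)")
  if (time[length(time)] - time[1] < 2)
    stop("recording must span at least 2 s (one full velocity window)")
  structure(list(time = time, position = position,
                 fs = 1 / stats::median(dt),
                 force = force, id = id),
            class = "mt_recording")
}

#' @export
print.mt_recording <- function(x, ...) {
  cat(sprintf("Force-clamp recording%s: %.1f s at %.0f Hz%s\n",
              if (is.na(x$id)) "" else paste0(" ", x$id),
              x$time[length(x$time)] - x$time[1], x$fs,
              if (is.na(x$force)) "" else sprintf(", F = %.2f pN", x$force)))
  invisible(x)
}

#' Sliding-window instantaneous growth speed
#'
#' Estimates the instantaneous growth speed at each sample as the slope of the
#' ordinary-least-squares line fitted to position versus time over a centered
#' window (default 2 s). Samples where the full window does not fit carry no
#' estimate; segmentation assigns them the adjacent interval's label.
#'
#' @param rec An [recording()].
#' @param window Window length (s), default 2.
#' @return An object of class `velocity_trace`: list with `time`, `speed`
#'   (um/min), `fs`, `window`, and the parent recording's time span and id.
#' @export
sliding_velocity <- function(rec, window = 2) {
  stopifnot(inherits(rec, "mt_recording"), window > 0)
  if (rec$time[length(rec$time)] - rec$time[1] < window)
    stop("recording is shorter than the velocity window")
  dt <- 1 / rec$fs
  h <- floor(window / (2 * dt))
  j <- (-h):h
  tj <- j * dt
  # OLS slope of position on time over the window, as a linear filter
  coefs <- tj / sum(tj^2)
  slope <- stats::filter(rec$position, rev(coefs), sides = 2)  # um/s
  ok <- !is.na(slope)
  structure(list(time = rec$time[ok],
                 speed = as.numeric(slope[ok]) * 60,
                 fs = rec$fs, window = window,
                 rec_start = rec$time[1],
                 rec_end = rec$time[length(rec$time)],
                 id = rec$id),
            class = "velocity_trace")
}

#' @export
print.velocity_trace <- function(x, ...) {
  cat(sprintf("Velocity trace: %d samples at %.0f Hz (%g s window)\n",
              length(x$speed), x$fs, x$window))
  invisible(x)
}

#' @keywords internal
#' @noRd
.gauss_mix_model <- function(k) {
  # sum of k Gaussians evaluated at x, parameters packed as (A, mu, sigma) * k
  function(p, x) {
    y <- 0
    for (i in seq_len(k)) {
      a <- p[3 * i - 2]; mu <- p[3 * i - 1]; s <- p[3 * i]
      y <- y + a * exp(-(x - mu)^2 / (2 * s^2))
    }
    y
  }
}

#' @keywords internal
#' @noRd
.fit_gauss_mix <- function(mids, counts, k, speeds, binwidth) {
  # initialize: one component pinned near zero, others at quantiles of the
  # positive speeds; amplitudes from the local histogram height.  Component
  # widths are bounded below by one bin: a peak narrower than the histogram
  # resolution is an overfitting artifact, not a kinetic state.
  qs <- stats::quantile(speeds[speeds > 0],
                        probs = seq(0.35, 0.9, length.out = k - 1),
                        names = FALSE)
  if (anyNA(qs) || length(qs) < k - 1) return(NULL)
  mu0 <- c(0, qs)
  s0 <- rep(max(diff(range(mids)) / (4 * k), binwidth), k)
  a0 <- vapply(mu0, function(m) max(counts[which.min(abs(mids - m))], 1),
               numeric(1))
  p0 <- as.numeric(rbind(a0, mu0, s0))
  fn <- .gauss_mix_model(k)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0,
                       fn = function(p) counts - fn(p, mids),
                       lower = rep(c(0, -Inf, binwidth), k),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- fit$par
  comp <- data.frame(amplitude = p[seq(1, 3 * k, by = 3)],
                     mean = p[seq(2, 3 * k, by = 3)],
                     sd = abs(p[seq(3, 3 * k, by = 3)]))
  list(k = k, components = comp, rss = sum(fit$fvec^2))
}

#' @keywords internal
#' @noRd
.gauss_intersection <- function(a1, mu1, s1, a2, mu2, s2) {
  # solve a1*exp(-(x-mu1)^2/2s1^2) = a2*exp(-(x-mu2)^2/2s2^2) between means
  lo <- min(mu1, mu2); hi <- max(mu1, mu2)
  A <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
  B <- mu1 / s1^2 - mu2 / s2^2
  C <- mu2^2 / (2 * s2^2) - mu1^2 / (2 * s1^2) + log(a1 / a2)
  roots <- if (abs(A) < 1e-12) {
    if (abs(B) < 1e-12) numeric(0) else -C / B
  } else {
    disc <- B^2 - 4 * A * C
    if (disc < 0) numeric(0)
    else (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  }
  roots <- roots[roots > lo & roots < hi]
  if (length(roots)) roots[which.min(abs(roots - (lo + hi) / 2))]
  else (lo + hi) / 2   # densities never cross between means: split midway
}

#' Per-recording pause/run speed threshold
#'
#' Builds a histogram of the instantaneous growth speeds (Freedman-Diaconis
#' binning by default) and fits it with sums of 2 to `max_components`
#' Gaussian peaks by damped least squares. The number of peaks is the
#' smallest k for which adding another peak improves the residual sum of
#' squares by less than `improve_tol` (relative). The component whose mean is
#' nearest zero (and within `pause_mean_tol`) is the pause peak; the
#' threshold is the speed at which the pause peak's density intersects the
#' density of the component with the lowest mean above it, between the two
#' means.
#'
#' If no component qualifies as a pause peak, the recording has no detectable
#' pause state and a sentinel (`no_pause = TRUE`) is returned; segmentation
#' then labels the whole recording as a single run.
#'
#' @param vt A [sliding_velocity()] trace with at least 500 samples.
#' @param max_components Largest number of Gaussian peaks to try (default 6).
#' @param pause_mean_tol How close to zero (um/min) a component's mean must
#'   be to qualify as the pause peak (default 0.1).
#' @param improve_tol Relative residual improvement below which a larger
#'   model order is not accepted (default 0.05).
#' @param binwidth Histogram bin width (um/min); Freedman-Diaconis by default.
#' @return An object of class `pause_threshold`: list with `threshold`
#'   (um/min, `NA` if no pause state), `no_pause`, `k`, and the fitted
#'   `components` (amplitude, mean, sd).
#' @export
pause_threshold <- function(vt, max_components = 6, pause_mean_tol = 0.1,
                            improve_tol = 0.05, binwidth = NULL) {
  stopifnot(inherits(vt, "velocity_trace"))
  speeds <- vt$speed
  if (length(speeds) < 500)
    stop("velocity trace too short to form a speed histogram (need >= 500 samples)")
  if (is.null(binwidth)) {
    binwidth <- 2 * stats::IQR(speeds) / length(speeds)^(1 / 3)
    if (!is.finite(binwidth) || binwidth <= 0) binwidth <- diff(range(speeds)) / 30
  }
  breaks <- seq(floor(min(speeds) / binwidth) * binwidth,
                max(speeds) + binwidth, by = binwidth)
  hh <- graphics::hist(speeds, breaks = breaks, plot = FALSE)
  mids <- hh$mids; counts <- hh$counts

  best <- NULL
  for (k in 2:max_components) {
    f <- .fit_gauss_mix(mids, counts, k, speeds, binwidth)
    if (is.null(f)) next
    if (is.null(best)) { best <- f; next }
    if ((best$rss - f$rss) < improve_tol * best$rss) break
    best <- f
  }
  if (is.null(best))
    stop("Gaussian-mixture fit failed for all model orders (2-",
         max_components, " peaks)")
  comp <- best$components
  comp <- comp[comp$amplitude > 0 & comp$sd > 0, , drop = FALSE]
  i_pause <- which.min(abs(comp$mean))
  no_pause <- length(i_pause) == 0 || abs(comp$mean[i_pause]) >= pause_mean_tol
  threshold <- NA_real_
  if (!no_pause) {
    # run-side candidates must clear the near-zero tolerance: a second
    # component inside it is pause structure, not a growth state
    above <- which(comp$mean >= pause_mean_tol &
                     seq_len(nrow(comp)) != i_pause)
    if (!length(above)) {
      no_pause <- TRUE   # nothing but near-zero peaks: treat as single run
    } else {
      i_run <- above[which.min(comp$mean[above])]
      threshold <- .gauss_intersection(
        comp$amplitude[i_pause], comp$mean[i_pause], comp$sd[i_pause],
        comp$amplitude[i_run], comp$mean[i_run], comp$sd[i_run])
    }
  }
  structure(list(threshold = threshold, no_pause = no_pause,
                 k = best$k, components = comp, binwidth = binwidth),
            class = "pause_threshold")
}

#' @export
print.pause_threshold <- function(x, ...) {
  if (x$no_pause) cat("Pause threshold: no pause state detected (single run)\n")
  else cat(sprintf("Pause threshold: %.3f um/min (%d Gaussian peaks)\n",
                   x$threshold, x$k))
  invisible(x)
}

#' @keywords internal
#' @noRd
.merge_short_runs <- function(len, val, min_len) {
  # iteratively absorb interior runs shorter than min_len into their
  # flanking opposite-label intervals (three become one), shortest first
  repeat {
    n <- length(len)
    if (n < 3L) break
    interior <- c(FALSE, rep(TRUE, n - 2L), FALSE)
    cand <- which(interior & len < min_len)
    if (!length(cand)) break
    i <- cand[which.min(len[cand])]
    len <- c(len[seq_len(i - 2L)], len[i - 1L] + len[i] + len[i + 1L],
             len[-seq_len(i + 1L)])
    val <- c(val[seq_len(i - 2L)], val[i - 1L], val[-seq_len(i + 1L)])
  }
  list(lengths = len, values = val)
}

#' Segment a velocity trace into runs and pauses
#'
#' Thresholds the instantaneous growth speed: samples below the threshold are
#' provisional pauses, samples at or above it provisional runs. Any interior
#' interval shorter than `min_duration` is absorbed into its flanking
#' opposite-label intervals (the three become one), applied iteratively,
#' shortest interval first, until stable. If the threshold is never crossed
#' (or the threshold object carries the no-pause sentinel) the recording is a
#' single run interval. The intervals are extended to the parent recording's
#' edges, so boundary samples without a velocity estimate take the adjacent
#' interval's label.
#'
#' @param vt A [sliding_velocity()] trace.
#' @param threshold Numeric threshold speed (um/min) or a [pause_threshold()]
#'   object.
#' @param min_duration Minimum interior run/pause duration (s), default 1.
#' @return An object of class `interval_set`: data.frame with columns
#'   `start`, `end` (s), `label` (`"run"`/`"pause"`), `mean_speed` (um/min),
#'   with the threshold and recording id as attributes.
#' @export
segment_trace <- function(vt, threshold, min_duration = 1) {
  stopifnot(inherits(vt, "velocity_trace"))
  if (inherits(threshold, "pause_threshold")) {
    if (threshold$no_pause) threshold <- -Inf else threshold <- threshold$threshold
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  below <- vt$speed < threshold
  r <- rle(below)
  m <- .merge_short_runs(r$lengths, r$values,
                         min_len = round(min_duration * vt$fs))
  ends_idx <- cumsum(m$lengths)
  starts_idx <- c(1L, utils::head(ends_idx, -1L) + 1L)
  start <- vt$time[starts_idx]
  end <- vt$time[ends_idx]
  # extend boundary intervals to the full recording span
  start[1] <- vt$rec_start
  end[length(end)] <- vt$rec_end
  # interior boundaries: an interval ends where the next begins
  if (length(start) > 1L) start[-1L] <- end[-length(end)]
  mean_speed <- vapply(seq_along(starts_idx), function(i)
    mean(vt$speed[starts_idx[i]:ends_idx[i]]), numeric(1))
  iv <- data.frame(start = start, end = end,
                   label = ifelse(m$values, "pause", "run"),
                   mean_speed = mean_speed, stringsAsFactors = FALSE)
  structure(iv, class = c("interval_set", "data.frame"),
            threshold = threshold, id = vt$id)
}

#' Event and occupancy summary of an interval set
#'
#' Counts pause entrances (run-to-pause transitions) and exits
#' (pause-to-run), and total time in each state. Transitions at the trace
#' boundaries are not counted as events; boundary intervals contribute their
#' time only.
#'
#' @param iv An [segment_trace()] interval set.
#' @return List with `entrances`, `exits`, `time_run`, `time_pause` (s).
#' @export
interval_counts <- function(iv) {
  stopifnot(inherits(iv, "interval_set"))
  dur <- iv$end - iv$start
  lab <- iv$label
  trans_to <- lab[-1L]
  list(entrances = sum(trans_to == "pause"),
       exits = sum(trans_to == "run"),
       time_run = sum(dur[lab == "run"]),
       time_pause = sum(dur[lab == "pause"]))
}

#' Overall growth speed during runs for one recording
#'
#' Duration-weighted mean of the per-interval mean speeds over run intervals:
#' \deqn{v_{run} = \sum_i v_i t_i / T,}
#' where v_i and t_i are the mean speed and duration of the i-th run interval
#' and T is the total time in run.
#'
#' @param iv An [segment_trace()] interval set.
#' @return Run speed (um/min), or `NA` if the recording has no run interval.
#' @export
recording_run_speed <- function(iv) {
  stopifnot(inherits(iv, "interval_set"))
  runs <- iv[iv$label == "run", , drop = FALSE]
  if (!nrow(runs)) return(NA_real_)
  dur <- runs$end - runs$start
  sum(runs$mean_speed * dur) / sum(dur)
}

#' Segment a recording end to end
#'
#' Convenience wrapper: sliding-window velocity, per-recording threshold,
#' segmentation, and per-recording summary in one call.
#'
#' @param rec An [recording()].
#' @param window Velocity window (s).
#' @param min_duration Minimum interior interval duration (s).
#' @param threshold Optional fixed threshold (um/min); estimated from the
#'   speed histogram via [pause_threshold()] when `NULL`.
#' @param ... Passed to [pause_threshold()].
#' @return List with components `velocity`, `threshold`, `intervals`, and
#'   `summary` (a one-row data.frame with force, counts, times and run speed).
#' @export
segment_recording <- function(rec, window = 2, min_duration = 1,
                              threshold = NULL, ...) {
  vt <- sliding_velocity(rec, window = window)
  thr <- if (is.null(threshold)) pause_threshold(vt, ...) else threshold
  iv <- segment_trace(vt, thr, min_duration = min_duration)
  cts <- interval_counts(iv)
  summary <- data.frame(
    id = rec$id, force = rec$force,
    entrances = cts$entrances, exits = cts$exits,
    time_run = cts$time_run, time_pause = cts$time_pause,
    run_speed = recording_run_speed(iv),
    threshold = if (inherits(thr, "pause_threshold")) thr$threshold
                else as.numeric(thr),
    stringsAsFactors = FALSE)
  list(velocity = vt, threshold = thr, intervals = iv, summary = summary)
}
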