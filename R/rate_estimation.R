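#' Force-bin scheme for force-clamp recordings
#'
#' Ordered bin edges (pN) used to group constant-force recordings. The
#' default is the standard seven-bin scheme with edges 0.69, 1.94, 2.97,
#' 3.999, 5.98, 7.99, 10.3, 18 pN.
#'
#' @param edges Strictly increasing numeric vector of bin edges (pN).
#' @return An object of class `force_bins`.
#' @export
force_bins <- function(edges = c(0.69, 1.94, 2.97, 3.999, 5.98, 7.99, 10.3, 18)) {
  stopifnot(is.numeric(edges), length(edges) >= 2L, all(diff(edges) > 0))
  structure(list(edges = edges, n_bins = length(edges) - 1L),
            class = "force_bins")
}

#' @export
print.force_bins <- function(x, ...) {
  cat(sprintf("Force bin scheme: %d bins, edges %s pN\n", x$n_bins,
              paste(x$edges, collapse = ", ")))
  invisible(x)
}

#' Aggregate segmented recordings into force-binned kinetics
#'
#' Each recording (one row of `summaries`, as produced by
#' [segment_recording()]) is assigned to a force bin by its nominal clamp
#' force. Per bin, pause entrance and exit rates are total event counts
#' divided by the total time spent in run and pause respectively:
#' k_EN = entrances / time-in-run, k_EX = exits / time-in-pause (min^-1).
#' Counting uncertainties are SEM = k / sqrt(N_events); the run-speed SEM is
#' sd / sqrt(N_recordings); the x-uncertainty is the SD of forces in the bin.
#'
#' @param summaries Data frame with one row per recording and columns
#'   `force`, `entrances`, `exits`, `time_run`, `time_pause`, `run_speed`.
#' @param scheme A [force_bins()].
#' @return An object of class `binned_kinetics`: data.frame with one row per
#'   bin (bin, force_lo, force_hi, n_recordings, entrances, exits,
#'   time_run_s, time_pause_s, k_en, sem_k_en, k_ex, sem_k_ex,
#'   mean_run_speed, sem_run_speed, force_mean, force_sd).
#' @export
bin_recordings <- function(summaries, scheme = force_bins()) {
  stopifnot(is.data.frame(summaries),
            all(c("force", "entrances", "exits", "time_run", "time_pause",
                  "run_speed") %in% names(summaries)),
            inherits(scheme, "force_bins"))
  edges <- scheme$edges
  idx <- findInterval(summaries$force, edges, rightmost.closed = TRUE)
  out_of_range <- idx < 1L | idx > scheme$n_bins
  if (any(out_of_range)) {
    warning(sum(out_of_range), " recording(s) with forces outside all bins ",
            "were excluded")
    summaries <- summaries[!out_of_range, , drop = FALSE]
    idx <- idx[!out_of_range]
  }
  rows <- lapply(seq_len(scheme$n_bins), function(b) {
    s <- summaries[idx == b, , drop = FALSE]
    en <- sum(s$entrances); ex <- sum(s$exits)
    t_run <- sum(s$time_run); t_pause <- sum(s$time_pause)
    k_en <- if (t_run > 0) en / t_run * 60 else NA_real_
    k_ex <- if (t_pause > 0) ex / t_pause * 60 else NA_real_
    rs <- s$run_speed[!is.na(s$run_speed)]
    data.frame(
      bin = b, force_lo = edges[b], force_hi = edges[b + 1L],
      n_recordings = nrow(s), entrances = en, exits = ex,
      time_run_s = t_run, time_pause_s = t_pause,
      k_en = k_en,
      sem_k_en = if (en > 0) k_en / sqrt(en) else NA_real_,
      k_ex = k_ex,
      sem_k_ex = if (ex > 0) k_ex / sqrt(ex) else NA_real_,
      mean_run_speed = if (length(rs)) mean(rs) else NA_real_,
      sem_run_speed = if (length(rs) > 1) stats::sd(rs) / sqrt(length(rs))
                      else NA_real_,
      force_mean = if (nrow(s)) mean(s$force) else NA_real_,
      force_sd = if (nrow(s) > 1) stats::sd(s$force) else NA_real_)
  })
  structure(do.call(rbind, rows),
            class = c("binned_kinetics", "data.frame"), scheme = scheme)
}

#' Fit an exponential force law to binned kinetics
#'
#' Unweighted damped (Levenberg-Marquardt) least-squares fit of
#' `amplitude * exp(force / force_scale)` to the per-bin values against the
#' mean force in each bin. For the pause entrance and exit rates the highest
#' force bin is excluded by default (low statistics). Initial values come
#' from a log-linear regression.
#'
#' @param binned A [bin_recordings()] result.
#' @param which One of `"entrance"`, `"exit"`, `"run_speed"`.
#' @param exclude_highest Drop the highest force bin (default `TRUE` for the
#'   entrance/exit rates, `FALSE` for run speed).
#' @param exclude_bins Additional bin indices to drop.
#' @param weighted If `TRUE`, weight by 1/SEM^2 (off by default; the standard
#'   analysis uses plain least squares).
#' @return An object of class `rate_law_fit`: list with `law` (an
#'   [exp_law()]), standard errors `se_amplitude` and `se_force_scale`, the
#'   quantity fitted, and the (force, value) points used.
#' @export
fit_rate_law <- function(binned, which = c("entrance", "exit", "run_speed"),
                         exclude_highest = NULL, exclude_bins = integer(0),
                         weighted = FALSE) {
  which <- match.arg(which)
  stopifnot(inherits(binned, "binned_kinetics"))
  if (is.null(exclude_highest)) exclude_highest <- which != "run_speed"
  y <- switch(which, entrance = binned$k_en, exit = binned$k_ex,
              run_speed = binned$mean_run_speed)
  w <- switch(which, entrance = binned$sem_k_en, exit = binned$sem_k_ex,
              run_speed = binned$sem_run_speed)
  f <- binned$force_mean
  drop <- binned$bin %in% exclude_bins
  if (exclude_highest) drop <- drop | binned$bin == max(binned$bin)
  use <- !drop & is.finite(y) & is.finite(f) & y > 0
  if (sum(use) < 3L)
    stop("need at least 3 usable bins to fit a force law (have ", sum(use), ")")
  f <- f[use]; y <- y[use]; w <- w[use]
  # log-linear initialization
  ll <- stats::lm(log(y) ~ f)
  a0 <- exp(stats::coef(ll)[1]); fs0 <- 1 / stats::coef(ll)[2]
  if (!is.finite(fs0) || fs0 == 0) fs0 <- 1e6
  wts <- if (weighted) {
    if (any(!is.finite(w) | w <= 0))
      stop("weighted fit requested but some bins lack a finite SEM")
    1 / w^2
  } else rep(1, length(y))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(f / fs),
                      start = list(a = as.numeric(a0), fs = as.numeric(fs0)),
                      weights = wts,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("exponential fit did not converge (start: amplitude = ",
           signif(a0, 4), ", force scale = ", signif(fs0, 4), "): ",
           conditionMessage(e)))
  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) c(NA, NA))
  structure(list(law = exp_law(est[["a"]], est[["fs"]]),
                 se_amplitude = se[[1]], se_force_scale = se[[2]],
                 which = which,
                 points = data.frame(force = f, value = y)),
            class = "rate_law_fit")
}

#' @export
print.rate_law_fit <- function(x, ...) {
  cat(sprintf("Exponential force-law fit (%s): %.4g * exp(F / %.4g pN)\n",
              x$which, x$law$amplitude, x$law$force_scale))
  cat(sprintf("  SE(amplitude) = %.3g, SE(force scale) = %.3g, %d bins\n",
              x$se_amplitude, x$se_force_scale, nrow(x$points)))
  invisible(x)
}

#' Write binned kinetics to a tabular file
#'
#' @param binned A [bin_recordings()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_binned_kinetics <- function(binned, path) {
  stopifnot(inherits(binned, "binned_kinetics"))
  utils::write.csv(as.data.frame(binned), path, row.names = FALSE)
  invisible(path)
}
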