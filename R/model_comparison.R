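#' Normalized tip-separation histogram
#'
#' Histogram of tip separations in fixed-width bins (default 0.1 um) starting
#' at zero, normalized to unit area: density = count / (n * binwidth).
#'
#' @param separations Numeric vector of tip separations (um), >= 0.
#' @param binwidth Bin width (um), default 0.1.
#' @param support_max Optional upper edge of the histogram support (um);
#'   defaults to the largest separation, padded by one bin. Extend it when
#'   the observations to be scored exceed the model's own range.
#' @return An object of class `sep_histogram`: list with `breaks`, `density`
#'   (um^-1), `n`, `binwidth`.
#' @export
separation_histogram <- function(separations, binwidth = 0.1,
                                 support_max = NULL) {
  stopifnot(is.numeric(separations), length(separations) >= 1L,
            all(is.finite(separations)), all(separations >= 0), binwidth > 0)
  top <- max(separations, support_max %||% 0)
  breaks <- seq(0, (floor(top / binwidth) + 1L) * binwidth, by = binwidth)
  idx <- findInterval(separations, breaks, rightmost.closed = FALSE,
                      left.open = FALSE)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  structure(list(breaks = breaks,
                 density = counts / (length(separations) * binwidth),
                 n = length(separations), binwidth = binwidth),
            class = "sep_histogram")
}

#' @export
print.sep_histogram <- function(x, ...) {
  cat(sprintf("Separation histogram: %d samples, %d bins of %g um\n",
              x$n, length(x$density), x$binwidth))
  invisible(x)
}

#' Likelihood of an observed separation under a model histogram
#'
#' The likelihood of one measurement is the model's normalized probability in
#' the observation's bin: L = binwidth * density. Empty model bins (and
#' observations beyond the histogram support) take a configurable pseudo-
#' density floor, half a count by default, so a single unanticipated
#' observation does not send the total log-likelihood to minus infinity;
#' set `floor = 0` to disable.
#'
#' @param hist A [separation_histogram()] built from model simulations.
#' @param observed Observed separations (um); vectorized.
#' @param floor Pseudo-density for empty bins (um^-1); default
#'   `0.5 / (n * binwidth)`.
#' @return Numeric vector of likelihoods (unitless, in \[0, 1\] whenever
#'   `floor <= 1/binwidth`).
#' @export
measurement_likelihood <- function(hist, observed,
                                   floor = 0.5 / (hist$n * hist$binwidth)) {
  stopifnot(inherits(hist, "sep_histogram"), is.numeric(observed),
            all(is.finite(observed)), all(observed >= 0), floor >= 0)
  idx <- findInterval(observed, hist$breaks)
  dens <- rep(floor, length(observed))
  inside <- idx >= 1L & idx <= length(hist$density)
  dens[inside] <- hist$density[idx[inside]]
  dens <- pmax(dens, floor)
  hist$binwidth * dens
}

#' Total log-likelihood of observations under a model histogram
#'
#' Sum of base-10 log likelihoods of the observations in one
#' condition/time cell; the larger (less negative), the better the model
#' explains the measurements. With `floor = 0`, any observation in an empty
#' model bin makes the total `-Inf`, reported as such.
#'
#' @param hist A [separation_histogram()] of model-simulated separations.
#' @param observed Observed separations (um) for the matching condition and
#'   evaluation time.
#' @param floor Empty-bin pseudo-density; see [measurement_likelihood()].
#' @return Total log10 likelihood (scalar).
#' @export
total_log_likelihood <- function(hist, observed,
                                 floor = 0.5 / (hist$n * hist$binwidth)) {
  sum(log10(measurement_likelihood(hist, observed, floor = floor)))
}
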