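#' @keywords internal
#' @noRd
.read_delim_file <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delim))
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- tryCatch(utils::read.delim(path, sep = delim, header = TRUE,
                                   check.names = FALSE),
                 error = function(e) stop("could not parse ", path, ": ",
                                          conditionMessage(e)))
  if (!nrow(df)) stop("file is empty: ", path)
  df
}

#' Read a trace file
#'
#' Reads a single-microtubule or pair trace from a delimited text file with
#' a mandatory header. Single traces carry columns `time_s`, `position_um`
#' and optionally `force_pN`; pair traces carry `time_s`, `x1_um`, `x2_um`
#' and optionally `F1_pN`, `F2_pN`. The time column must be strictly
#' increasing; single traces must be uniformly sampled within 1%.
#'
#' @param path CSV (default) or TSV file path.
#' @param type `"auto"` (decide from the columns), `"single"`, or `"pair"`.
#' @param delim Field delimiter; inferred from the extension when `NULL`.
#' @return An [recording()] or [pair_recording()].
#' @export
read_trace <- function(path, type = c("auto", "single", "pair"),
                       delim = NULL) {
  type <- match.arg(type)
  df <- .read_delim_file(path, delim)
  if (is.null(df$time_s)) stop(path, ": missing required column time_s")
  if (any(diff(df$time_s) <= 0))
    stop(path, ": time_s must be strictly increasing")
  is_pair <- !is.null(df$x1_um) && !is.null(df$x2_um)
  if (type == "auto") type <- if (is_pair) "pair" else "single"
  if (type == "pair") {
    for (k in c("x1_um", "x2_um"))
      if (is.null(df[[k]])) stop(path, ": missing required column ", k)
    pair_recording(df$time_s, df$x1_um, df$x2_um,
                   f1 = df$F1_pN, f2 = df$F2_pN,
                   id = basename(path))
  } else {
    if (is.null(df$position_um))
      stop(path, ": missing required column position_um")
    force <- if (is.null(df$force_pN)) NA_real_ else df$force_pN[1]
    recording(df$time_s, df$position_um, force = force, id = basename(path))
  }
}

#' Write a trace file
#'
#' Inverse of [read_trace()]: writes a [recording()] or [pair_recording()]
#' as a delimited text file in the package's trace dialect.
#'
#' @param x An [recording()] or [pair_recording()].
#' @param path Output path (`.csv` or `.tsv`).
#' @param delim Field delimiter; inferred from the extension when `NULL`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path, delim = NULL) {
  if (is.null(delim))
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- if (inherits(x, "mt_recording")) {
    d <- data.frame(time_s = x$time, position_um = x$position)
    if (!is.na(x$force)) d$force_pN <- x$force
    d
  } else if (inherits(x, "pair_recording")) {
    d <- data.frame(time_s = x$time, x1_um = x$x1, x2_um = x$x2)
    if (!is.null(x$f1)) { d$F1_pN <- x$f1; d$F2_pN <- x$f2 }
    d
  } else stop("`x` must be an mt_recording or pair_recording")
  utils::write.table(df, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an interval set as a tabular file
#'
#' @param iv An [segment_trace()] interval set.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(iv, path) {
  stopifnot(inherits(iv, "interval_set"))
  df <- data.frame(start_s = iv$start, end_s = iv$end, label = iv$label,
                   mean_speed_um_per_min = iv$mean_speed)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records what produced a set of outputs: package version, seed, and any
#' parameters, as YAML. Every randomized pipeline entry point can be
#' reproduced from its manifest.
#'
#' @param path Output YAML path.
#' @param seed Integer seed used.
#' @param ... Further named fields to record.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, seed, ...) {
  yaml::write_yaml(c(list(
    package = "mtcoupler",
    version = as.character(utils::packageVersion("mtcoupler")),
    date = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    seed = seed), list(...)), path)
  invisible(path)
}
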