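#' Spring-coupler configuration
#'
#' Describes the elastic coupling between microtubule plus-ends and a shared
#' load: each tip is connected to a massless "kinetochore" by an identical
#' Hookean spring of stiffness `kappa`, and the kinetochore bears a constant
#' total tension `f_total`.
#'
#' @param kappa Spring stiffness of each connection (pN/um). Must be > 0.
#' @param f_total Total shared load (pN). Must be > 0.
#' @param force_floor Optional minimum per-tip force (pN). By default the
#'   partition is purely linear and forces may become arbitrarily small or
#'   negative at large separations; set a floor to clamp them (e.g. when
#'   emulating an instrument that cannot push). Clamping breaks exact
#'   conservation of `f_total` and is off by default.
#' @return An object of class `coupler_config`.
#' @seealso [partition_force()]
#' @export
coupler_config <- function(kappa, f_total, force_floor = NULL) {
  stopifnot(is.numeric(kappa), length(kappa) == 1L, is.finite(kappa),
            is.numeric(f_total), length(f_total) == 1L, is.finite(f_total))
  if (kappa <= 0) stop("`kappa` must be > 0 (pN/um)")
  if (f_total <= 0) stop("`f_total` must be > 0 (pN)")
  if (!is.null(force_floor)) {
    stopifnot(is.numeric(force_floor), length(force_floor) == 1L,
              is.finite(force_floor))
  }
  structure(list(kappa = kappa, f_total = f_total, force_floor = force_floor),
            class = "coupler_config")
}

#' @export
print.coupler_config <- function(x, ...) {
  cat(sprintf("Spring coupler: kappa = %g pN/um, F_TOT = %g pN\n",
              x$kappa, x$f_total))
  if (!is.null(x$force_floor))
    cat(sprintf("  per-tip force floor: %g pN\n", x$force_floor))
  invisible(x)
}

#' Partition a shared load between coupled microtubule tips
#'
#' Solves the static force balance for N tips connected by identical Hookean
#' springs to a massless kinetochore bearing a constant total tension. The
#' unique solution is
#' \deqn{F_i = F_{TOT}/N + \kappa (\bar{x} - x_i),}
#' so forces always sum to `f_total` and, for two tips,
#' \eqn{F_1 - F_2 = \kappa (x_2 - x_1)}: the lagging tip carries more tension.
#'
#' @param tip_positions Numeric vector of tip positions along the shared axis
#'   (um); at least two, all finite.
#' @param cfg A [coupler_config()].
#' @return Numeric vector of per-tip tensions (pN), same length as
#'   `tip_positions`.
#' @examples
#' cfg <- coupler_config(kappa = 5, f_total = 8)
#' partition_force(c(0, 0), cfg)     # equal sharing: 4, 4
#' partition_force(c(0, 0.4), cfg)   # lagging tip at 0 carries 5 pN
#' @export
partition_force <- function(tip_positions, cfg) {
  if (!inherits(cfg, "coupler_config")) stop("`cfg` must be a coupler_config")
  if (length(tip_positions) < 2L)
    stop("force partition requires at least 2 tip positions")
  if (!is.numeric(tip_positions) || !all(is.finite(tip_positions)))
    stop("tip positions must all be finite numbers")
  f <- cfg$f_total / length(tip_positions) +
    cfg$kappa * (mean(tip_positions) - tip_positions)
  if (!is.null(cfg$force_floor)) f <- pmax(f, cfg$force_floor)
  f
}

#' Write / read a coupler configuration
#'
#' Serializes a [coupler_config()] to a small YAML file with explicit units
#' (`kappa_pN_per_um`, `f_total_pN`, optional `force_floor_pN`).
#'
#' @param cfg A [coupler_config()].
#' @param path File path.
#' @return `write_coupler_config()` returns `path` invisibly;
#'   `read_coupler_config()` returns a [coupler_config()].
#' @export
write_coupler_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "coupler_config"))
  x <- list(kappa_pN_per_um = cfg$kappa, f_total_pN = cfg$f_total)
  if (!is.null(cfg$force_floor)) x$force_floor_pN <- cfg$force_floor
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_coupler_config
#' @export
read_coupler_config <- function(path) {
  x <- yaml::read_yaml(path)
  for (k in c("kappa_pN_per_um", "f_total_pN"))
    if (is.null(x[[k]])) stop("coupler config is missing key: ", k)
  coupler_config(kappa = x$kappa_pN_per_um, f_total = x$f_total_pN,
                 force_floor = x$force_floor_pN)
}
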