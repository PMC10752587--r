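#' Synthetic stand-ins for the trajectory-terminating laws
#'
#' The rates at which growth episodes end (detachment from the kinetochore,
#' catastrophe, and force-independent interruption) were estimated in the
#' original force-clamp study and are not bundled with this package. These
#' synthetic defaults reproduce the qualitative structure -- detachment
#' mildly promoted by tension, catastrophe suppressed by tension,
#' interruption constant -- at magnitudes that let most simulated pairs
#' grow for several minutes. They are an artifact of the synthetic-data
#' module, clearly not measured values.
#'
#' @return List of three [exp_law()]s: `detachment`, `catastrophe`,
#'   `interruption` (rates in min^-1).
#' @export
synthetic_termination_laws <- function() {
  list(detachment = exp_law(0.05, 18),
       catastrophe = exp_law(0.05, -11),
       interruption = exp_law(0.03, Inf))
}

#' Kinetic parameters with synthetic termination laws attached
#'
#' Convenience wrapper: the standard [kinetic_params()] defaults plus the
#' [synthetic_termination_laws()], ready for terminating simulations.
#'
#' @param ... Passed to [kinetic_params()].
#' @return A [kinetic_params()].
#' @export
synthetic_params <- function(...) {
  term <- synthetic_termination_laws()
  kinetic_params(..., detachment = term$detachment,
                 catastrophe = term$catastrophe,
                 interruption = term$interruption)
}

# per-bin recording counts and mean recording durations (s) matching the
# reference force-clamp corpus: durations are the corpus' total observed
# time per bin divided by its recording count
.CORPUS_COUNTS <- c(41L, 85L, 77L, 60L, 60L, 25L, 9L)
.CORPUS_DURATIONS <- c(7364 + 10957, 18952 + 18047, 18159 + 12842,
                       16993 + 9661, 18465 + 5930, 6559 + 1298,
                       712 + 93) / .CORPUS_COUNTS

#' Specification of a synthetic force-clamp corpus
#'
#' Describes a corpus of synthetic constant-force recordings with the same
#' statistical structure the analysis assumes: per-bin recording counts
#' defaulting to the reference corpus occupancy (41, 85, 77, 60, 60, 25, 9
#' across the seven standard force bins), per-recording forces uniform
#' within their bin, two-state run/pause growth with the [kinetic_params()]
#' rate laws, per-microtubule intrinsic run-speed heterogeneity (log-normal
#' multiplier with unit mean), Gaussian position noise, and 200-Hz sampling.
#'
#' @param counts Integer vector of recordings per force bin.
#' @param scheme A [force_bins()] with `length(counts)` bins.
#' @param params Generating [kinetic_params()].
#' @param speed_cv Coefficient of variation of the log-normal intrinsic
#'   run-speed multiplier (default 0.5). The multiplier has unit mean, so
#'   the population mean run speed follows the run-speed law.
#' @param noise_sd Gaussian position noise SD (um), default 0.01.
#' @param fs Sampling rate (Hz), default 200.
#' @param durations Per-bin recording durations (s); defaults to the
#'   reference corpus' mean observed time per recording in each bin.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(counts = .CORPUS_COUNTS, scheme = force_bins(),
                        params = kinetic_params(), speed_cv = 0.5,
                        noise_sd = 0.01, fs = 200,
                        durations = NULL) {
  stopifnot(inherits(scheme, "force_bins"),
            length(counts) == scheme$n_bins, all(counts >= 0),
            inherits(params, "kinetic_params"),
            speed_cv >= 0, noise_sd >= 0, fs > 0)
  if (is.null(durations)) {
    durations <- if (identical(as.integer(counts), .CORPUS_COUNTS))
      .CORPUS_DURATIONS else rep(400, length(counts))
  }
  stopifnot(length(durations) == length(counts), all(durations > 0))
  structure(list(counts = as.integer(counts), scheme = scheme,
                 params = params, speed_cv = speed_cv, noise_sd = noise_sd,
                 fs = fs, durations = durations),
            class = "corpus_spec")
}

#' @keywords internal
#' @noRd
.rlnorm_unit_mean <- function(n, cv, cap = Inf) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  m <- stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  while (any(bad <- m > cap))
    m[bad] <- stats::rlnorm(sum(bad), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  m
}

#' Generate one synthetic force-clamp recording
#'
#' Simulates a two-state run/pause trajectory at constant force with the
#' single-tip Gillespie engine, renders it as a position-versus-time trace
#' sampled at `fs` Hz with i.i.d. Gaussian position noise, and attaches the
#' true switch times for validation.
#'
#' @param force Constant tension (pN), in (0, 18].
#' @param params Generating [kinetic_params()].
#' @param v0 Intrinsic unloaded run speed (um/min); defaults to the
#'   run-speed law amplitude.
#' @param duration Recording length (s).
#' @param noise_sd Gaussian position noise SD (um).
#' @param fs Sampling rate (Hz).
#' @param termination If `TRUE`, the params' termination laws can end the
#'   recording early; disabled by default (force-clamp recordings are
#'   taken over their observed span).
#' @param seed Optional integer seed.
#' @param id Optional identifier.
#' @return An [recording()] with attributes `truth` (data.frame of true
#'   `start`, `end`, `label` intervals), `v0`, and `noise_sd`.
#' @export
gen_force_clamp_recording <- function(force, params = kinetic_params(),
                                      v0 = NULL, duration = 400,
                                      noise_sd = 0.01, fs = 200,
                                      termination = FALSE, seed = NULL,
                                      id = NA_character_) {
  stopifnot(force > 0, force <= 18)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(v0)) v0 <- params$run_speed$amplitude
  traj <- simulate_single(force, params = params, model = "pausing",
                          v0 = v0, duration = duration, grid_dt = duration,
                          termination = termination)
  t_end <- if (is.na(traj$censor_time)) duration else traj$censor_time
  sw <- traj$events$time[traj$events$event %in%
                           c("pause_entrance", "pause_exit")]
  bk <- c(0, sw, t_end)
  state_run <- rep(c(TRUE, FALSE), length.out = length(bk) - 1L)
  v_run <- v0 * exp(force / params$run_speed$force_scale) / 60   # um/s
  pos_bk <- cumsum(c(0, diff(bk) * ifelse(state_run, v_run, 0)))
  tt <- seq(0, t_end, by = 1 / fs)
  pos <- stats::approx(bk, pos_bk, xout = tt)$y
  if (noise_sd > 0) pos <- pos + stats::rnorm(length(pos), 0, noise_sd)
  rec <- recording(tt, pos, force = force, id = id)
  attr(rec, "truth") <- data.frame(
    start = utils::head(bk, -1L), end = bk[-1L],
    label = ifelse(state_run, "run", "pause"), stringsAsFactors = FALSE)
  attr(rec, "v0") <- v0
  attr(rec, "noise_sd") <- noise_sd
  rec
}

#' Generate a synthetic force-clamp corpus
#'
#' Draws, for every recording of the corpus spec, a force uniform within its
#' bin and an intrinsic unloaded run speed (run-speed amplitude times a unit-
#' mean log-normal multiplier, capped at 1.8 um/min unloaded), then generates
#' the recording with [gen_force_clamp_recording()].
#'
#' @param spec A [corpus_spec()].
#' @param seed Integer seed; the corpus is bit-identical under the same seed.
#' @return List of [recording()]s, each carrying its ground truth.
#' @export
gen_corpus <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "corpus_spec"))
  set.seed(seed)
  recs <- list()
  cap_mult <- .UNLOADED_SPEED_CAP / spec$params$run_speed$amplitude
  for (b in seq_along(spec$counts)) {
    for (i in seq_len(spec$counts[b])) {
      force <- stats::runif(1, spec$scheme$edges[b], spec$scheme$edges[b + 1L])
      v0 <- spec$params$run_speed$amplitude *
        .rlnorm_unit_mean(1L, spec$speed_cv, cap = cap_mult)
      recs[[length(recs) + 1L]] <- gen_force_clamp_recording(
        force, params = spec$params, v0 = v0,
        duration = spec$durations[b], noise_sd = spec$noise_sd, fs = spec$fs,
        id = sprintf("bin%d_rec%03d", b, i))
    }
  }
  attr(recs, "spec") <- spec
  attr(recs, "seed") <- seed
  recs
}

#' Generate, segment, bin, and fit a synthetic corpus in one pass
#'
#' Runs the full estimation chain -- generate each synthetic recording,
#' sliding-window velocity, per-recording Gaussian-mixture threshold,
#' run/pause segmentation, force binning, exponential force-law fits --
#' streaming one recording at a time so the full corpus never resides in
#' memory.
#'
#' @param spec A [corpus_spec()].
#' @param seed Integer seed (same stream as [gen_corpus()]).
#' @param window,min_duration Segmentation settings (s).
#' @return List with `summaries` (one row per recording), `binned` (a
#'   [bin_recordings()] table), and `fits` (list of [fit_rate_law()] results
#'   for `entrance`, `exit`, `run_speed`).
#' @export
recover_rate_laws <- function(spec, seed = 1L, window = 2, min_duration = 1) {
  stopifnot(inherits(spec, "corpus_spec"))
  set.seed(seed)
  cap_mult <- .UNLOADED_SPEED_CAP / spec$params$run_speed$amplitude
  summaries <- vector("list", sum(spec$counts))
  k <- 0L
  for (b in seq_along(spec$counts)) {
    for (i in seq_len(spec$counts[b])) {
      force <- stats::runif(1, spec$scheme$edges[b], spec$scheme$edges[b + 1L])
      v0 <- spec$params$run_speed$amplitude *
        .rlnorm_unit_mean(1L, spec$speed_cv, cap = cap_mult)
      rec <- gen_force_clamp_recording(
        force, params = spec$params, v0 = v0,
        duration = spec$durations[b], noise_sd = spec$noise_sd, fs = spec$fs,
        id = sprintf("bin%d_rec%03d", b, i))
      k <- k + 1L
      summaries[[k]] <- segment_recording(rec, window = window,
                                          min_duration = min_duration)$summary
    }
  }
  summaries <- do.call(rbind, summaries)
  binned <- bin_recordings(summaries, spec$scheme)
  fits <- list(entrance = fit_rate_law(binned, "entrance"),
               exit = fit_rate_law(binned, "exit"),
               run_speed = fit_rate_law(binned, "run_speed"))
  list(summaries = summaries, binned = binned, fits = fits)
}

#' Generate a synthetic intrinsic-speed pool
#'
#' Emulates the per-recording (speed, force) measurement pool from which
#' simulated microtubules draw their intrinsic speeds. Forces follow the
#' corpus bin occupancy (uniform within a bin).
#'
#' For the run-speed pool (`law = "run"`), each speed is the run-speed law
#' at the drawn force times a unit-mean log-normal multiplier; entries whose
#' unloaded-equivalent speed exceeds 1.8 um/min (30 nm/s) are resampled
#' (outlier rule). The whole-trace growth-speed pool (`law = "growth"`, used
#' by the non-pausing model) emulates how such a dataset arises in practice:
#' each entry is the total-displacement-over-duration growth speed of a
#' two-state run/pause trajectory simulated at the drawn force with an
#' intrinsic run speed drawn as above. Its spread therefore combines
#' intrinsic heterogeneity with pause-occupancy fluctuations, exactly the
#' variability that the non-pausing model then attributes entirely to
#' persistent speed differences. The growth pool is unfiltered.
#'
#' @param n Pool size.
#' @param params [kinetic_params()] providing the laws.
#' @param law `"run"` or `"growth"`.
#' @param counts,scheme Bin occupancy and [force_bins()] scheme.
#' @param speed_cv Intrinsic multiplier coefficient of variation
#'   (default 0.5).
#' @param trace_duration Simulated trace length (s) behind each
#'   growth-speed entry.
#' @param seed Optional integer seed.
#' @return A [speed_pool()].
#' @export
gen_intrinsic_pool <- function(n = 356L, params = kinetic_params(),
                               law = c("run", "growth"),
                               counts = .CORPUS_COUNTS, scheme = force_bins(),
                               speed_cv = 0.5, trace_duration = 400,
                               seed = NULL) {
  law <- match.arg(law)
  stopifnot(n >= 1L, length(counts) == scheme$n_bins)
  if (!is.null(seed)) set.seed(seed)
  bins <- sample.int(length(counts), n, replace = TRUE, prob = counts)
  force <- stats::runif(n, scheme$edges[bins], scheme$edges[bins + 1L])
  # intrinsic unloaded run speeds, capped at the 1.8 um/min outlier rule
  mult <- .rlnorm_unit_mean(n, speed_cv,
                            cap = .UNLOADED_SPEED_CAP /
                              params$run_speed$amplitude)
  v0 <- params$run_speed$amplitude * mult
  if (law == "run") {
    speed <- v0 * exp(force / params$run_speed$force_scale)
  } else {
    speed <- vapply(seq_len(n), function(i) {
      tr <- simulate_single(force[i], params = params, model = "pausing",
                            v0 = v0[i], duration = trace_duration,
                            grid_dt = trace_duration, termination = FALSE)
      ng <- nrow(tr$x)
      max(tr$x[ng, 1] / tr$time[ng] * 60, 1e-3)   # um/min over the trace
    }, numeric(1))
  }
  pool <- speed_pool(speed, force)
  attr(pool, "law") <- law
  attr(pool, "speed_cv") <- speed_cv
  pool
}

#' Generate a synthetic dual-trap dataset
#'
#' Simulates `n` coupled microtubule pairs with the given coupler and model,
#' drawing each tip's intrinsic unloaded speed from the pool, adding
#' Gaussian position noise on the 1-s output grid, and recording censoring
#' from terminating events.
#'
#' @param n Number of pairs.
#' @param coupler A [coupler_config()].
#' @param params [kinetic_params()]; defaults to [synthetic_params()] so
#'   termination is configured.
#' @param model Growth model variant (see [simulate_pair()]).
#' @param pool [speed_pool()] of intrinsic-speed measurements; defaults to a
#'   synthetic pool matched to the model.
#' @param noise_sd Position noise SD (um), default 0.01.
#' @param duration Observation horizon (s), default 400.
#' @param label Condition label attached to every pair (defaults to
#'   `"soft"`/`"stiff"` for kappa <= 2 / > 2, purely as a mnemonic).
#' @param termination Passed to [simulate_pair()]; set `FALSE` to generate
#'   uncensored datasets from parameter sets without termination laws.
#' @param seed Integer seed.
#' @return List of [pair_recording()]s.
#' @export
gen_dual_trap_dataset <- function(n, coupler, params = synthetic_params(),
                                  model = c("pausing", "non_pausing",
                                            "pausing_ergodic"),
                                  pool = NULL, noise_sd = 0.01,
                                  duration = 400, label = NULL,
                                  termination = TRUE, seed = NULL) {
  model <- match.arg(model)
  stopifnot(n >= 1L, inherits(coupler, "coupler_config"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(label)) label <- if (coupler$kappa <= 2) "soft" else "stiff"
  if (is.null(pool) && model != "pausing_ergodic")
    pool <- gen_intrinsic_pool(356L, params = params,
                               law = if (model == "pausing") "run" else "growth")
  lapply(seq_len(n), function(i) {
    v0 <- if (model == "pausing_ergodic") NULL
    else if (model == "pausing")
      sample_intrinsic_speed(pool, params$run_speed$force_scale, n = 2L)
    else
      sample_intrinsic_speed(pool, params$f_g, n = 2L, max_unloaded = Inf)
    traj <- simulate_pair(coupler, params = params, model = model, v0 = v0,
                          duration = duration, termination = termination)
    as_pair_recording(traj, noise_sd = noise_sd, label = label,
                      id = sprintf("%s_pair%04d", label, i))
  })
}
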