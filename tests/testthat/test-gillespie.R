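no_term <- function(...) kinetic_params(...)

test_that("with all stochastic rates off, growth is a deterministic ramp", {
  # 1 um/min at the applied force for 300 s -> exactly 5 um
  tr <- simulate_single(4, params = kinetic_params(f_g = Inf),
                        model = "non_pausing", v0 = 1, duration = 300,
                        termination = FALSE)
  expect_equal(unname(tr$x[nrow(tr$x), 1]), 5, tolerance = 1e-12)
  expect_equal(tr$time, 0:300)
  expect_true(is.na(tr$censor_time))
})

test_that("termination must be configured or explicitly disabled", {
  expect_error(simulate_single(4, model = "pausing_ergodic", duration = 10),
               "termination")
  expect_silent(simulate_single(4, model = "pausing_ergodic", duration = 10,
                                termination = FALSE, seed = 1))
  # configured termination laws end the trace and record the cause
  p <- kinetic_params(interruption = exp_law(60, Inf))  # 1/s: dies fast
  tr <- simulate_single(4, params = p, model = "pausing_ergodic",
                        duration = 400, seed = 2)
  expect_false(is.na(tr$censor_time))
  expect_identical(tr$termination_cause, "interruption")
})

test_that("run/pause occupancy and dwell times match two-state kinetics", {
  f <- 4
  p <- kinetic_params()
  k_en <- eval_law(p$pause_entrance, f)   # min^-1
  k_ex <- eval_law(p$pause_exit, f)
  tr <- simulate_single(f, params = p, model = "pausing_ergodic",
                        duration = 20000, termination = FALSE, seed = 31)
  # stationary paused fraction k_EN/(k_EN+k_EX), within Monte-Carlo error
  frac <- mean(tr$mode[, 1] == 0L)
  expected <- k_en / (k_en + k_ex)
  n_dwells <- nrow(tr$events)
  expect_gt(n_dwells, 2000)
  expect_lt(abs(frac - expected), 4 * expected / sqrt(n_dwells / 2))
  # dwell times in each state are exponential with the configured means
  dw <- dwell_times(tr)
  expect_gt(ks.test(dw$run, "pexp", k_en / 60)$p.value, 0.01)
  expect_gt(ks.test(dw$pause, "pexp", k_ex / 60)$p.value, 0.01)
})

test_that("identical deterministic tips under coupling never separate", {
  cfg <- coupler_config(5, 8)
  tr <- simulate_pair(cfg, params = kinetic_params(f_g = 8.4),
                      model = "non_pausing", v0 = c(0.5, 0.5),
                      duration = 200, termination = FALSE)
  expect_equal(tr$x[, 1], tr$x[, 2], tolerance = 1e-12)
  expect_equal(tr$force[, 1], rep(4, nrow(tr$force)), tolerance = 1e-12)
})

test_that("a vanishing coupler decouples the tips at half-load each", {
  # with kappa -> 0 both tips stay at F_TOT/2, so the separation is the
  # closed-form difference of two exponential-speed ramps at 4 pN
  cfg <- coupler_config(1e-9, 8)
  v0 <- c(0.4, 0.8)
  tr <- simulate_pair(cfg, params = kinetic_params(f_g = 8.4),
                      model = "non_pausing", v0 = v0, duration = 300,
                      termination = FALSE)
  sep_expected <- (v0[2] - v0[1]) * exp(4 / 8.4) / 60 * 300
  expect_equal(abs(diff(tr$x[nrow(tr$x), ])), sep_expected, tolerance = 1e-6)
})

test_that("a very stiff coupler drives the pair to its fixed-point separation", {
  # steady state: v1(F/2 + kappa*dx/2) = v2(F/2 - kappa*dx/2); solve by a
  # 1-D root-finding oracle on the coupled speed laws
  kappa <- 100; v0 <- c(0.4, 0.8); fg <- 8.4
  cfg <- coupler_config(kappa, 8)
  gap <- uniroot(function(dx)
    v0[2] * exp((4 - kappa * dx / 2) / fg) -
      v0[1] * exp((4 + kappa * dx / 2) / fg), c(0, 1))$root
  tr <- simulate_pair(cfg, params = kinetic_params(f_g = fg),
                      model = "non_pausing", v0 = v0, duration = 400,
                      termination = FALSE)
  expect_equal(abs(diff(tr$x[nrow(tr$x), ])), gap, tolerance = 0.02)
})

test_that("coupled-pair trajectories conserve the load and are seed-reproducible", {
  cfg <- coupler_config(5, 8)
  tr <- simulate_pair(cfg, params = synthetic_params(), model = "pausing",
                      v0 = c(0.45, 0.6), duration = 400, seed = 5)
  tot <- rowSums(tr$force)
  expect_true(all(abs(tot - 8) < 8 * 1e-9))
  expect_equal(abs(tr$force[, 1] - tr$force[, 2]),
               5 * abs(tr$x[, 1] - tr$x[, 2]), tolerance = 1e-9)
  # positions never decrease (tips grow or pause only)
  expect_true(all(diff(tr$x[, 1]) >= -1e-12))
  expect_true(all(diff(tr$x[, 2]) >= -1e-12))
  tr2 <- simulate_pair(cfg, params = synthetic_params(), model = "pausing",
                       v0 = c(0.45, 0.6), duration = 400, seed = 5)
  expect_identical(tr$x, tr2$x)
  expect_identical(tr$events, tr2$events)
})

test_that("ensemble summary equals a brute-force recomputation", {
  cfg <- coupler_config(1, 8)
  set.seed(9)
  trs <- replicate(8, simulate_pair(cfg, params = synthetic_params(),
                                    model = "pausing", v0 = runif(2, 0.3, 0.8),
                                    duration = 120), simplify = FALSE)
  sm <- summarize_ensemble(trs)
  # recompute from the raw trajectories
  for (tq in c(0, 50, 120)) {
    seps <- unlist(lapply(trs, function(tr) {
      i <- match(tq, tr$time)
      if (is.na(i)) NULL else abs(tr$x[i, 1] - tr$x[i, 2])
    }))
    row <- sm[sm$time == tq, ]
    expect_equal(row$n, length(seps))
    if (length(seps)) expect_equal(row$mean_sep, mean(seps))
    if (length(seps) >= 2)
      expect_equal(row$sem, sd(seps) / sqrt(length(seps)))
  }
  # conventions: single trajectory has no SEM; identical trajectories have 0
  one <- summarize_ensemble(trs[1])
  expect_true(all(is.na(one$sem)))
  two <- summarize_ensemble(list(trs[[1]], trs[[1]]))
  expect_equal(max(two$sem, na.rm = TRUE), 0)
})
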