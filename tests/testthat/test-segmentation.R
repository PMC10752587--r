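test_that("sliding-window velocity recovers exact and piecewise slopes", {
  fs <- 200
  tt <- seq(0, 30, by = 1 / fs)
  # perfect line at 0.01 um/s -> 0.6 um/min everywhere
  rec <- recording(tt, 0.01 * tt, force = 4)
  vt <- sliding_velocity(rec, window = 2)
  expect_true(all(abs(vt$speed - 0.6) < 1e-9))
  expect_lt(length(vt$speed), length(tt))        # edges carry no estimate
  # flat trace with noise: mean speed ~ 0
  set.seed(21)
  recf <- recording(tt, rnorm(length(tt), 0, 0.01))
  vtf <- sliding_velocity(recf)
  se <- sd(vtf$speed) / sqrt(sum(!is.na(vtf$speed)) / (2 * fs))
  expect_lt(abs(mean(vtf$speed)), 3 * max(se, 0.02))
  # piecewise-linear trace agrees with a direct per-window regression oracle
  pos <- c(0.01 * tt[tt <= 15], 0.15 + 0 * tt[tt > 15]) +
    rnorm(length(tt), 0, 0.005)
  recp <- recording(tt, pos)
  vtp <- sliding_velocity(recp)
  expect_equal(vtp$speed, oracle_window_slopes(tt, pos, 2, fs),
               tolerance = 1e-8)
  expect_error(sliding_velocity(recording(seq(0, 2.5, by = 0.005),
                                          rnorm(501)), window = 3),
               "shorter than")
})

test_that("the mixture threshold lands at the two-Gaussian density intersection", {
  set.seed(33)
  speeds <- c(rnorm(6000, 0, 0.05), rnorm(6000, 0.6, 0.1))
  vt <- make_velocity_trace(speeds)
  th <- pause_threshold(vt)
  expect_false(th$no_pause)
  expect_gt(th$threshold, 0.1)
  expect_lt(th$threshold, 0.5)
  oracle <- oracle_gauss_intersection(0.5, 0, 0.05, 0.5, 0.6, 0.1)
  expect_lt(abs(th$threshold - oracle), 0.06)
})

test_that("a single-peak speed distribution yields the no-pause sentinel", {
  set.seed(34)
  vt <- make_velocity_trace(rnorm(4000, 0.6, 0.08))
  th <- pause_threshold(vt)
  expect_true(th$no_pause)
  iv <- segment_trace(vt, th)
  expect_equal(nrow(iv), 1L)
  expect_identical(iv$label, "run")
  expect_equal(iv$start, vt$rec_start)
  expect_equal(iv$end, vt$rec_end)
  expect_error(pause_threshold(make_velocity_trace(rnorm(100))), "500")
})

test_that("sub-second excursions are merged into their flanking intervals", {
  fs <- 200
  # run 5 s, 0.5 s dip, run 5 s -> one merged run
  speeds <- c(rep(0.6, 5 * fs), rep(0, 0.5 * fs), rep(0.6, 5 * fs))
  iv <- segment_trace(make_velocity_trace(speeds, fs), threshold = 0.3)
  expect_equal(nrow(iv), 1L)
  expect_identical(iv$label, "run")
  # a 2-s dip survives; labels alternate and interior intervals are >= 1 s
  speeds2 <- c(rep(0.6, 5 * fs), rep(0, 2 * fs), rep(0.6, 5 * fs))
  iv2 <- segment_trace(make_velocity_trace(speeds2, fs), threshold = 0.3)
  expect_identical(iv2$label, c("run", "pause", "run"))
  expect_equal(iv2$end[2] - iv2$start[2], 2, tolerance = 0.02)
  # threshold never crossed -> single run covering the recording
  iv3 <- segment_trace(make_velocity_trace(rep(0.6, 2000), fs),
                       threshold = 0.3)
  expect_equal(nrow(iv3), 1L)
  # merging is stable: interior intervals never end up below min_duration
  set.seed(35)
  noisy <- rep(c(0.6, 0), times = 40)[sample.int(80)]
  speeds4 <- rep(noisy, each = 60) + rnorm(4800, 0, 0.05)
  iv4 <- segment_trace(make_velocity_trace(speeds4, fs), threshold = 0.3)
  if (nrow(iv4) > 2) {
    interior <- iv4[-c(1, nrow(iv4)), ]
    expect_true(all(interior$end - interior$start >= 1 - 1 / fs))
  }
  expect_true(all(iv4$label[-1] != head(iv4$label, -1)))
})

test_that("segmentation recovers well-separated switches from synthetic truth", {
  # slow switching (dwells ~20-60 s): boundaries must land within one
  # window half-width of the true switch times and labels must match
  slow <- kinetic_params(pause_entrance = exp_law(3, -4.6),
                         pause_exit = exp_law(2, 14.1))
  set.seed(36)
  hits <- 0; total <- 0
  for (rep in 1:3) {
    rec <- gen_force_clamp_recording(4, params = slow, v0 = 0.6,
                                     duration = 400, noise_sd = 0.01)
    truth <- attr(rec, "truth")
    sr <- segment_recording(rec)
    iv <- sr$intervals
    true_sw <- truth$end[-nrow(truth)]
    est_sw <- iv$end[-nrow(iv)]
    for (ts in true_sw) {
      total <- total + 1
      if (any(abs(est_sw - ts) <= 1.25)) hits <- hits + 1
    }
  }
  expect_gt(hits / total, 0.9)
})

test_that("per-recording run speed is the duration-weighted mean over runs", {
  iv <- make_interval_set(start = c(0, 10, 12), end = c(10, 12, 42),
                          label = c("run", "pause", "run"),
                          mean_speed = c(0.4, 0.01, 0.8))
  # runs of 0.4 for 10 s and 0.8 for 30 s -> 0.7
  expect_equal(recording_run_speed(iv), 0.7)
  one <- make_interval_set(0, 30, "run", 0.6)
  expect_equal(recording_run_speed(one), 0.6)
  none <- make_interval_set(0, 30, "pause", 0.0)
  expect_true(is.na(recording_run_speed(none)))
  # boundary transitions are not counted as events
  cts <- interval_counts(iv)
  expect_equal(cts$entrances, 1)
  expect_equal(cts$exits, 1)
  expect_equal(cts$time_run, 40)
  expect_equal(cts$time_pause, 2)
})
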