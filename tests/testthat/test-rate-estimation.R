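make_summary <- function(force, entrances, exits, time_run, time_pause,
                         run_speed = 0.6) {
  data.frame(force = force, entrances = entrances, exits = exits,
             time_run = time_run, time_pause = time_pause,
             run_speed = run_speed)
}

test_that("binned rates are event counts over state-resolved observation time", {
  # the reference corpus' lowest force bin: 1834 entrances over 7364 s in
  # run gives ~14.9 min^-1; 1830 exits over 10957 s in pause gives ~10.0
  s <- make_summary(1.3, 1834, 1830, 7364, 10957, run_speed = 0.45)
  b <- bin_recordings(s)
  r1 <- b[b$bin == 1, ]
  expect_equal(r1$k_en, 1834 / 7364 * 60, tolerance = 1e-12)
  expect_equal(r1$k_ex, 1830 / 10957 * 60, tolerance = 1e-12)
  expect_equal(r1$k_en, 14.94, tolerance = 1e-3)
  expect_equal(r1$k_ex, 10.02, tolerance = 1e-3)
  # counting uncertainties k/sqrt(N)
  expect_equal(r1$sem_k_en, r1$k_en / sqrt(1834))
  expect_equal(r1$sem_k_ex, r1$k_ex / sqrt(1830))
  # empty bins carry no rate; zero-event bins have rate 0 and no SEM
  expect_true(is.na(b$k_en[b$bin == 4]))
  s0 <- make_summary(4.5, 0, 0, 100, 50)
  b0 <- bin_recordings(s0)
  expect_equal(b0$k_en[b0$bin == 4], 0)
  expect_true(is.na(b0$sem_k_en[b0$bin == 4]))
})

test_that("binning conserves counts, warns on out-of-range forces, and scales", {
  set.seed(41)
  s <- make_summary(runif(40, 1, 17), rpois(40, 20), rpois(40, 18),
                    runif(40, 50, 300), runif(40, 20, 200),
                    runif(40, 0.3, 0.9))
  b <- bin_recordings(s)
  expect_equal(sum(b$entrances), sum(s$entrances))
  expect_equal(sum(b$exits), sum(s$exits))
  expect_equal(sum(b$n_recordings), nrow(s))
  # recordings outside all bins are excluded with a warning
  s_bad <- rbind(s, make_summary(0.2, 5, 5, 100, 100))
  expect_warning(b2 <- bin_recordings(s_bad), "outside")
  expect_equal(sum(b2$entrances), sum(s$entrances) + 0)
  # multiplying all times by c divides all rates by c
  s_scaled <- s
  s_scaled$time_run <- s$time_run * 3
  s_scaled$time_pause <- s$time_pause * 3
  b3 <- bin_recordings(s_scaled)
  expect_equal(b3$k_en, b$k_en / 3, tolerance = 1e-12)
  expect_equal(b3$k_ex, b$k_ex / 3, tolerance = 1e-12)
})

test_that("exponential force-law fits recover known generating laws", {
  scheme <- force_bins()
  mids <- (head(scheme$edges, -1) + tail(scheme$edges, -1)) / 2
  # noiseless bins generated from the pause-entrance law: recovered to
  # at least 6 significant digits
  k_true <- 19.4 * exp(mids / -4.6)
  s <- do.call(rbind, lapply(seq_along(mids), function(i)
    make_summary(mids[i], round(k_true[i] * 1e6), 1000, 60e6 / 1, 1000)))
  s$entrances <- k_true * 1e6   # exact counts to avoid rounding
  s$time_run <- 60e6
  b <- bin_recordings(s)
  fit <- fit_rate_law(b, "entrance")
  expect_equal(fit$law$amplitude, 19.4, tolerance = 1e-6)
  expect_equal(fit$law$force_scale, -4.6, tolerance = 1e-6)
  # highest bin excluded by default for rates
  expect_equal(nrow(fit$points), 6)
  fit_all <- fit_rate_law(b, "entrance", exclude_highest = FALSE)
  expect_equal(nrow(fit_all$points), 7)
  # run-speed law (0.52, 14.8) via the run-speed column, all bins used
  s2 <- make_summary(rep(mids, each = 2), 1, 1, 10, 10,
                     run_speed = rep(0.52 * exp(mids / 14.8), each = 2))
  fit2 <- fit_rate_law(bin_recordings(s2), "run_speed")
  expect_equal(fit2$law$amplitude, 0.52, tolerance = 1e-6)
  expect_equal(fit2$law$force_scale, 14.8, tolerance = 1e-6)
  expect_equal(nrow(fit2$points), 7)
})

test_that("fits on noisy bins are nearly unbiased (simulation study)", {
  scheme <- force_bins()
  mids <- (head(scheme$edges, -1) + tail(scheme$edges, -1)) / 2
  k_true <- 19.4 * exp(mids / -4.6)
  set.seed(42)
  est <- t(replicate(100, {
    y <- k_true * (1 + rnorm(7, 0, 0.05))
    s <- make_summary(mids, y * 100, 100, 6000, 1000)
    f <- fit_rate_law(bin_recordings(s), "entrance")$law
    c(f$amplitude, f$force_scale)
  }))
  expect_lt(abs(mean(est[, 1]) / 19.4 - 1), 0.02)
  expect_lt(abs(mean(est[, 2]) / -4.6 - 1), 0.02)
})

test_that("degenerate fits fail loudly", {
  s <- make_summary(c(1.2, 2.5), c(10, 12), c(9, 11), c(100, 100),
                    c(50, 50))
  expect_error(fit_rate_law(bin_recordings(s), "entrance"), "3 usable bins")
})
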