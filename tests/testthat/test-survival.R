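test_that("exceedance tables record first crossings and censorings", {
  mk <- function(sep) data.frame(time = seq_along(sep) - 1, separation = sep)
  series <- list(mk(c(0, 0.2, 0.5, 0.9, 1.0)),   # exceeds 0.8 at t = 3
                 mk(c(0, 0.1, 0.2, 0.3, 0.4)))   # censored at t = 4
  tbl <- exceedance_table(series, threshold = 0.8)
  expect_equal(tbl$time, c(3, 4))
  expect_equal(tbl$status, c(1L, 0L))
})

test_that("the product-limit curve follows its defining product", {
  # no events: survival stays at 1
  tbl0 <- data.frame(time = c(10, 20, 30), status = 0L)
  km0 <- km_curve(tbl0, horizon = 40)
  expect_true(all(km0$surv == 1))
  expect_equal(km0$surv[1], 1)
  # 4 pairs, one event at t = 1: S = 0.75 thereafter
  tbl1 <- data.frame(time = c(1, 50, 50, 50), status = c(1L, 0L, 0L, 0L))
  km1 <- km_curve(tbl1, horizon = 50)
  expect_equal(km1$surv[km1$time >= 1], rep(0.75, 50))
  expect_true(all(diff(km1$surv) <= 0))
})

test_that("km_curve matches an independent product-limit implementation", {
  skip_if_not_installed("survival")
  set.seed(61)
  for (i in 1:100) {
    tbl <- random_exceedance_table(sample(3:40, 1), horizon = 50)
    km <- km_curve(tbl, horizon = 50)
    o <- oracle_km(tbl, horizon = 50)
    expect_equal(km$surv, o$surv, tolerance = 1e-12)
    # the stated SEM formula is Greenwood's formula
    ok <- !is.na(km$sem) & is.finite(o$sem)
    expect_equal(km$sem[ok], o$sem[ok], tolerance = 1e-9)
  }
  # without censoring the curve is the empirical survival function
  ev <- data.frame(time = c(2, 2, 5, 7), status = 1L)
  km <- km_curve(ev, horizon = 10)
  expect_equal(km$surv[km$time == 2], 0.5)
  expect_equal(km$surv[km$time == 5], 0.25)
  expect_equal(km$surv[km$time == 7], 0)
})

test_that("log-rank expected counts match the standard computation", {
  skip_if_not_installed("survival")
  # identical groups: no signal
  tbl <- data.frame(time = c(3, 8, 20, 30), status = c(1L, 1L, 0L, 1L))
  lr0 <- logrank(tbl, tbl, horizon = 40)
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)
  set.seed(62)
  for (i in 1:50) {
    a <- random_exceedance_table(sample(5:30, 1), horizon = 60)
    b <- random_exceedance_table(sample(5:30, 1), horizon = 60)
    if (sum(a$status) + sum(b$status) == 0) next
    lr <- logrank(a, b, horizon = 60)
    grp <- c(rep(1, nrow(a)), rep(2, nrow(b)))
    sd_fit <- survival::survdiff(
      survival::Surv(c(a$time, b$time), c(a$status, b$status)) ~ grp)
    expect_equal(lr$observed, unname(sd_fit$obs))
    expect_equal(lr$expected, unname(sd_fit$exp), tolerance = 1e-9)
    expect_equal(lr$chisq,
                 sum((sd_fit$obs - sd_fit$exp)^2 / sd_fit$exp),
                 tolerance = 1e-9)
    # symmetry in group order
    lr_sw <- logrank(b, a, horizon = 60)
    expect_equal(lr_sw$chisq, lr$chisq)
  }
  # no events in either group: test undefined
  none <- data.frame(time = c(10, 20), status = 0L)
  expect_true(is.na(logrank(none, none)$chisq))
})

test_that("the summed-E log-rank test holds its size under the null", {
  set.seed(63)
  n <- 30
  rejections <- mean(replicate(1000, {
    a <- random_exceedance_table(n, horizon = 60)
    b <- random_exceedance_table(n, horizon = 60)
    p <- logrank(a, b, horizon = 60)$p
    !is.na(p) && p < 0.05
  }))
  expect_gte(rejections, 0.01)
  expect_lte(rejections, 0.065)
})

test_that("the rank-sum test matches exhaustive enumeration and handles ties", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p, 1, tolerance = 1e-9)
  expect_equal(rank_sum_test(rep(2, 4), rep(2, 3))$p, 1)
  # fully separated triples: the most extreme of C(6,3) = 20 orderings,
  # two-sided -> p = 0.1
  expect_equal(rank_sum_test(c(1, 2, 3), c(10, 11, 12))$p, 0.1,
               tolerance = 1e-9)
  set.seed(64)
  for (i in 1:10) {
    a <- runif(sample(3:8, 1)); b <- runif(sample(3:8, 1)) + runif(1, -0.5, 0.5)
    expect_equal(rank_sum_test(a, b)$p, oracle_ranksum_exact_p(a, b),
                 tolerance = 1e-9)
  }
})

test_that("rank-sum p-values are uniform under the null", {
  set.seed(65)
  pv <- replicate(2000, rank_sum_test(rnorm(30), rnorm(30))$p)
  # p-values are mildly discrete, so check uniformity by rejection rates
  expect_gt(mean(pv < 0.05), 0.035)
  expect_lt(mean(pv < 0.05), 0.065)
  expect_gt(mean(pv < 0.5), 0.45)
  expect_lt(mean(pv < 0.5), 0.55)
})
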