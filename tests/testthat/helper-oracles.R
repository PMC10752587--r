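`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths.

# N-spring static equilibrium by numeric root-finding: locate the kinetochore
# position y at which the summed spring tensions balance the total load, then
# read off the per-tip forces.
oracle_nspring_forces <- function(x, kappa, f_total) {
  bal <- function(y) sum(kappa * (y - x)) - f_total
  lo <- min(x) - 2 * abs(f_total) / kappa - 1
  hi <- max(x) + 2 * abs(f_total) / kappa + 1
  y <- uniroot(bal, c(lo, hi), tol = 1e-12)$root
  kappa * (y - x)
}

# per-window OLS slopes computed one window at a time with lm()
oracle_window_slopes <- function(time, position, window, fs) {
  h <- floor(window * fs / 2)
  idx <- (h + 1):(length(time) - h)
  vapply(idx, function(i) {
    sel <- (i - h):(i + h)
    unname(coef(lm(position[sel] ~ time[sel]))[2])
  }, numeric(1)) * 60
}

# density intersection of two Gaussians between their means
oracle_gauss_intersection <- function(w1, mu1, s1, w2, mu2, s2) {
  f <- function(x) w1 * dnorm(x, mu1, s1) - w2 * dnorm(x, mu2, s2)
  uniroot(f, c(mu1 + 1e-6, mu2 - 1e-6))$root
}

# exact two-sided rank-sum p-value by exhaustive enumeration of group
# assignments (no ties assumed)
oracle_ranksum_exact_p <- function(a, b) {
  na <- length(a)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(na)])
  all_w <- apply(combn(na + length(b), na), 2,
                 function(ix) sum(rank(c(a, b))[ix]))
  mean_w <- mean(all_w)
  # the permutation distribution of W is symmetric, so the two-sided p is
  # the total mass at least as far from the center as observed
  mean(abs(all_w - mean_w) >= abs(w_obs - mean_w) - 1e-9)
}

# random censored exceedance-style table on an integer grid
random_exceedance_table <- function(n, horizon = 50) {
  ev <- ceiling(rexp(n, 1 / 15))
  cn <- ceiling(rexp(n, 1 / 25))
  time <- pmin(ev, cn, horizon)
  status <- as.integer(ev <= cn & ev <= horizon)
  structure(data.frame(time = time, status = status),
            class = c("exceedance_table", "data.frame"), horizon = horizon)
}

# textbook product-limit estimate on the 1-s grid via survival::survfit
oracle_km <- function(tbl, horizon) {
  fit <- survival::survfit(survival::Surv(tbl$time, tbl$status) ~ 1)
  s <- summary(fit, times = 0:horizon, extend = TRUE)
  list(surv = s$surv, sem = s$std.err)
}

# hand-built velocity trace (for threshold tests that need raw speeds)
make_velocity_trace <- function(speeds, fs = 200) {
  structure(list(time = seq_along(speeds) / fs, speed = speeds, fs = fs,
                 window = 2, rec_start = 0,
                 rec_end = (length(speeds) + 1) / fs, id = NA_character_),
            class = "velocity_trace")
}

# hand-built interval set
make_interval_set <- function(start, end, label, mean_speed, threshold = 0.3) {
  structure(data.frame(start = start, end = end, label = label,
                       mean_speed = mean_speed, stringsAsFactors = FALSE),
            class = c("interval_set", "data.frame"), threshold = threshold)
}
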