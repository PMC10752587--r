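#' First-exceedance table for a separation threshold
#'
#' For each pair, finds the first 1-s grid time at which the tip separation
#' exceeded the threshold. Pairs that never exceed it within their usable
#' trace (or within the observation horizon) are censored at the end of the
#' usable trace, capped at the horizon.
#'
#' @param series_list List of separation series (see [separation_series()]).
#' @param threshold Separation threshold (um); conventional values are 0.4,
#'   0.6, 0.8, 1.2.
#' @param horizon Observation horizon (s), default 400.
#' @return An object of class `exceedance_table`: data.frame with columns
#'   `time` (s) and `status` (1 = exceeded, 0 = censored).
#' @export
exceedance_table <- function(series_list, threshold, horizon = 400) {
  stopifnot(is.list(series_list), length(series_list) >= 1L,
            is.numeric(threshold), threshold > 0, horizon > 0)
  rows <- lapply(series_list, function(s) {
    s <- s[s$time <= horizon, , drop = FALSE]
    hit <- which(s$separation > threshold)
    if (length(hit)) data.frame(time = s$time[hit[1L]], status = 1L)
    else data.frame(time = max(s$time), status = 0L)
  })
  structure(do.call(rbind, rows),
            class = c("exceedance_table", "data.frame"),
            threshold = threshold, horizon = horizon)
}

#' Kaplan-Meier survival of threshold exceedance
#'
#' Product-limit estimate on a 1-s grid:
#' \deqn{S_t = \prod_{j \le t} (n_j - d_j) / n_j,}
#' where n_j is the number of pairs still at risk (usable and within the
#' threshold) at j seconds and d_j the number that exceeded the threshold
#' between j-1 and j seconds. Censored pairs leave the risk set without an
#' event; censorings at the same integer second as events are processed
#' after the events. The SEM is Greenwood's formula,
#' \deqn{SEM_t = S_t \sqrt{\sum_{j \le t} d_j / (n_j (n_j - d_j))},}
#' reported as missing from the first time at which n_j = d_j makes the term
#' singular.
#'
#' @param tbl An [exceedance_table()] (or data.frame with `time`, `status`).
#' @param horizon Last grid time (s); defaults to the table's horizon
#'   attribute or the largest recorded time.
#' @return An object of class `survival_curve`: data.frame with columns
#'   `time` (0..horizon), `n_risk`, `n_event`, `surv`, `sem`.
#' @export
km_curve <- function(tbl, horizon = NULL) {
  stopifnot(is.data.frame(tbl), nrow(tbl) >= 1L,
            all(c("time", "status") %in% names(tbl)))
  if (is.null(horizon))
    horizon <- attr(tbl, "horizon") %||% ceiling(max(tbl$time))
  grid <- seq_len(horizon)
  cnt <- .risk_event_counts(tbl, horizon)
  n_risk <- cnt$n_risk
  n_event <- cnt$n_event
  frac <- ifelse(n_risk > 0, (n_risk - n_event) / n_risk, 1)
  surv <- cumprod(frac)
  term <- ifelse(n_risk > 0 & n_risk > n_event,
                 n_event / (n_risk * (n_risk - n_event)), NA_real_)
  term[n_risk > 0 & n_event == 0] <- 0
  term[n_risk == 0] <- 0
  singular <- n_risk > 0 & n_risk == n_event & n_event > 0
  sem <- surv * sqrt(cumsum(ifelse(is.na(term), 0, term)))
  if (any(singular)) sem[seq_along(grid) >= which(singular)[1L]] <- NA_real_
  structure(data.frame(time = c(0, grid), n_risk = c(nrow(tbl), n_risk),
                       n_event = c(0L, n_event), surv = c(1, surv),
                       sem = c(0, sem)),
            class = c("survival_curve", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# at-risk and event counts on the 1-s grid; departures (event or censoring)
# at integer second j leave the risk set after j, so n_j counts pairs with
# departure time >= j
#' @keywords internal
#' @noRd
.risk_event_counts <- function(tbl, horizon) {
  tj <- pmax(1L, ceiling(tbl$time))
  gone <- tabulate(pmin(tj, horizon + 1L), nbins = horizon)
  n_risk <- nrow(tbl) - c(0L, cumsum(gone))[seq_len(horizon)]
  n_event <- tabulate(tj[tbl$status == 1L & tj <= horizon], nbins = horizon)
  list(n_risk = n_risk, n_event = n_event)
}

#' Log-rank comparison of two exceedance survival curves
#'
#' At each 1-s step, the expected number of events in each group is
#' \deqn{E_t = (n_t / n_{tot}) d_{tot},}
#' with n_t the group's at-risk count, n_tot the pooled at-risk count, and
#' d_tot the pooled event count at that step. The statistic sums observed
#' and expected counts over the horizon:
#' \deqn{\chi^2 = \sum_{groups} (\sum_t d_t - \sum_t E_t)^2 / \sum_t E_t,}
#' with the p-value from the chi-square distribution with 1 degree of
#' freedom.
#'
#' @param tbl_a,tbl_b [exceedance_table()]s for the two groups.
#' @param horizon Number of 1-s steps (default 400).
#' @return List with `chisq`, `p`, `observed` and `expected` (2-vectors),
#'   and `df = 1`. If neither group has any events the test is undefined and
#'   `chisq`/`p` are `NA`.
#' @export
logrank <- function(tbl_a, tbl_b, horizon = 400) {
  stopifnot(is.data.frame(tbl_a), nrow(tbl_a) >= 1L,
            is.data.frame(tbl_b), nrow(tbl_b) >= 1L)
  a <- .risk_event_counts(tbl_a, horizon)
  b <- .risk_event_counts(tbl_b, horizon)
  a$d <- a$n_event; a$n <- a$n_risk
  b$d <- b$n_event; b$n <- b$n_risk
  d_tot <- a$d + b$d
  n_tot <- a$n + b$n
  if (sum(d_tot) == 0L)
    return(list(chisq = NA_real_, p = NA_real_,
                observed = c(0, 0), expected = c(0, 0), df = 1L))
  e_a <- ifelse(n_tot > 0, a$n / n_tot * d_tot, 0)
  e_b <- ifelse(n_tot > 0, b$n / n_tot * d_tot, 0)
  O <- c(sum(a$d), sum(b$d))
  E <- c(sum(e_a), sum(e_b))
  chisq <- sum((O - E)^2 / E)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       observed = O, expected = E, df = 1L)
}

#' Two-sample Wilcoxon-Mann-Whitney rank test
#'
#' Two-sided two-sample rank test: exact for small samples without ties,
#' normal approximation with tie correction otherwise. If every value in
#' both samples is identical the test is degenerate and p = 1.
#'
#' @param a,b Numeric samples, both non-empty.
#' @return List with `p` and the rank-sum statistic `w`.
#' @export
rank_sum_test <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 1L, length(b) >= 1L)
  if (length(unique(c(a, b))) == 1L)
    return(list(p = 1, w = length(a) * length(b) / 2))
  ht <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  list(p = ht$p.value, w = unname(ht$statistic))
}
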