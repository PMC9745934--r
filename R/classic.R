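#' Mantel-Haenszel pooled odds ratio
#'
#' Weighted average of study odds ratios with weights
#' `w_k = (n_kT - y_kT) y_kC / n_k`, algebraically equal to
#' `sum(a_k d_k / n_k) / sum(b_k c_k / n_k)`. No continuity correction is
#' applied; by default every study whose 2x2 table contains a zero cell is
#' dropped (the convention used here mirrors ignoring single- and double-zero
#' studies). The standard error of the log odds ratio is the
#' Robins-Breslow-Greenland variance, with a normal 95% CI.
#'
#' @inheritParams fit_bbst
#' @param drop_zero_studies Drop studies with any zero cell (default `TRUE`).
#'   Set to `FALSE` for the conventional Mantel-Haenszel behaviour in which
#'   single-zero studies still contribute.
#' @return A one-row tibble as in [fit_bbst()] (log-OR scale);
#'   `n_studies_used` counts the retained studies.
#' @export
fit_mh <- function(data, drop_zero_studies = TRUE) {
  data <- validate_studies(data)
  K <- nrow(data)
  a <- data$y_t; b <- data$n_t - data$y_t
  cc <- data$y_c; d <- data$n_c - data$y_c
  n <- data$n_t + data$n_c
  keep <- if (drop_zero_studies) a > 0 & b > 0 & cc > 0 & d > 0 else rep(TRUE, K)
  base <- method_result("mh", "or", n_studies_used = sum(keep))
  if (!any(keep)) return(base)
  a <- a[keep]; b <- b[keep]; cc <- cc[keep]; d <- d[keep]; n <- n[keep]

  R <- a * d / n
  S <- b * cc / n
  if (sum(R) <= 0 || sum(S) <= 0) return(base)
  est <- log(sum(R) / sum(S))
  P <- (a + d) / n
  Q <- (b + cc) / n
  v <- sum(P * R) / (2 * sum(R)^2) +
    sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
    sum(Q * S) / (2 * sum(S)^2)
  se <- sqrt(v)
  if (!is.finite(se) || se <= 0) return(base)
  half <- 1.96 * se
  method_result("mh", "or", est = est, se = se, ci_lo = est - half,
                ci_hi = est + half, converged = TRUE,
                n_studies_used = sum(keep))
}

#' Peto one-step pooled odds ratio
#'
#' `log(POR) = sum(O_k - E_k) / sum(V_k)` with observed treatment-arm events
#' `O_k = y_kT`, expectation `E_k = (y_kT + y_kC) n_kT / n_k` under no effect,
#' and hypergeometric variance
#' `V_k = E_k (n_k - m_k)/n_k * n_kC/(n_k - 1)`, `m_k = y_kT + y_kC`.
#' Single-zero studies contribute without correction; studies with `V_k = 0`
#' (no events, or events in everyone) carry no information and are excluded.
#' The 95% CI uses `se = 1/sqrt(sum(V_k))` and the normal approximation.
#'
#' @inheritParams fit_bbst
#' @return A one-row tibble as in [fit_bbst()] (log-POR scale).
#' @export
fit_peto <- function(data) {
  data <- validate_studies(data)
  n <- data$n_t + data$n_c
  m <- data$y_t + data$y_c
  O <- data$y_t
  E <- m * data$n_t / n
  V <- E * ((n - m) / n) * (data$n_c / pmax(n - 1, 1))
  keep <- V > 0
  base <- method_result("peto", "or", n_studies_used = sum(keep))
  if (!any(keep)) return(base)
  sumV <- sum(V[keep])
  est <- sum(O[keep] - E[keep]) / sumV
  se <- 1 / sqrt(sumV)
  half <- 1.96 * se
  method_result("peto", "or", est = est, se = se, ci_lo = est - half,
                ci_hi = est + half, converged = TRUE,
                n_studies_used = sum(keep))
}

#' Collapsed-table estimate
#'
#' Aggregates all studies into one 2x2 table, ignoring stratification (and
#' therefore vulnerable to Simpson's paradox), and computes the log odds
#' ratio or log relative risk with the delta-method (Woolf) standard error
#' and a normal 95% CI. If the pooled table contains a zero cell, 0.5 is
#' added to all four cells.
#'
#' @inheritParams fit_bbst
#' @return A one-row tibble as in [fit_bbst()].
#' @export
fit_collapsed <- function(data, measure = c("or", "rr")) {
  data <- validate_studies(data)
  measure <- match.arg(measure)
  K <- nrow(data)
  a <- sum(data$y_t); b <- sum(data$n_t) - a
  cc <- sum(data$y_c); d <- sum(data$n_c) - cc
  if (min(a, b, cc, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  n_t <- a + b; n_c <- cc + d
  if (measure == "or") {
    est <- log(a * d / (b * cc))
    v <- 1 / a + 1 / b + 1 / cc + 1 / d
  } else {
    est <- log((a / n_t) / (cc / n_c))
    v <- 1 / a - 1 / n_t + 1 / cc - 1 / n_c
  }
  se <- sqrt(v)
  half <- 1.96 * se
  method_result("coll", measure, est = est, se = se, ci_lo = est - half,
                ci_hi = est + half, converged = TRUE, n_studies_used = K)
}
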