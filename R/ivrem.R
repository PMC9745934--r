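included_effects <- function(effects) {
  eff <- dplyr::filter(effects, .data$included)
  if (nrow(eff) < 1) abort("no included effect estimates")
  eff
}

#' Inverse-variance fixed-effect pooled estimate
#'
#' @param effects A tibble of per-study effects as returned by
#'   [per_study_log_effects()].
#' @return A one-row tibble with `theta_fem` (inverse-variance weighted mean)
#'   and `se_fem` (`sqrt(1/sum(w))`, `w = 1/var`).
#' @export
fixed_effect <- function(effects) {
  eff <- included_effects(effects)
  w <- 1 / eff$var
  tibble::tibble(
    theta_fem = sum(w * eff$theta_hat) / sum(w),
    se_fem = sqrt(1 / sum(w))
  )
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum(w_k (theta_k - theta_FEM)^2)` with fixed-effect weights
#' `w_k = 1/var_k`, referred to a chi-square distribution with `K - 1`
#' degrees of freedom.
#'
#' @inheritParams fixed_effect
#' @return A one-row tibble with `Q`, `df` and `p_value`.
#' @export
cochran_q <- function(effects) {
  eff <- included_effects(effects)
  K <- nrow(eff)
  if (K < 2) abort("Cochran's Q needs at least 2 included studies")
  w <- 1 / eff$var
  theta_fem <- sum(w * eff$theta_hat) / sum(w)
  Q <- sum(w * (eff$theta_hat - theta_fem)^2)
  tibble::tibble(Q = Q, df = K - 1, p_value = pchisq(Q, K - 1, lower.tail = FALSE))
}

#' DerSimonian-Laird between-study variance
#'
#' Method-of-moments estimator
#' `max(0, (Q - (K-1)) / (sum(w) - sum(w^2)/sum(w)))` with fixed-effect
#' weights.
#'
#' @inheritParams fixed_effect
#' @return The non-negative heterogeneity estimate.
#' @export
tau2_dsl <- function(effects) {
  eff <- included_effects(effects)
  K <- nrow(eff)
  if (K < 2) return(0)
  w <- 1 / eff$var
  Q <- cochran_q(effects)$Q
  max(0, (Q - (K - 1)) / (sum(w) - sum(w^2) / sum(w)))
}

#' Paule-Mandel between-study variance
#'
#' Solves the generalised Q equation `Q(tau2) = K - 1`, where `Q(tau2)` uses
#' weights `1/(var_k + tau2)` and the corresponding weighted mean. `Q(tau2)`
#' is strictly decreasing, so the root is unique; if `Q(0) <= K - 1` no
#' positive solution exists and the estimate is 0.
#'
#' @inheritParams fixed_effect
#' @param tol Absolute tolerance for the root.
#' @param max_iter Maximum number of bracket expansions / iterations.
#' @return The non-negative heterogeneity estimate.
#' @export
tau2_pm <- function(effects, tol = 1e-8, max_iter = 200) {
  eff <- included_effects(effects)
  K <- nrow(eff)
  if (K < 2) return(0)
  gen_q <- function(tau2) {
    w <- 1 / (eff$var + tau2)
    th <- sum(w * eff$theta_hat) / sum(w)
    sum(w * (eff$theta_hat - th)^2)
  }
  f <- function(tau2) gen_q(tau2) - (K - 1)
  if (f(0) <= 0) return(0)
  hi <- 1
  it <- 0
  while (f(hi) > 0) {
    hi <- hi * 2
    it <- it + 1
    if (it > max_iter) abort("Paule-Mandel bracketing failed: Q(tau2) stayed above K - 1")
  }
  uniroot(f, c(0, hi), tol = tol, maxiter = max_iter)$root
}

ivrem_effects <- function(data, measure, effects) {
  if (is.null(effects)) per_study_log_effects(data, measure) else effects
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Inverse-variance pooling with weights `1/(var_k + tau2_DSL)` and the
#' normal-approximation 95% CI `theta_hat +/- 1.96 * se`. Single-zero studies
#' are continuity-corrected and double-zero studies excluded (the
#' inverse-variance policy of [per_study_log_effects()]).
#'
#' @inheritParams fit_bbst
#' @param effects Optionally, a precomputed tibble from
#'   [per_study_log_effects()]; by default it is derived from `data` with the
#'   `"ivrem"` policy.
#' @return A one-row tibble as in [fit_bbst()]; `tau2_hat` records the DSL
#'   heterogeneity estimate.
#' @export
fit_dsl <- function(data, measure = c("or", "rr"), effects = NULL) {
  measure <- match.arg(measure)
  eff <- tryCatch(included_effects(ivrem_effects(data, measure, effects)),
                  error = function(e) NULL)
  if (is.null(eff)) return(method_result("dsl", measure, n_studies_used = 0L))
  tau2 <- tau2_dsl(dplyr::mutate(eff, included = TRUE))
  w <- 1 / (eff$var + tau2)
  est <- sum(w * eff$theta_hat) / sum(w)
  se <- sqrt(1 / sum(w))
  half <- 1.96 * se
  method_result("dsl", measure, est = est, se = se, ci_lo = est - half,
                ci_hi = est + half, tau2_hat = tau2, converged = TRUE,
                n_studies_used = nrow(eff))
}

#' Hartung-Knapp-Sidik-Jonkman meta-analysis with Paule-Mandel heterogeneity
#'
#' Pools with Paule-Mandel weights `1/(var_k + tau2_PM)` and builds the 95% CI
#' `theta_hat +/- t(K-1, 0.975) * sqrt(q) * se`, where
#' `q = sum(w_k (theta_k - theta_hat)^2) / (K - 1)`. If that interval is
#' narrower than the DerSimonian-Laird interval on the same data, the ad-hoc
#' modification `q* = max(1, q)` is applied instead, guaranteeing an interval
#' at least as wide as a plain t interval.
#'
#' @inheritParams fit_dsl
#' @return A one-row tibble as in [fit_bbst()]; `se` already includes the
#'   `sqrt(q)` scaling, so `ci = est +/- t(df) * se` with `df = K - 1`. The
#'   unscaled `q` and whether the ad-hoc rule fired are attached as attributes
#'   `"q"` and `"adhoc"`.
#' @export
fit_hksj <- function(data, measure = c("or", "rr"), effects = NULL) {
  measure <- match.arg(measure)
  eff <- tryCatch(included_effects(ivrem_effects(data, measure, effects)),
                  error = function(e) NULL)
  if (is.null(eff) || nrow(eff) < 2) {
    return(method_result("hksj", measure,
                         n_studies_used = if (is.null(eff)) 0L else nrow(eff)))
  }
  K <- nrow(eff)
  tau2 <- tau2_pm(dplyr::mutate(eff, included = TRUE))
  w <- 1 / (eff$var + tau2)
  est <- sum(w * eff$theta_hat) / sum(w)
  sigma <- sqrt(1 / sum(w))
  q <- sum(w * (eff$theta_hat - est)^2) / (K - 1)
  tq <- qt(0.975, K - 1)

  dsl <- fit_dsl(data, measure, effects = effects)
  adhoc <- FALSE
  q_used <- q
  ci_len <- 2 * tq * sqrt(q) * sigma
  if (isTRUE(dsl$converged) && ci_len < (dsl$ci_hi - dsl$ci_lo)) {
    adhoc <- TRUE
    q_used <- max(1, q)
  }
  se <- sqrt(q_used) * sigma
  half <- tq * se
  out <- method_result("hksj", measure, est = est, se = se, ci_lo = est - half,
                       ci_hi = est + half, df = K - 1, tau2_hat = tau2,
                       converged = TRUE, n_studies_used = K)
  attr(out, "q") <- q
  attr(out, "adhoc") <- adhoc
  out
}
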