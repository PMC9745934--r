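#' Beta-binomial probability mass function
#'
#' Density of the beta-binomial distribution with shape parameters `alpha` and
#' `beta`, computed through the log-beta function:
#' \deqn{P(Y = y) = \binom{n}{y} B(y + \alpha, n - y + \beta) / B(\alpha, \beta).}
#' This equals the expanded nine-log-gamma form of the arm-level log
#' likelihood used by the beta-binomial meta-analysis models.
#'
#' @param y Event count(s), `0 <= y <= n`.
#' @param n Number of trials.
#' @param alpha,beta Positive shape parameters.
#' @param log If `TRUE`, return the log density.
#' @return Density (or log density), vectorised over the arguments.
#' @examples
#' dbetabinom(0:2, 2, alpha = 2, beta = 3) # 0.4, 0.4, 0.2
#' @export
dbetabinom <- function(y, n, alpha, beta, log = FALSE) {
  if (any(!is.finite(alpha)) || any(!is.finite(beta)) ||
      any(alpha <= 0) || any(beta <= 0)) {
    abort("alpha and beta must be finite and positive")
  }
  if (any(y < 0 | y > n)) abort("y must satisfy 0 <= y <= n")
  out <- lchoose(n, y) + lbeta(y + alpha, n - y + beta) - lbeta(alpha, beta)
  if (log) out else exp(out)
}

# Beta shapes implied by a mean mu and intraclass correlation rho:
# alpha = mu (1 - rho) / rho, beta = (1 - mu)(1 - rho) / rho, so that
# alpha + beta = (1 - rho) / rho is common to any arm sharing rho.
bb_shapes <- function(mu, rho) {
  s <- (1 - rho) / rho
  list(alpha = mu * s, beta = (1 - mu) * s)
}

# lean vectorised beta-binomial log pmf for optimizer inner loops: the
# binomial coefficient is precomputed once per dataset and no argument
# validation is repeated
bb_ll_fast <- function(y, n, lc, alpha, beta) {
  lc + lbeta(y + alpha, n - y + beta) - lbeta(alpha, beta)
}

# Inverse link: probability implied by a linear predictor. Returns NA outside
# (0, 1) so callers can emit an infinite penalty (log link can exceed 1).
inv_link <- function(eta, link) {
  mu <- if (link == "logit") plogis(eta) else exp(eta)
  mu[mu <= 0 | mu >= 1] <- NA_real_
  mu
}

link_for <- function(measure) if (measure == "or") "logit" else "log"

PENALTY <- 1e10

#' Negative log likelihood of the common-rho beta-binomial model
#'
#' The common-rho model treats each arm's event count as beta-binomial with an
#' arm-group-specific mean (`mu_C` for control arms, `mu_T` for treatment
#' arms, tied together through the linear predictor `b0 + b_t * i` on the link
#' scale) and a single intraclass correlation `rho` shared by every arm, which
#' is equivalent to `alpha_C + beta_C = alpha_T + beta_T`.
#'
#' @inheritParams validate_studies
#' @param params Numeric vector `c(b0, b_t, rho)` on the natural scale.
#' @param measure `"or"` (logit link) or `"rr"` (log link).
#' @return The negated log likelihood; parameter values implying an arm mean
#'   outside (0, 1) receive a large finite penalty.
#' @export
bbst_negloglik <- function(params, data, measure = c("or", "rr")) {
  measure <- match.arg(measure)
  link <- link_for(measure)
  b0 <- params[1]; bt <- params[2]; rho <- params[3]
  if (!all(is.finite(params)) || rho <= 0 || rho >= 1) return(PENALTY)
  mu_c <- inv_link(b0, link)
  mu_t <- inv_link(b0 + bt, link)
  if (is.na(mu_c) || is.na(mu_t)) return(PENALTY)
  sc <- bb_shapes(mu_c, rho)
  st <- bb_shapes(mu_t, rho)
  ll <- sum(dbetabinom(data$y_c, data$n_c, sc$alpha, sc$beta, log = TRUE)) +
    sum(dbetabinom(data$y_t, data$n_t, st$alpha, st$beta, log = TRUE))
  if (!is.finite(ll)) return(PENALTY)
  -ll
}

#' 95% t confidence interval
#'
#' @param est Point estimate.
#' @param se Standard error (positive).
#' @param df Degrees of freedom (>= 1).
#' @return A numeric vector `c(lo, hi)` equal to `est +/- t(df, 0.975) * se`.
#' @export
t_ci <- function(est, se, df) {
  if (df < 1) abort("df must be >= 1")
  if (se < 0) abort("se must be non-negative")
  half <- qt(0.975, df) * se
  c(est - half, est + half)
}

df_from_rule <- function(df_rule, K) {
  switch(df_rule, "k-1" = K - 1, "2k-2" = 2 * K - 2,
         abort("df_rule must be 'k-1' or '2k-2'"))
}

# Quasi-Newton ML with numeric gradients on a transformed scale (nlminb, then
# a BFGS polish), followed by a numeric observed-information matrix.
# Convergence requires optimizer success, a positive-definite information
# matrix and a finite standard error for the target parameter; fits failing
# any of these are reported as non-converged, never as errors. Variance-type
# nuisance parameters that have drifted to a flat boundary (e.g. rho -> 0 or
# sigma2 -> 0 on homogeneous data) contribute no curvature; they are dropped
# from the information matrix before inversion, which yields the standard
# error conditional on the boundary.
ml_fit <- function(nll, start, target) {
  best_par <- start
  best_val <- nll(start)
  opt_ok <- FALSE
  opt <- tryCatch(
    nlminb(start, nll, control = list(iter.max = 500, eval.max = 2000)),
    error = function(e) NULL
  )
  if (!is.null(opt) && is.finite(opt$objective) && opt$objective <= best_val) {
    best_par <- opt$par
    best_val <- opt$objective
    opt_ok <- opt$convergence == 0
  }
  if (!opt_ok) {
    # nlminb "false convergence" is common when a variance-type parameter
    # drifts to its boundary; a BFGS polish settles those fits (its final
    # value may sit a numerical-noise epsilon above nlminb's)
    pol <- tryCatch(
      optim(best_par, nll, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (!is.null(pol) && is.finite(pol$value) && pol$value <= best_val + 1e-3) {
      if (pol$value < best_val) {
        best_par <- pol$par
        best_val <- pol$value
      }
      opt_ok <- pol$convergence == 0
    }
  }
  fail <- list(ok = FALSE)
  if (!opt_ok || !is.finite(best_val) || best_val >= PENALTY / 2) return(fail)
  H <- tryCatch(
    optimHess(best_par, nll,
              control = list(ndeps = rep(5e-3, length(best_par)))),
    error = function(e) NULL
  )
  if (is.null(H) || any(!is.finite(H))) return(fail)
  dH <- diag(H)
  keep <- dH > 1e-7 * max(dH, 1)
  if (!keep[target]) return(fail)
  # if the kept block is still not positive definite (boundary directions
  # with junk curvature), drop the weakest non-target directions one by one
  V <- NULL
  repeat {
    ch <- tryCatch(chol(H[keep, keep, drop = FALSE]), error = function(e) NULL)
    if (!is.null(ch)) {
      V <- chol2inv(ch)
      break
    }
    droppable <- which(keep & seq_along(keep) != target)
    if (length(droppable) == 0) return(fail)
    keep[droppable[which.min(dH[droppable])]] <- FALSE
  }
  ti <- sum(keep[seq_len(target)])
  se <- sqrt(V[ti, ti])
  if (!is.finite(se) || se <= 0) return(fail)
  list(ok = TRUE, par = best_par, value = best_val, se = se)
}

bb_start <- function(data, measure) {
  link <- link_for(measure)
  p_c <- (sum(data$y_c) + 0.5) / (sum(data$n_c) + 1)
  p_t <- (sum(data$y_t) + 0.5) / (sum(data$n_t) + 1)
  g <- if (link == "logit") qlogis else log
  c(b0 = g(p_c), bt = g(p_t) - g(p_c))
}

# A whole arm group with zero events leaves the OR/RR undefined in the
# arm-mean parameterisation; such datasets are flagged inestimable upfront.
bb_inestimable <- function(data) sum(data$y_t) == 0 || sum(data$y_c) == 0

#' Fit the common-rho beta-binomial meta-analysis model (BBST)
#'
#' Maximum likelihood on `(b0, b_t, logit rho)`, with the treatment effect
#' `b_t` interpreted as log odds ratio (logit link) or log relative risk (log
#' link). Single- and double-zero studies need no continuity correction and
#' contribute to the fit. The 95% CI uses the t distribution.
#'
#' @inheritParams validate_studies
#' @param measure `"or"` or `"rr"`.
#' @param df_rule Degrees of freedom for the t interval: `"2k-2"` (default) or
#'   `"k-1"`.
#' @return A one-row tibble with columns `method`, `measure`, `est`, `se`,
#'   `ci_lo`, `ci_hi`, `df`, `tau2_hat`, `converged`, `n_studies_used`,
#'   `loglik`. The fitted natural-scale parameters are attached as the
#'   `"params"` attribute.
#' @examples
#' studies <- tibble::tibble(
#'   study_id = 1:2, y_t = c(3, 4), n_t = c(10, 12), y_c = c(1, 2), n_c = c(10, 12)
#' )
#' fit_bbst(studies)
#' @export
fit_bbst <- function(data, measure = c("or", "rr"), df_rule = c("2k-2", "k-1")) {
  data <- validate_studies(data)
  measure <- match.arg(measure)
  df_rule <- match.arg(df_rule)
  K <- nrow(data)
  df <- df_from_rule(df_rule, K)
  base <- method_result("bbst", measure, df = df, n_studies_used = K)
  if (bb_inestimable(data)) return(base)

  nll <- function(p) {
    bbst_negloglik(c(p[1], p[2], plogis(p[3])), data, measure)
  }
  start <- c(bb_start(data, measure), lrho = qlogis(0.1))
  fit <- ml_fit(nll, start, target = 2)
  if (!fit$ok) return(base)

  est <- fit$par[2]
  se <- fit$se
  ci <- t_ci(est, se, df)
  rho <- plogis(fit$par[3])
  mu_c <- inv_link(fit$par[1], link_for(measure))
  mu_t <- inv_link(fit$par[1] + fit$par[2], link_for(measure))
  out <- method_result("bbst", measure, est = est, se = se, ci_lo = ci[1],
                       ci_hi = ci[2], df = df, converged = TRUE,
                       n_studies_used = K, loglik = -fit$value)
  attr(out, "params") <- list(
    b0 = unname(fit$par[1]), b_t = unname(est), rho = unname(rho),
    alpha_c = bb_shapes(mu_c, rho)$alpha, beta_c = bb_shapes(mu_c, rho)$beta,
    alpha_t = bb_shapes(mu_t, rho)$alpha, beta_t = bb_shapes(mu_t, rho)$beta
  )
  out
}

# Adaptive Gauss-Hermite marginal log likelihood, vectorised over studies.
# cond_ll(g) takes a vector of random-effect values (one per study) and
# returns the per-study conditional log likelihood. With one node this is the
# Laplace approximation around the per-study mode.
agh_marginal <- function(cond_ll, K, sigma2, quad_points = 1, g_init = NULL) {
  if (sigma2 < 1e-10) return(cond_ll(rep(0, K)))
  sig <- sqrt(sigma2)
  h <- function(g) cond_ll(g) + dnorm(g, 0, sig, log = TRUE)
  # vectorised damped Newton for the per-study modes (numeric derivatives,
  # step halving whenever a step would decrease h); `g_init` lets the caller
  # seed the iteration with an approximate posterior mode
  g <- rep(0, K)
  if (!is.null(g_init)) {
    gi_ok <- is.finite(g_init) & is.finite(h(g_init))
    g[gi_ok] <- g_init[gi_ok]
  }
  # gradient step small; curvature step larger, because second differences of
  # log-gamma-based likelihoods lose ~5 digits to cancellation at tiny rho
  eps <- 1e-3
  eps2 <- 1e-2
  for (iter in 1:100) {
    h0 <- h(g); hp <- h(g + eps); hm <- h(g - eps)
    h1 <- (hp - hm) / (2 * eps)
    h2 <- (hp - 2 * h0 + hm) / eps^2
    h2[!is.finite(h2) | h2 >= -1e-12] <- -1 / sigma2
    step <- -h1 / h2
    step[!is.finite(step)] <- 0
    step <- pmin(pmax(step, -20 * sig), 20 * sig)
    for (j in 1:30) {
      hc <- h(g + step)
      bad <- !is.finite(hc) | hc < h0 - 1e-12
      if (!any(bad)) break
      step[bad] <- step[bad] / 2
    }
    g <- g + step
    if (max(abs(step)) < 1e-10) break
  }
  # curvature at the final mode
  h0 <- h(g)
  h2 <- (h(g + eps2) - 2 * h0 + h(g - eps2)) / eps2^2
  h2[!is.finite(h2) | h2 >= -1e-12] <- -1 / sigma2
  sd_hat <- 1 / sqrt(-h2)
  if (quad_points == 1) {
    return(h0 + 0.5 * log(2 * pi) + log(sd_hat))
  }
  gq <- pracma::gaussHermite(quad_points)
  terms <- vapply(seq_along(gq$x), function(j) {
    h(g + sqrt(2) * sd_hat * gq$x[j]) + gq$x[j]^2 + log(gq$w[j])
  }, numeric(K))
  terms <- matrix(terms, nrow = K)
  m <- apply(terms, 1, max)
  m + log(rowSums(exp(terms - m))) + 0.5 * log(2) + log(sd_hat)
}

#' Fit the common-rho beta-binomial model with a random treatment effect (BBFR)
#'
#' Extends the common-rho model by a per-study normal deviation `gamma_k ~
#' N(0, sigma2)` added to the treatment effect, so that the pairing of each
#' treatment arm with its own control arm enters the likelihood. The
#' treatment-arm contribution of each study is marginalised over `gamma_k` by
#' adaptive Gauss-Hermite quadrature; one node (the default) is the Laplace
#' approximation.
#'
#' @inheritParams fit_bbst
#' @param quad_points Number of adaptive quadrature nodes (1 = Laplace).
#' @return A one-row tibble as in [fit_bbst()]; `tau2_hat` carries the
#'   estimated random-effect variance.
#' @export
fit_bbfr <- function(data, measure = c("or", "rr"), df_rule = c("2k-2", "k-1"),
                     quad_points = 1) {
  data <- validate_studies(data)
  measure <- match.arg(measure)
  df_rule <- match.arg(df_rule)
  link <- link_for(measure)
  K <- nrow(data)
  df <- df_from_rule(df_rule, K)
  base <- method_result("bbfr", measure, df = df, n_studies_used = K)
  if (bb_inestimable(data)) return(base)

  y_t <- data$y_t; n_t <- data$n_t; y_c <- data$y_c; n_c <- data$n_c
  lc_t <- lchoose(n_t, y_t); lc_c <- lchoose(n_c, y_c)
  logit_link <- link == "logit"
  p_hat <- (y_t + 0.5) / (n_t + 1)
  eta_star <- if (logit_link) qlogis(p_hat) else log(p_hat)
  fisher_t <- n_t * p_hat * (1 - p_hat)
  nll <- function(p) {
    b0 <- p[1]; bt <- p[2]; rho <- plogis(p[3]); sigma2 <- exp(p[4])
    if (!all(is.finite(p))) return(PENALTY)
    mu_c <- inv_link(b0, link)
    if (is.na(mu_c)) return(PENALTY)
    s <- (1 - rho) / rho
    ll_c <- sum(bb_ll_fast(y_c, n_c, lc_c, mu_c * s, (1 - mu_c) * s))
    cond_ll <- function(g) {
      eta <- b0 + bt + g
      mu_t <- if (logit_link) plogis(eta) else exp(eta)
      out <- bb_ll_fast(y_t, n_t, lc_t, mu_t * s, (1 - mu_t) * s)
      out[!is.finite(out) | mu_t <= 0 | mu_t >= 1] <- -PENALTY
      out
    }
    # normal-approximation posterior mean as the mode search seed
    g_init <- (eta_star - b0 - bt) * sigma2 * fisher_t / (1 + sigma2 * fisher_t)
    ll_t <- sum(agh_marginal(cond_ll, K, sigma2, quad_points, g_init = g_init))
    if (!is.finite(ll_c + ll_t)) return(PENALTY)
    -(ll_c + ll_t)
  }
  start <- c(bb_start(data, measure), lrho = qlogis(0.1), lsig2 = log(0.01))
  fit <- ml_fit(nll, start, target = 2)
  if (!fit$ok) return(base)

  est <- fit$par[2]
  se <- fit$se
  ci <- t_ci(est, se, df)
  sigma2 <- exp(fit$par[4])
  out <- method_result("bbfr", measure, est = est, se = se, ci_lo = ci[1],
                       ci_hi = ci[2], df = df,
                       tau2_hat = if (sigma2 < 1e-8) 0 else sigma2,
                       converged = TRUE, n_studies_used = K,
                       loglik = -fit$value)
  attr(out, "params") <- list(b0 = unname(fit$par[1]), b_t = unname(est),
                              rho = plogis(unname(fit$par[3])),
                              sigma2 = unname(sigma2))
  out
}

#' Fit the common-beta beta-binomial model conditioning on study group (BBCB1)
#'
#' Assumes one shared second shape parameter `beta` for all arms and
#' group-specific first shape parameters `alpha_C` and `alpha_T`, pooling arms
#' of the same kind across studies: `y_ki ~ BetaBin(n_ki; alpha_i, beta)`.
#' The treatment effect is the log odds ratio of the implied arm means,
#' `b_t = logit(alpha_T / (alpha_T + beta)) - logit(alpha_C / (alpha_C +
#' beta)) = log(alpha_T / alpha_C)`; only the odds ratio is estimable in this
#' parameterisation.
#'
#' @inheritParams fit_bbst
#' @return A one-row tibble as in [fit_bbst()].
#' @export
fit_bbcb1 <- function(data, df_rule = c("2k-2", "k-1")) {
  data <- validate_studies(data)
  df_rule <- match.arg(df_rule)
  K <- nrow(data)
  df <- df_from_rule(df_rule, K)
  base <- method_result("bbcb1", "or", df = df, n_studies_used = K)
  if (bb_inestimable(data)) return(base)

  # parameterised as (logit mu_C, b_t, log beta): alpha_C = beta exp(p1),
  # alpha_T = beta exp(p1 + p2), so b_t = log(alpha_T/alpha_C) is a direct
  # coordinate and the no-overdispersion ridge (beta -> Inf) is axis-aligned
  nll <- function(p) {
    if (!all(is.finite(p)) || any(abs(p) > 30)) return(PENALTY)
    b <- exp(p[3])
    a_c <- b * exp(p[1]); a_t <- b * exp(p[1] + p[2])
    ll <- sum(dbetabinom(data$y_c, data$n_c, a_c, b, log = TRUE)) +
      sum(dbetabinom(data$y_t, data$n_t, a_t, b, log = TRUE))
    if (!is.finite(ll)) return(PENALTY)
    -ll
  }
  p_c <- (sum(data$y_c) + 0.5) / (sum(data$n_c) + 1)
  p_t <- (sum(data$y_t) + 0.5) / (sum(data$n_t) + 1)
  b_start <- (1 - 0.1) / 0.1 * (1 - (p_c + p_t) / 2)
  start <- c(qlogis(p_c), qlogis(p_t) - qlogis(p_c), log(b_start))
  fit <- ml_fit(nll, start, target = 2)
  if (!fit$ok) return(base)

  est <- fit$par[2]
  se <- fit$se
  ci <- t_ci(est, se, df)
  out <- method_result("bbcb1", "or", est = est, se = se, ci_lo = ci[1],
                       ci_hi = ci[2], df = df, converged = TRUE,
                       n_studies_used = K, loglik = -fit$value)
  beta_hat <- exp(fit$par[3])
  attr(out, "params") <- list(alpha_c = beta_hat * exp(fit$par[1]),
                              alpha_t = beta_hat * exp(fit$par[1] + fit$par[2]),
                              beta = beta_hat)
  out
}

#' Fit the common-beta beta-binomial model conditioning on the study (BBCB2)
#'
#' The study-conditional common-beta likelihood: given the total event count
#' `m_k = y_kT + y_kC` of study `k`, the treatment-arm count follows
#' `y_kT | m_k ~ BetaBin(m_k; lambda_kT, lambda_kC)` with rate parameters
#' `lambda_kT = n_kT exp(b0 + b_t)` and `lambda_kC = n_kC exp(b0)` -- the
#' two-arm reduction of the fixed-effects negative-binomial panel likelihood
#' with arm-size exposure offsets. Conditioning on the study respects the
#' randomisation; only the odds ratio is estimable. Studies with `m_k = 0`
#' drop out of the conditional likelihood.
#'
#' @inheritParams fit_bbst
#' @return A one-row tibble as in [fit_bbst()]; `n_studies_used` counts the
#'   studies with at least one event.
#' @export
fit_bbcb2 <- function(data, df_rule = c("2k-2", "k-1")) {
  data <- validate_studies(data)
  df_rule <- match.arg(df_rule)
  K <- nrow(data)
  df <- df_from_rule(df_rule, K)
  m <- data$y_t + data$y_c
  use <- m > 0
  base <- method_result("bbcb2", "or", df = df, n_studies_used = sum(use))
  if (!any(use) || bb_inestimable(data)) return(base)
  d <- data[use, ]
  m <- m[use]

  nll <- function(p) {
    if (!all(is.finite(p)) || any(abs(p) > 30)) return(PENALTY)
    lam_t <- d$n_t * exp(p[1] + p[2])
    lam_c <- d$n_c * exp(p[1])
    ll <- sum(dbetabinom(d$y_t, m, lam_t, lam_c, log = TRUE))
    if (!is.finite(ll)) return(PENALTY)
    -ll
  }
  rate <- (sum(d$y_t) + sum(d$y_c) + 0.5) / (sum(d$n_t) + sum(d$n_c) + 1)
  start <- c(b0 = log(rate), bt = 0)
  fit <- ml_fit(nll, start, target = 2)
  if (!fit$ok) return(base)

  est <- fit$par[2]
  se <- fit$se
  ci <- t_ci(est, se, df)
  out <- method_result("bbcb2", "or", est = est, se = se, ci_lo = ci[1],
                       ci_hi = ci[2], df = df, converged = TRUE,
                       n_studies_used = sum(use), loglik = -fit$value)
  attr(out, "params") <- list(b0 = unname(fit$par[1]), b_t = unname(est))
  out
}
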