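#' Marginal negative log likelihood of the logistic mixed meta-analysis models
#'
#' Computes the marginal likelihood of the two binomial mixed models used for
#' meta-analysis of 2x2 tables, with linear predictor
#' `g(pi_ki) = gamma_k + i * theta + i * eps_k`, `eps_k ~ N(0, tau2)`:
#' fixed per-study intercepts (`"glfr"`) or a normal random intercept
#' `gamma_k ~ N(gamma, sigma2_int)` (`"glrri"`). Random effects are integrated
#' out per study by adaptive Gauss-Hermite quadrature; one node (the default)
#' is the Laplace approximation. This function exists mainly as a reference
#' likelihood: [fit_glfr()] and [fit_glrri()] fit the same models through
#' \pkg{lme4}.
#'
#' @inheritParams validate_studies
#' @param params A list with elements `gamma` (length-K vector of intercepts
#'   for `"glfr"`, or a single intercept mean for `"glrri"`), `theta`, `tau2`,
#'   and for `"glrri"` also `sigma2_int`.
#' @param model `"glfr"` or `"glrri"`.
#' @param measure `"or"` (logit link) or `"rr"` (log link).
#' @param quad_points Adaptive quadrature nodes for the treatment-effect
#'   integral (1 = Laplace).
#' @return The negated marginal log likelihood.
#' @export
glmm_marginal_negloglik <- function(params, data, model = c("glfr", "glrri"),
                                    measure = c("or", "rr"), quad_points = 1) {
  data <- validate_studies(data)
  model <- match.arg(model)
  measure <- match.arg(measure)
  link <- link_for(measure)
  K <- nrow(data)
  tau2 <- params$tau2
  if (tau2 < 0) abort("tau2 must be >= 0")

  lbin <- function(y, n, eta) {
    mu <- inv_link(eta, link)
    out <- rep(-PENALTY, length(eta))
    ok <- !is.na(mu)
    out[ok] <- dbinom(y[ok], n[ok], mu[ok], log = TRUE)
    out
  }

  if (model == "glfr") {
    gamma <- params$gamma
    if (length(gamma) != K) abort("glfr needs one intercept per study")
    ll_c <- lbin(data$y_c, data$n_c, gamma)
    cond_ll <- function(e) lbin(data$y_t, data$n_t, gamma + params$theta + e)
    ll_t <- agh_marginal(cond_ll, K, tau2, quad_points)
    nl <- -(sum(ll_c) + sum(ll_t))
  } else {
    gamma <- params$gamma[1]
    sigma2_int <- params$sigma2_int
    if (sigma2_int < 0) abort("sigma2_int must be >= 0")
    # joint integral over (intercept deviation u, treatment deviation e);
    # integrate e out innermost (adaptive GH), then u (adaptive GH around the
    # profile mode found numerically)
    ll_k <- vapply(seq_len(K), function(k) {
      one <- data[k, ]
      prof <- function(u) {
        # u may be a vector: per-u marginal over e
        vapply(u, function(ui) {
          ll_c <- lbin(one$y_c, one$n_c, gamma + ui)
          cond <- function(e) lbin(one$y_t, one$n_t, gamma + ui + params$theta + e)
          ll_c + agh_marginal(cond, 1, tau2, quad_points)
        }, numeric(1))
      }
      agh_marginal(prof, 1, sigma2_int, quad_points)
    }, numeric(1))
    nl <- -sum(ll_k)
  }
  if (!is.finite(nl)) PENALTY else nl
}

glmm_long <- function(data) {
  K <- nrow(data)
  tibble::tibble(
    study = factor(rep(seq_len(K), 2)),
    arm = rep(c(0, 1), each = K),
    y = c(data$y_c, data$y_t),
    n = c(data$n_c, data$n_t)
  )
}

glmer_result <- function(method, data, measure, formula) {
  data <- validate_studies(data)
  measure <- match.arg(measure, c("or", "rr"))
  K <- nrow(data)
  base <- method_result(method, measure, n_studies_used = K)
  long <- glmm_long(data)
  if (K == 1) {
    # a single study cannot inform the random effect: tau2 is pinned at 0 and
    # the fit collapses to the saturated fixed-effect logistic model
    fit <- tryCatch(
      stats::glm(cbind(y, n - y) ~ arm, data = long,
                 family = binomial(link = link_for(measure))),
      error = function(e) NULL
    )
    if (is.null(fit)) return(base)
    est <- unname(stats::coef(fit)["arm"])
    se <- sqrt(stats::vcov(fit)["arm", "arm"])
    if (!is.finite(est) || !is.finite(se) || se <= 0) return(base)
    half <- 1.96 * se
    return(method_result(method, measure, est = est, se = se,
                         ci_lo = est - half, ci_hi = est + half, tau2_hat = 0,
                         converged = TRUE, n_studies_used = K,
                         loglik = as.numeric(stats::logLik(fit))))
  }
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::glmer(formula, data = long,
                  family = binomial(link = link_for(measure)),
                  control = lme4::glmerControl(
                    optimizer = "bobyqa",
                    optCtrl = list(maxfun = 1e5),
                    calc.derivs = FALSE
                  ))
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) return(base)
  opt_ok <- isTRUE(fit@optinfo$conv$opt == 0)
  est <- tryCatch(unname(lme4::fixef(fit)["arm"]), error = function(e) NA_real_)
  se <- tryCatch(suppressWarnings(sqrt(as.matrix(stats::vcov(fit))["arm", "arm"])),
                 error = function(e) NA_real_)
  if (!opt_ok || !is.finite(est) || !is.finite(se) || se <= 0) return(base)
  vc <- as.data.frame(lme4::VarCorr(fit))
  tau2 <- vc$vcov[vc$var1 == "arm" & !is.na(vc$var1)][1]
  half <- 1.96 * se
  out <- method_result(method, measure, est = est, se = se, ci_lo = est - half,
                       ci_hi = est + half, tau2_hat = tau2, converged = TRUE,
                       n_studies_used = K,
                       loglik = as.numeric(stats::logLik(fit)))
  attr(out, "fit") <- fit
  out
}

#' Fit the fixed-intercept, random-treatment-effect logistic mixed model (GLFR)
#'
#' One fixed intercept per study and a random treatment effect
#' `eps_k ~ N(0, tau2)`, estimated by Laplace-approximated maximum likelihood
#' (via [lme4::glmer()] with `nAGQ = 1`). The 95% CI is the Wald normal
#' interval `theta_hat +/- 1.96 * se`.
#'
#' @inheritParams fit_bbst
#' @return A one-row tibble as in [fit_bbst()]; `tau2_hat` is the estimated
#'   random-effect variance and `df` is `NA` (normal interval).
#' @export
fit_glfr <- function(data, measure = c("or", "rr")) {
  measure <- match.arg(measure)
  glmer_result("glfr", data, measure,
               cbind(y, n - y) ~ 0 + study + arm + (0 + arm | study))
}

#' Fit the random-intercept, random-treatment-effect logistic mixed model (GLRRI)
#'
#' A normal random intercept `gamma_k ~ N(gamma, sigma2_int)` and an
#' uncorrelated random treatment effect `eps_k ~ N(0, tau2)`, estimated by
#' Laplace-approximated maximum likelihood with a Wald normal CI. This model
#' fails to converge noticeably often under strong heterogeneity; such fits
#' are reported with `converged = FALSE`.
#'
#' @inheritParams fit_bbst
#' @return A one-row tibble as in [fit_bbst()].
#' @export
fit_glrri <- function(data, measure = c("or", "rr")) {
  measure <- match.arg(measure)
  glmer_result("glrri", data, measure,
               cbind(y, n - y) ~ 1 + arm + (1 | study) + (0 + arm | study))
}
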