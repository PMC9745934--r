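# nine-log-gamma expansion of the arm-level beta-binomial log likelihood,
# used as an independent oracle for dbetabinom()
lgamma_form <- function(y, n, alpha, beta) {
  lgamma(n + 1) + lgamma(y + alpha) + lgamma(n - y + beta) +
    lgamma(alpha + beta) - lgamma(y + 1) - lgamma(n - y + 1) -
    lgamma(n + alpha + beta) - lgamma(alpha) - lgamma(beta)
}

test_that("beta-binomial pmf matches closed-form examples", {
  # single trial: P(event) = mu = alpha / (alpha + beta)
  expect_equal(dbetabinom(1, 1, 2.3, 0.7, log = TRUE), log(2.3 / 3),
               tolerance = 1e-12)
  # Beta(1,1) mixing gives the discrete uniform on 0..n
  expect_equal(dbetabinom(0:5, 5, 1, 1), rep(1 / 6, 6), tolerance = 1e-12)
  # brute-force beta-function identity for n = 2, alpha = 2, beta = 3
  expect_equal(dbetabinom(0:2, 2, 2, 3), c(0.4, 0.4, 0.2), tolerance = 1e-12)
  expect_error(dbetabinom(1, 2, -1, 1), "positive")
  expect_error(dbetabinom(3, 2, 1, 1), "0 <= y <= n")
})

test_that("pmf normalises and agrees with the nine-log-gamma form", {
  set.seed(401)
  for (i in 1:25) {
    n <- sample(1:50, 1)
    alpha <- exp(runif(1, -3, 5))
    beta <- exp(runif(1, -3, 5))
    expect_equal(sum(dbetabinom(0:n, n, alpha, beta)), 1, tolerance = 1e-10)
    y <- sample(0:n, 1)
    expect_equal(dbetabinom(y, n, alpha, beta, log = TRUE),
                 lgamma_form(y, n, alpha, beta), tolerance = 1e-10)
  }
})

test_that("common-rho likelihood equals naive per-arm summation and its limits", {
  d <- toy_k2()
  set.seed(402)
  for (i in 1:10) {
    b0 <- runif(1, -3, 0); bt <- runif(1, -1, 1); rho <- runif(1, 0.01, 0.6)
    s <- (1 - rho) / rho
    mu_c <- plogis(b0); mu_t <- plogis(b0 + bt)
    oracle <- -(sum(dbetabinom(d$y_c, d$n_c, mu_c * s, (1 - mu_c) * s, log = TRUE)) +
                  sum(dbetabinom(d$y_t, d$n_t, mu_t * s, (1 - mu_t) * s, log = TRUE)))
    expect_equal(bbst_negloglik(c(b0, bt, rho), d, "or"), oracle,
                 tolerance = 1e-10)
  }
  # rho -> 0 recovers the two-group binomial likelihood
  b0 <- -1.2; bt <- 0.4
  binom_ll <- sum(dbinom(d$y_c, d$n_c, plogis(b0), log = TRUE)) +
    sum(dbinom(d$y_t, d$n_t, plogis(b0 + bt), log = TRUE))
  expect_equal(bbst_negloglik(c(b0, bt, 1e-9), d, "or"), -binom_ll,
               tolerance = 1e-4)
  # mu outside (0,1) under the log link is penalised
  expect_gt(bbst_negloglik(c(0.5, 0.2, 0.1), d, "rr"), 1e9)
})

test_that("t intervals match tabulated quantiles and degenerate cleanly", {
  expect_equal(t_ci(0, 1, 4), c(-1, 1) * qt(0.975, 4), tolerance = 1e-12)
  expect_equal(qt(0.975, 4), 2.776, tolerance = 1e-3)
  expect_equal(t_ci(0, 1, 1), c(-12.706, 12.706), tolerance = 1e-3)
  expect_equal(t_ci(1.5, 0, 3), c(1.5, 1.5))
  expect_error(t_ci(0, 1, 0.5), "df")
})

test_that("BBST maximum likelihood agrees with a dense grid-search oracle", {
  d <- tibble::tibble(study_id = 1:2, y_t = c(3, 4), n_t = c(10, 12),
                      y_c = c(1, 2), n_c = c(10, 12))
  fit <- fit_bbst(d)
  expect_true(fit$converged)
  # coarse-to-fine grid over (b0, b_t, rho)
  best <- c(NA, NA, NA); best_val <- Inf
  b0s <- seq(-3, 0, length.out = 31)
  bts <- seq(-0.5, 2.5, length.out = 31)
  rhos <- c(1e-6, 1e-4, seq(0.01, 0.5, length.out = 13))
  for (b0 in b0s) for (bt in bts) for (rho in rhos) {
    v <- bbst_negloglik(c(b0, bt, rho), d, "or")
    if (v < best_val) { best_val <- v; best <- c(b0, bt, rho) }
  }
  # refine around the coarse optimum down to a ~1e-3 grid
  for (rep in 1:3) {
    span <- 0.12 / 4^(rep - 1)
    b0s <- seq(best[1] - span, best[1] + span, length.out = 21)
    bts <- seq(best[2] - span, best[2] + span, length.out = 21)
    for (b0 in b0s) for (bt in bts) {
      v <- bbst_negloglik(c(b0, bt, best[3]), d, "or")
      if (v < best_val) { best_val <- v; best[1:2] <- c(b0, bt) }
    }
  }
  expect_lte(-fit$loglik, best_val + 1e-6)
  expect_equal(fit$est, best[2], tolerance = 2e-3)
})

test_that("BBST is symmetric, order-invariant and honours the rho constraint", {
  d <- toy_k3()
  fit <- fit_bbst(d)
  # arm swap negates the estimate
  fit_sw <- fit_bbst(swap_arms(d))
  expect_equal(fit$est, -fit_sw$est, tolerance = 1e-3)
  # study order is irrelevant
  fit_perm <- fit_bbst(d[c(3, 1, 2), ])
  expect_equal(fit$est, fit_perm$est, tolerance = 1e-8)
  expect_equal(fit$se, fit_perm$se, tolerance = 1e-6)
  # identical arms give a null estimate
  sym <- tibble::tibble(study_id = 1:2, y_t = c(4, 6), n_t = c(20, 30),
                        y_c = c(4, 6), n_c = c(20, 30))
  expect_equal(fit_bbst(sym)$est, 0, tolerance = 1e-4)
  # alpha_C + beta_C = alpha_T + beta_T by construction of the common rho
  p <- attr(fit, "params")
  expect_equal(p$alpha_c + p$beta_c, p$alpha_t + p$beta_t, tolerance = 1e-8)
  # a whole arm group without events is inestimable
  z <- tibble::tibble(study_id = 1:2, y_t = c(0, 0), n_t = c(10, 10),
                      y_c = c(2, 3), n_c = c(10, 10))
  expect_false(fit_bbst(z)$converged)
})

test_that("t interval with K-1 df is never shorter than with 2K-2 df", {
  d <- toy_k3()
  f1 <- fit_bbst(d, df_rule = "k-1")
  f2 <- fit_bbst(d, df_rule = "2k-2")
  expect_gte(f1$ci_hi - f1$ci_lo, f2$ci_hi - f2$ci_lo)
  expect_equal(f1$est, f2$est, tolerance = 1e-10)
})

test_that("BBST recovers its own generating parameters at large K and n", {
  d <- bbst_generated(seed = 403, K = 50, n_arm = 2000, b_t = -0.5, rho = 0.05)
  fit <- fit_bbst(d)
  expect_true(fit$converged)
  # with ICC 0.05 the design effect leaves ~20 effective observations per
  # arm, so the recovery tolerance is three model-based standard errors
  expect_lt(abs(fit$est - (-0.5)), 3 * fit$se)
  expect_lt(abs(attr(fit, "params")$rho - 0.05), 0.02)
})
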