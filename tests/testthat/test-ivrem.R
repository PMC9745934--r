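test_that("fixed-effect pooling matches hand computation", {
  one <- manual_effects(0.7, 0.3)
  fe <- fixed_effect(one)
  expect_equal(fe$theta_fem, 0.7)
  expect_equal(fe$se_fem, sqrt(0.3))

  two <- manual_effects(c(0, 2), c(0.5, 0.5))
  fe2 <- fixed_effect(two)
  expect_equal(fe2$theta_fem, 1)
  expect_equal(fe2$se_fem, 0.5)

  # equal variances give the arithmetic mean
  eq <- manual_effects(c(-1, 0, 4), c(2, 2, 2))
  expect_equal(fixed_effect(eq)$theta_fem, 1)
})

test_that("Cochran's Q matches hand computation and its invariances", {
  eff <- manual_effects(c(0, 2), c(0.5, 0.5))
  q <- cochran_q(eff)
  expect_equal(q$Q, 4)
  expect_equal(q$p_value, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(q$p_value, 0.0455, tolerance = 1e-3)

  ident <- manual_effects(c(1.2, 1.2, 1.2), c(0.3, 0.4, 0.5))
  qi <- cochran_q(ident)
  expect_equal(qi$Q, 0, tolerance = 1e-12)
  expect_equal(qi$p_value, 1)

  # adding a study exactly at the pooled mean leaves Q unchanged
  fe <- fixed_effect(eff)
  eff2 <- manual_effects(c(0, 2, fe$theta_fem), c(0.5, 0.5, 0.25))
  expect_equal(cochran_q(eff2)$Q, 4, tolerance = 1e-12)

  expect_error(cochran_q(manual_effects(1, 1)), "at least 2")
})

test_that("DerSimonian-Laird tau2 follows the method of moments with truncation", {
  eff <- manual_effects(c(0, 2), c(0.5, 0.5))
  # denominator: sum(w) - sum(w^2)/sum(w) = 4 - 8/4 = 2; tau2 = (4-1)/2
  expect_equal(tau2_dsl(eff), 1.5)
  expect_equal(tau2_dsl(manual_effects(c(1, 1, 1), c(1, 1, 1))), 0)
  # Q slightly below K-1 truncates exactly to zero
  near <- manual_effects(c(0, 0.1), c(1, 1))
  expect_identical(tau2_dsl(near), 0)
})

test_that("DSL fit reproduces the worked example and the tau2 = 0 limit", {
  eff <- manual_effects(c(0, 2), c(0.5, 0.5))
  fit <- fit_dsl(NULL, "or", effects = eff)
  expect_equal(fit$tau2_hat, 1.5)
  expect_equal(fit$est, 1)
  expect_equal(fit$se, 1)
  expect_equal(c(fit$ci_lo, fit$ci_hi), c(-0.96, 2.96), tolerance = 1e-12)

  hom <- manual_effects(c(0.5, 0.5, 0.5), c(0.2, 0.3, 0.6))
  fe <- fixed_effect(hom)
  fith <- fit_dsl(NULL, "or", effects = hom)
  expect_equal(fith$est, fe$theta_fem)
  expect_equal(fith$se, fe$se_fem)
})

test_that("Paule-Mandel solves the generalised Q equation", {
  eff <- manual_effects(c(0, 2), c(1, 1))
  # closed form: 2/(1+tau2) = 1 at tau2 = 1
  expect_equal(tau2_pm(eff), 1, tolerance = 1e-7)
  expect_equal(tau2_pm(manual_effects(c(1, 1), c(1, 2))), 0)

  # defining property at the root, and monotonicity of Q(tau2)
  set.seed(431)
  for (i in 1:10) {
    K <- sample(3:8, 1)
    eff <- manual_effects(rnorm(K, 0, 1.5), exp(runif(K, -2, 1)))
    t2 <- tau2_pm(eff)
    gen_q <- function(tau2) {
      w <- 1 / (eff$var + tau2)
      th <- sum(w * eff$theta_hat) / sum(w)
      sum(w * (eff$theta_hat - th)^2)
    }
    if (t2 > 0) {
      expect_lt(abs(gen_q(t2) - (K - 1)), 1e-6)
      grid <- seq(0, t2 * 2 + 1, length.out = 20)
      expect_true(all(diff(vapply(grid, gen_q, numeric(1))) < 0))
    } else {
      expect_lte(gen_q(0), K - 1)
    }
  }
})

test_that("HKSJ reproduces the worked example and the ad-hoc rule", {
  eff <- manual_effects(c(0, 2), c(1, 1))
  fit <- fit_hksj(NULL, "or", effects = eff)
  expect_equal(fit$tau2_hat, 1, tolerance = 1e-7)
  expect_equal(fit$est, 1)
  expect_equal(attr(fit, "q"), 1, tolerance = 1e-7)
  expect_equal(fit$df, 1)
  expect_equal(c(fit$ci_lo, fit$ci_hi), 1 + c(-1, 1) * qt(0.975, 1),
               tolerance = 1e-4)
  expect_equal(qt(0.975, 1), 12.706, tolerance = 1e-3)

  # homogeneous effects: q < 1, the unmodified CI undershoots DSL's, the
  # ad-hoc modification replaces q by max(1, q) = 1
  hom <- manual_effects(c(0.5, 0.52, 0.48), c(0.4, 0.4, 0.4))
  fh <- fit_hksj(NULL, "or", effects = hom)
  expect_true(attr(fh, "adhoc"))
  expect_lt(attr(fh, "q"), 1)
  dsl <- fit_dsl(NULL, "or", effects = hom)
  expect_gte(fh$ci_hi - fh$ci_lo, dsl$ci_hi - dsl$ci_lo)
  # with the rule fired, the interval is est +/- t * sqrt(max(1,q)) * sigma
  w <- 1 / hom$var
  sigma <- sqrt(1 / sum(w))
  expect_equal(fh$se, sigma, tolerance = 1e-7)
})

test_that("IVREM machinery agrees with metafor on simulated data", {
  cfg <- scenario_config(K = 4, reps = 1, hypothesis = "h1", seed = 7)
  for (seed in c(101, 202, 303)) {
    set.seed(seed)
    d <- simulate_meta(cfg)
    eff <- per_study_log_effects(d, "or")
    eff_in <- eff[eff$included, ]
    dl <- metafor::rma(yi = eff_in$theta_hat, vi = eff_in$var, method = "DL")
    ours <- fit_dsl(d, "or")
    expect_equal(ours$est, as.numeric(dl$beta), tolerance = 1e-8)
    expect_equal(ours$tau2_hat, dl$tau2, tolerance = 1e-8)
    expect_equal(ours$se, dl$se, tolerance = 1e-8)

    pm <- metafor::rma(yi = eff_in$theta_hat, vi = eff_in$var, method = "PM")
    expect_equal(tau2_pm(eff), pm$tau2, tolerance = 1e-3)

    knha <- metafor::rma(yi = eff_in$theta_hat, vi = eff_in$var,
                         method = "PM", test = "knha")
    hk <- fit_hksj(d, "or")
    if (!attr(hk, "adhoc")) {
      expect_equal(hk$est, as.numeric(knha$beta), tolerance = 1e-4)
      expect_equal(hk$ci_lo, knha$ci.lb, tolerance = 1e-3)
      expect_equal(hk$ci_hi, knha$ci.ub, tolerance = 1e-3)
    }
  }
})

test_that("pooling operations are order- and label-invariant", {
  eff <- manual_effects(c(0.3, -0.2, 1.1), c(0.2, 0.5, 0.9))
  perm <- eff[c(2, 3, 1), ]
  expect_equal(fixed_effect(eff), fixed_effect(perm))
  expect_equal(cochran_q(eff)$Q, cochran_q(perm)$Q)
  expect_equal(tau2_dsl(eff), tau2_dsl(perm))
  expect_equal(tau2_pm(eff), tau2_pm(perm))
})
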