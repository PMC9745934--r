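test_that("study-size draws honour rounding, minimum size and determinism", {
  cfg <- scenario_config(K = 2, reps = 1, seed = 1)
  set.seed(11)
  s <- draw_study_sizes(5000, cfg)
  expect_true(all(s$n >= cfg$min_total_n))
  expect_true(all(s$n_t >= 1 & s$n_c >= 1))
  expect_true(all(s$n == round(s$n)))
  expect_equal(s$n, s$n_t + s$n_c)
  # log-normal(4.615, 1.1) has mean ~185; rounding/truncation shift it little
  expect_equal(mean(s$n), exp(4.615 + 1.1^2 / 2), tolerance = 0.1)
  set.seed(11)
  expect_identical(draw_study_sizes(5000, cfg), s)
})

test_that("meta-level parameter draws follow the configured distributions", {
  cfg <- scenario_config(K = 3, reps = 1, hypothesis = "h0", seed = 1)
  set.seed(12)
  draws <- purrr::map_dfr(1:4000, ~draw_meta_parameters(cfg))
  expect_true(all(draws$theta_true == 0))
  expect_true(all(draws$tau2_true > 0))
  expect_true(all(draws$pi_c_true > 0 & draws$pi_c_true < 1))
  expect_equal(median(draws$pi_c_true), qbeta(0.5, 0.42, 1.43), tolerance = 0.02)

  cfg1 <- scenario_config(K = 3, reps = 1, hypothesis = "h1", seed = 1)
  set.seed(13)
  d1 <- purrr::map_dfr(1:500, ~draw_meta_parameters(cfg1))
  expect_true(all(d1$theta_true != 0))
})

test_that("simulated datasets are valid, truthful and reproducible", {
  cfg <- scenario_config(K = 5, reps = 1, hypothesis = "h1", seed = 3)
  set.seed(21)
  d <- simulate_meta(cfg)
  expect_silent(validate_studies(d))
  tr <- attr(d, "truth")
  expect_length(tr$delta_k, 5)
  expect_true(all(d$y_t <= d$n_t) && all(d$y_c <= d$n_c))
  set.seed(21)
  d2 <- simulate_meta(cfg)
  expect_identical(as.data.frame(d), as.data.frame(d2))
  expect_identical(attr(d, "truth"), attr(d2, "truth"))
})

test_that("double-zero studies are excluded by default and possible otherwise", {
  cfg <- scenario_config(K = 4, reps = 1, seed = 5)
  set.seed(31)
  n_dz <- 0
  for (i in 1:300) {
    z <- classify_zero_studies(simulate_meta(cfg))$zero_class
    n_dz <- n_dz + sum(z == "double_zero")
  }
  expect_equal(n_dz, 0)

  cfg_raw <- scenario_config(K = 4, reps = 1, seed = 5,
                             exclude_double_zero = FALSE)
  set.seed(31)
  n_dz_raw <- 0
  for (i in 1:300) {
    z <- classify_zero_studies(simulate_meta(cfg_raw))$zero_class
    n_dz_raw <- n_dz_raw + sum(z == "double_zero")
  }
  expect_gt(n_dz_raw, 0L)
})

test_that("heterogeneity scaling switch controls the deviation spread", {
  base <- list(K = 100, reps = 1, hypothesis = "h0", seed = 8)
  cfg_sd <- do.call(scenario_config, base)
  cfg_var <- do.call(scenario_config, c(base, heterogeneity_scale = "tau2_as_var"))
  set.seed(41); d1 <- simulate_meta(cfg_sd)
  set.seed(41); d2 <- simulate_meta(cfg_var)
  t1 <- attr(d1, "truth"); t2 <- attr(d2, "truth")
  expect_equal(t1$tau2_true, t2$tau2_true)
  # identical normal deviates underneath, scaled by tau2 vs sqrt(tau2)
  expect_equal(sd(t1$delta_k) / sd(t2$delta_k),
               t1$tau2_true / sqrt(t2$tau2_true), tolerance = 1e-8)
})

test_that("scenario sweeps account rows, stay deterministic, and decouple
           the data stream from the method subset", {
  cfg <- scenario_config(K = 3, reps = 3, hypothesis = "h0", seed = 17,
                         methods = "dsl")
  r <- run_scenario(cfg)
  expect_equal(nrow(r), 3L)
  expect_identical(run_scenario(cfg), r)

  cfg2 <- scenario_config(K = 3, reps = 3, hypothesis = "h0", seed = 17,
                          methods = c("dsl", "hksj", "coll"))
  r2 <- run_scenario(cfg2)
  expect_equal(nrow(r2), 9L)
  dsl2 <- dplyr::filter(r2, .data$method == "dsl")
  expect_equal(dsl2$est, r$est)
  expect_equal(dsl2$theta_true, r$theta_true)
  expect_equal(dsl2$pi_c_true, r$pi_c_true)

  cfg_h1 <- scenario_config(K = 3, reps = 3, hypothesis = "h1", seed = 17,
                            methods = "dsl")
  expect_true(all(run_scenario(cfg_h1)$theta_true != 0))
})

test_that("method failures surface as non-converged rows, not errors", {
  # mh on rare-event K=2 data fails in some replications
  cfg <- scenario_config(K = 2, reps = 30, hypothesis = "h0", seed = 19,
                         methods = c("mh", "dsl"))
  r <- run_scenario(cfg)
  expect_equal(nrow(r), 60L)
  expect_true(all(!is.na(r$converged)))
})

test_that("config validation catches unknown methods and measure conflicts", {
  expect_error(scenario_config(methods = "magic"), "unknown method")
  expect_error(scenario_config(measure = "rr", methods = c("bbst", "mh")),
               "odds ratio only")
  expect_error(scenario_config(K = 1), "K must be >= 2")
  rr_default <- scenario_config(measure = "rr")
  expect_false(any(c("bbcb1", "bbcb2", "mh") %in% rr_default$methods))
})
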