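#' Simulation scenario configuration
#'
#' Bundles every knob of the meta-analysis data generator and scenario runner.
#' The defaults emulate the realistic Cochrane-style data situations the
#' package's simulation study is built around: total study sizes from a
#' rounded log-normal(4.615, 1.1) with a minimum-size redraw, 1:1 binomial
#' arm allocation, control-arm risks from Beta(0.42, 1.43), heterogeneity
#' `tau2 = exp(-1.47 + 1.65 * Y)` with `Y` Fleishman-skewed (skew -0.55), and
#' under the alternative hypothesis log odds ratios `-0.59 + 0.61 * Y'` with
#' `Y'` Fleishman-transformed (skew -1.28, excess kurtosis 3.68).
#'
#' @param K Number of studies per meta-analysis (>= 2).
#' @param reps Number of replications.
#' @param hypothesis `"h0"` (true effect 0) or `"h1"` (effect drawn from the
#'   effect-size distribution).
#' @param measure `"or"` or `"rr"`.
#' @param seed Integer seed; every quantity drawn by [run_scenario()] derives
#'   from it.
#' @param df_rule t-interval degrees of freedom for the beta-binomial models.
#' @param methods Character vector of method identifiers among `"bbst"`,
#'   `"bbfr"`, `"bbcb1"`, `"bbcb2"`, `"glfr"`, `"glrri"`, `"dsl"`, `"hksj"`,
#'   `"mh"`, `"peto"`, `"coll"`. Defaults to all methods applicable to
#'   `measure` (the common-beta models and Mantel-Haenszel are OR-only).
#' @param min_total_n Minimum total study size; smaller draws are redrawn.
#' @param size_meanlog,size_sdlog Log-normal parameters of the total study
#'   size.
#' @param risk_shape1,risk_shape2 Beta parameters of the true control risk.
#' @param tau2_meanlog,tau2_sdlog,tau2_skew,tau2_exkurt Parameters of the
#'   log-scale heterogeneity distribution.
#' @param effect_mean,effect_sd,effect_skew,effect_exkurt Parameters of the
#'   log-effect distribution under the alternative.
#' @param quad_points Quadrature nodes for the random-effect beta-binomial
#'   model (1 = Laplace).
#' @param exclude_double_zero Redraw a study's event-count pair while both
#'   arms have zero events (default `TRUE`). The realistic-scenario design
#'   this generator emulates produced single-zero but no double-zero studies,
#'   which cannot happen under the untruncated distributions; the truncation
#'   reproduces that data situation. Set to `FALSE` for the untruncated
#'   generator.
#' @param heterogeneity_scale How the drawn heterogeneity value `tau2` scales
#'   the per-study deviations `delta_k` of the linear predictor.
#'   `"tau2_as_sd"` (default) draws `delta_k ~ N(0, sd = tau2)`, the reading
#'   consistent with the realised summaries of the simulation design this
#'   generator reproduces (a `RAND("NORMAL", 0, tau2)` call, whose second
#'   argument is a standard deviation); `"tau2_as_var"` draws
#'   `delta_k ~ N(0, sd = sqrt(tau2))`, the conventional random-effects-model
#'   reading in which `tau2` is the between-study variance. See the methods
#'   vignette for the evidence behind the default.
#' @return A list of class `"scenario_config"` (Fleishman coefficients
#'   pre-solved).
#' @export
scenario_config <- function(K = 3, reps = 1000,
                            hypothesis = c("h0", "h1"),
                            measure = c("or", "rr"),
                            seed = 1L,
                            df_rule = c("2k-2", "k-1"),
                            methods = NULL,
                            min_total_n = 8,
                            size_meanlog = 4.615, size_sdlog = 1.1,
                            risk_shape1 = 0.42, risk_shape2 = 1.43,
                            tau2_meanlog = -1.47, tau2_sdlog = 1.65,
                            tau2_skew = -0.55, tau2_exkurt = 0,
                            effect_mean = -0.59, effect_sd = 0.61,
                            effect_skew = -1.28, effect_exkurt = 3.68,
                            quad_points = 1,
                            exclude_double_zero = TRUE,
                            heterogeneity_scale = c("tau2_as_sd", "tau2_as_var")) {
  hypothesis <- match.arg(hypothesis)
  measure <- match.arg(measure)
  df_rule <- match.arg(df_rule)
  heterogeneity_scale <- match.arg(heterogeneity_scale)
  if (K < 2) abort("K must be >= 2")
  if (reps < 1) abort("reps must be >= 1")
  all_methods <- c("bbst", "bbfr", "bbcb1", "bbcb2", "glfr", "glrri",
                   "dsl", "hksj", "mh", "peto", "coll")
  or_only <- c("bbcb1", "bbcb2", "mh")
  if (is.null(methods)) {
    methods <- if (measure == "or") all_methods else setdiff(all_methods, or_only)
  }
  bad <- setdiff(methods, all_methods)
  if (length(bad) > 0) abort(paste0("unknown method(s): ", paste(bad, collapse = ", ")))
  if (measure == "rr" && any(methods %in% or_only)) {
    abort(paste0(paste(intersect(methods, or_only), collapse = ", "),
                 " estimate the odds ratio only"))
  }
  structure(list(
    K = as.integer(K), reps = as.integer(reps), hypothesis = hypothesis,
    measure = measure, seed = as.integer(seed), df_rule = df_rule,
    methods = methods, min_total_n = min_total_n,
    size_meanlog = size_meanlog, size_sdlog = size_sdlog,
    risk_shape1 = risk_shape1, risk_shape2 = risk_shape2,
    tau2_meanlog = tau2_meanlog, tau2_sdlog = tau2_sdlog,
    tau2_skew = tau2_skew, tau2_exkurt = tau2_exkurt,
    exclude_double_zero = isTRUE(exclude_double_zero),
    heterogeneity_scale = heterogeneity_scale,
    effect_mean = effect_mean, effect_sd = effect_sd,
    effect_skew = effect_skew, effect_exkurt = effect_exkurt,
    quad_points = quad_points,
    tau2_coeffs = fleishman_coeffs(tau2_skew, tau2_exkurt),
    effect_coeffs = fleishman_coeffs(effect_skew, effect_exkurt)
  ), class = "scenario_config")
}

#' Draw total and per-arm study sizes
#'
#' Total sizes are rounded log-normal draws, redrawn while below
#' `min_total_n`; treatment-arm sizes are Binomial(n, 0.5) (1:1
#' randomisation), redrawn while either arm would be empty. Uses the current
#' RNG state.
#'
#' @param n_studies Number of studies to draw.
#' @param config A [scenario_config()].
#' @return A tibble with columns `n`, `n_t`, `n_c`.
#' @export
draw_study_sizes <- function(n_studies, config = scenario_config()) {
  n <- rep(NA_real_, n_studies)
  todo <- rep(TRUE, n_studies)
  for (i in 1:1000) {
    if (!any(todo)) break
    n[todo] <- round(rlnorm(sum(todo), config$size_meanlog, config$size_sdlog))
    todo <- n < config$min_total_n
  }
  if (any(todo)) abort("study-size redraw limit exceeded")
  n_t <- rep(NA_real_, n_studies)
  todo <- rep(TRUE, n_studies)
  for (i in 1:1000) {
    if (!any(todo)) break
    n_t[todo] <- rbinom(sum(todo), n[todo], 0.5)
    todo <- n_t == 0 | n_t == n
  }
  if (any(todo)) abort("arm-size redraw limit exceeded")
  tibble::tibble(n = n, n_t = n_t, n_c = n - n_t)
}

#' Draw the meta-analysis-level true parameters
#'
#' Control risk from the beta distribution, heterogeneity as the exponential
#' of a Fleishman-skewed variate, and the true log effect (0 under the null).
#' Uses the current RNG state.
#'
#' @param config A [scenario_config()].
#' @return A one-row tibble with `pi_c_true`, `tau2_true`, `theta_true`.
#' @export
draw_meta_parameters <- function(config = scenario_config()) {
  pi_c <- rbeta(1, config$risk_shape1, config$risk_shape2)
  tau2 <- exp(rfleishman(1, config$tau2_meanlog, config$tau2_sdlog,
                         coeffs = config$tau2_coeffs))
  theta <- if (config$hypothesis == "h0") 0 else {
    rfleishman(1, config$effect_mean, config$effect_sd,
               coeffs = config$effect_coeffs)
  }
  tibble::tibble(pi_c_true = pi_c, tau2_true = tau2, theta_true = theta)
}

#' Simulate one meta-analysis dataset
#'
#' Draws the meta-analysis-level truth, then for each study: arm sizes,
#' control events `y_C ~ Bin(n_C, pi_C)`, a study deviation
#' `delta_k ~ N(0, tau2)`, the treatment risk
#' `pi_kT = expit(logit(pi_C) + theta + delta_k)` (odds-ratio measure) or
#' `min(exp(log(pi_C) + theta + delta_k), 1 - 1e-12)` (relative-risk
#' measure), and treatment events `y_T ~ Bin(n_T, pi_kT)`. Uses the current
#' RNG state.
#'
#' @param config A [scenario_config()].
#' @return A validated study tibble with the generating truth attached as the
#'   `"truth"` attribute (a list with `measure`, `hypothesis`, `theta_true`,
#'   `pi_c_true`, `tau2_true`, `delta_k`).
#' @export
simulate_meta <- function(config = scenario_config()) {
  truth <- draw_meta_parameters(config)
  sizes <- draw_study_sizes(config$K, config)
  delta_sd <- if (identical(config$heterogeneity_scale, "tau2_as_var")) {
    sqrt(truth$tau2_true)
  } else {
    truth$tau2_true
  }
  delta <- rnorm(config$K, 0, delta_sd)
  eta <- if (config$measure == "or") {
    qlogis(truth$pi_c_true) + truth$theta_true + delta
  } else {
    log(truth$pi_c_true) + truth$theta_true + delta
  }
  pi_t <- if (config$measure == "or") plogis(eta) else pmin(exp(eta), 1 - 1e-12)
  y_c <- rbinom(config$K, sizes$n_c, truth$pi_c_true)
  y_t <- rbinom(config$K, sizes$n_t, pi_t)
  if (config$exclude_double_zero) {
    todo <- y_c == 0 & y_t == 0
    for (i in 1:1000) {
      if (!any(todo)) break
      y_c[todo] <- rbinom(sum(todo), sizes$n_c[todo], truth$pi_c_true)
      y_t[todo] <- rbinom(sum(todo), sizes$n_t[todo], pi_t[todo])
      todo <- y_c == 0 & y_t == 0
    }
    if (any(todo)) {
      # event probabilities so small that rejection cannot finish: in that
      # limit the conditional law given >= 1 event is a single event in one
      # arm, chosen proportionally to the arm's expected count
      ec <- sizes$n_c[todo] * truth$pi_c_true
      et <- sizes$n_t[todo] * pi_t[todo]
      tot <- ec + et
      p_ctrl <- ifelse(tot > 0, ec / tot,
                       sizes$n_c[todo] / (sizes$n_c[todo] + sizes$n_t[todo]))
      ctrl <- rbinom(sum(todo), 1, p_ctrl) == 1
      y_c[todo][ctrl] <- 1
      y_t[todo][!ctrl] <- 1
    }
  }
  data <- tibble::tibble(
    study_id = seq_len(config$K),
    y_t = y_t, n_t = sizes$n_t, y_c = y_c, n_c = sizes$n_c
  )
  attr(data, "truth") <- list(
    measure = config$measure, hypothesis = config$hypothesis,
    theta_true = truth$theta_true, pi_c_true = truth$pi_c_true,
    tau2_true = truth$tau2_true, delta_k = delta
  )
  data
}

fit_method <- function(method, data, measure, df_rule, quad_points = 1) {
  switch(method,
    bbst = fit_bbst(data, measure, df_rule),
    bbfr = fit_bbfr(data, measure, df_rule, quad_points),
    bbcb1 = fit_bbcb1(data, df_rule),
    bbcb2 = fit_bbcb2(data, df_rule),
    glfr = fit_glfr(data, measure),
    glrri = fit_glrri(data, measure),
    dsl = fit_dsl(data, measure),
    hksj = fit_hksj(data, measure),
    mh = fit_mh(data),
    peto = fit_peto(data),
    coll = fit_collapsed(data, measure),
    abort(paste0("unknown method: ", method))
  )
}

#' Run a simulation scenario
#'
#' Simulates `reps` meta-analyses from the configured generator and fits every
#' requested method to each, producing one row per (replication, method).
#' All datasets are generated before any fitting, from per-replication seeds
#' spawned deterministically from `config$seed`, so the data stream is
#' unaffected by which methods are requested. Method failures are captured as
#' non-converged rows and never abort the sweep.
#'
#' @param config A [scenario_config()].
#' @return A tibble with columns `rep`, `method`, `measure`, `est`, `se`,
#'   `ci_lo`, `ci_hi`, `df`, `tau2_hat`, `converged`, `n_studies_used`,
#'   `q_pvalue` (Cochran's Q p-value of the dataset), and the generating
#'   truth `theta_true`, `pi_c_true`, `tau2_true`.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  rep_seeds <- sample.int(2147483646L, config$reps)
  datasets <- lapply(rep_seeds, function(s) {
    set.seed(s)
    simulate_meta(config)
  })
  purrr::map_dfr(seq_len(config$reps), function(r) {
    data <- datasets[[r]]
    truth <- attr(data, "truth")
    qp <- tryCatch(
      cochran_q(per_study_log_effects(data, config$measure))$p_value,
      error = function(e) NA_real_
    )
    rows <- purrr::map_dfr(config$methods, function(m) {
      res <- tryCatch(
        fit_method(m, data, config$measure, config$df_rule, config$quad_points),
        error = function(e) method_result(m, config$measure,
                                          n_studies_used = config$K)
      )
      res$loglik <- NULL
      res
    })
    rows <- dplyr::mutate(rows,
      rep = r, q_pvalue = qp, theta_true = truth$theta_true,
      pi_c_true = truth$pi_c_true, tau2_true = truth$tau2_true
    )
    dplyr::relocate(rows, "rep", "method", "measure")
  })
}
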