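q13 <- function(x, na.rm = FALSE) {
  # type-7 linear interpolation, pinned so summaries are reproducible
  quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE, na.rm = na.rm)
}

#' Summarise scenario results into performance measures
#'
#' Computes, per method and over converged replications only: the converged
#' count `r_converged`; quartiles of the bias `theta_hat - theta_true`;
#' under the alternative also quartiles of the percentage bias
#' `100 (theta_hat - theta_true) / theta_true` (undefined, and skipped, when
#' the true effect is numerically zero); the coverage (percent of 95% CIs
#' containing the true effect); quartiles of the CI length; and under the
#' alternative the power (percent of CIs excluding 0). All on the log-effect
#' scale.
#'
#' @param results A replication-level tibble from [run_scenario()].
#' @param hypothesis `"h0"` or `"h1"`; by default inferred from `theta_true`
#'   (all zero means the null).
#' @return A tibble with one row per method. Methods that never converged are
#'   retained with `r_converged = 0` and `NA` statistics.
#' @export
summarize_performance <- function(results, hypothesis = NULL) {
  if (is.null(hypothesis)) {
    hypothesis <- if (all(results$theta_true == 0)) "h0" else "h1"
  }
  hypothesis <- match.arg(hypothesis, c("h0", "h1"))

  reps_total <- dplyr::n_distinct(results$rep)
  work <- results |>
    dplyr::filter(.data$converged) |>
    dplyr::mutate(
      bias = .data$est - .data$theta_true,
      pct_bias = dplyr::if_else(abs(.data$theta_true) > 1e-12,
                                100 * .data$bias / .data$theta_true, NA_real_),
      ci_len = .data$ci_hi - .data$ci_lo,
      covered = .data$ci_lo <= .data$theta_true & .data$theta_true <= .data$ci_hi,
      rejected = .data$ci_lo > 0 | .data$ci_hi < 0
    )
  out <- work |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      r_converged = dplyr::n(),
      bias_q1 = q13(.data$bias)[1],
      bias_med = q13(.data$bias)[2],
      bias_q3 = q13(.data$bias)[3],
      pct_bias_q1 = q13(.data$pct_bias, na.rm = TRUE)[1],
      pct_bias_med = q13(.data$pct_bias, na.rm = TRUE)[2],
      pct_bias_q3 = q13(.data$pct_bias, na.rm = TRUE)[3],
      coverage = 100 * mean(.data$covered),
      ci_len_q1 = q13(.data$ci_len)[1],
      ci_len_med = q13(.data$ci_len)[2],
      ci_len_q3 = q13(.data$ci_len)[3],
      power = 100 * mean(.data$rejected),
      .groups = "drop"
    )
  all_methods <- unique(results$method)
  missing <- setdiff(all_methods, out$method)
  if (length(missing) > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(method = missing, r_converged = 0L))
  }
  if (hypothesis == "h0") {
    out <- dplyr::select(out, -dplyr::starts_with("pct_bias"), -"power")
  }
  out |>
    dplyr::mutate(reps = reps_total, hypothesis = hypothesis) |>
    dplyr::arrange(match(.data$method, all_methods))
}

#' Restrict results to replications without significant heterogeneity
#'
#' Keeps the replications whose Cochran's Q test p-value exceeds `alpha`,
#' mirroring the practice of not pooling when heterogeneity is statistically
#' significant. Downstream [summarize_performance()] calls run unchanged on
#' the filtered table.
#'
#' @inheritParams summarize_performance
#' @param alpha Significance level of the Q test (default 0.05).
#' @return The filtered results tibble.
#' @export
sensitivity_subset <- function(results, alpha = 0.05) {
  if (!"q_pvalue" %in% names(results)) abort("results lack a q_pvalue column")
  out <- dplyr::filter(results, !is.na(.data$q_pvalue), .data$q_pvalue > alpha)
  if (nrow(out) == 0) warn("sensitivity subset is empty")
  out
}
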