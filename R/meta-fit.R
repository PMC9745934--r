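#' Fit several meta-analysis methods to one dataset
#'
#' Runs any subset of the eleven pooling methods on a dataset of per-study
#' 2x2 tables and collects their results in one object. Methods that cannot
#' be estimated on the data (e.g. every retained study dropped, or an
#' optimizer failure) appear as non-converged rows rather than errors.
#'
#' @inheritParams fit_bbst
#' @param methods Character vector of method identifiers (see
#'   [scenario_config()] for the list); defaults to all methods applicable to
#'   `measure`.
#' @param quad_points Quadrature nodes for the `bbfr` model.
#' @return An object of class `"meta_fit"`. Use [tidy()] for the per-method
#'   results table, [glance()] for dataset-level summaries, and [autoplot()]
#'   for a forest-style comparison of the methods.
#' @examples
#' studies <- tibble::tibble(
#'   study_id = 1:3, y_t = c(2, 5, 1), n_t = c(40, 60, 30),
#'   y_c = c(5, 9, 3), n_c = c(38, 62, 31)
#' )
#' fit <- meta_fit(studies, methods = c("bbst", "dsl", "hksj"))
#' tidy(fit)
#' @export
meta_fit <- function(data, measure = c("or", "rr"), methods = NULL,
                     df_rule = c("2k-2", "k-1"), quad_points = 1) {
  data <- validate_studies(data)
  measure <- match.arg(measure)
  df_rule <- match.arg(df_rule)
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
  results <- purrr::map_dfr(methods, function(m) {
    tryCatch(fit_method(m, data, measure, df_rule, quad_points),
             error = function(e) method_result(m, measure,
                                               n_studies_used = nrow(data)))
  })
  structure(
    list(results = results, data = data, measure = measure, df_rule = df_rule),
    class = "meta_fit"
  )
}

#' @export
print.meta_fit <- function(x, ...) {
  cat("Meta-analysis of", nrow(x$data), "studies (",
      toupper(x$measure), ", log scale )\n\n", sep = " ")
  print(tidy(x))
  invisible(x)
}

#' Tidy method results of a meta-analysis fit
#'
#' @param x A [meta_fit()] object.
#' @param exponentiate Append `or`/`rr`-scale columns (`exp(est)` and CI).
#' @param ... Unused.
#' @return A tibble with one row per method.
#' @export
tidy.meta_fit <- function(x, exponentiate = FALSE, ...) {
  out <- x$results
  if (exponentiate) {
    ratio_col <- x$measure
    out[[ratio_col]] <- exp(out$est)
    out$ci_lo_exp <- exp(out$ci_lo)
    out$ci_hi_exp <- exp(out$ci_hi)
  }
  out
}

#' Dataset-level summary of a meta-analysis fit
#'
#' @param x A [meta_fit()] object.
#' @param ... Unused.
#' @return A one-row tibble with the number of studies, total sample size,
#'   single/double-zero counts, and Cochran's Q with its p-value (NA when
#'   fewer than two studies contribute an estimate).
#' @export
glance.meta_fit <- function(x, ...) {
  zc <- classify_zero_studies(x$data)$zero_class
  q <- tryCatch(cochran_q(per_study_log_effects(x$data, x$measure)),
                error = function(e) tibble::tibble(Q = NA_real_, p_value = NA_real_))
  tibble::tibble(
    k = nrow(x$data),
    total_n = sum(x$data$n_t + x$data$n_c),
    n_single_zero = sum(zc == "single_zero"),
    n_double_zero = sum(zc == "double_zero"),
    q_stat = q$Q,
    q_pvalue = q$p_value
  )
}

#' Forest-style comparison plot of pooled estimates
#'
#' Point estimates and 95% confidence intervals of every converged method,
#' on the log-effect scale.
#'
#' @param object A [meta_fit()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meta_fit <- function(object, ...) {
  res <- dplyr::filter(object$results, .data$converged)
  lab <- if (object$measure == "or") "log odds ratio" else "log relative risk"
  ggplot2::ggplot(res, ggplot2::aes(x = .data$est,
                                    y = factor(.data$method,
                                               levels = rev(unique(.data$method))))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = paste0("Pooled ", lab, " (95% CI)"), y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a performance measure across methods
#'
#' Companion plot for [summarize_performance()] output, e.g. coverage per
#' method with the nominal 95% level marked.
#'
#' @param summary A tibble from [summarize_performance()] (optionally row-bound
#'   over scenarios with an extra grouping column such as `K`).
#' @param metric One of `"coverage"`, `"power"`, `"ci_len_med"`, `"bias_med"`.
#' @return A ggplot object.
#' @export
plot_performance <- function(summary,
                             metric = c("coverage", "power", "ci_len_med",
                                        "bias_med")) {
  metric <- match.arg(metric)
  if (!metric %in% names(summary)) {
    abort(paste0("summary has no '", metric, "' column"))
  }
  p <- ggplot2::ggplot(summary, ggplot2::aes(x = .data$method,
                                             y = .data[[metric]])) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
  if (metric == "coverage") {
    p <- p + ggplot2::geom_hline(yintercept = 95, linetype = 2)
  }
  p
}
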