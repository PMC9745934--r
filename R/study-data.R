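#' Validate a meta-analysis dataset of 2x2 tables
#'
#' A meta-analysis dataset is an ordinary data frame with one row per study
#' and columns `study_id`, `y_t`, `n_t` (events and sample size in the
#' treatment arm) and `y_c`, `n_c` (control arm). `validate_studies()` checks
#' the structural invariants -- counts are non-negative integers, events never
#' exceed the arm size, both arms are non-empty, study labels are unique --
#' and returns the data as a tibble, so it can open a pipe of downstream
#' fitting calls.
#'
#' @param data A data frame with columns `study_id`, `y_t`, `n_t`, `y_c`, `n_c`.
#' @return The validated dataset as a tibble (one row per study).
#' @examples
#' studies <- tibble::tibble(
#'   study_id = c("a", "b"), y_t = c(3, 1), n_t = c(10, 12),
#'   y_c = c(5, 2), n_c = c(10, 12)
#' )
#' validate_studies(studies)
#' @export
validate_studies <- function(data) {
  cols <- c("study_id", "y_t", "n_t", "y_c", "n_c")
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)[, cols]
  if (nrow(data) < 1) abort("K must be >= 1: dataset contains no studies")
  for (col in c("y_t", "n_t", "y_c", "n_c")) {
    x <- data[[col]]
    if (!is.numeric(x) || anyNA(x) || any(x != round(x))) {
      abort(paste0("column '", col, "' must contain non-missing integers"))
    }
  }
  bad <- function(cond, msg) {
    i <- which(cond)
    if (length(i) > 0) abort(paste0(msg, " (study ", data$study_id[i[1]], ", row ", i[1], ")"))
  }
  bad(data$n_t < 1 | data$n_c < 1, "empty study arm: arm sizes must be >= 1")
  bad(data$y_t < 0 | data$y_c < 0, "negative event count")
  bad(data$y_t > data$n_t | data$y_c > data$n_c, "events exceed arm size")
  if (anyDuplicated(data$study_id)) abort("study_id values must be unique")
  data
}

#' Classify studies by zero-event pattern
#'
#' Labels each study as `none`, `single_zero` (no events in exactly one arm)
#' or `double_zero` (no events in either arm). Single- and double-zero studies
#' are the data situations where the different pooling methods diverge: the
#' beta-binomial and mixed models keep them, inverse-variance methods correct
#' or drop them, and Mantel-Haenszel drops them outright.
#'
#' @inheritParams validate_studies
#' @return The dataset with a `zero_class` factor column appended.
#' @export
classify_zero_studies <- function(data) {
  data <- validate_studies(data)
  n_zero_arms <- (data$y_t == 0) + (data$y_c == 0)
  dplyr::mutate(data, zero_class = factor(
    c("none", "single_zero", "double_zero")[n_zero_arms + 1],
    levels = c("none", "single_zero", "double_zero")
  ))
}

#' Per-study log odds ratios or log relative risks
#'
#' Computes study-level effect estimates on the log scale together with their
#' delta-method (Woolf-type) variances, applying the zero-cell policy used by
#' the inverse-variance machinery: under `policy = "ivrem"`, studies with no
#' events in both arms are excluded, and 0.5 is added to all four cells of any
#' remaining study whose 2x2 table contains a zero cell (this covers both
#' zero-event and all-event arms, either of which leaves the variance
#' undefined). Under `policy = "none"` no correction is applied and any study
#' with a zero cell is excluded (the Mantel-Haenszel convention).
#'
#' @inheritParams validate_studies
#' @param measure `"or"` for the log odds ratio, `"rr"` for the log relative
#'   risk.
#' @param policy Zero-cell policy, `"ivrem"` (default) or `"none"`.
#' @return A tibble with columns `study_id`, `theta_hat`, `var`, `included`,
#'   `corrected`. Excluded studies carry `NA` estimates and `included = FALSE`.
#' @examples
#' studies <- tibble::tibble(study_id = 1, y_t = 10, n_t = 20, y_c = 5, n_c = 20)
#' per_study_log_effects(studies, "or") # log 3, variance 1/10+1/10+1/5+1/15
#' @export
per_study_log_effects <- function(data, measure = c("or", "rr"),
                                  policy = c("ivrem", "none")) {
  data <- validate_studies(data)
  measure <- match.arg(measure)
  policy <- match.arg(policy)

  a <- data$y_t; b <- data$n_t - data$y_t
  c_ <- data$y_c; d <- data$n_c - data$y_c
  zero_cell <- a == 0 | b == 0 | c_ == 0 | d == 0
  double_zero <- data$y_t == 0 & data$y_c == 0

  if (policy == "ivrem") {
    included <- !double_zero
    corrected <- included & zero_cell
    cc <- ifelse(corrected, 0.5, 0)
  } else {
    included <- !zero_cell
    corrected <- rep(FALSE, length(a))
    cc <- rep(0, length(a))
  }
  a <- a + cc; b <- b + cc; c_ <- c_ + cc; d <- d + cc
  n_t <- a + b; n_c <- c_ + d

  if (measure == "or") {
    theta <- log(a * d / (b * c_))
    v <- 1 / a + 1 / b + 1 / c_ + 1 / d
  } else {
    theta <- log((a / n_t) / (c_ / n_c))
    v <- 1 / a - 1 / n_t + 1 / c_ - 1 / n_c
  }
  theta[!included] <- NA_real_
  v[!included] <- NA_real_
  if (!any(included)) abort("no estimable studies after applying the zero-cell policy")

  tibble::tibble(
    study_id = data$study_id, theta_hat = theta, var = v,
    included = included, corrected = corrected
  )
}

#' Read a meta-analysis dataset from CSV
#'
#' Expects the header `study_id,y_t,n_t,y_c,n_c`, one row per study.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble of studies.
#' @export
read_studies <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  validate_studies(data)
}

# One-row tibble shared by every fitting method. Non-converged fits carry
# converged = FALSE and NA estimates/intervals.
method_result <- function(method, measure, est = NA_real_, se = NA_real_,
                          ci_lo = NA_real_, ci_hi = NA_real_, df = NA_real_,
                          tau2_hat = NA_real_, converged = FALSE,
                          n_studies_used = NA_integer_, loglik = NA_real_) {
  if (!converged) {
    se <- NA_real_; ci_lo <- NA_real_; ci_hi <- NA_real_
  }
  tibble::tibble(
    method = method, measure = measure, est = unname(est), se = unname(se),
    ci_lo = unname(ci_lo), ci_hi = unname(ci_hi), df = unname(df),
    tau2_hat = unname(tau2_hat), converged = converged,
    n_studies_used = as.integer(n_studies_used), loglik = unname(loglik)
  )
}
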