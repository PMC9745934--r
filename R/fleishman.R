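#' Fleishman power-method coefficients
#'
#' Solves the three-moment system of Fleishman's power method for the cubic
#' `Y = a + b Z + c Z^2 + d Z^3` of a standard normal `Z`, such that `Y` has
#' mean 0, variance 1, and the requested skewness and excess kurtosis
#' (`a = -c` enforces the zero mean). The target pair must lie inside the
#' feasible region `excess_kurt >= -1.2264489 + 1.6410373 * skew^2`. A Newton
#' iteration from the near-normal start `(b, c, d) = (1, 0, 0)` (with random
#' restarts as fallback) selects the standard monotone solution.
#'
#' @param skew Target skewness.
#' @param excess_kurt Target excess kurtosis.
#' @param tol Residual tolerance of the moment system.
#' @return A list with components `a`, `b`, `c`, `d`.
#' @examples
#' fleishman_coeffs(0, 0)            # identity: a = c = d = 0, b = 1
#' fleishman_coeffs(1.75, 3.75)      # classic tabulated case
#' @export
fleishman_coeffs <- function(skew, excess_kurt = 0, tol = 1e-10) {
  # approximate lower boundary of the feasible region; cases slightly below
  # it can still admit a solution (the classic (1.75, 3.75) pair does), so
  # the solver is always attempted and the boundary is reported on failure
  boundary <- -1.2264489 + 1.6410373 * skew^2
  infeasible_msg <- sprintf(
    paste0("infeasible Fleishman targets: skew %.4g needs excess kurtosis ",
           ">= about %.4f (got %.4g)"),
    skew, boundary, excess_kurt
  )
  if (skew == 0 && excess_kurt == 0) {
    return(list(a = 0, b = 1, c = 0, d = 0))
  }
  # sign symmetry: solve for |skew|, then negate a and c
  s <- abs(skew)
  sys <- function(p) {
    b <- p[1]; cc <- p[2]; d <- p[3]
    c(b^2 + 6 * b * d + 2 * cc^2 + 15 * d^2 - 1,
      2 * cc * (b^2 + 24 * b * d + 105 * d^2 + 2) - s,
      24 * (b * d + cc^2 * (1 + b^2 + 28 * b * d) +
              d^2 * (12 + 48 * b * d + 141 * cc^2 + 225 * d^2)) - excess_kurt)
  }
  newton <- function(p) {
    for (i in 1:200) {
      f <- sys(p)
      if (max(abs(f)) < tol) return(p)
      J <- pracma::jacobian(sys, p)
      step <- tryCatch(solve(J, f), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) return(NULL)
      p <- p - step
    }
    if (max(abs(sys(p))) < tol) p else NULL
  }
  p <- newton(c(1, 0, 0))
  if (!is.null(p) && p[1] <= 0) p <- NULL # standard root has b > 0
  if (is.null(p)) {
    for (try in 1:20) {
      start <- c(1, 0.2, 0) + c(0.3, 0.2, 0.1) * sin(try * c(1, 2, 3))
      p <- newton(start)
      if (!is.null(p) && p[1] > 0) break
      p <- NULL
    }
  }
  if (is.null(p)) {
    if (excess_kurt < boundary) abort(infeasible_msg)
    abort("Fleishman solver failed to converge")
  }
  cc <- p[2] * sign(skew)
  list(a = -cc, b = p[1], c = cc, d = p[3])
}

fleishman_transform <- function(z, mean, sd, coeffs) {
  mean + sd * (coeffs$a + coeffs$b * z + coeffs$c * z^2 + coeffs$d * z^3)
}

#' Sample Fleishman-transformed non-normal variates
#'
#' Draws `mean + sd * (a + b Z + c Z^2 + d Z^3)` for iid standard normal `Z`,
#' where the cubic coefficients match the requested skewness and excess
#' kurtosis. Exponentiate the result when a log-scale quantity (e.g. a
#' heterogeneity variance or an odds ratio) is wanted.
#'
#' @param n Number of draws.
#' @param mean,sd Location and scale applied after the unit-variance cubic.
#' @param skew,excess_kurt Shape targets of the standardised distribution.
#' @param coeffs Optionally, precomputed coefficients from
#'   [fleishman_coeffs()] (skipping the solve).
#' @return A numeric vector of length `n`.
#' @export
rfleishman <- function(n, mean = 0, sd = 1, skew = 0, excess_kurt = 0,
                       coeffs = NULL) {
  if (sd <= 0) abort("sd must be positive")
  if (is.null(coeffs)) coeffs <- fleishman_coeffs(skew, excess_kurt)
  fleishman_transform(rnorm(n), mean, sd, coeffs)
}
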