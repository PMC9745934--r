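# Small deterministic datasets shared across test files.

toy_k1 <- function() {
  tibble::tibble(study_id = 1L, y_t = 10, n_t = 20, y_c = 5, n_c = 20)
}

toy_k2 <- function() {
  tibble::tibble(study_id = 1:2, y_t = c(3, 4), n_t = c(10, 12),
                 y_c = c(1, 2), n_c = c(10, 12))
}

toy_k3 <- function() {
  tibble::tibble(study_id = 1:3, y_t = c(2, 5, 1), n_t = c(40, 60, 30),
                 y_c = c(5, 9, 3), n_c = c(38, 62, 31))
}

# effect tibble in the shape produced by per_study_log_effects()
manual_effects <- function(theta, var) {
  tibble::tibble(study_id = seq_along(theta), theta_hat = theta, var = var,
                 included = TRUE, corrected = FALSE)
}

swap_arms <- function(data) {
  dplyr::rename(data, y_t = "y_c", n_t = "n_c", y_c = "y_t", n_c = "n_t")
}

# beta-binomial meta-analysis data generated from the common-rho model itself
bbst_generated <- function(seed, K = 50, n_arm = 2000, b0 = -2, b_t = -0.5,
                           rho = 0.05) {
  set.seed(seed)
  s <- (1 - rho) / rho
  mu_c <- plogis(b0); mu_t <- plogis(b0 + b_t)
  pi_c <- rbeta(K, mu_c * s, (1 - mu_c) * s)
  pi_t <- rbeta(K, mu_t * s, (1 - mu_t) * s)
  tibble::tibble(
    study_id = seq_len(K),
    y_t = rbinom(K, n_arm, pi_t), n_t = n_arm,
    y_c = rbinom(K, n_arm, pi_c), n_c = n_arm
  )
}
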