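# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths.

# From-scratch cyclic coordinate descent for the elastic net objective that
# glmnet actually solves with intercept = FALSE, standardize = FALSE:
#   1/(2n) ||y - X b||^2 + lambda * (alpha |b|_1 + (1-alpha)/(2 s_y) ||b||^2)
# where s_y = sqrt(mean(y^2)). The 1/s_y factor on the quadratic term comes
# from glmnet's internal response scaling, which rescales the L1 but not the
# L2 penalty; it is verified here against closed forms rather than assumed.
oracle_cd_enet <- function(X, y, lambda, alpha, max_iter = 50000,
                           tol = 1e-14) {
  n <- nrow(X)
  J <- ncol(X)
  s_y <- sqrt(mean(y^2))
  b <- numeric(J)
  xx <- colSums(X^2) / n
  soft <- function(z, t) sign(z) * max(abs(z) - t, 0)
  for (it in seq_len(max_iter)) {
    b_old <- b
    for (j in seq_len(J)) {
      r <- y - X %*% b + X[, j] * b[j]
      z <- sum(X[, j] * r) / n
      b[j] <- soft(z, lambda * alpha) /
        (xx[j] + lambda * (1 - alpha) / s_y)
    }
    if (max(abs(b - b_old)) < tol) break
  }
  b
}

# Monte-Carlo tail probability of sum_j lambda_j * chisq_1.
oracle_chisq_mix_mc <- function(q, lambda, n_draws = 1e6) {
  m <- length(lambda)
  draws <- colSums(matrix(lambda * stats::rnorm(m * n_draws)^2, nrow = m))
  p_hat <- mean(draws > q)
  list(p = p_hat, se = sqrt(p_hat * (1 - p_hat) / n_draws))
}

# Small block-diagonal LD matrix with constant within-block correlation.
oracle_block_ld <- function(J, block, rho) {
  Sigma <- matrix(0, J, J)
  for (b in seq_len(J / block)) {
    idx <- ((b - 1) * block + 1):(b * block)
    Sigma[idx, idx] <- rho
  }
  diag(Sigma) <- 1
  Sigma
}

# Summary-statistics tibble on one chromosome with evenly spaced positions.
oracle_stats <- function(beta_hat, chrom = "1", spacing = 1000L) {
  tibble::tibble(
    snp_id = sprintf("s%03d", seq_along(beta_hat)),
    chrom = chrom,
    pos = seq_along(beta_hat) * spacing,
    beta_hat = beta_hat
  )
}
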