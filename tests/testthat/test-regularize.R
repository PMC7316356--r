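test_that("ols_effects matches per-SNP least squares on standardized data", {
  set.seed(21)
  N <- 300; J <- 8
  G <- matrix(rbinom(N * J, 2, 0.3), N, J,
              dimnames = list(NULL, sprintf("s%d", 1:J)))
  y <- rnorm(N)
  beta <- ols_effects(G, y)
  ys <- as.numeric(scale(y))
  for (j in seq_len(J)) {
    xj <- as.numeric(scale(G[, j]))
    expect_equal(unname(beta[j]), sum(xj * ys) / sum(xj^2), tolerance = 1e-10)
  }
  expect_error(ols_effects(G[1:10, ], y), class = "genequad_validation_error")
  expect_error(ols_effects(cbind(G, 1), y), class = "genequad_validation_error")
})

test_that("the internal penalized solver matches a from-scratch coordinate descent", {
  set.seed(31)
  for (rep in 1:6) {
    J <- sample(2:5, 1)
    Sigma <- crossprod(matrix(rnorm(60 * J), 60, J)) / 60
    d <- sqrt(diag(Sigma)); Sigma <- Sigma / outer(d, d)
    beta_hat <- rnorm(J, 0, 0.3)
    mixing <- runif(1, 0, 0.8)          # surface convention: 0 = LASSO
    alpha <- 1 - mixing                  # solver convention
    lam <- runif(1, 0.01, 0.2)
    fit <- genequad:::.fit_path(beta_hat, Sigma, lam * c(8, 4, 2, 1), alpha,
                                thresh = 1e-14)
    got <- as.numeric(fit$beta[, 4])
    want <- oracle_cd_enet(Sigma, beta_hat, lam, alpha)
    expect_lt(max(abs(got - want)), 1e-6)
  }
})

test_that("ridge closed form matches a generic optimizer and the iterative ridge path", {
  set.seed(32)
  J <- 5
  Sigma <- crossprod(matrix(rnorm(80 * J), 80, J)) / 80
  d <- sqrt(diag(Sigma)); Sigma <- Sigma / outer(d, d)
  beta_hat <- rnorm(J, 0, 0.3)
  for (theta in c(0.05, 0.3, 1)) {
    cf <- ridge_closed_form(beta_hat, Sigma, theta)
    opt <- optim(rep(0, J),
                 function(b) sum((beta_hat - Sigma %*% b)^2) + theta * sum(b^2),
                 method = "BFGS",
                 control = list(reltol = 1e-15, maxit = 10000))
    expect_lt(max(abs(cf$coef - opt$par)), 1e-6)
  }
  # iterative ridge (mixing = 1 -> glmnet alpha = 0) at penalty lambda solves
  # ||beta_hat - Sigma b||^2 + theta ||b||^2 with theta = J * lambda / s_y
  lam <- 0.05
  s_y <- sqrt(mean(beta_hat^2))
  fit <- genequad:::.fit_path(beta_hat, Sigma, lam * c(8, 4, 2, 1), alpha = 0,
                              thresh = 1e-14)
  got <- as.numeric(fit$beta[, 4])
  want <- ridge_closed_form(beta_hat, Sigma, J * lam / s_y)$coef
  expect_lt(max(abs(got - want)), 1e-6)
})

test_that("the penalty grid starts at a full-shrinkage penalty and spans the configured decades", {
  set.seed(33)
  Sigma <- oracle_block_ld(20, 5, 0.5)
  beta_hat <- as.numeric(Sigma %*% rnorm(20, 0, 0.1)) + rnorm(20, 0, 0.01)
  config <- regularization_config()
  grid <- genequad:::.penalty_grid(beta_hat, Sigma, config)
  expect_length(grid, config$grid_steps)
  expect_true(all(diff(grid) < 0))
  expect_equal(log10(grid[1] / grid[length(grid)]),
               config$grid_step_size * (config$grid_steps - 1),
               tolerance = 1e-8)
  # at the top of the grid every coefficient is zero (LASSO/EN path start)
  fit <- genequad:::.fit_path(beta_hat, Sigma, grid[1:2], alpha = 0.5)
  expect_equal(sum(fit$beta[, 1] != 0), 0)
})

test_that("regularize_effects undoes LD inflation on a block-LD toy", {
  # beta_hat = Sigma %*% beta_true + noise is the exact generative model the
  # penalized regression inverts, so the fit must recover beta_true closely
  set.seed(34)
  J <- 60
  Sigma <- oracle_block_ld(J, 5, 0.4)
  beta_true <- c(rnorm(6, 0, 0.5), rep(0, J - 6))
  beta_hat <- as.numeric(Sigma %*% beta_true) + rnorm(J, 0, 0.01)
  stats <- oracle_stats(beta_hat)
  reg <- regularize_effects(stats, Sigma,
                            regularization_config(selection = "best_fit"))
  expect_gt(cor(reg$beta_tilde, beta_true)^2, 0.98)
})

test_that("an all-zero effect vector passes through with an NA penalty", {
  stats <- oracle_stats(rep(0, 12))
  reg <- regularize_effects(stats, diag(12))
  expect_true(all(reg$beta_tilde == 0))
  expect_true(is.na(attr(reg, "chosen_lambda")[["1"]]))
})

test_that("one-SE selection never picks a smaller penalty than best-fit", {
  set.seed(35)
  J <- 100
  Sigma <- oracle_block_ld(J, 10, 0.6)
  beta <- ifelse(runif(J) < 0.1, rnorm(J, 0, 0.3), 0)
  beta_hat <- as.numeric(Sigma %*% beta) + rnorm(J, 0, 0.02)
  stats <- oracle_stats(beta_hat)
  one_se <- regularize_effects(stats, Sigma,
                               regularization_config(selection = "one_se"))
  best <- regularize_effects(stats, Sigma,
                             regularization_config(selection = "best_fit"))
  expect_gte(attr(one_se, "chosen_lambda")[["1"]],
             attr(best, "chosen_lambda")[["1"]])
  expect_lte(sum(one_se$beta_tilde != 0), sum(best$beta_tilde != 0))
})

test_that("SNP-order mismatch between stats and LD aborts naming the first offender", {
  stats <- oracle_stats(rnorm(4))
  Sigma <- diag(4)
  ids <- stats$snp_id
  rownames(Sigma) <- colnames(Sigma) <- c(ids[1], ids[3], ids[2], ids[4])
  expect_error(regularize_effects(stats, Sigma),
               class = "genequad_validation_error", regexp = "s003")
})

test_that("regularization_config validates its inputs", {
  expect_error(regularization_config(mixing = 1.5),
               class = "genequad_validation_error")
  expect_error(regularization_config(grid_steps = 1),
               class = "genequad_validation_error")
  expect_equal(genequad:::.glmnet_alpha(0), 1)    # 0 = LASSO surface
  expect_equal(genequad:::.glmnet_alpha(1), 0)    # 1 = ridge surface
})
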