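test_that("EM log-likelihood trace is monotone non-decreasing", {
  set.seed(41)
  x <- c(rep(0, 500), rnorm(300, 0, 0.3), rnorm(200, 0, 0.02))
  fit <- em_fit(x, K = 3, seed = 7L)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  expect_true(fit$converged)
})

test_that("exact zeros are pinned to the zero component", {
  set.seed(42)
  x <- c(rep(0, 400), rnorm(600, 0, 0.1))
  fit <- em_fit(x, K = 2, seed = 1L)
  expect_equal(fit$n_zero, 400L)
  expect_equal(fit$sigma2[fit$K], 0)
  expect_true(all(fit$responsibilities[x == 0, fit$K] == 1))
  expect_equal(fit$pi[fit$K], 0.4)
  # weights always sum to one
  expect_equal(sum(fit$pi), 1, tolerance = 1e-12)
})

test_that("EM is invariant to permutation of the input order", {
  set.seed(43)
  x <- c(rep(0, 300), rnorm(400, 0, 0.2), rnorm(300, 0, 0.01))
  fit1 <- em_fit(x, K = 3, seed = 5L)
  fit2 <- em_fit(sample(x), K = 3, seed = 5L)
  expect_equal(fit1$sigma2, fit2$sigma2, tolerance = 1e-10)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-8)
})

test_that("variances come out strictly decreasing with the zero component last", {
  set.seed(44)
  x <- c(rep(0, 200), rnorm(500, 0, 0.3), rnorm(300, 0, 0.01))
  fit <- em_fit(x, K = 3, seed = 2L)
  expect_true(all(diff(fit$sigma2) < 0))
  expect_equal(fit$sigma2[3], 0)
})

test_that("the zero-mean EM cannot beat a free-mean mixture on likelihood", {
  skip_if_not_installed("mclust")
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller frame
  set.seed(45)
  x <- c(rnorm(700, 0, 0.3), rnorm(300, 0, 0.02))
  ours <- em_fit(x, K = 3, seed = 3L)     # 2 fitted zero-mean components
  free <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  # same component count, strictly more parameters -> at least as good a fit
  expect_lte(ours$loglik, free$loglik + 1e-6)
})

test_that("em_fit validates K against the data", {
  expect_error(em_fit(rnorm(100), K = 1),
               class = "genequad_validation_error")
  expect_error(em_fit(c(0, 0, 0.5, -0.5, 0.5), K = 4),
               class = "genequad_validation_error", regexp = "distinct")
})

test_that("an all-zero vector yields the degenerate fit with a warning", {
  expect_warning(fit <- em_fit(rep(0, 50), K = 3), regexp = "all effects")
  expect_equal(fit$sigma2, c(0, 0, 0))
  expect_equal(fit$pi[3], 1)
})

test_that("null_threshold extracts the second variance and flags degeneracy", {
  set.seed(46)
  x <- c(rep(0, 300), rnorm(400, 0, 0.3), rnorm(300, 0, 0.01))
  fit <- em_fit(x, K = 3, seed = 1L)
  thr <- null_threshold(fit)
  expect_s3_class(thr, "genequad_threshold")
  expect_equal(thr$sigma2_eps, fit$sigma2[2])
  expect_false(thr$degenerate)

  fit2 <- em_fit(c(rep(0, 300), rnorm(700, 0, 0.1)), K = 2, seed = 1L)
  expect_warning(thr2 <- null_threshold(fit2), regexp = "degenerate")
  expect_true(thr2$degenerate)
  expect_equal(thr2$sigma2_eps, 0)
})

test_that("classify_snps assigns the three tiers by maximal responsibility", {
  set.seed(47)
  x <- c(rnorm(200, 0, 0.5), rnorm(500, 0, 0.01), rep(0, 300))
  fit <- em_fit(x, K = 3, seed = 1L)
  cls <- classify_snps(fit)
  expect_equal(nrow(cls), 1000L)
  expect_equal(as.character(cls$category[x == 0]), rep("zero", 300))
  # effects an order of magnitude above the intermediate scale are all
  # called associated (the crossover sits near the intermediate sd itself)
  big <- which(abs(x) > 10 * sqrt(fit$sigma2[2]))
  expect_true(all(cls$category[big] == "associated"))
  expect_gt(length(big), 100)
  expect_equal(attr(cls, "frac_associated"), mean(cls$component < fit$K))
})

test_that("select_K recovers a three-scale mixture and its parameters", {
  # three-scale vectors: 60% exact zeros, 15% N(0, 0.1), 25% N(0, 0.001);
  # recovery is judged on the mean estimate across replicates against its
  # Monte-Carlo standard error
  s2_hi <- 0.1; s2_lo <- 0.001
  R <- 10
  est <- matrix(NA_real_, R, 2)
  k_sel <- integer(R)
  for (r in seq_len(R)) {
    x <- withr::with_seed(4100 + r, {
      c(rep(0, 3000), rnorm(750, 0, sqrt(s2_hi)), rnorm(1250, 0, sqrt(s2_lo)))
    })
    fit <- select_K(x, K_max = 6, seed = 1L)
    k_sel[r] <- fit$K
    est[r, ] <- fit$sigma2[1:2]
  }
  expect_gte(sum(k_sel == 3L), 8L)
  for (j in 1:2) {
    mc_se <- sd(est[, j]) / sqrt(R)
    expect_lt(abs(mean(est[, j]) - c(s2_hi, s2_lo)[j]), 3 * mc_se)
  }
})

test_that("select_K exposes the BIC table and the winner maximizes it", {
  set.seed(48)
  x <- c(rep(0, 500), rnorm(700, 0, 0.2), rnorm(800, 0, 0.005))
  fit <- select_K(x, K_max = 5, seed = 1L)
  tab <- attr(fit, "bic_table")
  expect_true(all(c("K", "loglik", "bic") %in% names(tab)))
  expect_equal(fit$bic, max(tab$bic))
})

test_that("mixture tidy/glance return the documented shapes", {
  set.seed(49)
  x <- c(rep(0, 200), rnorm(800, 0, 0.1))
  fit <- em_fit(x, K = 2, seed = 1L)
  td <- generics::tidy(fit)
  expect_equal(nrow(td), fit$K)
  expect_equal(sum(td$n_snps), fit$n)
  gl <- generics::glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$sigma2_eps, fit$sigma2[2])
})
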