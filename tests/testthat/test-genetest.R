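test_that("gene_statistic matches the brute-force double sum", {
  set.seed(51)
  m <- 6
  bt <- rnorm(m, 0, 0.1)
  expect_equal(gene_statistic(bt), sum(bt^2), tolerance = 1e-14)
  A <- crossprod(matrix(rnorm(m * m), m, m)) / m
  brute <- 0
  for (j in seq_len(m)) for (k in seq_len(m)) {
    brute <- brute + bt[j] * A[j, k] * bt[k]
  }
  expect_equal(gene_statistic(bt, A), brute, tolerance = 1e-12)
})

test_that("weight-matrix validation rejects bad A", {
  bt <- rnorm(3)
  expect_error(gene_statistic(bt, diag(4)),
               class = "genequad_validation_error")
  Asym <- matrix(c(1, 0.5, 0.1, 1), 2, 2)
  expect_error(gene_statistic(rnorm(2), Asym),
               class = "genequad_validation_error", regexp = "symmetric")
  Aneg <- diag(c(1, -1))
  expect_error(gene_statistic(rnorm(2), Aneg),
               class = "genequad_validation_error", regexp = "semi-definite")
})

test_that("null eigenvalues with identity weights are the scaled LD spectrum", {
  set.seed(52)
  Sigma_g <- oracle_block_ld(6, 3, 0.5)
  s2 <- 3e-4
  lam <- null_eigenvalues(Sigma_g, s2)
  want <- sort(s2 * eigen(Sigma_g, symmetric = TRUE)$values,
               decreasing = TRUE)
  expect_equal(as.numeric(lam), want, tolerance = 1e-12)
})

test_that("null eigenvalues with general A match the pracma matrix square root", {
  skip_if_not_installed("pracma")
  set.seed(53)
  m <- 5
  Sigma_g <- crossprod(matrix(rnorm(40 * m), 40, m)) / 40
  d <- sqrt(diag(Sigma_g)); Sigma_g <- Sigma_g / outer(d, d)
  A <- crossprod(matrix(rnorm(m * m), m, m)) / m
  s2 <- 2e-4
  lam <- null_eigenvalues(Sigma_g, s2, A)
  S <- pracma::sqrtm(Sigma_g)$B
  want <- sort(s2 * eigen(S %*% A %*% S, symmetric = TRUE)$values,
               decreasing = TRUE)
  expect_equal(as.numeric(lam), want, tolerance = 1e-8)
})

test_that("Imhof p-values match the scaled chi-square closed form for equal weights", {
  for (m in c(1, 2, 5, 10)) {
    for (scale in c(0.3, 1, 4)) {
      for (quant in c(0.5, 0.9, 0.99, 0.999)) {
        q <- scale * qchisq(quant, df = m)
        p <- imhof_pvalue(q, rep(scale, m))
        expect_equal(p, pchisq(q / scale, df = m, lower.tail = FALSE),
                     tolerance = 1e-6)
      }
    }
  }
})

test_that("Imhof p-values are monotone decreasing in the statistic", {
  set.seed(54)
  lam <- exp(rnorm(6, 0, 0.5))
  qs <- seq(0.1, 10 * sum(lam), length.out = 40)
  ps <- vapply(qs, imhof_pvalue, numeric(1), lambdas = lam)
  expect_true(all(diff(ps) <= 1e-10))
  expect_true(all(ps >= 0 & ps <= 1))
})

test_that("Imhof handles boundary inputs and degenerate spectra", {
  expect_equal(imhof_pvalue(0, c(1, 2)), 1)
  expect_equal(imhof_pvalue(-1, c(1, 2)), 1)
  expect_error(imhof_pvalue(1, numeric(0)),
               class = "genequad_degenerate_null")
  expect_error(imhof_pvalue(1, c(0, 1e-305)),
               class = "genequad_degenerate_null")
  expect_error(imhof_pvalue(Inf, 1), class = "genequad_validation_error")
  # far-tail statistics clamp to the reporting floor
  expect_equal(imhof_pvalue(1e6, rep(1, 3)), 1e-20)
})

test_that("bonferroni_threshold reproduces the published gene- and SNP-level cutoffs", {
  expect_equal(bonferroni_threshold(1408), 0.05 / 1408)
  expect_equal(signif(bonferroni_threshold(1408), 3), 3.55e-5)
  expect_equal(signif(bonferroni_threshold(1916), 3), 2.61e-5)
  expect_equal(signif(bonferroni_threshold(14322), 3), 3.49e-6)
  expect_equal(signif(bonferroni_threshold(1070306), 3), 4.67e-8)
  expect_equal(bonferroni_threshold(100, alpha = 0.01), 1e-4)
})

test_that("run_scan produces coherent per-gene results on a constructed example", {
  set.seed(55)
  J <- 30
  Sigma <- oracle_block_ld(J, 5, 0.4)
  stats <- oracle_stats(rnorm(J, 0, 0.02))
  # regularized effects: one loud gene (SNPs 1-5), the rest quiet
  stats$beta_tilde <- c(rnorm(5, 0, 0.2), rnorm(J - 5, 0, 0.005))
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:6), chrom = "1",
    start = seq(1L, J, by = 5L) * 1000L,
    end = (seq(1L, J, by = 5L) + 4L) * 1000L
  )
  gm <- map_snps_to_genes(stats, genes)
  scan <- run_scan(stats, Sigma, gm, threshold = 2.5e-5)
  expect_s3_class(scan, "genequad_scan")
  expect_equal(nrow(scan), 6L)
  expect_true(all(scan$p_value >= 0 & scan$p_value <= 1))
  expect_false(is.unsorted(scan$p_value))
  expect_equal(scan$gene_id[1], "g01")
  expect_equal(attr(scan, "bonferroni"), 0.05 / 6)
  expect_equal(scan$significant, scan$p_value < attr(scan, "bonferroni"))
  # h2_g is the statistic itself under identity weights
  expect_equal(scan$h2_g, scan$q_stat)
})

test_that("genes that capture no SNPs stay out of the testing burden", {
  set.seed(56)
  J <- 10
  stats <- oracle_stats(rnorm(J, 0, 0.02))
  stats$beta_tilde <- rnorm(J, 0, 0.01)
  genes <- tibble::tibble(
    gene_id = c("gIn", "gOut"), chrom = "1",
    start = c(1000L, 90000L), end = c(10000L, 95000L)
  )
  gm <- map_snps_to_genes(stats, genes)
  scan <- run_scan(stats, diag(J), gm, threshold = 1e-4)
  expect_equal(attr(scan, "n_testable"), 1L)
  expect_equal(attr(scan, "bonferroni"), 0.05)
  out_row <- scan[scan$gene_id == "gOut", ]
  expect_true(is.na(out_row$p_value))
  expect_false(out_row$testable)
})

test_that("a degenerate zero threshold flags genes and zero-statistic genes survive", {
  J <- 6
  stats <- oracle_stats(rep(0, J))
  stats$beta_tilde <- c(0.1, rep(0, J - 1))
  genes <- tibble::tibble(gene_id = c("hot", "cold"), chrom = "1",
                          start = c(1000L, 4000L), end = c(3000L, 6000L))
  gm <- map_snps_to_genes(stats, genes)
  scan <- run_scan(stats, diag(J), gm, threshold = 0)
  hot <- scan[scan$gene_id == "hot", ]
  cold <- scan[scan$gene_id == "cold", ]
  expect_true(hot$degenerate_null)
  expect_equal(hot$p_value, 0)
  expect_equal(cold$p_value, 1)
})

test_that("scan tidy/glance summarize the result table", {
  set.seed(57)
  J <- 10
  stats <- oracle_stats(rnorm(J, 0, 0.02))
  stats$beta_tilde <- rnorm(J, 0, 0.01)
  genes <- tibble::tibble(gene_id = c("a", "b"), chrom = "1",
                          start = c(1000L, 6000L), end = c(5000L, 10000L))
  scan <- run_scan(stats, diag(J), map_snps_to_genes(stats, genes),
                   threshold = 1e-4)
  td <- generics::tidy(scan)
  expect_false(inherits(td, "genequad_scan"))
  expect_null(attr(td, "bonferroni"))
  gl <- generics::glance(scan)
  expect_equal(gl$n_genes, 2L)
  expect_equal(gl$n_testable, 2L)
  expect_equal(gl$total_h2, sum(scan$q_stat))
})
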