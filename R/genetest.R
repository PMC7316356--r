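#' Gene-level quadratic-form statistic
#'
#' `Q_g = beta_g' A beta_g` over the regularized effects of the SNPs in a
#' gene. With the default identity weight matrix this is the sum of squared
#' regularized effects, whose expectation is the heritability contributed by
#' the gene.
#'
#' @param beta_tilde_g Numeric vector of the gene's regularized effects.
#' @param A Optional symmetric positive semi-definite weight matrix
#'   (identity when `NULL`).
#' @return The scalar statistic (non-negative for PSD `A`).
#' @export
gene_statistic <- function(beta_tilde_g, A = NULL) {
  if (is.null(A)) return(sum(beta_tilde_g^2))
  .check_weight_matrix(A, length(beta_tilde_g))
  as.numeric(beta_tilde_g %*% A %*% beta_tilde_g)
}

.check_weight_matrix <- function(A, m) {
  if (nrow(A) != m || ncol(A) != m) {
    rlang::abort("weight matrix dimension does not match the SNP set",
                 class = "genequad_validation_error")
  }
  if (max(abs(A - t(A))) > 1e-10) {
    rlang::abort("weight matrix must be symmetric within 1e-10",
                 class = "genequad_validation_error")
  }
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    rlang::abort("weight matrix must be positive semi-definite",
                 class = "genequad_validation_error")
  }
  invisible(TRUE)
}

# Symmetric PSD square root; negative eigenvalues of the input are clipped
# at zero (empirical LD blocks can be slightly indefinite).
.sym_sqrt <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  d <- pmax(e$values, 0)
  e$vectors %*% (sqrt(d) * t(e$vectors))
}

#' Null eigenvalues of the gene statistic
#'
#' Under the reformulated null every regularized effect in the gene is
#' `N(0, sigma2_eps)` with covariance `sigma2_eps * Sigma_g`, so the
#' quadratic form is distributed as a weighted sum of 1-df chi-squares with
#' weights equal to the eigenvalues of
#' `sigma2_eps * Sigma_g^{1/2} A Sigma_g^{1/2}`. With `A = I` this is just
#' `sigma2_eps` times the spectrum of the LD block.
#'
#' @param Sigma_g Symmetric m x m LD block for the gene's SNPs.
#' @param sigma2_eps SNP-level null threshold (non-negative).
#' @param A Optional weight matrix as in [gene_statistic()].
#' @return Numeric vector of m eigenvalues, clipped at zero and sorted
#'   decreasing. The number of negative-eigenvalue clips applied to
#'   `Sigma_g` is attached as attribute `n_clipped`.
#' @export
null_eigenvalues <- function(Sigma_g, sigma2_eps, A = NULL) {
  if (sigma2_eps < 0) {
    rlang::abort("sigma2_eps must be non-negative",
                 class = "genequad_validation_error")
  }
  Sigma_g <- as.matrix(Sigma_g)
  if (max(abs(Sigma_g - t(Sigma_g))) > 1e-10) {
    rlang::abort("LD block must be symmetric",
                 class = "genequad_validation_error")
  }
  if (is.null(A)) {
    ev <- eigen(Sigma_g, symmetric = TRUE, only.values = TRUE)$values
  } else {
    .check_weight_matrix(A, nrow(Sigma_g))
    S <- .sym_sqrt(Sigma_g)
    M <- S %*% A %*% S
    M <- (M + t(M)) / 2
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  }
  n_clipped <- sum(ev < 0)
  lambda <- sort(sigma2_eps * pmax(ev, 0), decreasing = TRUE)
  attr(lambda, "n_clipped") <- n_clipped
  lambda
}

# Chernoff bound on P(sum lambda_j chisq_1 > q); used to short-circuit the
# oscillatory inversion integral when the tail probability is far below the
# reporting floor.
.chisq_mix_tail_bound <- function(q, lambda) {
  f <- function(t) -t * q - 0.5 * sum(log1p(-2 * t * lambda))
  upper <- 1 / (2 * max(lambda)) * (1 - 1e-9)
  opt <- stats::optimize(f, c(0, upper))
  exp(opt$objective)
}

#' Tail probability of a weighted sum of chi-squares (Imhof's method)
#'
#' Computes `P(sum_j lambda_j chisq_1j > q)` by numerical inversion of the
#' characteristic function:
#' `p = 1/2 + (1/pi) Int_0^Inf sin(theta(u)) / (u rho(u)) du` with
#' `theta(u) = (1/2) sum arctan(lambda_j u) - q u / 2` and
#' `rho(u) = prod (1 + lambda_j^2 u^2)^(1/4)`.
#'
#' The phase `theta(u)` is strictly concave (its derivative is strictly
#' decreasing), so the integration axis is partitioned at the zeros of
#' `sin(theta)`; the resulting panel integrals form an eventually
#' alternating, decaying series that is summed with Euler-type iterated
#' averaging of the partial sums. Probabilities far in the tail cannot be
#' resolved by quadrature, so results are clamped to `[p_floor, 1]`; a
#' Chernoff bound short-circuits the integration when the tail probability
#' is provably below the floor.
#'
#' @param q Observed statistic (finite, non-negative).
#' @param lambdas Positive chi-square weights; entries below `1e-300` are
#'   dropped.
#' @param p_floor Smallest reportable p-value (default 1e-20).
#' @param abs_tol Absolute tolerance for the inversion integral
#'   (default 1e-10).
#' @param max_panels Cap on the number of oscillation panels before series
#'   acceleration takes over (default 300).
#' @return A p-value in `[p_floor, 1]`.
#' @export
imhof_pvalue <- function(q, lambdas, p_floor = 1e-20, abs_tol = 1e-10,
                         max_panels = 300L) {
  if (!is.finite(q)) {
    rlang::abort("q must be finite", class = "genequad_validation_error")
  }
  lambda <- lambdas[lambdas > 1e-300]
  if (length(lambda) == 0) {
    rlang::abort("all eigenvalues are below tolerance: degenerate null",
                 class = "genequad_degenerate_null")
  }
  if (q <= 0) return(1)
  if (.chisq_mix_tail_bound(q, lambda) < p_floor) return(p_floor)

  theta <- function(u) 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
  f <- function(u) {
    u <- as.numeric(u)
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    ifelse(u == 0, 0.5 * (sum(lambda) - q), sin(theta(u)) / (u * rho))
  }
  dtheta <- function(u) 0.5 * sum(lambda / (1 + lambda^2 * u^2)) - 0.5 * q

  quad <- function(lo, hi) {
    r <- stats::integrate(f, lo, hi, subdivisions = 500L,
                          rel.tol = 1e-10, abs.tol = abs_tol / 10,
                          stop.on.error = FALSE)
    if (!r$message %in% c("OK", "roundoff error was detected")) {
      rlang::abort(
        sprintf("Imhof panel integration failed on [%g, %g] (q = %g, m = %d)",
                lo, hi, q, length(lambda)),
        class = "genequad_numeric_error"
      )
    }
    r$value
  }

  # theta rises (concavely) to a single maximum, then falls linearly with
  # asymptotic slope -q/2; locate the maximum
  u_star <- 0
  if (dtheta(0) > 0) {
    hi <- 1
    while (dtheta(hi) > 0) hi <- hi * 2
    u_star <- stats::uniroot(dtheta, c(0, hi), tol = 1e-12)$root
  }
  theta_star <- if (u_star > 0) theta(u_star) else 0

  # head: [0, u_star] holds at most m/4 oscillations (theta < m*pi/4)
  total <- if (u_star > 0) quad(0, u_star) else 0

  # tail: panels between successive solutions of theta(u) = k*pi, along the
  # decreasing branch; panel integrals alternate in sign
  step <- 2 * pi / q  # asymptotic distance between phase levels k*pi
  level <- floor(theta_star / pi) * pi
  if (level >= theta_star) level <- level - pi
  u_prev <- u_star
  terms <- numeric(0)
  repeat {
    lo <- u_prev
    hi <- u_prev + step
    while (theta(hi) > level) hi <- hi + step
    u_next <- stats::uniroot(function(u) theta(u) - level, c(lo, hi),
                             tol = 1e-13)$root
    terms <- c(terms, quad(u_prev, u_next))
    u_prev <- u_next
    level <- level - pi
    n <- length(terms)
    if (n >= 4 && abs(terms[n]) < abs_tol / 10) {
      total <- total + sum(terms)
      break
    }
    if (n >= max_panels) {
      # Euler-type acceleration: iterated averaging of the trailing
      # partial sums of the alternating series
      s <- cumsum(terms)
      m_acc <- min(60L, n - 1L)
      x <- s[(n - m_acc + 1L):n]
      while (length(x) > 1) x <- (x[-1] + x[-length(x)]) / 2
      total <- total + x
      break
    }
  }

  p <- 0.5 + total / pi
  min(max(p, p_floor), 1)
}

#' Plug-in gene heritability
#'
#' With the identity weight matrix the expected value of the gene statistic
#' equals the heritability contributed by the gene's SNPs, so the observed
#' statistic is its plug-in estimate.
#'
#' @param q_stat Non-negative gene statistic.
#' @return The heritability estimate (identical to `q_stat`).
#' @export
gene_heritability <- function(q_stat) {
  stopifnot(all(q_stat >= 0))
  q_stat
}

#' Bonferroni significance threshold
#'
#' @param n_genes Number of testable genes.
#' @param alpha Family-wise error rate (default 0.05).
#' @return `alpha / n_genes`.
#' @export
bonferroni_threshold <- function(n_genes, alpha = 0.05) {
  stopifnot(n_genes >= 1)
  alpha / n_genes
}

#' Genome scan: test every gene for enrichment
#'
#' For each testable gene, extracts the regularized effects and LD block,
#' computes the quadratic-form statistic, its null eigenvalues under the
#' chromosome's SNP-level null threshold, and an Imhof p-value. Significance
#' is called at the Bonferroni level `alpha / G` with `G` the number of
#' testable genes.
#'
#' When the null threshold is degenerate (zero), the smallest positive
#' fitted mixture variance is used instead if one exists; otherwise genes
#' with a positive statistic are reported at `p = 0` and flagged.
#'
#' @param stats Regularized summary statistics (output of
#'   [regularize_effects()], or any tibble with a `beta_tilde` column in the
#'   canonical SNP order).
#' @param ld LD matrix or named per-chromosome list, as in
#'   [regularize_effects()].
#' @param genes Gene map from [map_snps_to_genes()].
#' @param threshold A `genequad_threshold`, a named numeric vector of
#'   per-chromosome thresholds, or a single number.
#' @param A Optional weight matrix applied to every gene (identity when
#'   `NULL`).
#' @param alpha Family-wise error rate for the Bonferroni call (default
#'   0.05).
#' @param p_floor Smallest reportable p-value (default 1e-20).
#' @param snp_category Optional per-SNP classification (the `category`
#'   column of [classify_snps()], aligned with `stats` rows) used to flag
#'   genes containing an associated SNP.
#' @return A tibble of class `genequad_scan`, one row per gene, sorted by
#'   p-value then gene id: `gene_id`, `chrom`, `start`, `end`, `n_snps`,
#'   `q_stat`, `h2_g`, `p_value`, `significant`, `contains_associated`,
#'   `degenerate_null`, `testable`. Attributes: `bonferroni` (the
#'   threshold), `n_testable`, `alpha`, `eigenvalues` (named list).
#' @export
run_scan <- function(stats, ld, genes, threshold, A = NULL, alpha = 0.05,
                     p_floor = 1e-20, snp_category = NULL) {
  stats <- tibble::as_tibble(stats)
  if (!"beta_tilde" %in% names(stats)) {
    rlang::abort("stats must contain a beta_tilde column (run regularize_effects first)",
                 class = "genequad_validation_error")
  }
  chroms <- unique(stats$chrom)
  if (is.matrix(ld)) ld <- stats::setNames(list(ld), chroms)

  thr_for <- function(ch) {
    if (inherits(threshold, "genequad_threshold")) {
      list(s2 = threshold$sigma2_eps, degen = threshold$degenerate,
           fallback = {
             pos <- threshold$sigma2[threshold$sigma2 > 0]
             if (length(pos)) min(pos) else 0
           })
    } else if (is.list(threshold)) {
      thr_for_one(threshold[[ch]])
    } else if (!is.null(names(threshold)) && length(threshold) > 1) {
      list(s2 = threshold[[ch]], degen = threshold[[ch]] <= 0, fallback = 0)
    } else {
      list(s2 = as.numeric(threshold), degen = as.numeric(threshold) <= 0,
           fallback = 0)
    }
  }
  thr_for_one <- function(t) {
    if (inherits(t, "genequad_threshold")) {
      list(s2 = t$sigma2_eps, degen = t$degenerate,
           fallback = {
             pos <- t$sigma2[t$sigma2 > 0]
             if (length(pos)) min(pos) else 0
           })
    } else {
      list(s2 = as.numeric(t), degen = as.numeric(t) <= 0, fallback = 0)
    }
  }

  n_testable <- sum(genes$n_snps >= 1)
  if (n_testable == 0) {
    rlang::abort("no testable genes (no gene captured any SNP)",
                 class = "genequad_validation_error")
  }
  bonf <- bonferroni_threshold(n_testable, alpha)

  eig_list <- list()
  rows <- purrr::pmap(
    list(genes$gene_id, genes$chrom, genes$snp_indices, genes$n_snps),
    function(gene_id, chrom, idx, n_snps) {
      if (n_snps == 0) {
        return(tibble::tibble(q_stat = NA_real_, h2_g = NA_real_,
                              p_value = NA_real_, degenerate_null = FALSE,
                              contains_associated = FALSE))
      }
      thr <- thr_for(chrom)
      bt <- stats$beta_tilde[idx]
      q <- gene_statistic(bt, A)
      # local indices within the chromosome's LD block
      ch_rows <- which(stats$chrom == chrom)
      loc <- match(idx, ch_rows)
      Sg <- ld[[chrom]][loc, loc, drop = FALSE]
      s2 <- thr$s2
      degen <- FALSE
      if (thr$degen || s2 <= 0) {
        if (thr$fallback > 0) {
          s2 <- thr$fallback
          degen <- TRUE
        } else {
          eig_list[[gene_id]] <<- rep(0, n_snps)
          return(tibble::tibble(q_stat = q, h2_g = gene_heritability(q),
                                p_value = if (q > 0) 0 else 1,
                                degenerate_null = TRUE,
                                contains_associated = FALSE))
        }
      }
      lambda <- null_eigenvalues(Sg, s2, A)
      eig_list[[gene_id]] <<- lambda
      p <- imhof_pvalue(q, lambda, p_floor = p_floor)
      tibble::tibble(q_stat = q, h2_g = gene_heritability(q), p_value = p,
                     degenerate_null = degen, contains_associated = FALSE)
    }
  )
  res <- dplyr::bind_cols(
    dplyr::select(genes, "gene_id", "chrom", "start", "end", "n_snps"),
    dplyr::bind_rows(rows)
  )
  if (!is.null(snp_category)) {
    res$contains_associated <- purrr::map_lgl(
      genes$snp_indices, function(idx) any(snp_category[idx] == "associated")
    )
  }
  res <- dplyr::mutate(
    res,
    testable = .data$n_snps >= 1L,
    significant = !is.na(.data$p_value) & .data$p_value < bonf
  )
  res <- dplyr::arrange(res, .data$p_value, .data$gene_id)
  structure(res, class = c("genequad_scan", class(res)),
            bonferroni = bonf, n_testable = n_testable, alpha = alpha,
            eigenvalues = eig_list)
}

#' Tidy a genome scan
#'
#' @param x A `genequad_scan`.
#' @param ... Unused.
#' @return The per-gene results as a plain tibble.
#' @method tidy genequad_scan
#' @export
tidy.genequad_scan <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "genequad_scan")
  attr(out, "bonferroni") <- NULL
  attr(out, "n_testable") <- NULL
  attr(out, "alpha") <- NULL
  attr(out, "eigenvalues") <- NULL
  tibble::as_tibble(out)
}

#' One-row summary of a genome scan
#'
#' @param x A `genequad_scan`.
#' @param ... Unused.
#' @return A one-row tibble: `n_genes`, `n_testable`, `bonferroni`,
#'   `n_significant`, `total_h2` (sum of per-gene heritability estimates
#'   over testable genes).
#' @method glance genequad_scan
#' @export
glance.genequad_scan <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_testable = attr(x, "n_testable"),
    bonferroni = attr(x, "bonferroni"),
    n_significant = sum(x$significant, na.rm = TRUE),
    total_h2 = sum(x$h2_g[x$testable], na.rm = TRUE)
  )
}
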