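#' Fit a zero-mean Gaussian mixture to regularized effect sizes
#'
#' Fits a K-component mixture of zero-mean normals
#' `beta_tilde_j ~ sum_k pi_k N(0, sigma2_k)` by expectation-maximization,
#' with the K-th component pinned at variance zero. Exact zeros in the input
#' (which L1-containing regularization produces) are deterministically
#' assigned to the zero component; the remaining effects are fitted over the
#' K-1 positive-variance components. Component variances are returned in
#' strictly decreasing order, so the second component's variance is the
#' SNP-level null threshold (see [null_threshold()]): the largest
#' phenotypic-variance share a spurious, non-associated SNP is allowed to
#' carry.
#'
#' Restarted chains differ in their initial variance spread; the chain with
#' the highest final log-likelihood wins.
#'
#' @param beta_tilde Numeric vector of regularized effect sizes.
#' @param K Total number of components including the pinned zero component
#'   (K >= 2).
#' @param max_iter Maximum EM iterations per chain (default 100).
#' @param n_restarts Number of independently initialized chains (default 10).
#' @param seed Seed controlling chain initialization.
#' @param tol Stop when the log-likelihood improves by less than this
#'   (default 1e-8).
#' @param var_floor Variance floor; a fitted component collapsing below it is
#'   merged into the zero component with a warning (default 1e-12).
#' @return An object of class `genequad_mixture`: a list with elements `K`,
#'   `pi`, `sigma2` (decreasing, last entry 0), `responsibilities` (J x K),
#'   `loglik` (of the nonzero effects under the fitted positive components),
#'   `loglik_trace`, `bic`, `n_iter`, `converged`, `n_zero`, `n` (= J).
#' @export
em_fit <- function(beta_tilde, K, max_iter = 100, n_restarts = 10,
                   seed = 1L, tol = 1e-8, var_floor = 1e-12) {
  if (K < 2) {
    rlang::abort("K must be at least 2 (one fitted component plus the zero component)",
                 class = "genequad_validation_error")
  }
  J <- length(beta_tilde)
  is_zero <- beta_tilde == 0
  x <- beta_tilde[!is_zero]
  n_zero <- sum(is_zero)

  if (length(x) == 0) {
    rlang::warn("all effects are exactly zero; returning the degenerate null fit")
    gamma <- matrix(0, J, K)
    gamma[, K] <- 1
    fit <- structure(
      list(K = K, pi = c(rep(0, K - 1), 1), sigma2 = rep(0, K),
           responsibilities = gamma, loglik = 0, loglik_trace = numeric(0),
           bic = -Inf, n_iter = 0L, converged = TRUE, n_zero = n_zero, n = J),
      class = "genequad_mixture"
    )
    return(fit)
  }
  Kf <- K - 1L  # fitted positive-variance components
  if (length(unique(abs(x))) < Kf) {
    rlang::abort(
      sprintf("K = %d exceeds the number of distinct nonzero effect magnitudes (%d)",
              K, length(unique(abs(x)))),
      class = "genequad_validation_error"
    )
  }

  x2 <- x^2
  best <- NULL
  for (chain in seq_len(n_restarts)) {
    init <- withr::with_seed(seed + chain - 1L, {
      # geometric spread of initial variances between jittered quantiles of
      # the squared effects
      qs <- stats::quantile(x2, probs = c(0.15, 0.95), names = FALSE)
      qs <- pmax(qs, var_floor * 10)
      jitter <- stats::runif(2, 0.5, 2)
      exp(seq(log(qs[2] * jitter[2]), log(qs[1] * jitter[1]),
              length.out = Kf))
    })
    res <- .em_chain(x, x2, Kf, init, max_iter, tol, var_floor)
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }

  sig <- best$sigma2
  w <- best$pi
  # merge floor-collapsed components into the zero component
  collapsed <- sig <= var_floor
  if (any(collapsed)) {
    rlang::warn(sprintf("%d fitted component(s) collapsed onto the variance floor; merged into the zero component",
                        sum(collapsed)))
  }
  ord <- order(sig, decreasing = TRUE)
  sig <- sig[ord]
  w <- w[ord]

  # assemble full-K responsibilities in the sorted order
  gamma <- matrix(0, J, K)
  gamma[!is_zero, seq_len(Kf)] <- best$gamma[, ord, drop = FALSE]
  gamma[is_zero, K] <- 1
  pi_full <- c(w * (1 - n_zero / J), n_zero / J)
  sigma2_full <- c(sig, 0)
  if (any(collapsed)) {
    keep <- sigma2_full > var_floor
    moved <- sum(pi_full[!keep])
    gamma_zero <- rowSums(gamma[, !keep, drop = FALSE])
    gamma <- cbind(gamma[, keep, drop = FALSE], 0)
    gamma[, ncol(gamma)] <- gamma[, ncol(gamma)] + gamma_zero
    sigma2_full <- c(sigma2_full[keep], 0)
    pi_full <- c(pi_full[keep], moved)
    K <- length(sigma2_full)
  }

  n_fit <- length(x)
  df <- 2 * K - 3  # (K-1) variances + (K-1) weights - 1 sum constraint
  bic <- 2 * best$loglik - df * log(n_fit)

  structure(
    list(K = K, pi = pi_full, sigma2 = sigma2_full,
         responsibilities = gamma, loglik = best$loglik,
         loglik_trace = best$trace, bic = bic, n_iter = best$n_iter,
         converged = best$converged, n_zero = n_zero, n = J),
    class = "genequad_mixture"
  )
}

# One EM chain over the nonzero effects with Kf zero-mean components.
.em_chain <- function(x, x2, Kf, sigma2_init, max_iter, tol, var_floor) {
  n <- length(x)
  sigma2 <- sigma2_init
  w <- rep(1 / Kf, Kf)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  gamma <- matrix(1 / Kf, n, Kf)
  it <- 0L
  for (it in seq_len(max_iter)) {
    # E-step: responsibilities from current weights and variances
    logdens <- vapply(seq_len(Kf), function(k) {
      stats::dnorm(x, 0, sqrt(sigma2[k]), log = TRUE) + log(w[k])
    }, numeric(n))
    if (Kf == 1L) logdens <- matrix(logdens, ncol = 1)
    m <- apply(logdens, 1, max)
    p <- exp(logdens - m)
    rs <- rowSums(p)
    gamma <- p / rs
    ll <- sum(m + log(rs))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
    # M-step: closed-form zero-mean variance and weight updates
    Jk <- colSums(gamma)
    sigma2 <- pmax(colSums(gamma * x2) / Jk, var_floor)
    w <- Jk / n
  }
  list(sigma2 = sigma2, pi = w, gamma = gamma, loglik = ll_old,
       trace = trace, n_iter = it, converged = converged)
}

#' Select the number of mixture components by BIC
#'
#' Fits [em_fit()] for `K = 2, ..., K_max` and keeps the fit maximizing
#' `BIC = 2 loglik - df log(n_nonzero)` with `df = 2K - 3` (the pinned zero
#' component carries no fitted parameters). Candidate K values that exceed
#' the number of distinct effect magnitudes are skipped.
#'
#' @inheritParams em_fit
#' @param K_max Largest K to consider (default 10).
#' @return The winning `genequad_mixture`, with a `bic_table` attribute
#'   (tibble of K, loglik, bic per candidate).
#' @export
select_K <- function(beta_tilde, K_max = 10, max_iter = 100, n_restarts = 10,
                     seed = 1L, tol = 1e-8, var_floor = 1e-12) {
  if (K_max < 2) {
    rlang::abort("K_max must be at least 2", class = "genequad_validation_error")
  }
  fits <- list()
  for (K in 2:K_max) {
    fit <- tryCatch(
      em_fit(beta_tilde, K, max_iter = max_iter, n_restarts = n_restarts,
             seed = seed, tol = tol, var_floor = var_floor),
      genequad_validation_error = function(e) NULL
    )
    if (!is.null(fit)) fits[[as.character(K)]] <- fit
  }
  if (length(fits) == 0) {
    rlang::abort("no candidate K could be fitted",
                 class = "genequad_numeric_error")
  }
  bic_table <- tibble::tibble(
    K = as.integer(names(fits)),
    loglik = purrr::map_dbl(fits, "loglik"),
    bic = purrr::map_dbl(fits, "bic")
  )
  best <- fits[[which.max(bic_table$bic)]]
  attr(best, "bic_table") <- bic_table
  best
}

#' SNP-level null threshold from a mixture fit
#'
#' By construction the mixture variances decrease and the last is zero; the
#' null threshold is the variance of the second component: the largest
#' effect-size variance still treated as spurious. When the fit has only
#' K = 2 components, the threshold degenerates to zero and downstream tests
#' receive a degenerate-null flag.
#'
#' @param fit A `genequad_mixture`.
#' @param source_component Which (1-based) sorted component supplies the
#'   threshold; 2 by default.
#' @return A list of class `genequad_threshold` with `sigma2_eps`,
#'   `source_component`, `degenerate`.
#' @export
null_threshold <- function(fit, source_component = 2L) {
  stopifnot(inherits(fit, "genequad_mixture"))
  if (is.unsorted(rev(fit$sigma2))) {
    rlang::abort("mixture variances are not in decreasing order",
                 class = "genequad_validation_error")
  }
  s2 <- fit$sigma2[source_component]
  degenerate <- !is.na(s2) && s2 <= 0
  if (degenerate) {
    rlang::warn("null threshold is zero (K = 2 fit); degenerate null")
  }
  structure(list(sigma2_eps = max(s2, 0), source_component = source_component,
                 degenerate = degenerate, sigma2 = fit$sigma2),
            class = "genequad_threshold")
}

#' Classify SNPs from mixture responsibilities
#'
#' Hard assignment by maximal responsibility: the first (largest-variance)
#' component is called `associated` (the "causal" tier), middle components
#' `spurious` (nonzero but below the null threshold), and the pinned zero
#' component `zero`. Exact-zero effects always land in `zero`.
#'
#' @param fit A `genequad_mixture`.
#' @return A tibble with columns `component` (integer) and `category`
#'   (factor with levels associated/spurious/zero), one row per SNP, plus
#'   attributes `frac_associated` (share with any nonzero effect, components
#'   1..K-1) and `frac_causal` (share in component 1).
#' @export
classify_snps <- function(fit) {
  stopifnot(inherits(fit, "genequad_mixture"))
  K <- fit$K
  comp <- max.col(fit$responsibilities, ties.method = "first")
  category <- dplyr::case_when(
    comp == 1L ~ "associated",
    comp == K ~ "zero",
    TRUE ~ "spurious"
  )
  out <- tibble::tibble(
    component = as.integer(comp),
    category = factor(category, levels = c("associated", "spurious", "zero"))
  )
  attr(out, "frac_associated") <- mean(comp < K)
  attr(out, "frac_causal") <- mean(comp == 1L)
  out
}

#' @export
print.genequad_mixture <- function(x, ...) {
  cat(sprintf("Zero-mean Gaussian mixture: K = %d components, J = %d effects (%d exact zeros)\n",
              x$K, x$n, x$n_zero))
  cat("  variances:", format(signif(x$sigma2, 4)), "\n")
  cat("  weights:  ", format(signif(x$pi, 4)), "\n")
  cat(sprintf("  loglik = %.4f, BIC = %.4f, iterations = %d (%s)\n",
              x$loglik, x$bic, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Tidy a mixture fit into one row per component
#'
#' @param x A `genequad_mixture`.
#' @param ... Unused.
#' @return A tibble with columns `component`, `weight`, `variance`, `n_snps`
#'   (expected count from the responsibilities).
#' @method tidy genequad_mixture
#' @export
tidy.genequad_mixture <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$K),
    weight = x$pi,
    variance = x$sigma2,
    n_snps = colSums(x$responsibilities)
  )
}

#' One-row summary of a mixture fit
#'
#' @param x A `genequad_mixture`.
#' @param ... Unused.
#' @return A one-row tibble: `K`, `loglik`, `bic`, `n_iter`, `converged`,
#'   `sigma2_eps` (second-largest variance).
#' @method glance genequad_mixture
#' @export
glance.genequad_mixture <- function(x, ...) {
  tibble::tibble(
    K = x$K, loglik = x$loglik, bic = x$bic, n_iter = x$n_iter,
    converged = x$converged,
    sigma2_eps = if (x$K >= 2) x$sigma2[2] else NA_real_
  )
}
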