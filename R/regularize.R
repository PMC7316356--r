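#' Marginal OLS effect sizes
#'
#' Single-SNP ordinary-least-squares regressions of a standardized trait on
#' each standardized genotype column: `beta_hat_j = (x_j' x_j)^-1 x_j' y`.
#' These are the classical GWAS marginal effect sizes; because nearby SNPs
#' are correlated (LD), they are inflated relative to the joint additive
#' effects of the generative model.
#'
#' @param G Numeric N x J genotype matrix. Columns are standardized
#'   internally (mean 0, unit variance).
#' @param y Numeric length-N trait vector, standardized internally.
#' @return Named numeric vector of length J of marginal effect sizes.
#' @export
ols_effects <- function(G, y) {
  G <- as.matrix(G)
  if (nrow(G) != length(y)) {
    rlang::abort("nrow(G) must equal length(y)",
                 class = "genequad_validation_error")
  }
  v <- apply(G, 2, stats::var)
  if (any(v == 0 | !is.finite(v))) {
    rlang::abort(
      paste0("zero-variance genotype column(s): ",
             paste(which(v == 0 | !is.finite(v)), collapse = ", ")),
      class = "genequad_validation_error"
    )
  }
  Gs <- scale(G)
  ys <- as.numeric(scale(y))
  beta <- as.numeric(crossprod(Gs, ys)) / (nrow(G) - 1)
  names(beta) <- colnames(G)
  beta
}

#' Regularization configuration
#'
#' Settings for shrinking marginal effect sizes against the LD matrix. The
#' `mixing` parameter follows the convention in which 0 is the LASSO, 1 is
#' Ridge regression and 0.5 the Elastic Net (note this is the reverse of
#' glmnet's `alpha`; the translation happens internally).
#'
#' @param mixing Penalty mixing in \[0, 1\]: 0 = LASSO, 0.5 = Elastic Net
#'   (the default), 1 = Ridge.
#' @param grid_steps Number of penalty grid points (default 100).
#' @param grid_step_size Log10-scale spacing between successive grid
#'   penalties (default 0.04, so the default grid descends four decades from
#'   the smallest penalty at which all coefficients are zero). The span must
#'   be wide enough for the cross-validation curve to turn over; a narrow
#'   grid silently truncates the path at heavily shrunk solutions.
#' @param selection `"one_se"` (default): the largest penalty whose
#'   cross-validated R-squared is within one standard error of the best
#'   grid point; `"best_fit"`: the penalty maximizing cross-validated
#'   R-squared.
#' @param cv_folds Number of cross-validation folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return A list of class `genequad_reg_config`.
#' @export
regularization_config <- function(mixing = 0.5, grid_steps = 100,
                                  grid_step_size = 0.04,
                                  selection = c("one_se", "best_fit"),
                                  cv_folds = 10, seed = 1L) {
  selection <- match.arg(selection)
  if (mixing < 0 || mixing > 1) {
    rlang::abort("mixing must lie in [0, 1]",
                 class = "genequad_validation_error")
  }
  if (grid_steps < 2) {
    rlang::abort("grid_steps must be at least 2",
                 class = "genequad_validation_error")
  }
  structure(
    list(mixing = mixing, grid_steps = as.integer(grid_steps),
         grid_step_size = grid_step_size, selection = selection,
         cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
    class = "genequad_reg_config"
  )
}

# glmnet parameterization of the mixing convention used at the API surface
.glmnet_alpha <- function(mixing) 1 - mixing

# Penalty grid: lambda_max is the solver's own path start (smallest penalty
# with an all-zero fit for L1-containing penalties; glmnet's surrogate start
# for pure ridge), descending on the log scale in steps of grid_step_size.
.penalty_grid <- function(beta_hat, Sigma, config) {
  alpha <- .glmnet_alpha(config$mixing)
  probe <- glmnet::glmnet(Sigma, beta_hat, alpha = alpha, intercept = FALSE,
                          standardize = FALSE, nlambda = 5)
  # glmnet's largest path penalty sits exactly at the first variable's entry
  # point; nudge the grid top above it so the path starts fully shrunk
  lambda_max <- probe$lambda[1L] * 1.001
  lambda_max * 10^(-config$grid_step_size * (seq_len(config$grid_steps) - 1L))
}

.fit_path <- function(beta_hat, Sigma, lambda, alpha, thresh = 1e-10) {
  glmnet::glmnet(Sigma, beta_hat, alpha = alpha, lambda = lambda,
                 intercept = FALSE, standardize = FALSE,
                 thresh = thresh, maxit = 1e5)
}

# Cross-validated R^2 (and its SE across folds) at every grid penalty.
# Fold assignment uses a private RNG stream so the caller's seed state is
# untouched.
.cv_r2 <- function(beta_hat, Sigma, lambda, alpha, n_folds, seed) {
  J <- length(beta_hat)
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(n_folds), J)))
  r2 <- matrix(NA_real_, n_folds, length(lambda))
  for (f in seq_len(n_folds)) {
    test <- folds == f
    # fold fits only rank penalties; a looser convergence threshold than the
    # final fit is sufficient for selection
    fit <- .fit_path(beta_hat[!test], Sigma[!test, , drop = FALSE],
                     lambda, alpha, thresh = 1e-7)
    pred <- glmnet::predict.glmnet(fit, Sigma[test, , drop = FALSE],
                                   s = lambda)
    ss_tot <- sum((beta_hat[test] - mean(beta_hat[test]))^2)
    ss_res <- colSums((beta_hat[test] - pred)^2)
    r2[f, ] <- 1 - ss_res / ss_tot
  }
  list(mean = colMeans(r2), se = apply(r2, 2, stats::sd) / sqrt(n_folds))
}

# Core per-chromosome regularization of a marginal effect-size vector.
.regularize_vector <- function(beta_hat, Sigma, config) {
  J <- length(beta_hat)
  if (nrow(Sigma) != J || ncol(Sigma) != J) {
    rlang::abort("LD matrix dimension does not match effect-size vector",
                 class = "genequad_validation_error")
  }
  if (!all(is.finite(beta_hat)) || !all(is.finite(Sigma))) {
    rlang::abort("non-finite entries in beta_hat or LD matrix",
                 class = "genequad_validation_error")
  }
  alpha <- .glmnet_alpha(config$mixing)
  if (all(beta_hat == 0)) {
    path <- tibble::tibble(lambda = NA_real_, r2 = 0, cv_r2 = 0,
                           cv_se = 0, nonzero = 0L)
    return(list(beta_tilde = numeric(J), chosen_lambda = NA_real_,
                path = path))
  }
  lambda <- .penalty_grid(beta_hat, Sigma, config)
  fit <- .fit_path(beta_hat, Sigma, lambda, alpha)
  coefs <- as.matrix(fit$beta)  # J x n_lambda
  pred <- Sigma %*% coefs
  ss_tot <- sum((beta_hat - mean(beta_hat))^2)
  insample_r2 <- 1 - colSums((beta_hat - pred)^2) / ss_tot
  nonzero <- colSums(coefs != 0)
  cv <- .cv_r2(beta_hat, Sigma, lambda, alpha, config$cv_folds, config$seed)
  best <- which.max(cv$mean)
  idx <- if (config$selection == "one_se") {
    # grid is ordered from the largest penalty down, so the first grid point
    # within one SE of the best is the sparsest acceptable model
    cand <- which(cv$mean >= cv$mean[best] - cv$se[best])
    cand[1L]
  } else {
    best
  }
  path <- tibble::tibble(lambda = fit$lambda, r2 = insample_r2,
                         cv_r2 = cv$mean, cv_se = cv$se,
                         nonzero = as.integer(nonzero))
  list(beta_tilde = as.numeric(coefs[, idx]),
       chosen_lambda = fit$lambda[idx], path = path)
}

#' Regularize marginal effect sizes against the LD matrix
#'
#' Solves the penalized regression of the observed marginal effect sizes on
#' the LD correlation matrix,
#' `argmin || beta_hat - Sigma beta ||^2` subject to a mixed L1/L2 penalty,
#' chromosome by chromosome. Because `E[beta_hat] = Sigma beta` for
#' standardized genotypes, the fitted coefficients are de-inflated estimates
#' of the true additive effects. The penalty is chosen on a 100-point
#' log-scale grid by the one-standard-error rule over cross-validated
#' R-squared (see [regularization_config()]).
#'
#' @param stats Summary-statistics tibble with `snp_id`, `chrom`, `pos`,
#'   `beta_hat` (see [read_summary_stats()]).
#' @param ld A single LD matrix (one chromosome) or a named list of LD
#'   matrices, one per chromosome, each matching that chromosome's SNP order
#'   in `stats`.
#' @param config A [regularization_config()].
#' @return The input tibble with a `beta_tilde` column appended, of class
#'   `genequad_regularized`. Attributes: `paths` (named list of per-chromosome
#'   penalty-path tibbles with columns `lambda`, `r2`, `cv_r2`, `cv_se`,
#'   `nonzero`), `chosen_lambda` (named numeric), `config`.
#' @export
regularize_effects <- function(stats, ld, config = regularization_config()) {
  stats <- validate_summary_stats(stats)
  chroms <- unique(stats$chrom)
  if (is.matrix(ld)) {
    if (length(chroms) != 1) {
      rlang::abort("a single LD matrix was given but stats span multiple chromosomes",
                   class = "genequad_validation_error")
    }
    ld <- stats::setNames(list(ld), chroms)
  }
  if (!all(chroms %in% names(ld))) {
    rlang::abort(paste0("missing LD matrix for chromosome(s): ",
                        paste(setdiff(chroms, names(ld)), collapse = ", ")),
                 class = "genequad_validation_error")
  }
  beta_tilde <- numeric(nrow(stats))
  paths <- list()
  chosen <- stats::setNames(numeric(length(chroms)), chroms)
  for (ch in chroms) {
    rows <- which(stats$chrom == ch)
    Sigma <- ld[[ch]]
    ids <- rownames(Sigma)
    if (!is.null(ids) && !identical(ids, stats$snp_id[rows])) {
      first <- which(ids != stats$snp_id[rows])[1L]
      rlang::abort(
        sprintf("LD/summary-statistics SNP order mismatch on chromosome %s at '%s'",
                ch, ids[min(first, length(ids))]),
        class = "genequad_validation_error"
      )
    }
    res <- .regularize_vector(stats$beta_hat[rows], Sigma, config)
    beta_tilde[rows] <- res$beta_tilde
    paths[[ch]] <- res$path
    chosen[ch] <- res$chosen_lambda
  }
  out <- dplyr::mutate(stats, beta_tilde = beta_tilde)
  structure(out,
            class = c("genequad_regularized", class(out)),
            paths = paths, chosen_lambda = chosen, config = config)
}

#' Closed-form ridge solution of the LD regression
#'
#' The exact minimizer of
#' `|| beta_hat - Sigma beta ||^2 + theta || beta ||^2`, namely
#' `(Sigma' Sigma + theta I)^-1 Sigma' beta_hat`. Also returns the classical
#' linear-shrinkage diagnostic `(Sigma + theta I)^-1 beta_hat`, which
#' approximates the same quantity when Sigma is close to idempotent. Used as
#' an analytic cross-check for the iterative ridge path.
#'
#' @param beta_hat Length-J numeric vector of marginal effects.
#' @param Sigma J x J LD matrix.
#' @param theta Non-negative ridge penalty.
#' @return A list with `coef` (the exact minimizer) and `approx` (the linear
#'   shrinkage form).
#' @export
ridge_closed_form <- function(beta_hat, Sigma, theta) {
  if (theta < 0) {
    rlang::abort("theta must be non-negative",
                 class = "genequad_validation_error")
  }
  J <- length(beta_hat)
  lhs <- crossprod(Sigma) + diag(theta, J)
  coef <- tryCatch(
    as.numeric(solve(lhs, crossprod(Sigma, beta_hat))),
    error = function(e) rlang::abort("singular ridge system",
                                     class = "genequad_numeric_error")
  )
  approx <- tryCatch(
    as.numeric(solve(Sigma + diag(theta, J), beta_hat)),
    error = function(e) rep(NA_real_, J)
  )
  list(coef = coef, approx = approx)
}
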