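#' Simulation scenario configuration
#'
#' Defines a synthetic GWAS: block-LD genotypes, a polygenic quantitative
#' trait with a chosen set of enriched genes carrying all of the
#' narrow-sense heritability, and (optionally) population stratification
#' acting through principal components of the genotype matrix. Defaults
#' mirror the main study conditions: N = 10,000 individuals, heritability
#' 0.6, 10% enriched genes, LD blocks of 10 SNPs with within-block
#' correlation 0.7 and minor-allele frequencies uniform on \[0.05, 0.5\].
#'
#' @param n_individuals Sample size N (default 10000).
#' @param n_snps Number of SNPs J (default 1000); must be a multiple of
#'   `ld_block_size`.
#' @param n_genes Number of non-overlapping genes tiled along the chromosome
#'   (default 200); must divide `n_snps`.
#' @param ld_block_size SNPs per LD block (default 10).
#' @param rho_block Latent within-block correlation (default 0.7).
#' @param maf_range Range minor-allele frequencies are drawn from (default
#'   c(0.05, 0.5)).
#' @param prop_enriched Proportion of genes that are enriched (default 0.1;
#'   the count is `ceiling(prop_enriched * n_genes)`).
#' @param h2 Narrow-sense heritability target in \[0, 1\] (default 0.6).
#' @param stratification Add a population-structure component through
#'   genotype principal components (default FALSE).
#' @param n_pcs Number of top PCs used for stratification (default 10).
#' @param strat_share Fraction of the non-genetic variance `1 - h2` carried
#'   by the stratification component (default 0.5).
#' @param causal_mode `"all"` (default): every SNP in an enriched gene is
#'   causal; `"fixed"`: `causal_per_gene` SNPs per enriched gene, drawn at
#'   random.
#' @param causal_per_gene Causal SNPs per enriched gene when
#'   `causal_mode = "fixed"`.
#' @param seed Seed for all randomness in the scenario.
#' @return A list of class `genequad_sim_config`.
#' @export
sim_config <- function(n_individuals = 10000, n_snps = 1000, n_genes = 200,
                       ld_block_size = 10, rho_block = 0.7,
                       maf_range = c(0.05, 0.5), prop_enriched = 0.1,
                       h2 = 0.6, stratification = FALSE, n_pcs = 10,
                       strat_share = 0.5,
                       causal_mode = c("all", "fixed"), causal_per_gene = 1,
                       seed = 1L) {
  causal_mode <- match.arg(causal_mode)
  if (h2 < 0 || h2 > 1) {
    rlang::abort("h2 must lie in [0, 1]", class = "genequad_validation_error")
  }
  if (prop_enriched <= 0 || prop_enriched > 1) {
    rlang::abort("prop_enriched must lie in (0, 1]",
                 class = "genequad_validation_error")
  }
  if (maf_range[1] <= 0 || maf_range[2] > 0.5) {
    rlang::abort("maf_range must be within (0, 0.5]",
                 class = "genequad_validation_error")
  }
  if (n_snps %% ld_block_size != 0) {
    rlang::abort("n_snps must be a multiple of ld_block_size",
                 class = "genequad_validation_error")
  }
  if (n_snps %% n_genes != 0) {
    rlang::abort("n_snps must be a multiple of n_genes",
                 class = "genequad_validation_error")
  }
  if (stratification && h2 >= 1) {
    rlang::abort("stratification needs a nonzero noise budget (h2 < 1)",
                 class = "genequad_validation_error")
  }
  structure(
    list(n_individuals = as.integer(n_individuals),
         n_snps = as.integer(n_snps), n_genes = as.integer(n_genes),
         ld_block_size = as.integer(ld_block_size), rho_block = rho_block,
         maf_range = maf_range, prop_enriched = prop_enriched, h2 = h2,
         stratification = stratification, n_pcs = as.integer(n_pcs),
         strat_share = strat_share, causal_mode = causal_mode,
         causal_per_gene = as.integer(causal_per_gene),
         seed = as.integer(seed)),
    class = "genequad_sim_config"
  )
}

#' Simulate block-LD genotypes
#'
#' Draws latent multivariate-normal vectors with block-diagonal correlation
#' (constant `rho_block` within blocks, zero across) and thresholds them
#' into `{0, 1, 2}` dosages by Hardy-Weinberg quantiles of a per-SNP
#' minor-allele frequency drawn uniformly from `maf_range`. This reproduces
#' the qualitative feature that matters for the method -- marginal effect
#' sizes inflated by local LD -- without modeling recombination or
#' haplotype history.
#'
#' @param config A [sim_config()].
#' @return A list with `G` (N x J integer dosage matrix, columns named
#'   `snp0001`, ...), `maf` (drawn frequencies) and `block` (block index per
#'   SNP).
#' @export
simulate_genotypes <- function(config) {
  N <- config$n_individuals
  J <- config$n_snps
  B <- config$ld_block_size
  n_blocks <- J / B
  withr::with_seed(config$seed, {
    maf <- stats::runif(J, config$maf_range[1], config$maf_range[2])
    # latent MVN with exchangeable within-block correlation, via the
    # one-factor representation z = sqrt(rho) f_block + sqrt(1-rho) e
    f <- matrix(stats::rnorm(N * n_blocks), N, n_blocks)
    e <- matrix(stats::rnorm(N * J), N, J)
    block <- rep(seq_len(n_blocks), each = B)
    Z <- sqrt(config$rho_block) * f[, block] + sqrt(1 - config$rho_block) * e
    # HWE genotype thresholds: P(0) = (1-p)^2, P(1) = 2p(1-p), P(2) = p^2
    q0 <- stats::qnorm((1 - maf)^2)
    q1 <- stats::qnorm(1 - maf^2)
    G <- matrix(0L, N, J)
    G[Z > rep(q0, each = N)] <- 1L
    G[Z > rep(q1, each = N)] <- 2L
    colnames(G) <- sprintf("snp%04d", seq_len(J))
    list(G = G, maf = maf, block = block)
  })
}

#' Gene map for a simulated chromosome
#'
#' Tiles `n_genes` equal-sized, non-overlapping genes along the simulated
#' chromosome; SNP j sits at position `j * 1000` bp on chromosome "1".
#'
#' @param config A [sim_config()].
#' @return A gene-annotation tibble (`gene_id`, `chrom`, `start`, `end`).
#' @export
sim_gene_annotations <- function(config) {
  spg <- config$n_snps / config$n_genes
  first <- (seq_len(config$n_genes) - 1L) * spg + 1L
  tibble::tibble(
    gene_id = sprintf("gene%03d", seq_len(config$n_genes)),
    chrom = "1",
    start = as.integer(first * 1000L),
    end = as.integer((first + spg - 1L) * 1000L)
  )
}

#' Simulate a polygenic trait over a genotype matrix
#'
#' Selects `ceiling(prop_enriched * n_genes)` enriched genes uniformly at
#' random, designates causal SNPs inside them, draws causal effects from a
#' standard normal, and rescales them so the genetic component explains
#' exactly `h2` of the phenotypic variance in this sample. With
#' stratification on, effects of the top genotype PCs are added and scaled
#' so structure plus noise carry `1 - h2`. The returned trait is
#' standardized to empirical mean 0, variance 1.
#'
#' @param G Genotype matrix from [simulate_genotypes()].
#' @param gene_map Output of [map_snps_to_genes()] on the simulated
#'   annotations (or any tibble with `gene_id` and `snp_indices`).
#' @param config A [sim_config()].
#' @return A list with `y` (standardized trait) and `truth`, a list of class
#'   `genequad_sim_truth`: `causal_snp_indices`, `enriched_gene_ids`,
#'   `true_beta` (standardized-scale effects, zero off the causal set),
#'   `realized_h2`, `gene_h2` (tibble of per-gene variance shares).
#' @export
simulate_trait <- function(G, gene_map, config) {
  N <- nrow(G)
  J <- ncol(G)
  withr::with_seed(config$seed + 1000000L, {
    n_enriched <- ceiling(config$prop_enriched * config$n_genes)
    enriched <- sort(sample(nrow(gene_map), n_enriched))
    causal <- unlist(lapply(enriched, function(g) {
      idx <- gene_map$snp_indices[[g]]
      if (config$causal_mode == "fixed") {
        sort(sample(idx, min(config$causal_per_gene, length(idx))))
      } else idx
    }))
    causal <- sort(unique(causal))

    Gs <- scale(G)
    beta <- numeric(J)
    genetic <- numeric(N)
    if (config$h2 > 0) {
      beta[causal] <- stats::rnorm(length(causal))
      genetic <- as.numeric(Gs[, causal, drop = FALSE] %*% beta[causal])
      sdg <- stats::sd(genetic)
      if (sdg == 0) {
        rlang::abort("degenerate genetic component", class = "genequad_numeric_error")
      }
      scale_g <- sqrt(config$h2) / sdg
      beta <- beta * scale_g
      genetic <- genetic * scale_g
    }
    residual_var <- 1 - config$h2
    structure_part <- numeric(N)
    if (config$stratification) {
      # top PCs of the standardized genotype matrix
      sv <- eigen(crossprod(Gs) / (N - 1), symmetric = TRUE)
      W <- Gs %*% sv$vectors[, seq_len(config$n_pcs), drop = FALSE]
      b <- stats::rnorm(config$n_pcs)
      structure_part <- as.numeric(W %*% b)
      target <- config$strat_share * residual_var
      structure_part <- structure_part * sqrt(target) / stats::sd(structure_part)
      residual_var <- residual_var * (1 - config$strat_share)
    }
    e <- stats::rnorm(N, 0, sqrt(residual_var))
    y_raw <- genetic + structure_part + e
    v_raw <- stats::var(y_raw)
    y <- as.numeric(scale(y_raw))
    realized_h2 <- stats::var(genetic) / v_raw
    # per-gene realized variance share (standardized-y scale)
    gene_h2 <- purrr::map_dbl(gene_map$snp_indices, function(idx) {
      cc <- intersect(idx, causal)
      if (length(cc) == 0) return(0)
      stats::var(as.numeric(Gs[, cc, drop = FALSE] %*% beta[cc])) / v_raw
    })
    truth <- structure(
      list(causal_snp_indices = causal,
           enriched_gene_ids = gene_map$gene_id[enriched],
           true_beta = beta / sqrt(v_raw),
           realized_h2 = realized_h2,
           gene_h2 = tibble::tibble(gene_id = gene_map$gene_id,
                                    h2_g = gene_h2)),
      class = "genequad_sim_truth"
    )
    list(y = y, truth = truth)
  })
}

#' GWAS summary statistics for a simulated dataset
#'
#' Marginal OLS effect sizes of the (standardized) trait on every
#' standardized SNP, with no adjustment for structure covariates -- the
#' realistic mis-specified analysis the method is designed to absorb.
#'
#' @param G Genotype matrix.
#' @param y Trait vector.
#' @param chrom Chromosome label (default "1").
#' @return A summary-statistics tibble (`snp_id`, `chrom`, `pos`,
#'   `beta_hat`, `n`).
#' @export
compute_gwas <- function(G, y, chrom = "1") {
  beta <- ols_effects(G, y)
  ids <- colnames(G)
  if (is.null(ids)) ids <- sprintf("snp%04d", seq_len(ncol(G)))
  tibble::tibble(
    snp_id = ids, chrom = chrom,
    pos = seq_len(ncol(G)) * 1000L,
    beta_hat = as.numeric(beta), n = nrow(G)
  )
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: genotypes, gene map, trait, summary statistics and
#' LD matrix in one call.
#'
#' @param config A [sim_config()].
#' @param keep_genotypes Keep the N x J dosage matrix in the result
#'   (default FALSE to save memory).
#' @return A list with `stats`, `ld`, `genes` (annotations), `gene_map`,
#'   `truth`, `y`, `config`, and optionally `G`.
#' @export
simulate_dataset <- function(config, keep_genotypes = FALSE) {
  geno <- simulate_genotypes(config)
  genes <- sim_gene_annotations(config)
  stats0 <- tibble::tibble(
    snp_id = colnames(geno$G), chrom = "1",
    pos = seq_len(config$n_snps) * 1000L, beta_hat = 0
  )
  gene_map <- map_snps_to_genes(stats0, genes, buffer_bp = 0)
  tr <- simulate_trait(geno$G, gene_map, config)
  stats <- compute_gwas(geno$G, tr$y)
  ld <- compute_ld(geno$G)
  out <- list(stats = stats, ld = ld, genes = genes, gene_map = gene_map,
              truth = tr$truth, y = tr$y, config = config)
  if (keep_genotypes) out$G <- geno$G
  out
}

#' ROC curve from gene p-values and enrichment truth
#'
#' Ranks genes by p-value (ties broken conservatively by averaging is not
#' needed: the sweep is over distinct p-value cutoffs) and traces true
#' positive rate against false positive rate.
#'
#' @param p_values Numeric vector of gene p-values (pooled across replicates
#'   is fine).
#' @param is_enriched Logical vector, TRUE for truly enriched genes.
#' @return A tibble of class `genequad_roc` with columns `threshold`, `tpr`,
#'   `fpr`, and attribute `auc` (trapezoidal).
#' @export
roc_curve <- function(p_values, is_enriched) {
  stopifnot(length(p_values) == length(is_enriched))
  n_pos <- sum(is_enriched)
  n_neg <- sum(!is_enriched)
  if (n_pos == 0 || n_neg == 0) {
    rlang::abort("need both enriched and non-enriched genes for a ROC curve",
                 class = "genequad_validation_error")
  }
  ord <- order(p_values)
  p_sorted <- p_values[ord]
  lab <- is_enriched[ord]
  tp <- cumsum(lab)
  fp <- cumsum(!lab)
  # collapse ties: evaluate at the last index of each distinct p-value
  keep <- c(p_sorted[-1] != p_sorted[-length(p_sorted)], TRUE)
  curve <- tibble::tibble(
    threshold = c(0, p_sorted[keep]),
    tpr = c(0, tp[keep] / n_pos),
    fpr = c(0, fp[keep] / n_neg)
  )
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                  utils::tail(curve$tpr, -1)) / 2)
  structure(curve, class = c("genequad_roc", class(curve)), auc = auc)
}

#' True positive rate at a fixed false positive rate
#'
#' @param roc A `genequad_roc`.
#' @param fpr Target false positive rate (default 0.01).
#' @return The largest TPR achieved at FPR at or below the target.
#' @export
tpr_at_fpr <- function(roc, fpr = 0.01) {
  ok <- roc$fpr <= fpr + 1e-12
  if (!any(ok)) return(0)
  max(roc$tpr[ok])
}

#' Evaluate a genome scan against the simulation truth
#'
#' @param results A `genequad_scan` (or tibble with `gene_id`, `p_value`,
#'   `significant`).
#' @param truth A `genequad_sim_truth`.
#' @param threshold P-value call threshold; defaults to the scan's
#'   Bonferroni threshold.
#' @return A list of class `genequad_eval`: `power` (TP / number of enriched
#'   genes), `fdr` (FP / max(1, calls)), `n_called`, `roc`
#'   (a [roc_curve()]), `auc`, `tpr_at_fpr01`.
#' @export
evaluate_calls <- function(results, truth, threshold = NULL) {
  if (length(truth$enriched_gene_ids) == 0) {
    rlang::abort("truth contains no enriched genes",
                 class = "genequad_validation_error")
  }
  res <- tibble::as_tibble(results)
  res <- dplyr::filter(res, !is.na(.data$p_value))
  if (is.null(threshold)) threshold <- attr(results, "bonferroni")
  # plain tables carry no threshold attribute: default to Bonferroni over
  # the genes actually tested
  if (is.null(threshold)) threshold <- bonferroni_threshold(nrow(res))
  enriched <- res$gene_id %in% truth$enriched_gene_ids
  called <- res$p_value < threshold
  tp <- sum(called & enriched)
  fp <- sum(called & !enriched)
  roc <- roc_curve(res$p_value, enriched)
  structure(
    list(power = tp / length(truth$enriched_gene_ids),
         fdr = fp / max(1, sum(called)),
         n_called = sum(called),
         threshold = threshold,
         roc = roc, auc = attr(roc, "auc"),
         tpr_at_fpr01 = tpr_at_fpr(roc, 0.01)),
    class = "genequad_eval"
  )
}

#' @export
print.genequad_eval <- function(x, ...) {
  cat(sprintf("Scan evaluation: power = %.3f, FDR = %.3f (%d calls at p < %.3g)\n",
              x$power, x$fdr, x$n_called, x$threshold))
  cat(sprintf("  ROC AUC = %.3f, TPR at FPR 0.01 = %.3f\n",
              x$auc, x$tpr_at_fpr01))
  invisible(x)
}
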