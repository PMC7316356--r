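#' Run the full gene-level association pipeline
#'
#' Orchestrates the three stages on summary statistics: (1) regularize
#' marginal effect sizes against the per-chromosome LD matrices, (2) fit the
#' zero-mean Gaussian mixture to the regularized effects and extract the
#' SNP-level null threshold, (3) test every gene with the quadratic-form
#' statistic and Imhof p-values at a Bonferroni threshold over testable
#' genes. All randomness (cross-validation folds, EM restarts) derives from
#' `seed`, so identical inputs and seed give identical outputs, file for
#' file.
#'
#' @param stats Summary-statistics tibble ([read_summary_stats()]).
#' @param ld LD matrix or named per-chromosome list of matrices; SNP order
#'   must match `stats` within each chromosome.
#' @param genes Gene annotations ([read_gene_annotations()]).
#' @param buffer_bp Basepair buffer for SNP-to-gene assignment (default 0).
#' @param reg_config A [regularization_config()]; its seed is overridden by
#'   `seed` when that is supplied.
#' @param K_max Largest mixture size for BIC selection (default 10).
#' @param n_restarts EM restarts (default 10).
#' @param mixture_scope `"per_chromosome"` (default): a null threshold per
#'   chromosome, each gene tested under its own chromosome's threshold;
#'   `"genome_wide"`: one pooled fit.
#' @param A Optional gene-test weight matrix (identity when `NULL`).
#' @param alpha Family-wise error rate (default 0.05).
#' @param p_floor Smallest reportable p-value (default 1e-20).
#' @param seed Master seed (default 1).
#' @param out_dir Optional directory; when given, writes
#'   `regularized_effects.tsv`, `mixture_report.tsv`,
#'   `snp_classification.tsv`, `gene_results.tsv` and `manifest.json`.
#' @return A list of class `genequad_pipeline`: `regularized` (stats tibble
#'   with `beta_tilde`), `mixtures` (named list of `genequad_mixture`),
#'   `thresholds` (named list of `genequad_threshold`), `classification`
#'   (per-SNP tibble), `gene_map`, `scan` (a `genequad_scan`), `seed`.
#' @export
run_pipeline <- function(stats, ld, genes, buffer_bp = 0,
                         reg_config = regularization_config(),
                         K_max = 10, n_restarts = 10,
                         mixture_scope = c("per_chromosome", "genome_wide"),
                         A = NULL, alpha = 0.05, p_floor = 1e-20,
                         seed = 1L, out_dir = NULL) {
  mixture_scope <- match.arg(mixture_scope)
  stats <- validate_summary_stats(stats)
  reg_config$seed <- as.integer(seed)
  chroms <- unique(stats$chrom)
  if (is.matrix(ld)) ld <- stats::setNames(list(ld), chroms)

  regularized <- regularize_effects(stats, ld, reg_config)
  gene_map <- map_snps_to_genes(stats, genes, buffer_bp = buffer_bp)

  mixtures <- list()
  thresholds <- list()
  category <- character(nrow(stats))
  if (mixture_scope == "genome_wide") {
    fit <- select_K(regularized$beta_tilde, K_max = K_max,
                    n_restarts = n_restarts, seed = seed)
    cls <- classify_snps(fit)
    thr <- suppressWarnings(null_threshold(fit))
    for (ch in chroms) {
      mixtures[[ch]] <- fit
      thresholds[[ch]] <- thr
    }
    category <- as.character(cls$category)
  } else {
    for (ch in chroms) {
      rows <- which(stats$chrom == ch)
      fit <- select_K(regularized$beta_tilde[rows], K_max = K_max,
                      n_restarts = n_restarts, seed = seed)
      mixtures[[ch]] <- fit
      thresholds[[ch]] <- suppressWarnings(null_threshold(fit))
      category[rows] <- as.character(classify_snps(fit)$category)
    }
  }
  classification <- tibble::tibble(
    snp_id = stats$snp_id, chrom = stats$chrom,
    category = factor(category, levels = c("associated", "spurious", "zero"))
  )

  scan <- run_scan(regularized, ld, gene_map, thresholds, A = A,
                   alpha = alpha, p_floor = p_floor,
                   snp_category = classification$category)

  out <- structure(
    list(regularized = regularized, mixtures = mixtures,
         thresholds = thresholds, classification = classification,
         gene_map = gene_map, scan = scan, seed = as.integer(seed)),
    class = "genequad_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' Write pipeline result files
#'
#' @param pipeline A `genequad_pipeline`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(pipeline, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(...) file.path(out_dir, ...)
  write_summary_stats(tibble::as_tibble(pipeline$regularized),
                      f("regularized_effects.tsv"))
  mix_report <- dplyr::bind_rows(purrr::imap(pipeline$mixtures, function(m, ch) {
    dplyr::mutate(tidy(m), chrom = ch,
                  sigma2_eps = pipeline$thresholds[[ch]]$sigma2_eps,
                  .before = 1)
  }))
  utils::write.table(mix_report, f("mixture_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(pipeline$classification, f("snp_classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  scan_tab <- dplyr::select(tidy(pipeline$scan), -dplyr::any_of("snp_indices"))
  utils::write.table(scan_tab, f("gene_results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(
    package = "genequad",
    version = as.character(utils::packageVersion("genequad")),
    seed = pipeline$seed,
    bonferroni = attr(pipeline$scan, "bonferroni"),
    n_testable = attr(pipeline$scan, "n_testable"),
    chromosomes = names(pipeline$mixtures),
    thresholds = purrr::map_dbl(pipeline$thresholds, "sigma2_eps")
  )
  jsonlite::write_json(manifest, f("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.genequad_pipeline <- function(x, ...) {
  g <- glance(x$scan)
  cat(sprintf("genequad pipeline: %d SNPs, %d chromosome(s), %d testable genes\n",
              nrow(x$regularized), length(x$mixtures), g$n_testable))
  for (ch in names(x$thresholds)) {
    cat(sprintf("  chr %s: K = %d, null threshold sigma2_eps = %.3g%s\n",
                ch, x$mixtures[[ch]]$K, x$thresholds[[ch]]$sigma2_eps,
                if (x$thresholds[[ch]]$degenerate) " (degenerate)" else ""))
  }
  cat(sprintf("  Bonferroni threshold %.3g; %d significant gene(s)\n",
              g$bonferroni, g$n_significant))
  invisible(x)
}

#' Write a simulated dataset to interchange files
#'
#' Emits the files [run_pipeline()] consumes -- summary statistics TSV, LD
#' matrix with SNP-id sidecar, gene annotations TSV -- plus the ground truth
#' (`truth_genes.tsv`, `truth_snps.tsv`) and a manifest.
#'
#' @param sim Output of [simulate_dataset()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(...) file.path(out_dir, ...)
  write_summary_stats(sim$stats, f("summary_stats.tsv"))
  write_ld_matrix(sim$ld, f("ld_chr1.txt"))
  utils::write.table(sim$genes, f("genes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    tibble::tibble(gene_id = sim$genes$gene_id,
                   enriched = sim$genes$gene_id %in% sim$truth$enriched_gene_ids),
    f("truth_genes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(
    tibble::tibble(snp_id = sim$stats$snp_id,
                   true_beta = sim$truth$true_beta,
                   causal = seq_along(sim$truth$true_beta) %in%
                     sim$truth$causal_snp_indices),
    f("truth_snps.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  manifest <- c(unclass(sim$config),
                list(realized_h2 = sim$truth$realized_h2))
  jsonlite::write_json(manifest, f("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(out_dir)
}
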