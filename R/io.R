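#' Read GWAS summary statistics
#'
#' Reads a tab- or comma-delimited table of SNP-level marginal effect sizes.
#' The file must have a header with at least the columns `snp_id`, `chrom`,
#' `pos` and `beta_hat`; an optional `n` column (the GWAS sample size) is kept
#' as metadata. Rows are returned sorted by `(chrom, pos)`, which is the
#' canonical SNP order used everywhere else in the package (LD matrices must
#' match it).
#'
#' @param path Path to a TSV or CSV file. The delimiter is sniffed from the
#'   header line.
#' @return A tibble with columns `snp_id` (character), `chrom` (character),
#'   `pos` (integer), `beta_hat` (double) and, when present in the file, `n`.
#' @export
read_summary_stats <- function(path) {
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("snp_id", "chrom", "pos", "beta_hat")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("summary-statistics file is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "genequad_format_error"
    )
  }
  beta <- suppressWarnings(as.numeric(raw$beta_hat))
  if (anyNA(beta)) {
    bad <- which(is.na(beta))[1L]
    rlang::abort(
      sprintf("non-numeric beta_hat value '%s' at data line %d",
              raw$beta_hat[bad], bad),
      class = "genequad_parse_error"
    )
  }
  stats <- tibble::tibble(
    snp_id = raw$snp_id,
    chrom = raw$chrom,
    pos = as.integer(raw$pos),
    beta_hat = beta
  )
  if ("n" %in% names(raw)) stats$n <- as.integer(raw$n)
  validate_summary_stats(stats)
}

#' Validate and canonically order summary statistics
#'
#' Checks uniqueness of SNP ids and finiteness of effect sizes, and sorts by
#' `(chrom, pos)`.
#'
#' @param stats A data frame with columns `snp_id`, `chrom`, `pos`, `beta_hat`.
#' @return The validated tibble, sorted by chromosome then position.
#' @export
validate_summary_stats <- function(stats) {
  stats <- tibble::as_tibble(stats)
  if (anyDuplicated(stats$snp_id)) {
    dup <- stats$snp_id[duplicated(stats$snp_id)][1L]
    rlang::abort(sprintf("duplicate snp_id '%s'", dup),
                 class = "genequad_validation_error")
  }
  if (!all(is.finite(stats$beta_hat))) {
    rlang::abort("beta_hat contains non-finite values",
                 class = "genequad_validation_error")
  }
  dplyr::arrange(stats, .data$chrom, .data$pos)
}

#' Write summary statistics (optionally with regularized effects) to TSV
#'
#' @param stats A summary-statistics tibble; any extra columns (for example
#'   `beta_tilde`) are written too.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Empirical LD (correlation) matrix from genotypes
#'
#' Computes the Pearson correlation matrix of genotype columns. Columns are
#' standardized internally, so `{0,1,2}` dosages and pre-standardized real
#' values give identical results. Monomorphic (zero-variance) SNPs are an
#' error rather than being dropped: they must be removed by upstream QC.
#'
#' @param G Numeric matrix, individuals in rows and SNPs in columns. Column
#'   names, when present, become the SNP ids carried on the LD matrix.
#' @return A J x J symmetric correlation matrix with unit diagonal and
#'   `dimnames` set to the SNP ids.
#' @export
compute_ld <- function(G) {
  G <- as.matrix(G)
  if (nrow(G) < 2) {
    rlang::abort("need at least two individuals to estimate LD",
                 class = "genequad_validation_error")
  }
  v <- apply(G, 2, stats::var)
  if (any(v == 0 | !is.finite(v))) {
    bad <- which(v == 0 | !is.finite(v))
    rlang::abort(
      paste0("monomorphic (zero-variance) SNP column(s): ",
             paste(bad, collapse = ", ")),
      class = "genequad_validation_error"
    )
  }
  Gs <- scale(G)
  Sigma <- crossprod(Gs) / (nrow(G) - 1)
  Sigma[Sigma > 1] <- 1
  Sigma[Sigma < -1] <- -1
  diag(Sigma) <- 1
  if (!is.null(colnames(G))) dimnames(Sigma) <- list(colnames(G), colnames(G))
  Sigma
}

#' Validate an LD matrix
#'
#' Checks symmetry (1e-10), unit diagonal (1e-8) and that entries lie in
#' \[-1, 1\] up to small numerical overshoot (which is clipped). Off-diagonal
#' pairs with |r| = 1 (perfect proxies) are reported; when
#' `prune_perfect = TRUE` the higher-index member of each such pair is
#' dropped, matching the assumption that perfectly redundant SNPs have been
#' pruned before analysis.
#'
#' @param Sigma Square numeric matrix.
#' @param prune_perfect Drop one member of each perfect-LD pair (default
#'   `FALSE`, which makes perfect off-diagonal LD an error).
#' @param tol Tolerance for detecting |r| = 1 off the diagonal.
#' @return The validated (possibly pruned, clipped) matrix. When SNPs were
#'   pruned, the kept column indices are attached as attribute `kept`.
#' @export
validate_ld <- function(Sigma, prune_perfect = FALSE, tol = 1e-12) {
  Sigma <- as.matrix(Sigma)
  if (nrow(Sigma) != ncol(Sigma)) {
    rlang::abort("LD matrix must be square", class = "genequad_validation_error")
  }
  if (max(abs(Sigma - t(Sigma))) > 1e-10) {
    rlang::abort("LD matrix is not symmetric within 1e-10",
                 class = "genequad_validation_error")
  }
  if (max(abs(diag(Sigma) - 1)) > 1e-8) {
    rlang::abort("LD matrix diagonal deviates from 1 beyond 1e-8",
                 class = "genequad_validation_error")
  }
  if (max(abs(Sigma)) > 1 + 1e-8) {
    rlang::abort("LD entries outside [-1, 1] beyond numerical overshoot",
                 class = "genequad_validation_error")
  }
  Sigma[Sigma > 1] <- 1
  Sigma[Sigma < -1] <- -1
  diag(Sigma) <- 1
  off <- abs(Sigma) >= 1 - tol
  diag(off) <- FALSE
  if (any(off)) {
    pairs <- which(off, arr.ind = TRUE)
    pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
    if (!prune_perfect) {
      rlang::abort(
        sprintf("%d SNP pair(s) in perfect LD (|r| = 1); prune before analysis",
                nrow(pairs)),
        class = "genequad_validation_error"
      )
    }
    drop <- integer(0)
    for (i in seq_len(nrow(pairs))) {
      # keep the lower index unless it was itself already dropped
      if (!(pairs[i, 1] %in% drop)) drop <- c(drop, pairs[i, 2])
    }
    drop <- sort(unique(drop))
    keep <- setdiff(seq_len(ncol(Sigma)), drop)
    rlang::warn(sprintf("pruned %d SNP(s) in perfect LD with a lower-index SNP",
                        length(drop)))
    Sigma <- Sigma[keep, keep, drop = FALSE]
    attr(Sigma, "kept") <- keep
  }
  Sigma
}

#' Read / write a dense LD matrix with a SNP-id sidecar
#'
#' The matrix is stored as whitespace-delimited text; the sidecar is one SNP
#' id per line, in the same order as the matrix rows (which must match the
#' chromosome's summary-statistics order).
#'
#' @param path Matrix file path.
#' @param snp_ids_path Sidecar path; defaults to `paste0(path, ".snps")`.
#' @return For the reader, the LD matrix with dimnames set from the sidecar.
#' @export
read_ld_matrix <- function(path, snp_ids_path = paste0(path, ".snps")) {
  values <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(values) <- NULL
  if (file.exists(snp_ids_path)) {
    ids <- readLines(snp_ids_path)
    if (length(ids) != nrow(values)) {
      rlang::abort("SNP-id sidecar length does not match LD matrix dimension",
                   class = "genequad_validation_error")
    }
    dimnames(values) <- list(ids, ids)
  }
  validate_ld(values)
}

#' @rdname read_ld_matrix
#' @param Sigma LD matrix to write (dimnames supply the sidecar ids).
#' @export
write_ld_matrix <- function(Sigma, path, snp_ids_path = paste0(path, ".snps")) {
  utils::write.table(Sigma, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(rownames(Sigma))) writeLines(rownames(Sigma), snp_ids_path)
  invisible(path)
}

#' Read gene annotations
#'
#' Two formats are supported: a 1-based inclusive TSV with header
#' `gene_id chrom start end`, or BED (0-based half-open, no header, columns
#' chrom/start/end/name), which is converted to the internal 1-based
#' inclusive convention (`start + 1`, `end`).
#'
#' @param path Annotation file.
#' @param format `"tsv"` or `"bed"`.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based, inclusive).
#' @export
read_gene_annotations <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
    genes <- tibble::tibble(
      gene_id = as.character(raw[[4]]),
      chrom = as.character(raw[[1]]),
      start = as.integer(raw[[2]]) + 1L,
      end = as.integer(raw[[3]])
    )
  } else {
    raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
    genes <- tibble::tibble(
      gene_id = as.character(raw$gene_id),
      chrom = as.character(raw$chrom),
      start = as.integer(raw$start),
      end = as.integer(raw$end)
    )
  }
  if (any(genes$end < genes$start)) {
    bad <- genes$gene_id[genes$end < genes$start][1L]
    rlang::abort(sprintf("gene '%s' has end < start", bad),
                 class = "genequad_validation_error")
  }
  genes
}

#' Map SNPs to genes with an optional basepair buffer
#'
#' A SNP belongs to a gene when its position lies in
#' `[start - buffer_bp, end + buffer_bp]` on the same chromosome. A SNP may
#' belong to several (overlapping or buffered) genes. Genes that capture no
#' SNPs are retained with `testable = FALSE` so the multiple-testing burden
#' counts only genes that can actually be tested.
#'
#' @param stats Summary-statistics tibble (canonical `(chrom, pos)` order;
#'   see [validate_summary_stats()]).
#' @param genes Gene-annotation tibble (`gene_id`, `chrom`, `start`, `end`,
#'   1-based inclusive).
#' @param buffer_bp Non-negative buffer in basepairs added on both sides of
#'   every gene (e.g. 50000 for a +/-50kb window).
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `start`,
#'   `end`, `snp_indices` (list-column of row indices into `stats`, sorted),
#'   `n_snps` and `testable`.
#' @export
map_snps_to_genes <- function(stats, genes, buffer_bp = 0) {
  if (buffer_bp < 0) {
    rlang::abort("buffer_bp must be non-negative",
                 class = "genequad_validation_error")
  }
  stats <- validate_summary_stats(stats)
  genes <- tibble::as_tibble(genes)
  assigned <- purrr::pmap(
    list(genes$chrom, genes$start, genes$end),
    function(chrom, start, end) {
      which(stats$chrom == chrom &
              stats$pos >= start - buffer_bp &
              stats$pos <= end + buffer_bp)
    }
  )
  dplyr::mutate(
    genes,
    snp_indices = assigned,
    n_snps = purrr::map_int(assigned, length),
    testable = .data$n_snps >= 1L
  )
}
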