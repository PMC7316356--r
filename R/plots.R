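#' Manhattan-style plot of a genome scan
#'
#' Gene midpoints against `-log10` p-values, with the Bonferroni threshold
#' drawn as a dashed line and significant genes highlighted.
#'
#' @param object A `genequad_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot genequad_scan
#' @export
autoplot.genequad_scan <- function(object, ...) {
  bonf <- attr(object, "bonferroni")
  df <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$p_value))
  df <- dplyr::mutate(df, midpoint = (.data$start + .data$end) / 2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$midpoint,
                                   y = -log10(.data$p_value),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(bonf), linetype = "dashed") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "gene midpoint (bp)",
                  y = expression(-log[10](italic(p))),
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Plot a fitted effect-size mixture
#'
#' Histogram of the nonzero regularized effects with the fitted zero-mean
#' component densities (weights renormalized to the nonzero mass) overlaid;
#' the null threshold, the variance of the second component, is annotated.
#'
#' @param object A `genequad_mixture`.
#' @param beta_tilde The effect sizes the mixture was fitted to.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot genequad_mixture
#' @export
autoplot.genequad_mixture <- function(object, beta_tilde, ...) {
  x <- beta_tilde[beta_tilde != 0]
  grid <- seq(-max(abs(x)), max(abs(x)), length.out = 400)
  pos <- which(object$sigma2 > 0)
  wsum <- sum(object$pi[pos])
  dens <- purrr::map_dfr(pos, function(k) {
    tibble::tibble(component = factor(k), x = grid,
                   density = object$pi[k] / wsum *
                     stats::dnorm(grid, 0, sqrt(object$sigma2[k])))
  })
  ggplot2::ggplot() +
    ggplot2::geom_histogram(
      data = tibble::tibble(x = x),
      ggplot2::aes(x = .data$x, y = ggplot2::after_stat(density)),
      bins = 60, fill = "grey85", colour = "grey70"
    ) +
    ggplot2::geom_line(
      data = dens,
      ggplot2::aes(x = .data$x, y = .data$density,
                   colour = .data$component)
    ) +
    ggplot2::labs(x = "regularized effect size", y = "density",
                  colour = "component",
                  subtitle = sprintf("null threshold sigma2 = %.3g",
                                     if (object$K >= 2) object$sigma2[2] else NA)) +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object A `genequad_roc` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot genequad_roc
#' @export
autoplot.genequad_roc <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("AUC = %.3f", attr(object, "auc"))) +
    ggplot2::theme_minimal()
}

#' Shrinkage diagnostic: observed versus regularized effects
#'
#' @param regularized Output of [regularize_effects()].
#' @param ... Unused.
#' @return A ggplot object comparing `beta_hat` and `beta_tilde`.
#' @export
plot_shrinkage <- function(regularized, ...) {
  df <- tibble::as_tibble(regularized)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta_hat,
                                   y = .data$beta_tilde)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "marginal OLS effect size",
                  y = "regularized effect size") +
    ggplot2::theme_minimal()
}
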