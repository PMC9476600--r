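#' Plot conditional fold-enrichment curves
#'
#' Nominal `-log10(p)` of the primary trait on the x-axis, fold enrichment
#' relative to the all-SNP baseline on the y-axis, one line per conditional
#' stratum. Under pleiotropic enrichment the lines fan out upward as the
#' conditional cutoff tightens; the baseline sits at 1.
#'
#' @param object An `enrichment_curves` tibble from [fold_enrichment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_curves <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$grid_t, y = .data$fold,
                               colour = factor(.data$stratum_cutoff))) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = expression(nominal ~ -log[10](p)),
      y = "fold enrichment",
      colour = "conditional p ≤",
      title = paste0("Enrichment of ",
                     attr(object, "trait_primary") %||% "primary trait",
                     " | ", attr(object, "trait_conditional") %||%
                       "conditional trait")) +
    ggplot2::theme_minimal()
}

#' Plot conditional Q-Q curves
#'
#' @param pair A `harmonized_pair`.
#' @param primary `"a"` or `"b"`.
#' @param cutoffs Conditional strata cutoffs (see
#'   [stratify_conditional()]).
#' @return A ggplot object.
#' @export
plot_conditional_qq <- function(pair, primary = c("a", "b"),
                                cutoffs = c(1, 0.1, 0.01, 0.001)) {
  qq <- conditional_qq(pair, primary, cutoffs)
  ggplot2::ggplot(qq, ggplot2::aes(x = .data$empirical, y = .data$nominal,
                                   colour = factor(.data$stratum_cutoff))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(empirical ~ -log[10](q)),
                  y = expression(nominal ~ -log[10](p)),
                  colour = "conditional p ≤") +
    ggplot2::theme_minimal()
}

#' Conjunctional Manhattan plot of shared loci
#'
#' Genomic position on the x-axis, `-log10(ccFDR)` on the y-axis.
#'
#' @param object A `shared_loci` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shared_loci <- function(object, ...) {
  mt <- manhattan_table(object)
  ggplot2::ggplot(mt, ggplot2::aes(x = .data$pos,
                                   y = .data$minus_log10_ccfdr)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (bp)", y = expression(-log[10](ccFDR))) +
    ggplot2::theme_minimal()
}
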