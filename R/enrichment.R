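#' Stratify SNPs by conditional-trait significance
#'
#' Splits the harmonized pair into nested strata: for each cutoff `c`, the
#' indices of SNPs whose p-value in the *conditional* trait (the one that
#' is not `primary`) is `<= c`. The first cutoff must be 1, so the first
#' stratum is the all-SNP baseline and the strata form a nested chain.
#' Cross-trait enrichment shows as the primary trait's p-values becoming
#' progressively more significant in tighter strata.
#'
#' @param pair A [harmonize_pair()] result.
#' @param primary `"a"` or `"b"`: the trait whose p-values are examined;
#'   the other trait defines the strata.
#' @param cutoffs Strictly decreasing conditional p-value cutoffs starting
#'   at 1 (default `c(1, 0.1, 0.01, 0.001)`).
#' @return Named list of integer index vectors, one per cutoff.
#' @export
stratify_conditional <- function(pair, primary = c("a", "b"),
                                 cutoffs = c(1, 0.1, 0.01, 0.001)) {
  primary <- match.arg(primary)
  check_cutoffs(cutoffs)
  if (nrow(pair) == 0) stop("pair is empty")
  p_cond <- if (primary == "a") pair$p_b else pair$p_a
  sets <- lapply(cutoffs, function(c) which(p_cond <= c))
  names(sets) <- format(cutoffs, trim = TRUE)
  sets
}

check_cutoffs <- function(cutoffs) {
  if (length(cutoffs) < 1 || cutoffs[1] != 1)
    stop("first cutoff must be 1 (baseline stratum)")
  if (any(diff(cutoffs) >= 0)) stop("cutoffs must be strictly decreasing")
  if (any(cutoffs <= 0)) stop("cutoffs must be positive")
  invisible(cutoffs)
}

#' Empirical Q-Q coordinates for a p-value vector
#'
#' For the order statistics `p_(1) <= ... <= p_(n)` the empirical quantile
#' at rank `r` is \eqn{r/(n+1)} (this convention keeps both axes finite).
#' Returns the paired `-log10` coordinates, sorted so `nominal` ascends; a
#' curve above the identity line means an excess of small p-values.
#'
#' @param pvals P-values in (0, 1], non-empty.
#' @return Tibble with columns `nominal` (`-log10` observed p) and
#'   `empirical` (`-log10 r/(n+1)`).
#' @export
qq_curve <- function(pvals) {
  if (length(pvals) == 0) stop("empty p-value vector")
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("p-values must be in (0, 1]")
  n <- length(pvals)
  p_sorted <- sort(pvals)          # ascending: rank r = position
  tibble::tibble(
    nominal = rev(-log10(p_sorted)),
    empirical = rev(-log10(seq_len(n) / (n + 1))))
}

#' Conditional fold-enrichment curves
#'
#' The workhorse diagnostic for cross-trait enrichment. For each
#' conditional stratum (see [stratify_conditional()]) and each grid point
#' `t` on the nominal `-log10(p)` axis, the fold enrichment is the
#' proportion of stratum SNPs with `-log10 p_primary >= t` divided by the
#' same proportion in the all-SNP baseline. A baseline curve is identically
#' 1; conditional strata rising above 1, the more so the tighter the
#' stratum, reproduce the classic stratified Q-Q "leftward shift" pattern
#' that signals pleiotropic enrichment.
#'
#' Grid points where the baseline has fewer than `min_baseline` exceedances
#' are trimmed (the ratio of two tiny tail counts is noise); empty strata
#' are dropped with a warning.
#'
#' @inheritParams stratify_conditional
#' @param grid Increasing nominal `-log10(p)` values; default 101 equally
#'   spaced points from 0 to the observed maximum (capped at 10).
#' @param min_baseline Minimum baseline exceedance count for a grid point
#'   to be reported (default 10).
#' @return Tibble of class `enrichment_curves` with columns
#'   `stratum_cutoff`, `grid_t`, `fold`, `n_stratum`, `n_exceed`; attribute
#'   `primary` records the direction.
#' @export
#' @examples
#' sim <- simulate_gwas_pair(sim_config(n_snps = 5000, seed = 7))
#' pair <- harmonize_pair(sim$a, sim$b)
#' fe <- fold_enrichment(pair, primary = "a")
#' head(fe)
fold_enrichment <- function(pair, primary = c("a", "b"),
                            cutoffs = c(1, 0.1, 0.01, 0.001),
                            grid = NULL, min_baseline = 10) {
  primary <- match.arg(primary)
  sets <- stratify_conditional(pair, primary, cutoffs)
  p_primary <- if (primary == "a") pair$p_a else pair$p_b
  nlp <- -log10(p_primary)
  if (is.null(grid)) grid <- seq(0, min(10, max(nlp)), length.out = 101)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")

  n_base <- length(sets[[1]])
  if (n_base == 0) stop("baseline stratum is empty")
  # exceedance counts per grid point for an index set, via sorted lookup
  exceed <- function(idx) {
    s <- sort(nlp[idx])
    length(idx) - findInterval(grid, s, left.open = TRUE)
  }
  base_exceed <- exceed(sets[[1]])
  keep_t <- base_exceed >= min_baseline

  curves <- purrr::imap(sets, function(idx, nm) {
    if (length(idx) == 0) {
      warning("stratum at cutoff ", nm, " is empty; curve omitted")
      return(NULL)
    }
    ex <- exceed(idx)
    tibble::tibble(
      stratum_cutoff = as.numeric(nm),
      grid_t = grid[keep_t],
      fold = (ex[keep_t] / length(idx)) / (base_exceed[keep_t] / n_base),
      n_stratum = length(idx),
      n_exceed = ex[keep_t])
  })
  out <- dplyr::bind_rows(curves)
  out <- tibble::new_tibble(out, class = "enrichment_curves")
  attr(out, "primary") <- primary
  attr(out, "trait_primary") <-
    if (primary == "a") attr(pair, "trait_a") else attr(pair, "trait_b")
  attr(out, "trait_conditional") <-
    if (primary == "a") attr(pair, "trait_b") else attr(pair, "trait_a")
  out
}

#' Conditional Q-Q curves for all strata
#'
#' Computes [qq_curve()] of the primary trait's p-values within each
#' conditional stratum, stacked into one tibble for plotting. The leftward/
#' upward shift of tight-stratum curves relative to the baseline is the
#' visual signature of cross-trait enrichment.
#'
#' @inheritParams stratify_conditional
#' @return Tibble with columns `stratum_cutoff`, `nominal`, `empirical`.
#' @export
conditional_qq <- function(pair, primary = c("a", "b"),
                           cutoffs = c(1, 0.1, 0.01, 0.001)) {
  primary <- match.arg(primary)
  sets <- stratify_conditional(pair, primary, cutoffs)
  p_primary <- if (primary == "a") pair$p_a else pair$p_b
  purrr::imap(sets, function(idx, nm) {
    if (length(idx) == 0) return(NULL)
    dplyr::mutate(qq_curve(p_primary[idx]),
                  stratum_cutoff = as.numeric(nm), .before = 1)
  }) |>
    dplyr::bind_rows()
}
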