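CHISQ1_MEDIAN <- qchisq(0.5, df = 1)   # 0.4549364...

#' Genomic inflation factor (lambda-GC)
#'
#' Converts each p-value to its 1-df chi-square statistic via the inverse
#' upper-tail CDF and reports the median chi-square divided by the null
#' median `qchisq(0.5, 1) = 0.4549`. Lambda near 1 indicates a
#' well-calibrated null; lambda above 1 indicates inflation (population
#' stratification, cryptic relatedness, or polygenicity).
#'
#' @param pvals P-values in (0, 1].
#' @return One-row tibble with `lambda` and `n_used`.
#' @export
#' @examples
#' genomic_control_lambda(rep(0.5, 10))  # lambda exactly 1
genomic_control_lambda <- function(pvals) {
  if (length(pvals) == 0) stop("empty p-value vector")
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("p-values must be in (0, 1]")
  chisq <- qchisq(pvals, df = 1, lower.tail = FALSE)
  tibble::tibble(lambda = median(chisq) / CHISQ1_MEDIAN,
                 n_used = length(pvals))
}

#' Genomic control correction of p-values
#'
#' Deflates each p-value's chi-square statistic by `lambda` and maps back
#' to the p scale: `p' = P(chi2_1 > chi2(p) / lambda)`. Lambda below 1 is
#' clamped to 1 — genomic control only ever corrects inflation, never
#' sharpens deflated statistics. The transform is monotone, so SNP ranking
#' is preserved.
#'
#' @param pvals P-values in (0, 1].
#' @param lambda Inflation factor, typically from
#'   [genomic_control_lambda()].
#' @return Corrected p-values, same length and order.
#' @export
gc_correct <- function(pvals, lambda) {
  stopifnot(length(lambda) == 1, is.finite(lambda))
  lambda <- max(lambda, 1)
  if (lambda == 1) return(pvals)
  chisq <- qchisq(pvals, df = 1, lower.tail = FALSE)
  pmax(pchisq(chisq / lambda, df = 1, lower.tail = FALSE), 1e-300)
}

#' Empirical conditional false discovery rate
#'
#' The condFDR of the primary trait given the conditional trait,
#' `cFDR(p_i | p_j) = Pr(H0_i | P_i <= p_i, P_j <= p_j)`, estimated
#' empirically for each SNP k as
#'
#' \deqn{\widehat{cFDR}_k = p_k \cdot
#'   \frac{\#\{m : p^{cond}_m \le p^{cond}_k\}}
#'        {\#\{m : p_m \le p_k,\; p^{cond}_m \le p^{cond}_k\}},}
#'
#' capped at 1. The null fraction is set to 1, making the estimate
#' conservative. All comparisons are inclusive and each SNP counts itself,
#' so the denominator is always at least 1; tied p-values receive identical
#' counts. With vacuous conditioning (`p_cond` all 1) this reduces to the
#' unconditional empirical FDR `p_k * n / rank(p_k)`. The joint counts are
#' computed exactly with an O(n log n) sweep (Fenwick tree over primary-p
#' ranks in conditional-p order), not a grid approximation.
#'
#' @param p_primary P-values of the primary trait, in (0, 1].
#' @param p_cond Aligned p-values of the conditional trait.
#' @return Numeric cFDR vector in (0, 1].
#' @export
#' @examples
#' empirical_cfdr(c(0.001, 0.2, 0.5, 0.04, 0.9),
#'                c(0.002, 0.3, 0.01, 0.5, 0.8))
empirical_cfdr <- function(p_primary, p_cond) {
  n <- length(p_primary)
  if (length(p_cond) != n) stop("p_primary and p_cond must have equal length")
  if (n == 0) stop("empty input")
  check_p <- function(p, nm) {
    if (any(is.na(p)) || any(p <= 0) || any(p > 1))
      stop(nm, " must be in (0, 1]")
  }
  check_p(p_primary, "p_primary"); check_p(p_cond, "p_cond")
  marginal <- rank(p_cond, ties.method = "max")
  joint <- dominance_count(p_primary, p_cond)
  pmin(p_primary * marginal / joint, 1)
}

#' Enforce monotonicity of cFDR in the observed p-values
#'
#' The empirical cFDR estimate can dip as `p_primary` grows (a small-count
#' artefact), which would let a less significant SNP report a better cFDR
#' than a more significant one under equal-or-looser conditioning. This
#' replaces each SNP's value with the running maximum over all SNPs it
#' dominates — those with `p_primary` and `p_cond` both at or below its
#' own — computed exactly with the same O(n log n) sweep as the estimator.
#' Output is elementwise at least the input and still at most 1; already
#' monotone input is a fixed point.
#'
#' @param cfdr cFDR values from [empirical_cfdr()].
#' @param p_primary,p_cond The aligned p-values that produced them.
#' @return Monotone cFDR vector.
#' @export
enforce_monotone <- function(cfdr, p_primary, p_cond) {
  n <- length(cfdr)
  if (length(p_primary) != n || length(p_cond) != n)
    stop("inputs must have equal length")
  if (n == 0) return(cfdr)
  pmin(dominance_max(cfdr, p_primary, p_cond), 1)
}

#' Conjunctional FDR (conjFDR / ccFDR)
#'
#' The conjunctional FDR of a SNP being associated with *both* traits is
#' the maximum of the two reciprocal condFDRs,
#' `ccFDR = max(cFDR(i|j), cFDR(j|i))` — a conservative estimate of the
#' FDR for a pleiotropic SNP. Symmetric in its arguments.
#'
#' @param cfdr_ab cFDR of trait A given trait B.
#' @param cfdr_ba cFDR of trait B given trait A, aligned.
#' @return Elementwise maximum.
#' @export
conjunction_fdr <- function(cfdr_ab, cfdr_ba) {
  if (length(cfdr_ab) != length(cfdr_ba))
    stop("cfdr vectors must have equal length")
  pmax(cfdr_ab, cfdr_ba)
}

#' Full condFDR/conjFDR analysis of a harmonized trait pair
#'
#' Runs the complete statistical pipeline on a [harmonize_pair()] table:
#' per-trait genomic inflation control (lambda estimated from all SNPs,
#' clamped at 1, applied before any conditioning), empirical condFDR in
#' both directions, optional monotonicity enforcement, and the
#' conjunctional FDR.
#'
#' @param pair A `harmonized_pair` tibble.
#' @param gc Apply genomic control to each trait's p-values first
#'   (default `TRUE`).
#' @param monotone Apply [enforce_monotone()] to each condFDR direction
#'   (default `TRUE`).
#' @return Object of class `cfdr_result`: list with `table` (per-SNP
#'   tibble: `snp_id`, `chrom`, `pos`, `p_a`, `p_b`, `p_a_gc`, `p_b_gc`,
#'   `cfdr_a_given_b`, `cfdr_b_given_a`, `ccfdr`), `lambda` (named numeric,
#'   estimated per trait), and the options used. Use [tidy()] for the
#'   per-SNP table and [glance()] for a one-row summary.
#' @export
#' @examples
#' sim <- simulate_gwas_pair(sim_config(n_snps = 2000, seed = 3))
#' fit <- cfdr_analysis(harmonize_pair(sim$a, sim$b))
#' glance(fit)
cfdr_analysis <- function(pair, gc = TRUE, monotone = TRUE) {
  stopifnot(inherits(pair, "harmonized_pair") || all(c("p_a", "p_b") %in% names(pair)))
  lam_a <- genomic_control_lambda(pair$p_a)$lambda
  lam_b <- genomic_control_lambda(pair$p_b)$lambda
  p_a_gc <- if (gc) gc_correct(pair$p_a, lam_a) else pair$p_a
  p_b_gc <- if (gc) gc_correct(pair$p_b, lam_b) else pair$p_b

  cfdr_ab <- empirical_cfdr(p_a_gc, p_b_gc)
  cfdr_ba <- empirical_cfdr(p_b_gc, p_a_gc)
  if (monotone) {
    cfdr_ab <- enforce_monotone(cfdr_ab, p_a_gc, p_b_gc)
    cfdr_ba <- enforce_monotone(cfdr_ba, p_b_gc, p_a_gc)
  }
  tab <- tibble::tibble(
    snp_id = pair$snp_id, chrom = pair$chrom, pos = pair$pos,
    p_a = pair$p_a, p_b = pair$p_b, p_a_gc = p_a_gc, p_b_gc = p_b_gc,
    cfdr_a_given_b = cfdr_ab, cfdr_b_given_a = cfdr_ba,
    ccfdr = conjunction_fdr(cfdr_ab, cfdr_ba))
  structure(list(table = tab,
                 lambda = c(a = lam_a, b = lam_b),
                 gc = gc, monotone = monotone,
                 trait_a = attr(pair, "trait_a") %||% "trait_a",
                 trait_b = attr(pair, "trait_b") %||% "trait_b"),
            class = "cfdr_result")
}

#' @export
print.cfdr_result <- function(x, ...) {
  cat("condFDR/conjFDR analysis:", x$trait_a, "vs", x$trait_b, "\n")
  cat(sprintf("  %d SNPs; lambda_GC = %.3f (A), %.3f (B); gc=%s, monotone=%s\n",
              nrow(x$table), x$lambda["a"], x$lambda["b"], x$gc, x$monotone))
  cat(sprintf("  SNPs at ccFDR < 0.01: %d\n", sum(x$table$ccfdr < 0.01)))
  invisible(x)
}

#' @rdname cfdr_analysis
#' @param x A `cfdr_result`.
#' @param ... Unused.
#' @export
tidy.cfdr_result <- function(x, ...) x$table

#' @rdname cfdr_analysis
#' @export
glance.cfdr_result <- function(x, ...) {
  tibble::tibble(
    n_snps = nrow(x$table),
    lambda_a = unname(x$lambda["a"]),
    lambda_b = unname(x$lambda["b"]),
    min_ccfdr = min(x$table$ccfdr),
    n_ccfdr_lt_0.01 = sum(x$table$ccfdr < 0.01))
}
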