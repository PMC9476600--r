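#' Configuration for the two-trait summary-statistics simulator
#'
#' Describes a four-groups mixture over SNPs: null in both traits, non-null
#' in trait A only, in trait B only, or in both (the pleiotropic class).
#' Per trait, a non-null SNP's z-score gains extra variance `sigma2` on top
#' of the unit sampling variance (the scaled-normal two-groups model the
#' condFDR literature is built on); optional genomic inflation multiplies
#' z-squared by `lambda`, and a fraction of rsIDs can be emitted twice to
#' exercise deduplication.
#'
#' Defaults describe a polygenic pair of traits with modest overlap: 97% of
#' SNPs null everywhere, 1% specific to each trait, 1% shared, non-null
#' effect variance 16 (typical hits around |z| = 4), no inflation, no
#' duplicate contamination.
#'
#' @param n_snps Number of SNPs.
#' @param pi_null,pi_a_only,pi_b_only,pi_shared Mixture fractions; must sum
#'   to 1.
#' @param sigma2_a,sigma2_b Non-null effect-size variance per trait
#'   (variance of z is `1 + sigma2` for non-null SNPs).
#' @param lambda_a,lambda_b Genomic inflation factors (>= 1) multiplying
#'   z-squared.
#' @param dup_fraction Fraction of rsIDs emitted a second time (independent
#'   noise redraw, same class and position).
#' @param seed Integer seed; simulation is bit-reproducible given the
#'   config.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 10000,
                       pi_null = 0.97, pi_a_only = 0.01, pi_b_only = 0.01,
                       pi_shared = 0.01,
                       sigma2_a = 16, sigma2_b = 16,
                       lambda_a = 1, lambda_b = 1,
                       dup_fraction = 0, seed = 1L) {
  cfg <- list(n_snps = as.integer(n_snps), pi_null = pi_null,
              pi_a_only = pi_a_only, pi_b_only = pi_b_only,
              pi_shared = pi_shared, sigma2_a = sigma2_a,
              sigma2_b = sigma2_b, lambda_a = lambda_a,
              lambda_b = lambda_b, dup_fraction = dup_fraction,
              seed = as.integer(seed))
  fr <- c(cfg$pi_null, cfg$pi_a_only, cfg$pi_b_only, cfg$pi_shared)
  if (cfg$n_snps < 1) stop("n_snps must be >= 1")
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-12)
    stop("mixture fractions must be non-negative and sum to 1")
  if (cfg$sigma2_a < 0 || cfg$sigma2_b < 0) stop("sigma2 must be >= 0")
  if (cfg$lambda_a < 1 || cfg$lambda_b < 1) stop("lambda must be >= 1")
  if (cfg$dup_fraction < 0 || cfg$dup_fraction >= 1)
    stop("dup_fraction must be in [0, 1)")
  structure(cfg, class = "sim_config")
}

#' Two-sided p-value of a z-score
#'
#' `p = 2 * (1 - Phi(|z|))`, evaluated on the log scale internally so very
#' large |z| does not underflow to an exact zero; results are clamped to a
#' 1e-300 floor (p-values of exactly 0 would break -log10 transforms and
#' the chi-square inversion used by genomic control).
#'
#' @param z Numeric vector of z-scores (finite).
#' @return P-values in (0, 1].
#' @export
#' @examples
#' z_to_p(0)         # 1
#' z_to_p(1.959964)  # 0.05
z_to_p <- function(z) {
  if (any(!is.finite(z))) stop("z must be finite")
  p <- 2 * pnorm(abs(z), lower.tail = FALSE)
  pmin(pmax(p, 1e-300), 1)
}

#' Simulate a pair of GWAS summary-statistics tables with known pleiotropy
#'
#' Draws each SNP's class from the four-groups multinomial of
#' [sim_config()], samples independent z-scores per trait with extra
#' variance where the trait is non-null, applies optional genomic inflation
#' (z-squared scaled by lambda), converts to two-sided p-values, and emits
#' two canonical summary-statistics tables plus the ground-truth class
#' labels. SNPs sit at unit spacing on a single synthetic chromosome "1":
#' downstream locus logic needs coordinates, not realism. There is no LD
#' and no sample-overlap correlation between the traits; conditional on
#' class, the two traits' z-scores are independent.
#'
#' @param config A [sim_config()].
#' @return List of class `gwas_sim` with elements `a`, `b`
#'   (summary-statistics tibbles), `truth` (tibble `snp_id`, `class` with
#'   one row per distinct SNP), and `config`.
#' @export
#' @examples
#' sim <- simulate_gwas_pair(sim_config(n_snps = 1000, seed = 42))
#' table(sim$truth$class)
simulate_gwas_pair <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  n <- config$n_snps
  classes <- c("null", "a_only", "b_only", "shared")
  class <- sample(classes, n, replace = TRUE,
                  prob = c(config$pi_null, config$pi_a_only,
                           config$pi_b_only, config$pi_shared))
  draw_z <- function(nonnull, sigma2, lambda) {
    z <- rnorm(n, 0, sqrt(1 + sigma2 * nonnull))
    z * sqrt(lambda)
  }
  z_a <- draw_z(class %in% c("a_only", "shared"), config$sigma2_a, config$lambda_a)
  z_b <- draw_z(class %in% c("b_only", "shared"), config$sigma2_b, config$lambda_b)

  snp_id <- sprintf("rs%d", seq_len(n))
  mk_table <- function(p, trait) {
    out <- tibble::tibble(snp_id = snp_id, chrom = "1", pos = seq_len(n),
                          pvalue = p)
    attr(out, "trait_name") <- trait
    out
  }
  a <- mk_table(z_to_p(z_a), "trait_a")
  b <- mk_table(z_to_p(z_b), "trait_b")

  if (config$dup_fraction > 0) {
    k <- floor(config$dup_fraction * n)
    if (k > 0) {
      idx <- sample.int(n, k)
      redraw <- function(tab, sigma2, lambda, nonnull) {
        z <- rnorm(k, 0, sqrt(1 + sigma2 * nonnull[idx])) * sqrt(lambda)
        dup <- tab[idx, ]
        dup$pvalue <- z_to_p(z)
        out <- dplyr::bind_rows(tab, dup)
        attr(out, "trait_name") <- attr(tab, "trait_name")
        out
      }
      a <- redraw(a, config$sigma2_a, config$lambda_a,
                  class %in% c("a_only", "shared"))
      b <- redraw(b, config$sigma2_b, config$lambda_b,
                  class %in% c("b_only", "shared"))
    }
  }

  structure(list(a = a, b = b,
                 truth = tibble::tibble(snp_id = snp_id, class = class),
                 config = config),
            class = "gwas_sim")
}
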