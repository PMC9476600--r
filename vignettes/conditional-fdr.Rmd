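---
title: "Conditional and conjunctional FDR for cross-trait pleiotropy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional and conjunctional FDR for cross-trait pleiotropy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleioconj)
```

## The model

The package works on nothing but two per-SNP p-value vectors. The implicit
generative picture is a four-groups mixture: each SNP is null for both
traits, non-null for one of them, or non-null for both (pleiotropic). Under
the null a two-sided association p-value is Uniform(0, 1); under the
alternative it concentrates near 0. If the pleiotropic class is non-empty,
the conditional distribution of trait A's p-values among SNPs that are
significant for trait B shifts toward 0 — which is exactly what the two
inferential tools here measure:

- **Stratified fold enrichment** (`fold_enrichment()`): for the stratum
  $\{p_B \le c\}$ and a nominal threshold $t$ on $-\log_{10} p_A$,
  $$\mathrm{fold}(c, t) =
    \frac{\#\{k \in S_c : -\log_{10} p_{A,k} \ge t\} / |S_c|}
         {\#\{k : -\log_{10} p_{A,k} \ge t\} / n}.$$
  Curves above 1 that fan out as $c$ tightens are the classic visual
  signature of cross-trait enrichment.

- **condFDR / conjFDR** (`empirical_cfdr()`, `conjunction_fdr()`): the
  conditional FDR $\mathrm{cFDR}(p_i \mid p_j) =
  \Pr(H_0^{(i)} \mid P_i \le p_i, P_j \le p_j)$ is estimated for SNP $k$ by
  $$\widehat{\mathrm{cFDR}}_k = p_{i,k}\,
    \frac{\#\{m : p_{j,m} \le p_{j,k}\}}
         {\#\{m : p_{i,m} \le p_{i,k},\ p_{j,m} \le p_{j,k}\}} \wedge 1 ,$$
  i.e. $p_i$ divided by the empirical conditional CDF of $p_i$ given the
  conditioning event, with the null fraction $\pi_0$ set to 1. The
  conjunctional FDR is the maximum of the two reciprocal condFDRs and is a
  conservative FDR for association with *both* traits.

Key assumptions: p-values are valid (uniform or stochastically larger under
the null), SNPs are treated as exchangeable observations (no LD weighting),
and the two studies share no systematic confounding beyond what genomic
control absorbs. Only p-values are used — signed effects never enter — so
no allele or strand harmonisation is performed and none is needed.

## Estimator conventions

Several small choices fix the estimator's behaviour; all are tested against
independent brute-force oracles.

- **Inclusive counting and self-counting.** All threshold comparisons are
  $\le$ and SNP $k$ is included in its own counts, so the denominator is
  at least 1 and $\widehat{\mathrm{cFDR}}_k \ge p_{i,k}$. Ties in p share
  identical counts; no randomised tie-breaking.
- **$\pi_0 = 1$.** The null-fraction factor is omitted rather than
  estimated. This makes every reported cFDR an upper bound and removes a
  density-estimation step that would be unstable at desk scale; the cost
  is reduced sensitivity (see *Operating characteristics*).
- **Exact counting, not a grid.** The joint counts are a 2-D dominance
  count, computed exactly in $O(n \log n)$ with a Fenwick tree swept in
  conditional-p order (tied groups inserted before any member queries).
  An interpolation grid would be faster per evaluation but introduces an
  approximation whose error concentrates exactly where calls are made (the
  joint tail); exactness also lets tests assert bit-equality with the
  naive $O(n^2)$ oracle at every scale.
- **Monotonicity enforcement** (`enforce_monotone()`). The raw estimate
  can dip as $p_i$ grows (small-count artefact). Each value is replaced by
  the running maximum over all SNPs it dominates (both p-values at or
  below its own) — the same exact sweep with a max-tree. This is
  idempotent, never decreases a value, and never pushes one above 1.
- **Reduction check.** With vacuous conditioning ($p_j \equiv 1$) the
  estimator collapses to the unconditional empirical FDR
  $p_k \, n / \mathrm{rank}(p_k)$, which anchors it to the familiar
  Benjamini–Hochberg quantity.
- **Genomic control.** $\lambda = \mathrm{median}(\chi^2) / q_{\chi^2_1}(0.5)$
  with the analytic null median `qchisq(0.5, 1)` ≈ 0.4549; correction
  divides each SNP's $\chi^2_1$ statistic by $\lambda$ and maps back. It
  is applied per trait before conditioning, and $\lambda < 1$ is clamped
  to 1 — the procedure only ever weakens evidence. With polygenic signal
  present the median-based $\lambda$ slightly exceeds 1, so the correction
  is mildly conservative by construction.
- **Numerical floors.** P-values of exactly 0 in input files are clamped
  at read time to 0.1 × the smallest positive p in the table;
  `z_to_p()` and `gc_correct()` floor at 1e-300. All are logged; nothing
  downstream ever sees $p = 0$.

## Calling and annotation

A **shared locus** is a SNP with ccFDR < 0.01 *and* $p <$ 1e-5 in both
traits, all strict inequalities (matching the "< 0.01" / "< 1e-5"
convention of the motivating analysis). Loci are SNP-level: the motivating
study reported 49 SNPs in one chromosome-11 region as 49 loci without LD
clumping, and this package follows suit. Duplicate rsIDs are averaged
twice, deliberately: at ingest (`dedupe_mean_p()`, mean p-value) and after
calling (`average_duplicate_ccfdr()`, mean ccFDR) — the upstream
prescription "average multiple ccFDR values" does not say at which stage
duplicates arose, so both stages are defensive.

Nearest-gene annotation takes a user-supplied BED/GFF3 interval file (read
via `rtracklayer`, so BED's 0-based half-open coordinates become the
package-wide 1-based inclusive convention). A SNP inside one or more gene
intervals gets all of them (ascending start); otherwise the gene(s) at
minimal distance $\max(\mathrm{start} - \mathrm{pos}, \mathrm{pos} -
\mathrm{end})$, with exact ties all kept and serialized comma-joined
("SPI1, MYBPC3"-style). The packaged published locus table is treated as
*data*: its gene assignments came from a curated database lookup, not from
this algorithm, so tests never compare the two.

## The simulator, and what passing tests mean

`simulate_gwas_pair()` draws each SNP's class from the four-groups
multinomial, then per trait $z \sim N(0, 1 + \sigma^2 \cdot
\mathbb{1}[\text{non-null}])$, independently across traits given class;
inflation multiplies $z^2$ by $\lambda \ge 1$; $p = 2(1 - \Phi(|z|))$.
Defaults: 97% doubly-null, 1% per trait-specific class, 1% shared,
$\sigma^2 = 16$ (typical non-null hits around $|z| = 4$, the edge of
genome-wide significance at desk-scale SNP counts), no inflation, no
duplicates. Positions are 1..n on one synthetic chromosome — locus logic
needs coordinates, not realism.

The simulator deliberately omits: LD (SNPs are independent), realistic
allele frequencies, ancestry structure, and sample overlap between the two
studies (shared controls induce cross-trait correlation of the *null*
z-scores, which would inflate enrichment; no correction is attempted here,
as none was specified upstream). Passing tests therefore demonstrate that
the estimator and caller are correct and calibrated *for independent SNPs
and independent studies*; they do not certify behaviour under strong LD or
overlapping cohorts, where conditional enrichment can arise without true
pleiotropy.

## Operating characteristics and problem sizes

The test suite fixes these study conditions (chosen once, stated here as
the package's own choices):

- **Null calibration**: 100,000 SNPs, all doubly null. Zero loci are called
  at ccFDR < 0.01 with dual p < 1e-5 (the suite allows at most 5).
- **Recovery**: 100,000 SNPs, 1% shared (trait-specific fractions set to
  zero so the recovery measurement isolates the pleiotropic class),
  $\sigma^2 = 25$. The empirical false-sharing proportion among SNPs with
  ccFDR < 0.05 stays below 10%, and fold-enrichment at $t = 3$ is above 1
  and strictly ordered by stratum stringency. Sensitivity at these
  conditions is modest (≈ 0.42–0.47 across seeds, recomputed by
  `scripts/acceptance.R`): with $\pi_0 = 1$ and inclusive counting, a
  shared SNP needs roughly $p \lesssim 0.015$ in *both* traits to clear
  ccFDR < 0.05, and at $\sigma^2 = 25$ only ~40–45% of shared SNPs do.
  This is the price of the conservative estimator, not a defect of the
  counting (which is oracle-exact); power rises steeply with effect
  variance (tested monotone over $\sigma^2 \in \{9, 16, 25\}$).
- **Enrichment flatness**: under zero sharing, fold curves stay within
  [0.8, 1.25] wherever both tail counts are well supported — with the
  caveat that conditioning also *dilutes* the primary trait's signal
  share, an effect proportional to the trait-specific non-null fractions;
  the envelope is checked at 1% fractions, where dilution is ≈ 5%.
- **Oracle equivalence**: 200+ random instances up to n = 500 compare the
  Fenwick-tree counting and monotone enforcement bit-for-bit against naive
  $O(n^2)$ oracles, with heavy-tie instances included.

Grid and trimming choices for enrichment curves: 101 equally spaced grid
points on $[0, \min(10, \max -\log_{10} p)]$; grid points with fewer than
10 baseline exceedances are trimmed (a ratio of two tiny tail counts is
noise); empty strata are dropped with a warning.

## Known limitations

- No LD model anywhere: clumping, pruning and LD-aware weighting are out of
  scope, so in real data the "49 loci" style of SNP-level calling counts
  correlated SNPs repeatedly.
- No genetic-correlation estimator ($r_g$): enrichment curves are the only
  global overlap summary surfaced.
- $\pi_0 = 1$ makes all FDR quantities upper bounds; users wanting tighter
  estimates need a null-fraction estimator, which is deliberately not
  included.
- Genomic control is median-based and per trait; intercept-based
  alternatives (e.g. LD-score intercepts) require LD information this
  package does not consume.
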