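# Independent brute-force oracles used to validate the production
# implementations. Deliberately naive (O(n^2) / exhaustive) and written
# without reference to the package internals.

# cFDR[k] = p[k] * #{q_m <= q_k} / #{p_m <= p_k & q_m <= q_k}, capped at 1
brute_cfdr <- function(p, q) {
  n <- length(p)
  out <- numeric(n)
  for (k in seq_len(n)) {
    marg <- sum(q <= q[k])
    joint <- sum(p <= p[k] & q <= q[k])
    out[k] <- min(1, p[k] * marg / joint)
  }
  out
}

# out[k] = max{ v_m : p_m <= p_k & q_m <= q_k }
brute_monotone <- function(v, p, q) {
  n <- length(v)
  out <- numeric(n)
  for (k in seq_len(n)) {
    out[k] <- min(1, max(v[p <= p[k] & q <= q[k]]))
  }
  out
}

# exhaustive nearest-gene lookup for a single position
brute_nearest <- function(chrom, pos, ann) {
  ann <- ann[ann$chrom == chrom, , drop = FALSE]
  if (nrow(ann) == 0) return(NA_character_)
  d <- pmax(ann$start - pos, pos - ann$end, 0)
  hit <- ann[d == min(d), , drop = FALSE]
  hit$gene_symbol[order(hit$start)]
}

# small canonical sumstats tibble for IO tests
make_sumstats <- function(n = 5, seed = 1, trait = "toy") {
  set.seed(seed)
  out <- tibble::tibble(
    snp_id = sprintf("rs%d", seq_len(n)),
    chrom = "1",
    pos = seq_len(n) * 100L,
    pvalue = round(runif(n), 6))
  attr(out, "trait_name") <- trait
  out
}

write_toy_file <- function(df, header = c("SNP", "CHR", "BP", "P"), ...) {
  f <- tempfile(fileext = ".tsv")
  names(df)[seq_along(header)] <- header
  readr::write_tsv(df, f, progress = FALSE)
  f
}
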