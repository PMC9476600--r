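toy_annotation <- function() {
  tibble::tibble(
    gene_symbol = c("G1", "G2", "G3"),
    chrom = c("1", "1", "2"),
    start = c(100L, 500L, 10L),
    end = c(200L, 600L, 50L),
    strand = "+")
}

make_result_pair <- function(p_a, p_b, ccfdr) {
  n <- length(p_a)
  pair <- tibble::new_tibble(
    tibble::tibble(snp_id = sprintf("rs%d", seq_len(n)), chrom = "1",
                   pos = seq_len(n), p_a = p_a, p_b = p_b),
    class = "harmonized_pair")
  tab <- tibble::tibble(snp_id = pair$snp_id, chrom = pair$chrom,
                        pos = pair$pos, p_a = p_a, p_b = p_b,
                        p_a_gc = p_a, p_b_gc = p_b,
                        cfdr_a_given_b = ccfdr, cfdr_b_given_a = ccfdr,
                        ccfdr = ccfdr)
  list(pair = pair, tab = tab)
}

test_that("locus calling applies all three strict filters", {
  x <- make_result_pair(p_a = c(1e-6, 1e-6, 1e-6, 2e-5),
                        p_b = c(2e-6, 2e-5, 1e-6, 1e-6),
                        ccfdr = c(0.005, 0.005, 0.02, 0.005))
  loci <- call_shared_loci(x$pair, x$tab)
  expect_equal(loci$snp_id, "rs1")   # rs2 fails p_b, rs3 fails ccfdr, rs4 fails p_a
  # boundary values fail strict inequalities
  y <- make_result_pair(1e-5, 1e-6, 0.01)
  expect_equal(nrow(call_shared_loci(y$pair, y$tab)), 0)
  expect_error(call_shared_loci(x$pair[1:2, ], x$tab), "aligned")
})

test_that("calling is a pure filter, invariant to input order, verified by refilter", {
  set.seed(77)
  sim <- simulate_gwas_pair(sim_config(
    n_snps = 20000, pi_null = 0.98, pi_a_only = 0, pi_b_only = 0,
    pi_shared = 0.02, sigma2_a = 25, sigma2_b = 25, seed = 77))
  pair <- harmonize_pair(sim$a, sim$b)
  fit <- cfdr_analysis(pair)
  loci <- call_shared_loci(pair, fit)
  tab <- tidy(fit)
  manual <- tab$snp_id[tab$ccfdr < 0.01 & tab$p_a_gc < 1e-5 & tab$p_b_gc < 1e-5]
  expect_setequal(loci$snp_id, manual)
  expect_true(all(loci$snp_id %in% pair$snp_id))
})

test_that("planted strong shared SNPs are always called at default thresholds", {
  sim <- simulate_gwas_pair(sim_config(
    n_snps = 50000, pi_null = 0.99, pi_a_only = 0, pi_b_only = 0,
    pi_shared = 0.01, sigma2_a = 36, sigma2_b = 36, seed = 123))
  pair <- harmonize_pair(sim$a, sim$b)
  fit <- cfdr_analysis(pair)
  strong <- sim$truth$snp_id[sim$truth$class == "shared"]
  strong <- intersect(strong,
                      pair$snp_id[pair$p_a < 1e-8 & pair$p_b < 1e-8])
  expect_gt(length(strong), 10)   # the seeded instance plants plenty
  loci <- call_shared_loci(pair, fit)
  expect_true(all(strong %in% loci$snp_id))
})

test_that("duplicate ccFDR values are averaged per rsID, idempotently", {
  loci <- tibble::new_tibble(tibble::tibble(
    snp_id = c("rsX", "rsX", "rsY"), chrom = "1", pos = c(10L, 10L, 20L),
    p_a = 1e-6, p_b = 1e-6, ccfdr = c(0.004, 0.006, 0.002)),
    class = "shared_loci")
  out <- average_duplicate_ccfdr(loci)
  expect_equal(nrow(out), 2)
  expect_equal(out$ccfdr[out$snp_id == "rsX"], 0.005)
  expect_equal(average_duplicate_ccfdr(out), out)

  # same rsID at different positions: kept separate with a warning
  loci$pos <- c(10L, 99L, 20L)
  expect_warning(out2 <- average_duplicate_ccfdr(loci), "different positions")
  expect_equal(nrow(out2), 3)
})

test_that("nearest-gene annotation handles containment, ties, and missing chromosomes", {
  ann <- toy_annotation()
  loci <- tibble::new_tibble(tibble::tibble(
    snp_id = c("a", "b", "c"), chrom = c("1", "1", "3"),
    pos = c(150L, 350L, 5L), p_a = 1e-6, p_b = 1e-6, ccfdr = 0.001),
    class = "shared_loci")
  expect_warning(out <- annotate_nearest_gene(loci, ann), "absent")
  expect_equal(out$closest_genes[[1]], "G1")          # inside G1
  expect_equal(out$closest_genes[[2]], c("G1", "G2")) # equidistant (150 each)
  expect_equal(out$closest_gene_label[2], "G1, G2")
  expect_equal(out$closest_genes[[3]], "NA")          # chrom 3 unannotated
})

test_that("annotation agrees with the exhaustive minimum-distance oracle", {
  set.seed(31)
  for (i in 1:15) {
    ng <- sample(2:50, 1)
    starts <- sort(sample.int(10000, ng))
    ann <- tibble::tibble(
      gene_symbol = sprintf("g%02d", seq_len(ng)),
      chrom = sample(c("1", "2"), ng, replace = TRUE),
      start = starts, end = starts + sample.int(300, ng), strand = "+")
    loci <- tibble::new_tibble(tibble::tibble(
      snp_id = sprintf("rs%d", 1:20), chrom = sample(c("1", "2"), 20, TRUE),
      pos = sample.int(11000, 20), p_a = 1e-6, p_b = 1e-6, ccfdr = 0.001),
      class = "shared_loci")
    loci <- loci[loci$chrom %in% ann$chrom, ]
    out <- annotate_nearest_gene(loci, ann)
    for (k in seq_len(nrow(out))) {
      expect_equal(out$closest_genes[[k]],
                   brute_nearest(out$chrom[k], out$pos[k], ann))
    }
  }
})

test_that("the packaged BED annotation reads as 1-based inclusive intervals", {
  bed <- system.file("extdata", "toy_genes.bed", package = "pleioconj")
  ann <- read_gene_annotation(bed)
  expect_true(all(c("SPI1", "MTCH2", "AGBL2") %in% ann$gene_symbol))
  spi1 <- ann[ann$gene_symbol == "SPI1", ]
  expect_equal(spi1$start, 47350001)    # BED 0-based start converted
  expect_equal(spi1$end, 47380000)
})

test_that("unique gene set is the sorted union of annotations", {
  loci <- load_table1_fixture()
  genes <- unique_gene_set(loci)
  expect_length(genes, 11)
  expect_equal(genes, sort(genes))
  expect_equal(unique_gene_set(loci[0, ]), character(0))
  one <- loci[2, ]
  expect_equal(unique_gene_set(one), "SPI1")
})

test_that("Manhattan coordinates are -log10(ccFDR) in genomic order", {
  loci <- load_table1_fixture()
  mt <- manhattan_table(loci)
  expect_equal(mt$minus_log10_ccfdr[mt$snp_id == "rs11039199"],
               -log10(9.99e-6), tolerance = 1e-9)
  expect_gt(mt$minus_log10_ccfdr[mt$snp_id == "rs11039199"], 5.0003)
  expect_equal(mt$pos, sort(mt$pos))
  simple <- loci[1, ]; simple$ccfdr <- 0.01
  expect_equal(manhattan_table(simple)$minus_log10_ccfdr, 2)
  bad <- loci[1, ]; bad$ccfdr <- 0
  expect_error(manhattan_table(bad), "positive")
})

test_that("replication overlap reports counts and Jaccard index", {
  a <- tibble::tibble(snp_id = c("r1", "r2", "r3"))
  b <- tibble::tibble(snp_id = c("r2", "r3", "r4", "r5"))
  ov <- replication_overlap(a, b)
  expect_equal(ov$n_intersect, 2)
  expect_equal(ov$n_union, 5)
  expect_equal(ov$jaccard, 0.4)
  expect_equal(sort(ov$shared_ids[[1]]), c("r2", "r3"))
  expect_equal(replication_overlap(a, a)$jaccard, 1)
  expect_equal(replication_overlap(a, tibble::tibble(snp_id = "zz"))$jaccard, 0)
})

test_that("the published locus fixture loads exactly as printed", {
  loci <- load_table1_fixture()
  expect_equal(nrow(loci), 49)
  expect_equal(loci$snp_id[1], "rs2856661")
  expect_equal(loci$chrom[1], "11")
  expect_equal(loci$pos[1], 47374998L)
  expect_equal(loci$closest_genes[[1]], c("SPI1", "MYBPC3"))
  expect_equal(loci$ccfdr[1], 2.59e-5)
  expect_equal(loci$snp_id[29], "rs1317164")
  expect_equal(loci$pos[29], 47419757L)
  expect_equal(loci$closest_genes[[29]], "MTCH2")
  expect_equal(loci$ccfdr[29], 9.46e-6)
  t2 <- load_table2_fixture()
  expect_equal(nrow(t2), 11)
  expect_setequal(t2$gene_symbol, unique_gene_set(loci))
})
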