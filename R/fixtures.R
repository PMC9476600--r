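#' Published shared AD-glaucoma loci (packaged table)
#'
#' Loads the packaged transcription of the published table of 49 pleiotropic
#' SNPs shared between Alzheimer's disease and glaucoma (all in one region
#' of chromosome 11), each with its genomic position, closest gene(s) as
#' assigned in the original study, and conjunctional FDR (ccFDR). These
#' values are data, not output of this package's annotation algorithm: the
#' original gene assignments came from a curated database lookup.
#'
#' @return Tibble with 49 rows and columns `rank`, `snp_id`, `chrom`,
#'   `pos`, `closest_genes` (list of character vectors), `ccfdr`, of class
#'   `shared_loci`.
#' @export
#' @examples
#' loci <- load_table1_fixture()
#' nrow(loci)           # 49
#' unique_gene_set(loci)
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_shared_loci.tsv",
                      package = "pleioconj", mustWork = TRUE)
  x <- readr::read_tsv(path, col_types = "iccicd",
                       show_col_types = FALSE, progress = FALSE)
  expect_cols <- c("rank", "rsid", "chrom", "pos", "closest_genes", "ccfdr")
  if (!identical(names(x), expect_cols))
    stop("fixture corrupted: unexpected columns")
  if (nrow(x) != 49) stop("fixture corrupted: expected 49 rows, got ", nrow(x))
  if (!identical(x$rank, 1:49)) stop("fixture corrupted: rank column")
  if (any(is.na(x$ccfdr)) || any(x$ccfdr <= 0) || any(x$ccfdr >= 1))
    stop("fixture corrupted: ccfdr out of range")
  out <- tibble::tibble(
    rank = x$rank,
    snp_id = x$rsid,
    chrom = as.character(x$chrom),
    pos = as.integer(x$pos),
    closest_genes = strsplit(x$closest_genes, ",\\s*"),
    ccfdr = x$ccfdr)
  tibble::new_tibble(out, class = "shared_loci")
}

#' Functional annotations of the shared genes (packaged table)
#'
#' Loads the packaged static table of the 11 protein-coding genes the 49
#' shared loci map to, with their full names and brief functional notes.
#' Documentation fixture only; nothing downstream computes on it.
#'
#' @return Tibble with 11 rows: `gene_symbol`, `full_name`, `function`.
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "table2_gene_functions.tsv",
                      package = "pleioconj", mustWork = TRUE)
  x <- readr::read_tsv(path, col_types = "ccc", show_col_types = FALSE,
                       progress = FALSE)
  if (nrow(x) != 11 || ncol(x) != 3) stop("fixture corrupted")
  x
}

#' Read a gene-annotation interval file (BED or GFF3)
#'
#' Reads gene intervals for nearest-gene annotation via
#' `rtracklayer::import()`, so BED's 0-based half-open coordinates are
#' converted to the 1-based inclusive convention used throughout this
#' package. For GFF3, only `gene` features are kept and the symbol is taken
#' from the `Name` attribute.
#'
#' A small synthetic example (`toy_genes.bed`, invented intervals for
#' testing, not real gene coordinates) ships with the package:
#' `system.file("extdata", "toy_genes.bed", package = "pleioconj")`.
#'
#' @param path BED or GFF3 file; format inferred from the extension unless
#'   given.
#' @param format `"bed"` or `"gff3"`.
#' @return Tibble with columns `gene_symbol`, `chrom`, `start`, `end`
#'   (1-based inclusive), `strand`.
#' @export
read_gene_annotation <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
      "gff3" else "bed"
  }
  gr <- rtracklayer::import(path, format = format)
  if (format == "gff3") {
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    symbols <- as.character(gr$Name)
  } else {
    symbols <- as.character(gr$name)
  }
  out <- tibble::tibble(
    gene_symbol = symbols,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)))
  out$strand[!out$strand %in% c("+", "-")] <- "unknown"
  if (any(is.na(out$gene_symbol)) || any(!nzchar(out$gene_symbol)))
    stop("annotation has features without a gene symbol")
  if (any(out$start > out$end)) stop("annotation has start > end intervals")
  out
}
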