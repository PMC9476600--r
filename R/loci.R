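#' Call shared (pleiotropic) loci
#'
#' A SNP is called shared when its conjunctional FDR is below `ccfdr_max`
#' (default 0.01) *and* it is suggestively significant in both traits
#' (p < `p_max`, default 1e-5, on the genomic-control-corrected scale when
#' correction was applied). All three comparisons are strict, matching the
#' "< 0.01" / "< 1e-5" convention. Calling is a pure filter: the result is
#' a subset of the input SNPs, sorted by genomic position.
#'
#' @param pair The `harmonized_pair` the analysis ran on.
#' @param result Matching [cfdr_analysis()] result (or its [tidy()] table).
#' @param ccfdr_max Conjunctional FDR calling threshold (default 0.01).
#' @param p_max Per-trait suggestive-significance threshold (default 1e-5).
#' @return Tibble of class `shared_loci`: `snp_id`, `chrom`, `pos`, `p_a`,
#'   `p_b`, `ccfdr`, sorted by (chrom, pos).
#' @export
call_shared_loci <- function(pair, result, ccfdr_max = 0.01, p_max = 1e-5) {
  tab <- if (inherits(result, "cfdr_result")) result$table else result
  if (nrow(tab) != nrow(pair) || !identical(tab$snp_id, pair$snp_id))
    stop("result is not aligned to pair (different SNPs or order)")
  p_a <- if ("p_a_gc" %in% names(tab)) tab$p_a_gc else tab$p_a
  p_b <- if ("p_b_gc" %in% names(tab)) tab$p_b_gc else tab$p_b
  keep <- tab$ccfdr < ccfdr_max & p_a < p_max & p_b < p_max
  out <- tibble::tibble(
    snp_id = tab$snp_id[keep], chrom = tab$chrom[keep], pos = tab$pos[keep],
    p_a = p_a[keep], p_b = p_b[keep], ccfdr = tab$ccfdr[keep])
  out <- out[order(chrom_rank(out$chrom), out$pos), , drop = FALSE]
  tibble::new_tibble(out, class = "shared_loci")
}

#' Average conjunctional FDR over duplicate rsIDs
#'
#' Loci sharing an rsID (at the same genomic position) are collapsed to a
#' single record whose ccFDR is the arithmetic mean of the copies;
#' remaining fields keep their first-seen values. Duplicate rsIDs at
#' *different* positions are ambiguous, so they are kept separate with a
#' warning. Idempotent.
#'
#' @param loci A `shared_loci` tibble.
#' @return Deduplicated `shared_loci` tibble.
#' @export
average_duplicate_ccfdr <- function(loci) {
  if (nrow(loci) == 0) return(loci)
  out <- loci |>
    dplyr::group_by(.data$snp_id, .data$chrom, .data$pos) |>
    dplyr::mutate(ccfdr = mean(.data$ccfdr)) |>
    dplyr::ungroup() |>
    dplyr::distinct(.data$snp_id, .data$chrom, .data$pos, .keep_all = TRUE)
  if (anyDuplicated(out$snp_id))
    warning("duplicate rsID(s) at different positions kept separate: ",
            paste(unique(out$snp_id[duplicated(out$snp_id)]), collapse = ", "))
  tibble::new_tibble(out, class = "shared_loci")
}

#' Annotate loci with their nearest gene(s)
#'
#' Maps each locus to gene(s) from an annotation table (see
#' [read_gene_annotation()]): every gene interval containing the position
#' (1-based inclusive), ordered by ascending start; otherwise the gene(s)
#' at minimal distance `max(start - pos, pos - end)`, with exact ties all
#' returned. Multi-gene assignments are serialized comma+space joined
#' (e.g. `"SPI1, MYBPC3"`). A locus on a chromosome absent from the
#' annotation gets `"NA"` with a warning.
#'
#' @param loci A `shared_loci` tibble.
#' @param annotation Gene-interval tibble (`gene_symbol`, `chrom`, `start`,
#'   `end`).
#' @return `loci` with list-column `closest_genes` and character column
#'   `closest_gene_label`.
#' @export
annotate_nearest_gene <- function(loci, annotation) {
  stopifnot(all(c("gene_symbol", "chrom", "start", "end") %in% names(annotation)))
  if (any(annotation$start > annotation$end))
    stop("annotation has start > end intervals")
  genes_for <- function(chrom, pos) {
    ann <- annotation[annotation$chrom == chrom, , drop = FALSE]
    if (nrow(ann) == 0) return(NA_character_)
    inside <- ann$start <= pos & pos <= ann$end
    if (any(inside)) {
      hit <- ann[inside, , drop = FALSE]
      return(hit$gene_symbol[order(hit$start)])
    }
    d <- pmax(ann$start - pos, pos - ann$end)
    hit <- ann[d == min(d), , drop = FALSE]
    hit$gene_symbol[order(hit$start)]
  }
  cg <- purrr::map2(loci$chrom, loci$pos, genes_for)
  n_missing <- sum(purrr::map_lgl(cg, function(g) all(is.na(g))))
  if (n_missing > 0) {
    warning(n_missing, " locus/loci on chromosomes absent from annotation")
    cg <- purrr::map(cg, function(g) if (all(is.na(g))) "NA" else g)
  }
  out <- dplyr::mutate(loci,
                       closest_genes = cg,
                       closest_gene_label = purrr::map_chr(cg, paste, collapse = ", "))
  tibble::new_tibble(out, class = "shared_loci")
}

#' Distinct genes implicated by a set of loci
#'
#' Union of all `closest_genes` entries, deduplicated and sorted
#' alphabetically; `"NA"` placeholders from unannotatable loci are
#' excluded.
#'
#' @param loci Annotated `shared_loci` tibble (or the packaged published
#'   table from [load_table1_fixture()]).
#' @return Character vector of gene symbols.
#' @export
unique_gene_set <- function(loci) {
  if (nrow(loci) == 0) return(character(0))
  if (!"closest_genes" %in% names(loci))
    stop("loci are not annotated (no closest_genes column)")
  g <- unique(unlist(loci$closest_genes))
  sort(setdiff(g, c(NA, "NA")))
}

#' Manhattan-plot coordinates of shared loci
#'
#' One row per locus with its chromosome, position, and `-log10(ccFDR)`
#' (the y-axis of a conjunctional Manhattan plot), ordered by genomic
#' position.
#'
#' @param loci A `shared_loci` tibble with positive `ccfdr`.
#' @return Tibble: `snp_id`, `chrom`, `pos`, `minus_log10_ccfdr`.
#' @export
manhattan_table <- function(loci) {
  if (any(loci$ccfdr <= 0)) stop("ccfdr must be positive")
  out <- tibble::tibble(
    snp_id = loci$snp_id, chrom = loci$chrom, pos = loci$pos,
    minus_log10_ccfdr = -log10(loci$ccfdr))
  out[order(chrom_rank(out$chrom), out$pos), , drop = FALSE]
}

#' Overlap between discovery and replication locus sets
#'
#' Compares two called-locus sets by rsID: intersection and union sizes and
#' the Jaccard index (`NA` when both sets are empty).
#'
#' @param discovery,replication `shared_loci` tibbles (or anything with an
#'   `snp_id` column).
#' @return One-row tibble: `n_discovery`, `n_replication`, `n_intersect`,
#'   `n_union`, `jaccard`, plus list-column `shared_ids`.
#' @export
replication_overlap <- function(discovery, replication) {
  d <- unique(discovery$snp_id)
  r <- unique(replication$snp_id)
  inter <- intersect(d, r)
  uni <- union(d, r)
  tibble::tibble(
    n_discovery = length(d), n_replication = length(r),
    n_intersect = length(inter), n_union = length(uni),
    jaccard = if (length(uni) == 0) NA_real_ else length(inter) / length(uni),
    shared_ids = list(inter))
}
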