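#' Read GWAS summary statistics from delimited text
#'
#' Reads a per-SNP association table (one trait) from TSV/CSV/other delimited
#' text, optionally gzip-compressed, maps source column names onto the
#' canonical fields, validates each row, and returns a tibble of clean
#' records. Rows failing validation are dropped and tallied in the
#' `"dropped"` attribute rather than aborting the read: public summary
#' statistics routinely contain a handful of malformed rows.
#'
#' Canonical fields are `snp_id` (rsID), `chrom` (chromosome label, kept as
#' character), `pos` (1-based base-pair position), `pvalue` in (0, 1], and
#' the optional QC fields `maf`, `hwe_p`, `call_rate`. Optional fields are
#' included only when their source column exists. P-values exactly zero
#' (they occur in downloaded summary statistics when the upstream tool
#' underflowed) are clamped to 0.1 x the smallest positive p in the table so
#' that -log10 transforms stay finite; the number clamped is reported.
#'
#' Only p-values are used downstream: no allele or strand harmonisation is
#' performed, so effect/other allele columns are ignored even if present.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping canonical field names to
#'   source column names. Defaults cover the common GWAS dialect
#'   (`SNP`/`CHR`/`BP`/`P`); supply only the entries that differ, e.g.
#'   `c(pvalue = "P-value")`.
#' @param delim Field delimiter (default tab). Use `","` for CSV or `" "`
#'   for single-space separation.
#' @param trait_name Label stored on the returned table; defaults to the
#'   file name without extension.
#'
#' @return A tibble with columns `snp_id`, `chrom`, `pos`, `pvalue` and any
#'   optional QC columns found, carrying attributes `trait_name` and
#'   `dropped` (named integer vector of rows removed per reason).
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("SNP\tCHR\tBP\tP", "rs1\t1\t100\t0.02", "rs2\t1\t200\t0.5"), f)
#' read_sumstats(f)
read_sumstats <- function(path,
                          column_map = NULL,
                          delim = "\t",
                          trait_name = NULL) {
  stopifnot(is.character(path), length(path) == 1)
  if (!file.exists(path)) stop("file not found: ", path)
  defaults <- c(snp_id = "SNP", chrom = "CHR", pos = "BP", pvalue = "P",
                maf = "MAF", hwe_p = "HWE_P", call_rate = "CALL_RATE")
  map <- defaults
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(defaults))
    if (length(bad)) stop("unknown canonical field(s) in column_map: ",
                          paste(bad, collapse = ", "))
    map[names(column_map)] <- column_map
  }

  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  mandatory <- c("snp_id", "chrom", "pos", "pvalue")
  for (fld in mandatory) {
    if (!map[[fld]] %in% names(raw))
      stop("mandatory column '", map[[fld]], "' (", fld, ") missing from header")
  }
  optional <- intersect(c("maf", "hwe_p", "call_rate"),
                        names(map)[map %in% names(raw)])

  out <- tibble::tibble(
    snp_id = as.character(raw[[map[["snp_id"]]]]),
    chrom  = as.character(raw[[map[["chrom"]]]]),
    pos    = suppressWarnings(as.numeric(raw[[map[["pos"]]]])),
    pvalue = suppressWarnings(as.numeric(raw[[map[["pvalue"]]]]))
  )
  for (fld in optional) {
    out[[fld]] <- suppressWarnings(as.numeric(raw[[map[[fld]]]]))
  }

  dropped <- c(bad_snp_id = 0L, bad_pos = 0L, bad_pvalue = 0L, bad_maf = 0L,
               bad_hwe_p = 0L, bad_call_rate = 0L)
  ok_id  <- !is.na(out$snp_id) & nzchar(out$snp_id)
  ok_pos <- !is.na(out$pos) & out$pos >= 1 & out$pos == floor(out$pos)
  ok_p   <- !is.na(out$pvalue) & out$pvalue >= 0 & out$pvalue <= 1
  dropped["bad_snp_id"] <- sum(!ok_id)
  dropped["bad_pos"]    <- sum(ok_id & !ok_pos)
  dropped["bad_pvalue"] <- sum(ok_id & ok_pos & !ok_p)
  keep <- ok_id & ok_pos & ok_p
  if ("maf" %in% names(out)) {
    ok <- is.na(out$maf) | (out$maf > 0 & out$maf <= 0.5)
    dropped["bad_maf"] <- sum(keep & !ok); keep <- keep & ok
  }
  if ("hwe_p" %in% names(out)) {
    ok <- is.na(out$hwe_p) | (out$hwe_p > 0 & out$hwe_p <= 1)
    dropped["bad_hwe_p"] <- sum(keep & !ok); keep <- keep & ok
  }
  if ("call_rate" %in% names(out)) {
    ok <- is.na(out$call_rate) | (out$call_rate >= 0 & out$call_rate <= 1)
    dropped["bad_call_rate"] <- sum(keep & !ok); keep <- keep & ok
  }
  out <- out[keep, , drop = FALSE]
  out$pos <- as.integer(out$pos)

  # p = 0 is an underflow artefact, not evidence of p = 0
  n_zero <- sum(out$pvalue == 0)
  if (n_zero > 0) {
    floor_p <- if (any(out$pvalue > 0)) min(out$pvalue[out$pvalue > 0]) * 0.1 else 1e-300
    out$pvalue[out$pvalue == 0] <- floor_p
    message(n_zero, " zero p-value(s) clamped to ", format(floor_p))
  }
  n_drop <- sum(dropped)
  if (n_drop > 0) {
    message(n_drop, " row(s) dropped during validation (",
            paste(names(dropped)[dropped > 0], dropped[dropped > 0],
                  sep = "=", collapse = ", "), ")")
  }
  if (is.null(trait_name))
    trait_name <- tools::file_path_sans_ext(basename(path), compression = TRUE)
  attr(out, "trait_name") <- trait_name
  attr(out, "dropped") <- dropped
  out
}

#' Write summary statistics in the canonical dialect
#'
#' Writes the canonical tab-separated layout (`snp_id`, `chrom`, `pos`,
#' `pvalue`, then any QC columns present). A table written this way reads
#' back identically via [read_sumstats()] with
#' `column_map = canonical_column_map()`.
#'
#' @param table Tibble as returned by [read_sumstats()] or
#'   [simulate_gwas_pair()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path) {
  cols <- intersect(c("snp_id", "chrom", "pos", "pvalue",
                      "maf", "hwe_p", "call_rate"), names(table))
  stopifnot(all(c("snp_id", "chrom", "pos", "pvalue") %in% cols))
  readr::write_tsv(table[cols], path, progress = FALSE)
  invisible(path)
}

#' Column map for the canonical on-disk dialect
#'
#' @return Named character vector usable as `column_map` in
#'   [read_sumstats()] for files produced by [write_sumstats()].
#' @export
canonical_column_map <- function() {
  c(snp_id = "snp_id", chrom = "chrom", pos = "pos", pvalue = "pvalue",
    maf = "maf", hwe_p = "hwe_p", call_rate = "call_rate")
}

#' Marker-level quality-control filters
#'
#' Removes SNPs with low minor allele frequency, strong Hardy-Weinberg
#' disequilibrium, or low call rate. Summary statistics frequently omit
#' these fields (the cohort-level QC happened upstream at genotype level);
#' a record lacking a field passes that filter, so a table carrying only
#' p-values is returned unchanged.
#'
#' @param table Summary-statistics tibble.
#' @param maf_min Minimum minor allele frequency (default 0.01, i.e. 1%).
#' @param hwe_min Minimum Hardy-Weinberg equilibrium p-value (default 1e-6).
#' @param call_rate_min Minimum genotyping call rate (default 0.95).
#' @return Filtered tibble; attribute `"qc_removed"` holds the count removed
#'   per criterion.
#' @export
apply_qc <- function(table, maf_min = 0.01, hwe_min = 1e-6,
                     call_rate_min = 0.95) {
  stopifnot(maf_min >= 0, maf_min < 1, hwe_min >= 0, hwe_min < 1,
            call_rate_min >= 0, call_rate_min < 1)
  pass_field <- function(x, lim) if (is.null(x)) TRUE else (is.na(x) | x >= lim)
  ok_maf <- pass_field(table[["maf"]], maf_min)
  ok_hwe <- pass_field(table[["hwe_p"]], hwe_min)
  ok_cr  <- pass_field(table[["call_rate"]], call_rate_min)
  keep <- ok_maf & ok_hwe & ok_cr
  out <- table[keep, , drop = FALSE]
  attr(out, "trait_name") <- attr(table, "trait_name")
  attr(out, "qc_removed") <- c(
    maf = sum(!ok_maf), hwe = sum(ok_maf & !ok_hwe),
    call_rate = sum(ok_maf & ok_hwe & !ok_cr))
  out
}

#' Collapse duplicate rsIDs by averaging p-values
#'
#' Some summary-statistics releases carry the same rsID more than once
#' (multi-allelic splits, merge artefacts). Duplicates on one chromosome are
#' collapsed to a single record whose p-value is the arithmetic mean of the
#' copies, keeping the first-seen coordinates; duplicates whose copies
#' disagree on chromosome are unresolvable and all copies are dropped (and
#' reported). Idempotent.
#'
#' @param table Summary-statistics tibble.
#' @return Deduplicated tibble, first-occurrence order preserved; attribute
#'   `"conflicting_ids"` lists rsIDs dropped for chromosome conflicts.
#' @export
dedupe_mean_p <- function(table) {
  trait <- attr(table, "trait_name")
  dup_ids <- unique(table$snp_id[duplicated(table$snp_id)])
  conflicting <- character(0)
  if (length(dup_ids)) {
    chrom_per_id <- tapply(table$chrom[table$snp_id %in% dup_ids],
                           table$snp_id[table$snp_id %in% dup_ids],
                           function(ch) length(unique(ch)))
    conflicting <- names(chrom_per_id)[chrom_per_id > 1]
    if (length(conflicting))
      warning(length(conflicting),
              " rsID(s) duplicated across chromosomes dropped: ",
              paste(head(conflicting, 5), collapse = ", "))
  }
  out <- table |>
    dplyr::filter(!.data$snp_id %in% conflicting) |>
    dplyr::mutate(.first = !duplicated(.data$snp_id)) |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::mutate(pvalue = mean(.data$pvalue)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$.first) |>
    dplyr::select(-".first")
  attr(out, "trait_name") <- trait
  attr(out, "conflicting_ids") <- conflicting
  out
}

# numeric-aware chromosome ordering: 1..22 then X, Y, MT, then others
chrom_rank <- function(chrom) {
  ch <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  num <- suppressWarnings(as.numeric(ch))
  special <- match(toupper(ch), c("X", "Y", "MT", "M"))
  rank <- ifelse(!is.na(num), num,
                 ifelse(!is.na(special), 22 + special, NA))
  ifelse(is.na(rank), 1000 + as.numeric(factor(ch)), rank)
}

#' Intersect and align two traits' summary statistics
#'
#' Builds the per-SNP paired p-value table all two-trait analyses run on:
#' the rsID intersection of the two tables, sorted by genomic position, with
#' one p-value column per trait. SNPs whose coordinates disagree between the
#' two sources (same rsID, different chromosome or position) cannot be
#' trusted and are excluded; they are reported in the `"conflicts"`
#' attribute. Only p-values are carried: the condFDR machinery never uses
#' signed effects, so no allele alignment is attempted.
#'
#' @param a,b Deduplicated summary-statistics tibbles (see
#'   [dedupe_mean_p()]).
#' @return A tibble of class `harmonized_pair` with columns `snp_id`,
#'   `chrom`, `pos`, `p_a`, `p_b`, sorted by (chrom, pos); attributes
#'   `trait_a`, `trait_b`, `conflicts`.
#' @export
harmonize_pair <- function(a, b) {
  if (anyDuplicated(a$snp_id) || anyDuplicated(b$snp_id))
    stop("inputs must be deduplicated; run dedupe_mean_p() first")
  m <- dplyr::inner_join(
    dplyr::select(a, "snp_id", "chrom", "pos", p_a = "pvalue"),
    dplyr::select(b, "snp_id", chrom_b = "chrom", pos_b = "pos", p_b = "pvalue"),
    by = "snp_id")
  conflict <- m$chrom != m$chrom_b | m$pos != m$pos_b
  conflicts <- m[conflict, c("snp_id", "chrom", "pos", "chrom_b", "pos_b")]
  if (nrow(conflicts))
    warning(nrow(conflicts), " SNP(s) with conflicting coordinates excluded")
  out <- m[!conflict, c("snp_id", "chrom", "pos", "p_a", "p_b")]
  if (nrow(out) == 0) stop("no SNPs shared between the two tables")
  out <- out[order(chrom_rank(out$chrom), out$pos), , drop = FALSE]
  out <- tibble::new_tibble(out, class = "harmonized_pair")
  attr(out, "trait_a") <- attr(a, "trait_name") %||% "trait_a"
  attr(out, "trait_b") <- attr(b, "trait_name") %||% "trait_b"
  attr(out, "conflicts") <- tibble::as_tibble(conflicts)
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
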