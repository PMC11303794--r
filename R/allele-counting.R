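#' Read-level filter for allelic counting
#'
#' Keeps a read/UMI record iff mapping quality is at least 20, the aligned
#' length is at least 30 nt and the SAM FLAG does not exceed 255 (i.e. no
#' secondary/supplementary/QC-fail/duplicate bits set).
#'
#' @param records data frame with columns `mapq`, `aligned_length`, `flag`.
#' @return logical vector, `TRUE` for records that pass.
#' @export
filter_read <- function(records) {
  records$mapq >= 20L & records$aligned_length >= 30L & records$flag <= 255L
}

#' Aggregate per-SNP allelic read records into gene-level AD/DP matrices
#'
#' UMI-deduplicating aggregation: within each (cell, gene), every UMI
#' contributes at most one count. A UMI spanning several SNPs is resolved by
#' majority vote over its unambiguous allele calls; an exact REF/ALT tie, or
#' a UMI with only ambiguous calls, contributes to neither AD nor DP. For
#' read-based (non-UMI) protocols the read ID plays the role of the UMI.
#'
#' ALT is the phased B haplotype: DP counts resolved UMIs, AD counts UMIs
#' resolved to ALT.
#'
#' @param records data frame with columns `barcode`, `umi`, `snp_pos`,
#'   `gene_id`, `allele` (one of `"REF"`, `"ALT"`, `"AMBIG"`), and
#'   optionally `mapq`, `aligned_length`, `flag` (pre-filtered with
#'   [filter_read()] when present).
#' @param genes gene annotation as from [gene_annotation()].
#' @param cells cell annotation as from [cell_meta()].
#' @param apply_filter apply [filter_read()] first when the quality columns
#'   are present (default `TRUE`).
#' @return list with cell-by-gene integer matrices `AD` and `DP` (aligned to
#'   `cells$barcode` x `genes$gene_id`) and `n_skipped` (records with
#'   unknown barcode or gene).
#' @export
aggregate_allele_counts <- function(records, genes, cells, apply_filter = TRUE) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("barcode", "umi", "snp_pos", "gene_id", "allele") %in% names(records)))
  if (apply_filter && all(c("mapq", "aligned_length", "flag") %in% names(records))) {
    records <- records[filter_read(records), , drop = FALSE]
  }
  known <- records$barcode %in% cells$barcode & records$gene_id %in% genes$gene_id
  n_skipped <- sum(!known)
  if (n_skipped > 0L) {
    warning(n_skipped, " record(s) with unknown barcode or gene skipped")
  }
  records <- records[known, , drop = FALSE]
  AD <- matrix(0L, nrow(cells), nrow(genes),
               dimnames = list(cells$barcode, genes$gene_id))
  DP <- AD
  if (nrow(records) > 0L) {
    per_umi <- records |>
      dplyr::group_by(.data$barcode, .data$gene_id, .data$umi) |>
      dplyr::summarise(n_alt = sum(.data$allele == "ALT"),
                       n_ref = sum(.data$allele == "REF"), .groups = "drop") |>
      dplyr::filter(.data$n_alt != .data$n_ref)  # tie or all-AMBIG -> dropped
    counts <- per_umi |>
      dplyr::group_by(.data$barcode, .data$gene_id) |>
      dplyr::summarise(DP = dplyr::n(), AD = sum(.data$n_alt > .data$n_ref),
                       .groups = "drop")
    i <- match(counts$barcode, cells$barcode)
    j <- match(counts$gene_id, genes$gene_id)
    AD[cbind(i, j)] <- as.integer(counts$AD)
    DP[cbind(i, j)] <- as.integer(counts$DP)
  }
  list(AD = AD, DP = DP, n_skipped = n_skipped)
}
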