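#' RPKM normalisation
#'
#' Reads per kilobase of reference per million mapped reads:
#' `(orf_reads + orf_singletons) / ((total_reads / 1e6) * (length_nt / 1e3))`.
#' Contig-mapped reads and singletons both contribute to the numerator; the
#' denominator uses the stage's total quality-filtered read count and the
#' length of the family's reference ORF.
#'
#' @param orf_reads Reads mapped through contigs/pileups (vectorised).
#' @param orf_singletons Singleton reads attributed to the family.
#' @param total_reads Total reads of the stage (scalar or vector).
#' @param ref_length_nt Reference ORF length in nt.
#' @return Numeric RPKM values.
#' @export
compute_rpkm <- function(orf_reads, orf_singletons, total_reads,
                         ref_length_nt) {
  if (any(total_reads <= 0)) abort("total_reads must be > 0")
  if (any(ref_length_nt <= 0)) abort("ref_length_nt must be > 0")
  (orf_reads + orf_singletons) /
    ((total_reads / 1e6) * (ref_length_nt / 1e3))
}

#' Percentage share of each family within its stage
#'
#' Sets `pct = 100 * rpkm / sum(rpkm)`, per stage when a `stage` column is
#' present. Shares within a stage sum to 100 (up to rendering).
#'
#' @param table Tibble with an `rpkm` column (and optionally `stage`).
#' @return The table with an updated `pct` column.
#' @export
family_percentages <- function(table) {
  grouping <- intersect("stage", names(table))
  table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::mutate(pct = 100 * .data$rpkm / sum(.data$rpkm)) |>
    dplyr::ungroup()
}

#' Build a per-family expression table
#'
#' Combines per-family counts with reference lengths into the standard
#' expression-table shape: contigs, mapped reads, singletons, RPKM and the
#' stage-internal percentage share.
#'
#' @param counts Tibble with `family`, `contigs`, `reads`, `singletons`,
#'   `ref_length_nt` (and optionally `stage`).
#' @param total_reads Total quality-filtered reads per stage: a single
#'   number, or a named vector indexed by stage.
#' @return Tibble with `rpkm` and `pct` columns appended.
#' @export
family_expression <- function(counts, total_reads) {
  tot <- if (length(total_reads) > 1L || !is.null(names(total_reads))) {
    unname(total_reads[counts$stage])
  } else {
    total_reads
  }
  counts |>
    dplyr::mutate(rpkm = ifelse(
      .data$reads + .data$singletons == 0, 0,
      compute_rpkm(.data$reads, .data$singletons, tot, .data$ref_length_nt)
    )) |>
    family_percentages()
}
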