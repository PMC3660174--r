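#' Build a reference pileup from annotated reads
#'
#' Aligns each read semi-globally onto one reference ORF (read global, free
#' at both reference ends; +5/-4 with affine gaps open 10 / extend 1) and
#' stacks the aligned read bases in reference coordinates. Reads whose
#' alignment identity (matches over aligned columns including indels) falls
#' below `min_identity` are excluded and counted.
#'
#' @param reads Read tibble (rows already assigned to this reference, e.g.
#'   by filtering [annotate_reads()] output).
#' @param ref One-row reference tibble (`ref_id`, `sequence`) or a single
#'   sequence string.
#' @param min_identity Identity floor for accepting a read (default 0.70).
#' @return A `venomshift_pileup`: list with `ref_id`, `ref_seq`, `mat`
#'   (character matrix, reads x reference positions, `-` where a read does
#'   not cover or deletes a column), `read_ids`, `n_excluded`.
#' @export
build_pileup <- function(reads, ref, min_identity = 0.70) {
  if (is.character(ref)) ref <- tibble(ref_id = "ref", sequence = ref)
  ref_seq <- ref$sequence[[1]]
  ref_len <- nchar(ref_seq)
  if (nrow(reads) == 0L) {
    return(structure(
      list(ref_id = ref$ref_id[[1]], ref_seq = ref_seq,
           mat = matrix(character(0), 0, ref_len),
           read_ids = character(0), n_excluded = 0L),
      class = "venomshift_pileup"
    ))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 5, mismatch = -4, baseOnly = FALSE
  )
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(reads$sequence),
    Biostrings::DNAString(ref_seq),
    type = "global-local", substitutionMatrix = mat,
    gapOpening = 10, gapExtension = 1
  )
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  ind <- Biostrings::nindel(aln)
  n_gap <- rowSums(Biostrings::insertion(ind)[, 2, drop = FALSE]) +
    rowSums(Biostrings::deletion(ind)[, 2, drop = FALSE])
  identity <- nm / pmax(nm + nmm + n_gap, 1L)
  keep <- identity >= min_identity
  aligned_str <- as.character(Biostrings::aligned(aln))[keep]
  pm <- if (sum(keep) > 0L) {
    do.call(rbind, strsplit(aligned_str, "", fixed = TRUE))
  } else {
    matrix(character(0), 0, ref_len)
  }
  structure(
    list(
      ref_id = ref$ref_id[[1]],
      ref_seq = ref_seq,
      mat = pm,
      read_ids = reads$read_id[keep],
      n_excluded = sum(!keep)
    ),
    class = "venomshift_pileup"
  )
}

#' @export
print.venomshift_pileup <- function(x, ...) {
  cat(sprintf(
    "<venomshift_pileup> ref %s (%d nt), %d reads (%d excluded)\n",
    x$ref_id, nchar(x$ref_seq), nrow(x$mat), x$n_excluded
  ))
  invisible(x)
}

#' Per-column base counts of a pileup
#'
#' @param pileup A [build_pileup()] result.
#' @return Integer matrix, 4 rows (A, C, G, T) x reference positions.
#' @export
pileup_counts <- function(pileup) {
  counts <- sapply(DNA_BASES, function(b) colSums(pileup$mat == b))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  t(counts)
}

#' Call a consensus with variable-position annotation
#'
#' Applies the read-support consensus rules: a column's consensus residue is
#' its majority base, reported only when the column depth is at least
#' `min_support` (default 4 reads), otherwise the position is undetermined.
#' A residue is a valid variant when its support is at least
#' `min_variant_reads` (default 3: the observing read plus two others); a
#' position is variable when two or more residues are valid variants,
#' suggesting co-transcribed alleles or isoforms.
#'
#' @param pileup A [build_pileup()] result.
#' @param min_support Minimum depth to call a consensus residue.
#' @param min_variant_reads Minimum support for a residue to count as a
#'   variant.
#' @return Tibble with `position` (1-based), `consensus` (base or NA when
#'   undetermined), `depth`, `variants` (list of named support counts for
#'   valid variants), `n_variants`, `is_variable`.
#' @export
call_consensus <- function(pileup, min_support = 4L, min_variant_reads = 3L) {
  counts <- pileup_counts(pileup)
  depth <- colSums(counts)
  ref_len <- ncol(counts)
  consensus <- rep(NA_character_, ref_len)
  determined <- depth >= min_support
  if (any(determined)) {
    # ties break to the lexicographically smallest base (row order A,C,G,T)
    consensus[determined] <- DNA_BASES[
      apply(counts[, determined, drop = FALSE], 2L, which.max)
    ]
  }
  variants <- lapply(seq_len(ref_len), function(j) {
    v <- counts[, j]
    v <- v[v >= min_variant_reads]
    sort(v, decreasing = TRUE)
  })
  n_variants <- vapply(variants, length, integer(1))
  tibble(
    position = seq_len(ref_len),
    consensus = consensus,
    depth = as.integer(depth),
    variants = variants,
    n_variants = n_variants,
    is_variable = n_variants >= 2L
  )
}

#' Consensus sequence string from consensus calls
#'
#' @param calls Tibble from [call_consensus()].
#' @param undetermined Character used for undetermined positions.
#' @return Single consensus string in reference coordinates.
#' @export
consensus_sequence <- function(calls, undetermined = "N") {
  x <- calls$consensus
  x[is.na(x)] <- undetermined
  paste(x, collapse = "")
}
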