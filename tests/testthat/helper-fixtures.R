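# Shared fixture builders. Everything is generated in code; nothing binary.

# A read tibble from parallel vectors; qualities recycled per read.
make_reads <- function(seqs, qv = 35L, ids = NULL) {
  ids <- ids %||% sprintf("r%03d", seq_along(seqs))
  tibble::tibble(
    read_id = ids,
    sequence = seqs,
    qualities = lapply(nchar(seqs), function(n) rep(as.integer(qv), n))
  )
}

# Fabricate a pileup from explicit aligned rows (strings over ACGT-, equal
# width), bypassing the aligner.
fake_pileup <- function(rows, ref_seq = NULL, ids = NULL) {
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  structure(
    list(
      ref_id = "ref",
      ref_seq = ref_seq %||% strrep("A", ncol(mat)),
      mat = mat,
      read_ids = ids %||% sprintf("r%03d", seq_along(rows)),
      n_excluded = 0L
    ),
    class = "venomshift_pileup"
  )
}

# A pileup with a single explicit column (all other columns empty), for
# enumerating consensus/variant rules: col is a named vector base -> count.
one_column_pileup <- function(col, width = 5L, at = 3L) {
  rows <- unlist(purrr::imap(col, function(n, base) {
    rep(paste0(strrep("-", at - 1L), base, strrep("-", width - at)), n)
  }))
  fake_pileup(unname(rows))
}

# Random DNA of length n under the current RNG stream.
rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Reverse complement of a DNA string.
rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# A small synthetic mature-miRNA reference with species tags, written to a
# temp FASTA; a quarter of the entries are tagged Anolis carolinensis.
write_mature_reference <- function(n = 50, seed = 7) {
  set.seed(seed)
  species <- rep(c("Anolis carolinensis", "Gallus gallus",
                   "Taeniopygia guttata", "Danio rerio"),
                 length.out = n)
  prefix <- c("Anolis carolinensis" = "aca", "Gallus gallus" = "gga",
              "Taeniopygia guttata" = "tgu", "Danio rerio" = "dre")
  seqs <- replicate(n, rand_dna(22))
  path <- tempfile(fileext = ".fa")
  writeLines(paste0(">", prefix[species], "-miR-", seq_len(n), " ",
                    species, "\n", seqs), path)
  path
}

`%||%` <- rlang::`%||%`
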