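# Ungapped Karlin-Altschul lambda for a scoring scheme under uniform letter
# frequencies: the positive root of sum_ij p_i p_j exp(lambda * s_ij) = 1.
# K is fixed at 0.1, a documented desk-scale stand-in; e-values here rank
# hits against a small curated panel, not a full database search.
ka_lambda <- function(scores, probs) {
  f <- function(lambda) {
    sum(outer(probs, probs) * exp(lambda * scores)) - 1
  }
  stats::uniroot(f, c(1e-4, 2), tol = 1e-9)$root
}

ka_cache <- new.env(parent = emptyenv())

lambda_nucleotide <- function(match = 5, mismatch = -4) {
  key <- paste0("nt_", match, "_", mismatch)
  if (is.null(ka_cache[[key]])) {
    s <- matrix(mismatch, 4, 4)
    diag(s) <- match
    ka_cache[[key]] <- ka_lambda(s, rep(0.25, 4))
  }
  ka_cache[[key]]
}

lambda_blosum62 <- function() {
  if (is.null(ka_cache$blosum62)) {
    mat <- get_blosum62()
    aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
            "M", "F", "P", "S", "T", "W", "Y", "V")
    ka_cache$blosum62 <- ka_lambda(mat[aa, aa], rep(1 / 20, 20))
  }
  ka_cache$blosum62
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

KA_K <- 0.1

#' Annotate reads against a toxin reference panel
#'
#' Each read is locally aligned against every panel reference -- directly in
#' nucleotide mode (+5/-4 match/mismatch), or through all six reading-frame
#' translations against the translated references under BLOSUM62 in
#' translated mode -- and the best-scoring hit is assigned a Karlin-Altschul
#' e-value (ungapped lambda estimated for the scoring scheme; database size =
#' total panel residue count). The local alignments are ungapped, keeping
#' the scores on the scale the ungapped e-value statistics describe. Hits
#' with e-value at or above the cutoff are dropped. Score ties break to the
#' lexicographically smaller `ref_id`.
#'
#' @param reads Read tibble (or character vector of sequences, in which case
#'   ids are generated).
#' @param panel Reference tibble with `ref_id`, `family`, `sequence` (one
#'   row per family reference; see [family_references()]).
#' @param mode `"nucleotide"` (default) or `"translated"`.
#' @param e_cutoff Retain hits with `e_value < e_cutoff` (default 1e-3).
#' @param keywords Optional character vector of family labels acting as the
#'   second-pass keyword filter; hits to other families are dropped.
#' @return Tibble with columns `read_id`, `ref_id`, `family`, `score`,
#'   `e_value`, `frame` (0 in nucleotide mode); one row per annotated read.
#' @export
annotate_reads <- function(reads, panel,
                           mode = c("nucleotide", "translated"),
                           e_cutoff = 1e-3, keywords = NULL) {
  mode <- match.arg(mode)
  if (nrow(panel) == 0L) abort("empty reference panel")
  if (is.character(reads)) {
    reads <- tibble(
      read_id = sprintf("read%06d", seq_along(reads)), sequence = reads
    )
  }
  if (nrow(reads) == 0L) {
    return(tibble(read_id = character(0), ref_id = character(0),
                  family = character(0), score = numeric(0),
                  e_value = numeric(0), frame = integer(0)))
  }
  panel <- dplyr::arrange(panel, .data$ref_id)
  if (mode == "nucleotide") {
    scores <- score_nucleotide(reads$sequence, panel$sequence)
    frames <- matrix(0L, nrow(scores), ncol(scores))
    lambda <- lambda_nucleotide()
    m <- nchar(reads$sequence)
  } else {
    sc <- score_translated(reads$sequence, panel$sequence)
    scores <- sc$scores
    frames <- sc$frames
    lambda <- lambda_blosum62()
    m <- pmax(nchar(reads$sequence) %/% 3L, 1L)
  }
  n_db <- if (mode == "nucleotide") sum(nchar(panel$sequence)) else
    sum(nchar(panel$sequence) %/% 3L)
  best <- apply(scores, 1L, which.max)  # first max = smaller ref_id
  best_score <- scores[cbind(seq_len(nrow(scores)), best)]
  e_value <- KA_K * m * n_db * exp(-lambda * best_score)
  hits <- tibble(
    read_id = reads$read_id,
    ref_id = panel$ref_id[best],
    family = panel$family[best],
    score = best_score,
    e_value = e_value,
    frame = frames[cbind(seq_len(nrow(scores)), best)]
  )
  hits <- dplyr::filter(hits, .data$e_value < e_cutoff)
  if (!is.null(keywords)) {
    hits <- dplyr::filter(hits, .data$family %in% keywords)
  }
  hits
}

score_nucleotide <- function(seqs, refs) {
  pats <- Biostrings::DNAStringSet(seqs)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 5, mismatch = -4, baseOnly = FALSE
  )
  s <- sapply(refs, function(r) {
    Biostrings::pairwiseAlignment(
      pats, Biostrings::DNAString(r), type = "local",
      substitutionMatrix = mat, gapOpening = 1e6, gapExtension = 1e6,
      scoreOnly = TRUE
    )
  })
  matrix(s, nrow = length(seqs))
}

translate_frames <- function(seqs) {
  dna <- Biostrings::DNAStringSet(seqs)
  rc <- Biostrings::reverseComplement(dna)
  frames <- list()
  for (off in 0:2) {
    frames[[paste0("+", off + 1)]] <- translate_offset(dna, off)
    frames[[paste0("-", off + 1)]] <- translate_offset(rc, off)
  }
  frames
}

translate_offset <- function(dna, off) {
  w <- Biostrings::width(dna)
  usable <- pmax(w - off, 0L)
  usable <- usable - usable %% 3L
  sub <- Biostrings::subseq(dna, start = pmin(off + 1L, w), width = usable)
  suppressWarnings(
    Biostrings::translate(sub, if.fuzzy.codon = "solve")
  )
}

score_translated <- function(seqs, refs) {
  b62 <- get_blosum62()
  ref_aa <- suppressWarnings(
    Biostrings::translate(Biostrings::DNAStringSet(refs),
                          if.fuzzy.codon = "solve")
  )
  fr <- translate_frames(seqs)
  frame_codes <- c(`+1` = 1L, `-1` = -1L, `+2` = 2L, `-2` = -2L,
                   `+3` = 3L, `-3` = -3L)
  scores <- matrix(-Inf, length(seqs), length(refs))
  frames <- matrix(0L, length(seqs), length(refs))
  for (j in seq_along(refs)) {
    for (fname in names(fr)) {
      s <- Biostrings::pairwiseAlignment(
        fr[[fname]], ref_aa[[j]], type = "local",
        substitutionMatrix = b62, gapOpening = 1e6, gapExtension = 1e6,
        scoreOnly = TRUE
      )
      upd <- s > scores[, j]
      scores[upd, j] <- s[upd]
      frames[upd, j] <- frame_codes[[fname]]
    }
  }
  list(scores = scores, frames = frames)
}
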