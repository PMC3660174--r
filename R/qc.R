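#' Quality-control parameters
#'
#' Bundles the read-filtering settings: the mean-quality cutoff for long
#' reads (kept only when the arithmetic mean Phred score strictly exceeds
#' `min_mean_qv`), the small-RNA length window, and the adapter set with the
#' minimum exact 3' overlap required to call an adapter match.
#'
#' @param min_mean_qv Mean quality threshold, strict `>` (default 20).
#' @param mirna_min_len,mirna_max_len Small-RNA length bounds (default
#'   15--40 nt).
#' @param adapters Character vector of adapter sequences.
#' @param min_adapter_overlap Minimum exact bases of adapter prefix at the
#'   read 3' end (default 8).
#' @return A `qc_params` list.
#' @export
qc_params <- function(min_mean_qv = 20, mirna_min_len = 15L,
                      mirna_max_len = 40L, adapters = default_adapters(),
                      min_adapter_overlap = 8L) {
  if (mirna_min_len > mirna_max_len) {
    abort("mirna_min_len must be <= mirna_max_len")
  }
  if (min_mean_qv < 0) abort("min_mean_qv must be >= 0")
  structure(
    list(
      min_mean_qv = min_mean_qv,
      mirna_min_len = as.integer(mirna_min_len),
      mirna_max_len = as.integer(mirna_max_len),
      adapters = adapters,
      min_adapter_overlap = as.integer(min_adapter_overlap)
    ),
    class = "qc_params"
  )
}

#' Filter reads by mean quality
#'
#' A read is kept iff the arithmetic mean of its per-base Phred scores is
#' strictly greater than `params$min_mean_qv`. Empty reads are discarded and
#' counted separately.
#'
#' @param reads Read tibble (`read_id`, `sequence`, `qualities`).
#' @param params A [qc_params()].
#' @return List with `reads` (kept rows) and `counts` (tibble with `input`,
#'   `kept`, `low_quality`, `empty`).
#' @export
filter_by_mean_quality <- function(reads, params = qc_params()) {
  mean_qv <- vapply(reads$qualities, function(q) {
    if (length(q) == 0L) return(NA_real_)
    mean(q)
  }, numeric(1))
  empty <- nchar(reads$sequence) == 0L | is.na(mean_qv)
  keep <- !empty & mean_qv > params$min_mean_qv
  list(
    reads = reads[keep, , drop = FALSE],
    counts = tibble(
      input = nrow(reads),
      kept = sum(keep),
      low_quality = sum(!keep & !empty),
      empty = sum(empty)
    )
  )
}

# Position at which an adapter prefix starts matching the read suffix,
# or NA. The longest matching suffix wins (smallest start position).
adapter_match_start <- function(sequence, adapter, min_overlap) {
  n <- nchar(sequence)
  alen <- nchar(adapter)
  if (n < min_overlap) return(NA_integer_)
  for (s in seq_len(n - min_overlap + 1L)) {
    l <- min(n - s + 1L, alen)
    if (substr(sequence, s, s + l - 1L) == substr(adapter, 1L, l)) {
      return(s)
    }
  }
  NA_integer_
}

#' Clip 3' adapters from small-RNA reads and apply length bounds
#'
#' For each read the longest 3' suffix that exactly matches a prefix of one
#' of the configured adapters (with at least `min_adapter_overlap` bases) is
#' removed. Reads that are entirely adapter are counted `adapter_only` and
#' dropped; clipped reads outside the `[mirna_min_len, mirna_max_len]` window
#' (including reads in which no adapter was found and that exceed the
#' maximum) are counted `too_short` -- the length-filter bucket -- and
#' dropped. Every input read falls in exactly one of `processed`,
#' `adapter_only`, `too_short`.
#'
#' @param reads Read tibble.
#' @param params A [qc_params()].
#' @return List with `reads` (clipped survivors, qualities trimmed to match)
#'   and `counts` (tibble with `input`, `processed`, `too_short`,
#'   `adapter_only`).
#' @export
clip_adapters <- function(reads, params = qc_params()) {
  # per unique sequence: clip position under the best (longest-suffix) adapter
  uniq <- unique(reads$sequence)
  clip_at <- vapply(uniq, function(s) {
    starts <- vapply(params$adapters, adapter_match_start, integer(1),
                     sequence = s, min_overlap = params$min_adapter_overlap)
    if (all(is.na(starts))) NA_integer_ else min(starts, na.rm = TRUE)
  }, integer(1))
  clip_map <- setNames(clip_at, uniq)
  pos <- unname(clip_map[reads$sequence])
  clipped_len <- ifelse(is.na(pos), nchar(reads$sequence), pos - 1L)
  adapter_only <- !is.na(pos) & clipped_len == 0L
  in_window <- clipped_len >= params$mirna_min_len &
    clipped_len <= params$mirna_max_len
  processed <- !adapter_only & in_window
  too_short <- !adapter_only & !in_window
  out <- reads[processed, , drop = FALSE]
  if (nrow(out) > 0L) {
    len <- clipped_len[processed]
    out$sequence <- substr(out$sequence, 1L, len)
    out$qualities <- purrr::map2(out$qualities, len, function(q, l) q[seq_len(l)])
  }
  list(
    reads = out,
    counts = tibble(
      input = nrow(reads),
      processed = sum(processed),
      too_short = sum(too_short),
      adapter_only = sum(adapter_only)
    )
  )
}

#' Full small-RNA processing for one stage
#'
#' Chains the mean-quality filter and adapter clipping, returning processed
#' reads together with the per-stage bookkeeping table (raw, quality
#' filtered, too-short, adapter-only and processed counts plus the mean
#' processed read length).
#'
#' @param reads Raw read tibble.
#' @param params A [qc_params()].
#' @param stage Optional stage label recorded in the counts table.
#' @return List with `reads` and `counts` (one-row tibble).
#' @export
qc_mirna <- function(reads, params = qc_params(), stage = NA_character_) {
  qf <- filter_by_mean_quality(reads, params)
  cl <- clip_adapters(qf$reads, params)
  counts <- tibble(
    stage = stage,
    total_raw_reads = nrow(reads),
    quality_filtered_reads = qf$counts$kept,
    too_short_reads = cl$counts$too_short,
    adapter_only_reads = cl$counts$adapter_only,
    processed_reads = cl$counts$processed,
    mean_read_length = if (nrow(cl$reads) > 0L) {
      mean(nchar(cl$reads$sequence))
    } else NA_real_
  )
  list(reads = cl$reads, counts = counts)
}

#' Mask low-complexity sequence
#'
#' A DUST-style triplet-composition masker: within each window the score
#' `sum(c_t * (c_t - 1) / 2) / (n_triplets - 1)` is computed over the counts
#' `c_t` of overlapping 3-mers (triplets containing N are ignored); windows
#' whose score exceeds the threshold are replaced by N. Windows slide by half
#' the window size. This is a declared stand-in for library-based repeat
#' masking: it flags tandem/low-complexity sequence only, not interspersed
#' repeats.
#'
#' @param sequence Character vector of nucleotide sequences.
#' @param window Window size in nt (default 64).
#' @param threshold DUST score threshold (default 2.0).
#' @return Character vector of masked sequences, with an `n_masked`
#'   attribute giving the per-sequence count of newly masked bases.
#' @export
mask_low_complexity <- function(sequence, window = 64L, threshold = 2.0) {
  masked <- vapply(sequence, function(s) {
    n <- nchar(s)
    if (n < 3L) return(s)
    chars <- seq_to_chars(s)
    step <- max(1L, window %/% 2L)
    starts <- unique(c(seq(1L, max(n - window + 1L, 1L), by = step)))
    for (st in starts) {
      en <- min(st + window - 1L, n)
      if (dust_score(chars[st:en]) > threshold) {
        chars[st:en] <- "N"
      }
    }
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  attr(masked, "n_masked") <-
    vapply(seq_along(masked), function(i) {
      sum(seq_to_chars(masked[i]) == "N") - sum(seq_to_chars(sequence[i]) == "N")
    }, integer(1))
  masked
}

# Brute-force DUST triplet score of a character window.
dust_score <- function(chars, .skip_n = TRUE) {
  n <- length(chars)
  if (n < 4L) return(0)
  trip <- paste0(chars[1:(n - 2L)], chars[2:(n - 1L)], chars[3:n])
  if (.skip_n) trip <- trip[!grepl("N", trip, fixed = TRUE)]
  k <- length(trip)
  if (k < 2L) return(0)
  cnt <- table(trip)
  sum(cnt * (cnt - 1) / 2) / (k - 1)
}
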