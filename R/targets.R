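#' Target-scan parameters
#'
#' Settings for miRanda-style target prediction. The three reporting filters
#' (score, duplex free energy, minimum targets per miRNA) follow the
#' published false-positive-limiting configuration (Score > 100,
#' deltaG < -19 kcal/mol, at least 2 target transcripts); the alignment
#' constants (+5 Watson-Crick, +1 G:U, -3 mismatch, gaps -9/-4, 5' weight
#' 2.0 over miRNA positions 1-11) follow the miRanda scoring scheme.
#'
#' @param min_score Report hits with score strictly above this (default 100).
#' @param max_dg Report hits with duplex energy strictly below this, in
#'   kcal/mol (default -19).
#' @param min_targets_per_mirna Minimum distinct target transcripts a miRNA
#'   must retain to be reported at all (default 2).
#' @param seed_start,seed_end Seed positions (miRNA 5' coordinates, default
#'   2--7) that must be Watson-Crick paired.
#' @param fiveprime_weight Score multiplier over miRNA positions 1-11.
#' @param allow_pos1_mismatch The 5'-most miRNA nucleotide is never required
#'   to pair (default `TRUE`, reflecting Argonaute anchoring of position 1).
#' @param allow_gu_in_seed Accept G:U wobbles inside the seed (default
#'   `FALSE`).
#' @param report_floor Raw-score floor below which candidate local optima
#'   are not enumerated (default 40).
#' @return A `scan_params` list.
#' @export
scan_params <- function(min_score = 100, max_dg = -19,
                        min_targets_per_mirna = 2L, seed_start = 2L,
                        seed_end = 7L, fiveprime_weight = 2.0,
                        allow_pos1_mismatch = TRUE,
                        allow_gu_in_seed = FALSE, report_floor = 40) {
  if (!(seed_start < seed_end && seed_end <= 8L)) {
    abort("require seed_start < seed_end <= 8")
  }
  if (min_targets_per_mirna < 1L) abort("min_targets_per_mirna must be >= 1")
  structure(
    list(
      min_score = min_score, max_dg = max_dg,
      min_targets_per_mirna = as.integer(min_targets_per_mirna),
      seed_start = as.integer(seed_start), seed_end = as.integer(seed_end),
      fiveprime_weight = fiveprime_weight,
      allow_pos1_mismatch = allow_pos1_mismatch,
      allow_gu_in_seed = allow_gu_in_seed,
      report_floor = report_floor
    ),
    class = "scan_params"
  )
}

# complementarity classes between a miRNA base and a target (mRNA) base,
# both read as RNA (T == U)
pair_class <- function(mb, tb) {
  wc <- (mb == "A" & tb == "U") | (mb == "U" & tb == "A") |
    (mb == "C" & tb == "G") | (mb == "G" & tb == "C")
  gu <- (mb == "G" & tb == "U") | (mb == "U" & tb == "G")
  ifelse(wc, "WC", ifelse(gu, "GU", "MM"))
}

as_rna_chars <- function(x, what) {
  chars <- seq_to_chars(toupper(x))
  chars[chars == "T"] <- "U"
  bad <- setdiff(unique(chars), c("A", "C", "G", "U", "N"))
  if (length(bad) > 0L) {
    abort(paste0("invalid characters in ", what, ": ",
                 paste(bad, collapse = ", ")))
  }
  chars
}

#' Scan one miRNA against one 3'-UTR
#'
#' Local alignment of the reversed miRNA (3' to 5') along the UTR (5' to 3')
#' under complementarity scoring: Watson-Crick pair +5, G:U wobble +1,
#' mismatch -3, gap open -9, gap extend -4, with pair scores over miRNA
#' positions 1--11 multiplied by the 5' weight. All non-overlapping local
#' optima scoring at least the reporting floor are returned as unfiltered
#' candidates, each carrying its duplex free energy and seed-pairing status.
#'
#' @param mirna Mature miRNA sequence, 5' to 3' (RNA or DNA letters),
#'   length 15--40.
#' @param utr Target 3'-UTR sequence, 5' to 3'.
#' @param params A [scan_params()].
#' @param mirna_id,target_id Labels stamped on the hits.
#' @return Tibble of candidate hits: `mirna_id`, `target_id`, `start`,
#'   `end` (1-based UTR window), `score`, `dg`, `seed_paired`, `n_wc`,
#'   `pairing` (list of per-position pairing tables) and `alignment`
#'   (three-line rendering, miRNA 3'->5' on top).
#' @export
scan_pair <- function(mirna, utr, params = scan_params(),
                      mirna_id = "mirna", target_id = "target") {
  mchars <- as_rna_chars(mirna, "miRNA")
  tchars <- as_rna_chars(utr, "UTR")
  L <- length(mchars)
  if (L < 15L || L > 40L) abort("miRNA length must be within [15, 40]")
  if (length(tchars) == 0L) abort("empty UTR")
  mrev <- rev(mchars)                 # row i = miRNA position L - i + 1
  mpos <- L - seq_len(L) + 1L
  weight <- ifelse(mpos <= 11L, params$fiveprime_weight, 1)
  masked <- rep(FALSE, length(tchars))
  hits <- list()
  repeat {
    hit <- sw_complement(mrev, mpos, weight, tchars, masked,
                         params$report_floor)
    if (is.null(hit)) break
    pairing <- hit$pairing
    pairing$mirna_base <- mchars[pairing$mirna_pos]
    sp <- seed_check(pairing, params)
    dg <- duplex_energy(pairing)
    hits[[length(hits) + 1L]] <- tibble(
      mirna_id = mirna_id, target_id = target_id,
      start = hit$t_start, end = hit$t_end,
      score = hit$score, dg = dg, seed_paired = sp,
      n_wc = sum(pairing$type == "WC"),
      pairing = list(pairing),
      alignment = render_alignment(hit, mchars, tchars)
    )
    masked[hit$t_start:hit$t_end] <- TRUE
    if (all(masked)) break
  }
  if (length(hits) == 0L) {
    return(tibble(
      mirna_id = character(0), target_id = character(0),
      start = integer(0), end = integer(0), score = numeric(0),
      dg = numeric(0), seed_paired = logical(0), n_wc = integer(0),
      pairing = list(), alignment = character(0)
    ))
  }
  dplyr::bind_rows(hits)
}

# Smith-Waterman with affine gaps over complementarity scores; masked target
# columns are unusable. Returns the best local hit above `floor`, or NULL.
sw_complement <- function(mrev, mpos, weight, tchars, masked, floor,
                          gap_open = 9, gap_ext = 4) {
  m <- length(mrev)
  n <- length(tchars)
  NEG <- -1e9
  base_score <- matrix(-3, m, n)
  for (i in seq_len(m)) {
    cls <- pair_class(mrev[i], tchars)
    base_score[i, ] <- ifelse(cls == "WC", 5, ifelse(cls == "GU", 1, -3)) *
      weight[i]
  }
  base_score[, masked] <- NEG
  H <- matrix(0, m + 1L, n + 1L)
  E <- matrix(NEG, m + 1L, n + 1L)   # gap in miRNA (consumes target)
  F_ <- matrix(NEG, m + 1L, n + 1L)  # gap in target (consumes miRNA)
  for (i in 2L:(m + 1L)) {
    for (j in 2L:(n + 1L)) {
      if (masked[j - 1L]) next
      E[i, j] <- max(H[i, j - 1L] - gap_open, E[i, j - 1L] - gap_ext)
      F_[i, j] <- max(H[i - 1L, j] - gap_open, F_[i - 1L, j] - gap_ext)
      diag <- H[i - 1L, j - 1L] + base_score[i - 1L, j - 1L]
      H[i, j] <- max(0, diag, E[i, j], F_[i, j])
    }
  }
  if (max(H) < floor) return(NULL)
  top <- which(H == max(H), arr.ind = TRUE)
  # deterministic pick: smallest target end, then smallest miRNA row
  top <- top[order(top[, 2], top[, 1]), , drop = FALSE]
  i <- top[1, 1]; j <- top[1, 2]
  score <- H[i, j]
  path <- list()
  state <- "H"
  while (i > 1L || j > 1L) {
    if (state == "H") {
      if (H[i, j] == 0) break
      diag <- H[i - 1L, j - 1L] + base_score[i - 1L, j - 1L]
      if (H[i, j] == diag) {
        path[[length(path) + 1L]] <- c(i - 1L, j - 1L)
        i <- i - 1L; j <- j - 1L
      } else if (H[i, j] == E[i, j]) {
        state <- "E"
      } else {
        state <- "F"
      }
    } else if (state == "E") {
      path[[length(path) + 1L]] <- c(NA_integer_, j - 1L)
      if (E[i, j] == H[i, j - 1L] - gap_open) state <- "H"
      j <- j - 1L
    } else {
      path[[length(path) + 1L]] <- c(i - 1L, NA_integer_)
      if (F_[i, j] == H[i - 1L, j] - gap_open) state <- "H"
      i <- i - 1L
    }
  }
  path <- rev(path)
  rows <- vapply(path, `[`, integer(1), 1L)
  cols <- vapply(path, `[`, integer(1), 2L)
  aligned <- !is.na(rows) & !is.na(cols)
  pairing <- tibble(
    mirna_pos = mpos[rows[aligned]],
    target_pos = cols[aligned],
    target_base = tchars[cols[aligned]],
    type = pair_class(mrev[rows[aligned]], tchars[cols[aligned]])
  )
  list(
    score = score,
    t_start = min(cols, na.rm = TRUE), t_end = max(cols, na.rm = TRUE),
    rows = rows, cols = cols,
    pairing = pairing
  )
}

render_alignment <- function(hit, mchars, tchars) {
  L <- length(mchars)
  mrev <- rev(mchars)
  top <- vapply(seq_along(hit$rows), function(k) {
    r <- hit$rows[k]
    if (is.na(r)) "-" else mrev[r]
  }, character(1))
  bot <- vapply(seq_along(hit$cols), function(k) {
    cpos <- hit$cols[k]
    if (is.na(cpos)) "-" else tchars[cpos]
  }, character(1))
  mid <- vapply(seq_along(top), function(k) {
    if (top[k] == "-" || bot[k] == "-") return(" ")
    cls <- pair_class(top[k], bot[k])
    if (cls == "WC") "|" else if (cls == "GU") ":" else " "
  }, character(1))
  paste(
    paste0("miRNA  3' ", paste(top, collapse = ""), " 5'"),
    paste0("          ", paste(mid, collapse = "")),
    paste0("target 5' ", paste(bot, collapse = ""), " 3'"),
    sep = "\n"
  )
}

# Nearest-neighbor RNA/RNA stacking parameters at 37 C (kcal/mol), keyed by
# the 5'->3' dinucleotide on the miRNA strand when both positions form
# Watson-Crick pairs; the 16 values are the 10 unique Watson-Crick stacks
# plus their reverse-complement completions. Duplex initiation +4.09.
NN_STACK <- c(
  AA = -0.93, AU = -1.10, UA = -1.33, CU = -2.08, CA = -2.11,
  GU = -2.24, GA = -2.35, CG = -2.36, GG = -3.26, GC = -3.42,
  UU = -0.93, AG = -2.08, UG = -2.11, AC = -2.24, UC = -2.35,
  CC = -3.26
)
NN_INIT <- 4.09

#' Duplex free energy of a pairing
#'
#' Two-state nearest-neighbor estimate of the miRNA:target duplex free
#' energy: the sum of stacking terms over consecutive Watson-Crick pairs at
#' adjacent positions on both strands, plus the duplex initiation penalty.
#' Mismatched, wobble, gapped or unpaired positions break stacks and
#' contribute nothing. More negative is more stable; a fully unpaired
#' alignment scores the initiation penalty alone.
#'
#' @param pairing Pairing table of a hit (from [scan_pair()]): columns
#'   `mirna_pos`, `mirna_base`, `target_pos`, `type`.
#' @return Free energy in kcal/mol.
#' @export
duplex_energy <- function(pairing) {
  dg <- NN_INIT
  if (nrow(pairing) < 2L) return(dg)
  p <- dplyr::arrange(pairing, .data$mirna_pos)
  for (r in seq_len(nrow(p) - 1L)) {
    contiguous <- p$mirna_pos[r + 1L] == p$mirna_pos[r] + 1L &&
      abs(p$target_pos[r + 1L] - p$target_pos[r]) == 1L
    if (contiguous && p$type[r] == "WC" && p$type[r + 1L] == "WC") {
      key <- paste0(sub("T", "U", p$mirna_base[r]),
                    sub("T", "U", p$mirna_base[r + 1L]))
      dg <- dg + NN_STACK[[key]]
    }
  }
  dg
}

#' Seed-pairing check
#'
#' `TRUE` iff every miRNA seed position (positions `seed_start` to
#' `seed_end` from the 5' end, default 2--7) is Watson-Crick paired in the
#' hit (G:U counts only when `allow_gu_in_seed`). Position 1 is exempt by
#' default, reflecting that the 5'-most nucleotide of an Argonaute-bound
#' guide is not paired to the target; with `allow_pos1_mismatch = FALSE` it
#' must pair as well.
#'
#' @param pairing Pairing table of a hit (from [scan_pair()]).
#' @param params A [scan_params()].
#' @return Logical flag.
#' @export
seed_check <- function(pairing, params = scan_params()) {
  required <- params$seed_start:params$seed_end
  if (!params$allow_pos1_mismatch) required <- union(1L, required)
  ok_types <- if (params$allow_gu_in_seed) c("WC", "GU") else "WC"
  all(vapply(required, function(p) {
    row <- which(pairing$mirna_pos == p)
    length(row) == 1L && pairing$type[row] %in% ok_types
  }, logical(1)))
}

#' Apply the reporting filters to candidate hits
#'
#' Keeps candidates with `score > min_score`, `dg < max_dg` and a paired
#' seed, then drops every miRNA that does not retain at least
#' `min_targets_per_mirna` distinct target transcripts. Output ordering is
#' deterministic: (`mirna_id`, `target_id`, `start`).
#'
#' @param candidates Candidate tibble from [scan_pair()]/[scan_targets()].
#' @param params A [scan_params()].
#' @return Filtered, ordered hit tibble.
#' @export
apply_filters <- function(candidates, params = scan_params()) {
  if (nrow(candidates) == 0L) return(candidates)
  passing <- dplyr::filter(
    candidates,
    .data$score > params$min_score,
    .data$dg < params$max_dg,
    .data$seed_paired
  )
  keep_mirnas <- passing |>
    dplyr::distinct(.data$mirna_id, .data$target_id) |>
    dplyr::count(.data$mirna_id) |>
    dplyr::filter(.data$n >= params$min_targets_per_mirna) |>
    dplyr::pull(.data$mirna_id)
  passing |>
    dplyr::filter(.data$mirna_id %in% keep_mirnas) |>
    dplyr::arrange(.data$mirna_id, .data$target_id, .data$start)
}

#' Scan a miRNA set against a set of 3'-UTRs
#'
#' Runs [scan_pair()] over every (miRNA, UTR) combination and applies the
#' reporting filters.
#'
#' @param mirnas Tibble with `mirna_id`/`cluster_id` and
#'   `sequence`/`consensus` columns, or a named character vector.
#' @param targets Tibble with `id`/`ref_id`/`family` and `utr` (or
#'   `sequence`) columns, or a named character vector of UTRs.
#' @param params A [scan_params()].
#' @return List with `hits` (filtered) and `candidates` (all scored local
#'   optima).
#' @export
scan_targets <- function(mirnas, targets, params = scan_params()) {
  if (is.character(mirnas)) {
    mirnas <- tibble(mirna_id = names(mirnas), sequence = unname(mirnas))
  }
  mid <- pick_col(mirnas, "mirna_id", "cluster_id")
  mseq <- pick_col(mirnas, "sequence", "consensus")
  if (is.character(targets)) {
    targets <- tibble(id = names(targets), utr = unname(targets))
  }
  tid <- pick_col(targets, "id", "ref_id", "family")
  tutr <- pick_col(targets, "utr", "sequence")
  combos <- tidyr::expand_grid(mi = seq_along(mid), ti = seq_along(tid))
  candidates <- purrr::pmap(combos, function(mi, ti) {
    scan_pair(mseq[mi], tutr[ti], params,
              mirna_id = mid[mi], target_id = tid[ti])
  }) |>
    dplyr::bind_rows()
  list(hits = apply_filters(candidates, params), candidates = candidates)
}
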