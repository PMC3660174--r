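# Global-alignment identity: matches / alignment columns (gaps included).
# `protein` switches the scoring to BLOSUM62; nucleotide mode uses +5/-4.
pairwise_identity <- function(queries, reference, protein = FALSE) {
  if (protein) {
    submat <- get_blosum62()
    set <- Biostrings::AAStringSet(queries)
    subj <- Biostrings::AAString(reference)
    go <- 10; ge <- 0.5
  } else {
    submat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 5, mismatch = -4, baseOnly = FALSE
    )
    set <- Biostrings::DNAStringSet(queries)
    subj <- Biostrings::DNAString(reference)
    go <- 10; ge <- 1
  }
  aln <- Biostrings::pairwiseAlignment(
    set, subj, type = "global", substitutionMatrix = submat,
    gapOpening = go, gapExtension = ge
  )
  Biostrings::nmatch(aln) /
    nchar(as.character(Biostrings::pattern(aln)))
}

#' Cluster stage-labelled protein sequences into shared and unique clusters
#'
#' Greedy incremental clustering in the CD-HIT style: sequences are sorted by
#' decreasing length (ties by id), and each sequence joins the first existing
#' cluster whose representative it matches at global-alignment identity
#' strictly above the threshold, otherwise it founds a new cluster. A cluster
#' is shared when it contains members from both stages.
#'
#' @param newborn,adult Tibbles with `id` and `sequence` columns (protein
#'   sequences; an optional `family` column is carried into the summary), or
#'   named character vectors.
#' @param identity_threshold Global identity threshold (default 0.8,
#'   strict `>`).
#' @return List with `clusters` (tibble: `cluster_id`, `id`, `stage`,
#'   `family`, `sequence`), and `summary` (per family when families are
#'   given, else overall: `n_unique_newborn`, `n_unique_adult`, `n_shared`).
#' @export
cluster_proteins <- function(newborn, adult, identity_threshold = 0.8) {
  as_tbl <- function(x, stage) {
    if (is.character(x)) {
      x <- tibble(id = names(x) %||% sprintf("%s%04d", stage, seq_along(x)),
                  sequence = unname(x))
    }
    if (!"family" %in% names(x)) x$family <- NA_character_
    dplyr::mutate(x, stage = stage)
  }
  all_seqs <- dplyr::bind_rows(
    as_tbl(newborn, "newborn"), as_tbl(adult, "adult")
  ) |>
    dplyr::arrange(dplyr::desc(nchar(.data$sequence)), .data$id)
  n <- nrow(all_seqs)
  cluster_of <- integer(n)
  reps <- character(0)
  for (i in seq_len(n)) {
    s <- all_seqs$sequence[i]
    assigned <- 0L
    if (length(reps) > 0L) {
      idents <- pairwise_identity(reps, s, protein = TRUE)
      hit <- which(idents > identity_threshold)
      if (length(hit) > 0L) assigned <- hit[1L]
    }
    if (assigned == 0L) {
      reps <- c(reps, s)
      assigned <- length(reps)
    }
    cluster_of[i] <- assigned
  }
  clusters <- dplyr::mutate(all_seqs, cluster_id = cluster_of) |>
    dplyr::select("cluster_id", "id", "stage", "family", "sequence")
  per_cluster <- clusters |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(
      family = .data$family[1],
      has_newborn = any(.data$stage == "newborn"),
      has_adult = any(.data$stage == "adult"),
      .groups = "drop"
    )
  grouping <- if (all(is.na(per_cluster$family))) character(0) else "family"
  summary <- per_cluster |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(
      n_unique_newborn = sum(.data$has_newborn & !.data$has_adult),
      n_unique_adult = sum(.data$has_adult & !.data$has_newborn),
      n_shared = sum(.data$has_newborn & .data$has_adult),
      .groups = "drop"
    )
  list(clusters = clusters, summary = summary)
}
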