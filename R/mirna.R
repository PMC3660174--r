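#' Cluster processed small-RNA reads into miRNA clusters
#'
#' Greedy incremental clustering of processed reads, CD-HIT style with the
#' accurate-mode rule: unique sequences are ordered by decreasing length,
#' then decreasing multiplicity, then sequence, and each joins the
#' best-matching (highest-identity) existing cluster whose representative it
#' matches at global identity strictly above the threshold, else founds a
#' new cluster. Identity is matches over global-alignment columns. The
#' cluster consensus is the per-column majority over members (weighted by
#' multiplicity) in representative coordinates. Note that for reads of at
#' most 40 nt the default 0.98 threshold admits only identical sequences:
#' one mismatch in a 40-mer is already 39/40 = 0.975.
#'
#' @param reads Read tibble (uses `sequence`) or character vector.
#' @param identity Identity threshold (default 0.98, strict `>`).
#' @param stage Optional stage label stamped on the clusters.
#' @param total_processed Denominator for counts-per-million (default: the
#'   number of input reads).
#' @return Tibble: `cluster_id`, `consensus`, `n_reads`, `cpm`, `stage`.
#' @export
cluster_mirnas <- function(reads, identity = 0.98, stage = NA_character_,
                           total_processed = NULL) {
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  total_processed <- total_processed %||% length(seqs)
  if (length(seqs) == 0L) {
    return(tibble(cluster_id = character(0), consensus = character(0),
                  n_reads = integer(0), cpm = numeric(0),
                  stage = character(0)))
  }
  mult <- table(seqs)
  uniq <- tibble(
    sequence = names(mult),
    n = as.integer(mult)
  ) |>
    dplyr::arrange(dplyr::desc(nchar(.data$sequence)),
                   dplyr::desc(.data$n), .data$sequence)
  reps <- character(0)
  members <- list()
  for (i in seq_len(nrow(uniq))) {
    s <- uniq$sequence[i]
    joined <- 0L
    if (length(reps) > 0L) {
      exact <- match(s, reps)
      if (!is.na(exact)) {
        joined <- exact
      } else {
        idents <- pairwise_identity(reps, s)
        ok <- idents > identity
        if (any(ok)) joined <- which(ok)[which.max(idents[ok])]
      }
    }
    if (joined == 0L) {
      reps <- c(reps, s)
      joined <- length(reps)
      members[[joined]] <- integer(0)
    }
    members[[joined]] <- c(members[[joined]], i)
  }
  prefix <- if (is.na(stage)) "c" else paste0(stage, "_c")
  out <- purrr::map(seq_along(reps), function(ci) {
    idx <- members[[ci]]
    n_reads <- sum(uniq$n[idx])
    cons <- cluster_consensus(reps[ci], uniq$sequence[idx], uniq$n[idx])
    tibble(consensus = cons, n_reads = n_reads)
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(dplyr::desc(.data$n_reads), .data$consensus) |>
    dplyr::mutate(
      cluster_id = sprintf("%s%04d", prefix, dplyr::row_number()),
      cpm = 1e6 * .data$n_reads / total_processed,
      stage = stage
    ) |>
    dplyr::select("cluster_id", "consensus", "n_reads", "cpm", "stage")
  out
}

# Majority-vote consensus of member sequences in representative coordinates.
cluster_consensus <- function(rep_seq, member_seqs, weights) {
  if (all(member_seqs == rep_seq)) return(rep_seq)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 5, mismatch = -4, baseOnly = FALSE
  )
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(member_seqs), Biostrings::DNAString(rep_seq),
    type = "global", substitutionMatrix = submat,
    gapOpening = 10, gapExtension = 1
  )
  m <- do.call(rbind, strsplit(as.character(Biostrings::aligned(aln)), "",
                               fixed = TRUE))
  cons <- vapply(seq_len(ncol(m)), function(j) {
    tab <- tapply(weights, m[, j], sum)
    tab <- tab[names(tab) %in% DNA_BASES]
    if (length(tab) == 0L) return("")
    names(tab)[which.max(tab)]  # ties: lexicographically smallest
  }, character(1))
  paste(cons[cons != ""], collapse = "")
}

#' Keep clusters above a minimum read count
#'
#' @param clusters Cluster tibble from [cluster_mirnas()].
#' @param min_reads Minimum member reads (default 100, inclusive).
#' @return Filtered tibble.
#' @export
abundance_filter <- function(clusters, min_reads = 100L) {
  dplyr::filter(clusters, .data$n_reads >= min_reads)
}

#' Compare newborn and adult miRNA cluster sets
#'
#' Cross-matches the two consensus sets at the identity threshold (one-to-one
#' pairing, highest identity first): pairs sharing a cross-cluster are
#' "shared", the rest are stage-unique. Differential expression on the
#' shared clusters is assessed with [noiseq_sim()] on their read counts.
#'
#' @param newborn,adult Cluster tibbles from [cluster_mirnas()].
#' @param identity Identity threshold (default 0.98, strict `>`).
#' @param prob_threshold,nss,pnr,v,k NOISeq-sim parameters.
#' @param seed Seed for the NOISeq-sim simulation.
#' @return A `stage_comparison`: list with `shared` (tibble pairing the
#'   clusters with both stages' counts and cpm), `unique_newborn`,
#'   `unique_adult`, and `diff` (a `noiseq_sim` on shared clusters, `NULL`
#'   when there are none).
#' @export
compare_stages <- function(newborn, adult, identity = 0.98,
                           prob_threshold = 0.9, nss = 5L, pnr = 0.2,
                           v = 0.02, k = 0.5, seed = 1) {
  if (nrow(newborn) == 0L || nrow(adult) == 0L) {
    return(structure(
      list(shared = tibble(), unique_newborn = newborn,
           unique_adult = adult, diff = NULL),
      class = "stage_comparison"
    ))
  }
  idm <- sapply(adult$consensus, function(a) {
    ifelse(newborn$consensus == a, 1,
           pairwise_identity(newborn$consensus, a))
  })
  idm <- matrix(idm, nrow = nrow(newborn))
  cand <- which(idm > identity, arr.ind = TRUE)
  pairs <- list()
  if (nrow(cand) > 0L) {
    ord <- order(idm[cand], decreasing = TRUE)
    cand <- cand[ord, , drop = FALSE]
    used_n <- used_a <- integer(0)
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (i %in% used_n || j %in% used_a) next
      used_n <- c(used_n, i); used_a <- c(used_a, j)
      pairs[[length(pairs) + 1L]] <- tibble(
        newborn_cluster = newborn$cluster_id[i],
        adult_cluster = adult$cluster_id[j],
        consensus = newborn$consensus[i],
        n_reads_newborn = newborn$n_reads[i],
        n_reads_adult = adult$n_reads[j],
        cpm_newborn = newborn$cpm[i],
        cpm_adult = adult$cpm[j]
      )
    }
  }
  shared <- if (length(pairs)) {
    dplyr::bind_rows(pairs)
  } else {
    tibble(
      newborn_cluster = character(0), adult_cluster = character(0),
      consensus = character(0), n_reads_newborn = integer(0),
      n_reads_adult = integer(0), cpm_newborn = numeric(0),
      cpm_adult = numeric(0)
    )
  }
  un <- newborn[!newborn$cluster_id %in% shared$newborn_cluster, ,
                drop = FALSE]
  ua <- adult[!adult$cluster_id %in% shared$adult_cluster, , drop = FALSE]
  diff <- NULL
  if (nrow(shared) > 0L) {
    diff <- noiseq_sim(
      shared$n_reads_newborn, shared$n_reads_adult,
      feature_ids = shared$newborn_cluster,
      k = k, nss = nss, pnr = pnr, v = v,
      prob_threshold = prob_threshold, seed = seed
    )
  }
  structure(
    list(shared = shared, unique_newborn = un, unique_adult = ua,
         diff = diff),
    class = "stage_comparison"
  )
}

#' @export
print.stage_comparison <- function(x, ...) {
  cat(sprintf(
    "<stage_comparison> %d shared, %d newborn-unique, %d adult-unique\n",
    nrow(x$shared), nrow(x$unique_newborn), nrow(x$unique_adult)
  ))
  invisible(x)
}

#' Abundance profile plot of a stage comparison
#'
#' Per-cluster abundance bars (counts per million, log10) for each stage,
#' shared clusters matched by fill colour; the dashed line marks a
#' configurable copy-number threshold.
#'
#' @param object A `stage_comparison`.
#' @param copy_threshold Reference line on the read-count scale (default
#'   1000).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stage_comparison <- function(object, copy_threshold = 1000, ...) {
  shared_long <- if (nrow(object$shared) > 0L) {
    dplyr::bind_rows(
      tibble(cluster = object$shared$newborn_cluster,
             pair = object$shared$newborn_cluster,
             stage = "newborn", n_reads = object$shared$n_reads_newborn),
      tibble(cluster = object$shared$adult_cluster,
             pair = object$shared$newborn_cluster,
             stage = "adult", n_reads = object$shared$n_reads_adult)
    )
  } else tibble()
  uniq_long <- dplyr::bind_rows(
    tibble(cluster = object$unique_newborn$cluster_id, pair = "unique",
           stage = "newborn", n_reads = object$unique_newborn$n_reads),
    tibble(cluster = object$unique_adult$cluster_id, pair = "unique",
           stage = "adult", n_reads = object$unique_adult$n_reads)
  )
  df <- dplyr::bind_rows(shared_long, uniq_long)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster, y = .data$n_reads,
                                   fill = .data$pair)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = copy_threshold, colour = "red",
                        linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~stage, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "reads per cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Annotate miRNA clusters against a mature-miRNA reference
#'
#' Best hit per cluster: the reference entry with the fewest mismatches over
#' a full-length-of-the-shorter ungapped alignment (the shorter sequence
#' slides along the longer; U and T are interchangeable). Hits with more
#' than `max_mismatches` are left unannotated. The species tag is parsed
#' from the reference header (second header token when present, otherwise
#' the id prefix before the first dash).
#'
#' @param clusters Cluster tibble from [cluster_mirnas()].
#' @param reference Mature-miRNA reference: a tibble from [read_fasta()]
#'   or a path to a FASTA file.
#' @param max_mismatches Maximum mismatches for a reported hit (default 2).
#' @return The cluster tibble with `hit_id`, `species`, `mismatches`
#'   columns (`NA` when unannotated).
#' @export
annotate_mirnas <- function(clusters, reference, max_mismatches = 2L) {
  if (is.character(reference) && length(reference) == 1L) {
    reference <- read_fasta(reference, mode = "rna")
  }
  ref_seq <- gsub("U", "T", toupper(reference$sequence), fixed = TRUE)
  species <- parse_species(reference)
  best <- purrr::map(clusters$consensus, function(cons) {
    cons <- gsub("U", "T", toupper(cons), fixed = TRUE)
    mm <- vapply(ref_seq, min_sliding_mismatches, integer(1), b = cons)
    j <- which.min(mm)
    list(hit = j, mm = mm[j])
  })
  hit_j <- vapply(best, `[[`, integer(1), "hit")
  mm <- vapply(best, `[[`, integer(1), "mm")
  ok <- mm <= max_mismatches
  dplyr::mutate(
    clusters,
    hit_id = ifelse(ok, reference$id[hit_j], NA_character_),
    species = ifelse(ok, species[hit_j], NA_character_),
    mismatches = ifelse(ok, mm, NA_integer_)
  )
}

# Minimum Hamming distance of the shorter of a, b over all ungapped
# placements along the longer.
min_sliding_mismatches <- function(a, b) {
  if (nchar(a) < nchar(b)) {
    short <- a; long <- b
  } else {
    short <- b; long <- a
  }
  ls <- nchar(short); ll <- nchar(long)
  sc <- seq_to_chars(short)
  best <- ls
  for (off in 0:(ll - ls)) {
    w <- substr(long, off + 1L, off + ls)
    d <- sum(seq_to_chars(w) != sc)
    if (d < best) best <- d
    if (best == 0L) break
  }
  as.integer(best)
}

parse_species <- function(reference) {
  desc <- reference$description %||% reference$id
  vapply(seq_along(desc), function(i) {
    toks <- strsplit(desc[i], "\\s+")[[1]]
    if (length(toks) >= 2L) {
      paste(toks[-1L], collapse = "_")
    } else {
      sub("-.*$", "", reference$id[i])
    }
  }, character(1))
}

#' Per-species hit summary of annotated clusters
#'
#' Counts annotated clusters per species and the percentage of total hits
#' each species represents (one-decimal convention in reports).
#'
#' @param annotated Output of [annotate_mirnas()].
#' @return Tibble: `species`, `n_hits`, `pct_of_hits`.
#' @export
species_hit_summary <- function(annotated) {
  hits <- dplyr::filter(annotated, !is.na(.data$species))
  hits |>
    dplyr::count(.data$species, name = "n_hits") |>
    dplyr::mutate(pct_of_hits = 100 * .data$n_hits / sum(.data$n_hits)) |>
    dplyr::arrange(dplyr::desc(.data$n_hits))
}
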