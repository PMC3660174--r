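#' Parameters of the binomial contig-distinctness model
#'
#' Two sequences aligned to the same reference are called the same gene when
#' the number of differing determined positions does not exceed what the
#' sequencing error rate explains. With per-base substitution error `e` on
#' each sequence, a column mismatches by error alone with probability
#' `p_mm = 1 - (1 - e)^2`; over `L` comparable columns the mismatch count is
#' Binomial(L, p_mm), and the pair is distinct when the observed count
#' exceeds the upper `1 - alpha` quantile.
#'
#' @param error_rate Per-base substitution error rate `e` (default 0.015).
#' @param alpha One-sided tail probability (default 0.01).
#' @param min_variant_reads Support a minority residue needs before it
#'   counts toward the difference count, when support information is
#'   available (default 3).
#' @return A `distinctness_params` list (with the derived `p_mismatch`).
#' @export
distinctness_params <- function(error_rate = 0.015, alpha = 0.01,
                                min_variant_reads = 3L) {
  if (error_rate <= 0 || error_rate >= 1) abort("error_rate must be in (0,1)")
  if (alpha <= 0 || alpha >= 0.5) abort("alpha must be in (0, 0.5)")
  structure(
    list(
      error_rate = error_rate,
      alpha = alpha,
      min_variant_reads = as.integer(min_variant_reads),
      p_mismatch = 1 - (1 - error_rate)^2
    ),
    class = "distinctness_params"
  )
}

#' Largest error-explainable mismatch count
#'
#' The smallest integer `Q` with `P(Binomial(L, p_mm) <= Q) >= 1 - alpha`;
#' two sequences are distinct when they differ at more than `Q` of their `L`
#' comparable positions.
#'
#' @param L Number of comparable (both-determined) columns.
#' @param params A [distinctness_params()].
#' @return Integer threshold `Q` (vectorised over `L`).
#' @export
distinctness_threshold <- function(L, params = distinctness_params()) {
  qbinom(1 - params$alpha, L, params$p_mismatch)
}

#' Test whether two aligned sequences are distinct genes
#'
#' Both sequences must be in common reference coordinates (equal length;
#' `N` or `-` marks undetermined positions). The comparison runs over columns
#' where both sequences are determined; optionally, logical masks restrict
#' the difference count to positions whose residue met the variant-support
#' rule (consensus-level comparisons carry that information, bare reads do
#' not).
#'
#' @param seq_a,seq_b Aligned sequence strings of equal length.
#' @param params A [distinctness_params()].
#' @param valid_a,valid_b Optional logical vectors (one per column): does
#'   the residue at this column meet the support rule? Differing columns
#'   where either mask is `FALSE` are not counted toward `d`.
#' @return One-row tibble: `call` (`"distinct"` or `"same_gene"`), `d`, `L`,
#'   `threshold`, `p_mismatch`.
#' @export
distinctness_test <- function(seq_a, seq_b, params = distinctness_params(),
                              valid_a = NULL, valid_b = NULL) {
  a <- seq_to_chars(seq_a)
  b <- seq_to_chars(seq_b)
  if (length(a) != length(b)) {
    abort("sequences must be aligned to the same reference (equal length)")
  }
  det <- a %in% DNA_BASES & b %in% DNA_BASES
  L <- sum(det)
  if (L == 0L) abort("no comparable columns")
  diff <- det & a != b
  if (!is.null(valid_a)) diff <- diff & valid_a
  if (!is.null(valid_b)) diff <- diff & valid_b
  d <- sum(diff)
  q <- distinctness_threshold(L, params)
  tibble(
    call = if (d > q) "distinct" else "same_gene",
    d = d, L = L, threshold = q, p_mismatch = params$p_mismatch
  )
}

# Union-find with path compression.
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Minimum gene count from aligned sequences
#'
#' Groups aligned sequences (reads or consensuses in common reference
#' coordinates) by single linkage under the binomial distinctness model:
#' two sequences are linked when their difference count over comparable
#' columns does not exceed the error-explainable threshold. The number of
#' connected components is the minimum number of distinct genes consistent
#' with the sequencing error rate. Pairs with fewer than `min_overlap`
#' comparable columns contribute no link. Input order is made deterministic
#' by sorting on `id`.
#'
#' @param seqs Character vector of aligned sequences (equal length), named
#'   by id, or a tibble with `id` and `aligned` columns.
#' @param params A [distinctness_params()].
#' @param min_overlap Minimum comparable columns for a pair to be
#'   informative (default 30).
#' @param support Optional 4 x L logical matrix (rows A, C, G, T): is each
#'   residue at each column backed by at least the variant-support minimum
#'   in the underlying pileup? When given, only differing columns where both
#'   residues are supported count toward the difference -- isolated,
#'   error-attributable differences then no longer inflate `d`.
#' @return List with `n_genes` and `membership` (tibble: `id`, `group`).
#' @export
count_min_genes <- function(seqs, params = distinctness_params(),
                            min_overlap = 30L, support = NULL) {
  if (is.data.frame(seqs)) {
    ids <- seqs$id
    seqs <- setNames(seqs$aligned, ids)
  }
  if (is.null(names(seqs))) {
    names(seqs) <- sprintf("seq%05d", seq_along(seqs))
  }
  seqs <- seqs[order(names(seqs))]
  n <- length(seqs)
  if (n == 0L) return(list(n_genes = 0L, membership = tibble(
    id = character(0), group = integer(0)
  )))
  if (n == 1L) {
    return(list(n_genes = 1L,
                membership = tibble(id = names(seqs), group = 1L)))
  }
  chars <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  ncol_aln <- ncol(chars)
  # one-hot per base: pairwise agreeing-determined and both-determined counts
  M <- matrix(0, n, n)
  D <- matrix(0, n, ncol_aln)
  Ms <- matrix(0, n, n)
  Ds <- matrix(0, n, ncol_aln)
  for (b in DNA_BASES) {
    Bb <- (chars == b) * 1
    M <- M + tcrossprod(Bb)
    D <- D + Bb
    if (!is.null(support)) {
      Sb <- Bb * rep(support[b, ], each = n)
      Ms <- Ms + tcrossprod(Sb)
      Ds <- Ds + Sb
    }
  }
  Lmat <- tcrossprod(D)        # both determined (exactly one-hot per column)
  dmat <- if (is.null(support)) {
    Lmat - M                   # differing determined columns
  } else {
    tcrossprod(Ds) - Ms        # differing columns, both residues supported
  }
  qmat <- matrix(
    distinctness_threshold(as.vector(Lmat), params), n, n
  )
  linked <- dmat <= qmat & Lmat >= min_overlap
  parent <- seq_len(n)
  for (i in seq_len(n - 1L)) {
    for (j in which(linked[i, ] & seq_len(n) > i)) {
      ri <- uf_find(parent, i)
      rj <- uf_find(parent, j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  group <- match(roots, unique(roots))
  list(
    n_genes = length(unique(group)),
    membership = tibble(id = names(seqs), group = group)
  )
}

#' Per-family minimum gene counts from a pileup
#'
#' Convenience driver: takes the aligned read rows of a pileup, derives the
#' per-column variant-support mask from the pileup's base counts, groups the
#' reads with [count_min_genes()] under that support rule, and returns the
#' per-group consensus sequences (each group's reads form their own
#' sub-pileup) together with the group count.
#'
#' @param pileup A [build_pileup()] result.
#' @param params A [distinctness_params()].
#' @param min_support,min_variant_reads Consensus-calling rules per group.
#' @param min_overlap Passed to [count_min_genes()]; the read-level default
#'   (150 columns) is higher than the generic one because pairs sharing only
#'   a short overlap give the binomial test too little power to separate
#'   isoforms near the detectable-divergence floor, and a single
#'   under-powered pair can chain two true groups together under single
#'   linkage.
#' @return List with `n_genes`, `membership`, and `consensuses` (tibble:
#'   `group`, `n_reads`, `aligned` consensus string).
#' @export
infer_gene_groups <- function(pileup, params = distinctness_params(),
                              min_support = 4L, min_variant_reads = 3L,
                              min_overlap = 150L) {
  n <- nrow(pileup$mat)
  if (n == 0L) {
    return(list(n_genes = 0L,
                membership = tibble(id = character(0), group = integer(0)),
                consensuses = tibble(group = integer(0), n_reads = integer(0),
                                     aligned = character(0))))
  }
  aligned <- apply(pileup$mat, 1L, paste, collapse = "")
  names(aligned) <- pileup$read_ids
  support <- pileup_counts(pileup) >= params$min_variant_reads
  grouping <- count_min_genes(aligned, params, min_overlap = min_overlap,
                              support = support)
  cons <- grouping$membership |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_reads = dplyr::n(),
      aligned = {
        sub <- pileup
        keep <- match(.data$id, pileup$read_ids)
        sub$mat <- pileup$mat[keep, , drop = FALSE]
        sub$read_ids <- pileup$read_ids[keep]
        consensus_sequence(call_consensus(
          sub, min_support = min_support,
          min_variant_reads = min_variant_reads
        ))
      },
      .groups = "drop"
    )
  list(n_genes = grouping$n_genes, membership = grouping$membership,
       consensuses = cons)
}
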