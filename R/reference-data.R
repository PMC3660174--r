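#' Published venom-gland toxin-family expression profile
#'
#' The per-family RPKM-normalised expression profile of the newborn and adult
#' *Crotalus simus simus* venom-gland transcriptomes (contig, mapped-read and
#' singleton counts, RPKM and percentage share per toxin family). These
#' published values serve two roles: they are the default per-family abundance
#' weights of the synthetic-data generator, and they are the worked input for
#' the percentage-share arithmetic that the acceptance checks recompute.
#'
#' @return A tibble with columns `family`, `stage`, `contigs`, `reads`,
#'   `singletons`, `rpkm`, `pct`.
#' @export
reference_family_profile <- function() {
  nb <- tibble(
    family = TOXIN_FAMILIES,
    stage = "newborn",
    contigs = c(1L, 2L, 3L, 6L, 1L, 2L, 2L, 1L, 1L, 0L, 1L, 27L, 48L, 191L, 2L),
    reads = c(395L, 42L, 62L, 483L, 143L, 346L, 15L, 1300L, 384L, 0L, 308L,
              41700L, 54601L, 156291L, 132L),
    singletons = c(1L, 1L, 0L, 5L, 2L, 4L, 0L, 0L, 0L, 0L, 0L, 37L, 79L,
                   194L, 2L),
    rpkm = c(212.20, 74.66, 81.26, 1035.42, 124.08, 245.52, 18.70, 793.68,
             501.22, 0, 383.50, 94942.21, 28306.34, 207689.54, 219.77),
    pct = c(0.06, 0.02, 0.02, 0.31, 0.04, 0.07, 0.01, 0.24, 0.15, 0, 0.11,
            28.37, 8.46, 62.07, 0.07)
  )
  ad <- tibble(
    family = TOXIN_FAMILIES,
    stage = "adult",
    contigs = c(2L, 1L, 0L, 13L, 3L, 4L, 2L, 1L, 1L, 0L, 1L, 18L, 62L, 83L, 4L),
    reads = c(334L, 11L, 0L, 1462L, 348L, 369L, 115L, 1440L, 917L, 0L, 77L,
              11015L, 69198L, 105104L, 19L),
    singletons = c(0L, 0L, 0L, 4L, 2L, 1L, 3L, 1L, 4L, 0L, 0L, 9L, 62L,
                   62L, 0L),
    rpkm = c(532.54, 56.83, 0, 9255.5, 891.07, 772.30, 437.76, 2617.77,
             3577.02, 0, 285.28, 74618.46, 106685.8, 415323.2, 92.72),
    pct = c(0.08, 0.01, 0, 1.5, 0.14, 0.12, 0.07, 0.42, 0.58, 0, 0.04,
            12.13, 17.34, 67.51, 0.01)
  )
  dplyr::bind_rows(nb, ad)
}

#' Published long-read sequencing statistics
#'
#' Per-stage pyrosequencing statistics of the newborn and adult *C. s. simus*
#' venom-gland transcriptomes: total quality-filtered reads, read-length
#' summaries, assembled-read counts and the published assembled percentage,
#' contig and singleton counts.
#'
#' @return A tibble, one row per stage.
#' @export
reference_sequencing_stats <- function() {
  tibble(
    stage = c("newborn", "adult"),
    total_reads = c(320907L, 355140L),
    mean_read_length = c(567.5, 535.4),
    max_read_length = c(1193L, 1320L),
    assembled_reads = c(276729L, 296470L),
    assembled_pct = c(86.23, 83.48),
    n_contigs = c(6047L, 6484L),
    mean_contig_length = c(560.87, 777.88),
    max_contig_length = c(5857L, 5947L),
    singletons = c(24136L, 33408L)
  )
}

#' Published small-RNA profiling statistics
#'
#' Per-stage Ion-Torrent miRNA statistics: read-processing bookkeeping
#' (raw, quality-filtered, too-short, adapter-only and processed read counts)
#' and the clustering / mature-miRNA annotation summary (total clusters,
#' clusters with at least 100 reads, unique and shared clusters, mature-miRNA
#' reference hits and the *Anolis carolinensis* subset).
#'
#' @return A tibble, one row per stage.
#' @export
reference_mirna_stats <- function() {
  tibble(
    stage = c("newborn", "adult"),
    total_raw_reads = c(314592L, 515040L),
    quality_filtered_reads = c(263517L, 450902L),
    too_short_reads = c(34579L, 55882L),
    adapter_only_reads = c(8390L, 5956L),
    processed_reads = c(220548L, 389064L),
    mean_read_length = c(24.58, 23.68),
    total_clusters = c(38738L, 64493L),
    clusters_ge_100 = c(283L, 419L),
    unique_clusters = c(132L, 268L),
    shared_clusters = c(151L, 151L),
    mirbase_hits = c(48L, 70L),
    anolis_hits = c(22L, 30L)
  )
}

#' Default per-family abundance weights for a stage
#'
#' Relative transcript-abundance weights per toxin family, taken from the
#' published percentage shares in [reference_family_profile()] and
#' renormalised to sum to one. Optionally restricted to a subset of families
#' (renormalised again), which is what the synthetic generator does when its
#' panel carries fewer families than the full vocabulary.
#'
#' @param stage `"newborn"` or `"adult"`.
#' @param families Optional character vector of families to keep.
#' @return Named numeric vector summing to 1.
#' @export
default_family_weights <- function(stage = c("newborn", "adult"),
                                   families = NULL) {
  stage <- match.arg(stage)
  prof <- dplyr::filter(reference_family_profile(), .data$stage == !!stage)
  w <- setNames(prof$pct, prof$family)
  if (!is.null(families)) {
    missing <- setdiff(families, names(w))
    if (length(missing) > 0L) {
      w <- c(w, setNames(rep(mean(w), length(missing)), missing))
    }
    w <- w[families]
  }
  w / sum(w)
}
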