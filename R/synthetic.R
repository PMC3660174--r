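#' Generate a synthetic toxin ORF panel with isoforms and 3'-UTRs
#'
#' Builds a reference panel emulating a venom-gland toxin ORF collection:
#' `n_families` toxin families, each with `isoforms_per_family` isoform
#' sequences and a downstream 3'-UTR segment shared by the family's
#' transcripts (the planting ground for miRNA target sites). Isoform 1 of a
#' family is the family reference; each further isoform differs from it at
#' `round(divergence * length)` substitution positions, so two isoforms of a
#' two-isoform family differ at approximately `divergence * length` sites.
#'
#' ORFs start with ATG, end with a stop codon and contain no internal stop in
#' the unmutated reference frame, so translated protein comparisons are
#' meaningful.
#'
#' @param n_families Number of toxin families (uses the default family
#'   vocabulary, most abundant first).
#' @param isoforms_per_family Isoforms per family.
#' @param divergence Substitutions per site between an isoform and the family
#'   reference, in `[0, 0.2]`.
#' @param orf_len Target ORF length in nt (rounded up to a codon multiple).
#' @param utr_len 3'-UTR length in nt.
#' @param seed Integer seed; the panel is a pure function of the arguments.
#' @return A tibble with columns `ref_id`, `family`, `isoform`, `sequence`,
#'   `utr`, `length_nt`.
#' @export
make_references <- function(n_families = 4, isoforms_per_family = 2,
                            divergence = 0.05, orf_len = 600, utr_len = 150,
                            seed = 1) {
  stopifnot(n_families >= 1, isoforms_per_family >= 1)
  if (divergence < 0 || divergence > 0.2) {
    abort("divergence must be in [0, 0.2]")
  }
  # Most abundant families first so small panels carry the dominant ones.
  fam_order <- c("SP", "PLA2", "SVMP", "CTL", "LAO", "NGF", "5'-NTase",
                 "PDE", "HYA", "GC", "CRISP", "BPP", "VEGF", "KUN", "OHA")
  if (n_families > length(fam_order)) {
    fam_order <- c(fam_order, paste0("FAM", seq_len(n_families)))
  }
  families <- fam_order[seq_len(n_families)]
  n_codons <- ceiling(orf_len / 3) - 2L
  stops <- c("TAA", "TAG", "TGA")
  codons <- setdiff(
    apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste0,
          collapse = ""),
    stops
  )
  with_seed(seed, {
    rows <- purrr::map(families, function(fam) {
      base <- paste0(
        "ATG", paste(sample(codons, n_codons, replace = TRUE), collapse = ""),
        "TAA"
      )
      len <- nchar(base)
      n_mut <- round(divergence * len)
      isoforms <- character(isoforms_per_family)
      isoforms[1] <- base
      if (isoforms_per_family > 1) {
        for (i in 2:isoforms_per_family) {
          ok <- FALSE
          for (attempt in seq_len(100)) {
            cand <- mutate_positions(base, n_mut)
            if (!cand %in% isoforms[seq_len(i - 1)]) {
              isoforms[i] <- cand
              ok <- TRUE
              break
            }
          }
          if (!ok) {
            abort(paste0(
              "could not generate distinct isoforms for family ", fam,
              " after 100 attempts; increase divergence"
            ))
          }
        }
      }
      utr <- random_dna(utr_len)
      tibble(
        ref_id = sprintf("%s_iso%d", fam, seq_len(isoforms_per_family)),
        family = fam,
        isoform = seq_len(isoforms_per_family),
        sequence = isoforms,
        utr = utr,
        length_nt = len
      )
    })
    dplyr::bind_rows(rows)
  })
}

mutate_positions <- function(seq, n_mut) {
  if (n_mut == 0L) return(seq)
  chars <- seq_to_chars(seq)
  # keep start/stop codons intact
  eligible <- 4:(length(chars) - 3L)
  pos <- sample(eligible, min(n_mut, length(eligible)))
  chars[pos] <- vapply(
    chars[pos], function(b) sample(setdiff(DNA_BASES, b), 1), character(1)
  )
  paste(chars, collapse = "")
}

#' One family reference per family
#'
#' Extracts isoform 1 of each family from a panel: the sequence used as the
#' alignment reference for annotation, pileups and RPKM length normalisation.
#'
#' @param panel Panel tibble from [make_references()].
#' @return Tibble with one row per family.
#' @export
family_references <- function(panel) {
  dplyr::filter(panel, .data$isoform == 1L)
}

#' Describe one life stage of the two-stage design
#'
#' A stage profile fixes the statistical conditions the simulators emulate:
#' per-family relative transcript abundances (defaults: the published
#' newborn/adult percentage shares), the per-base substitution error rate
#' (default 1.5%, the rate the distinctness model assumes), and desk-scale
#' library sizes.
#'
#' @param stage `"newborn"` or `"adult"`.
#' @param family_weights Named numeric vector of per-family abundances
#'   (renormalised to sum to 1). Default: published shares for the stage.
#' @param isoform_mix Optional named list, family -> numeric isoform weights.
#'   Default: uniform over the panel's isoforms.
#' @param total_long_reads Long reads to simulate for the stage.
#' @param total_mirna_reads Small-RNA reads to simulate for the stage.
#' @param error_rate Per-base substitution probability, in `[0, 0.1]`.
#' @return A `stage_profile` list.
#' @export
stage_profile <- function(stage = c("newborn", "adult"),
                          family_weights = NULL, isoform_mix = NULL,
                          total_long_reads = 4000L,
                          total_mirna_reads = 20000L,
                          error_rate = 0.015) {
  stage <- match.arg(stage)
  if (error_rate < 0 || error_rate > 0.1) {
    abort("error_rate must be in [0, 0.1]")
  }
  if (is.null(family_weights)) {
    family_weights <- default_family_weights(stage)
  }
  if (any(family_weights < 0)) abort("family weights must be non-negative")
  family_weights <- family_weights / sum(family_weights)
  if (!is.null(isoform_mix)) {
    for (fam in names(isoform_mix)) {
      w <- isoform_mix[[fam]]
      if (any(w < 0) || sum(w) <= 0) {
        abort("isoform mix weights must be non-negative and sum > 0")
      }
      isoform_mix[[fam]] <- w / sum(w)
    }
  }
  structure(
    list(
      stage = stage,
      family_weights = family_weights,
      isoform_mix = isoform_mix,
      total_long_reads = as.integer(total_long_reads),
      total_mirna_reads = as.integer(total_mirna_reads),
      error_rate = error_rate
    ),
    class = "stage_profile"
  )
}

#' Simulate long venom-gland transcriptome reads
#'
#' Draws reads from the panel's isoform sequences proportional to the
#' profile's family and isoform weights, applies substitution errors at the
#' profile's error rate, and assigns per-base quality scores such that a
#' configurable fraction of reads fails the mean-QV > 20 filter. A truth
#' table (read to source isoform, with error counts) accompanies the reads.
#'
#' @param profile A [stage_profile()].
#' @param panel Panel tibble from [make_references()].
#' @param read_len_mean,read_len_sd Read-length distribution (nt), truncated
#'   to `[50, isoform length]`.
#' @param n_reads Number of reads (default: the profile's
#'   `total_long_reads`).
#' @param fail_qv_frac Fraction of reads drawn with low mean quality
#'   (around QV 15) so they fail the QV > 20 filter.
#' @param seed Integer seed.
#' @param out_fastq,out_truth Optional paths; when given the FASTQ and the
#'   truth TSV are written.
#' @return List with `reads` (read tibble) and `truth` (tibble with
#'   `read_id`, `family`, `source_ref`, `start`, `n_errors`).
#' @export
simulate_long_reads <- function(profile, panel, read_len_mean = 560,
                                read_len_sd = 60, n_reads = NULL,
                                fail_qv_frac = 0.05, seed = 1,
                                out_fastq = NULL, out_truth = NULL) {
  if (nrow(panel) == 0L) abort("empty reference panel")
  n_reads <- n_reads %||% profile$total_long_reads
  fams <- unique(panel$family)
  w <- profile$family_weights[intersect(names(profile$family_weights), fams)]
  w <- w[w > 0]
  if (length(w) == 0L) {
    abort("no positive family weight matches a panel family")
  }
  w <- w / sum(w)
  with_seed(seed, {
    fam_draw <- sample(names(w), n_reads, replace = TRUE, prob = w)
    rows <- vector("list", n_reads)
    panel_by_fam <- split(panel, panel$family)
    iso_choice <- vapply(fam_draw, function(fam) {
      sub <- panel_by_fam[[fam]]
      mix <- profile$isoform_mix[[fam]]
      if (is.null(mix)) mix <- rep(1, nrow(sub))
      sample(nrow(sub), 1, prob = mix)
    }, integer(1))
    src <- purrr::map2(fam_draw, iso_choice, function(fam, i) {
      panel_by_fam[[fam]][i, ]
    })
    src_len <- vapply(src, function(s) nchar(s$sequence), integer(1))
    rl <- pmin(pmax(round(rnorm(n_reads, read_len_mean, read_len_sd)), 50L),
               src_len)
    start <- vapply(seq_len(n_reads), function(i) {
      sample.int(src_len[i] - rl[i] + 1L, 1)
    }, integer(1))
    low_q <- runif(n_reads) < fail_qv_frac
    mean_qv <- ifelse(low_q, rnorm(n_reads, 15, 2), rnorm(n_reads, 32, 3))
    out <- purrr::map(seq_len(n_reads), function(i) {
      s <- substr(src[[i]]$sequence, start[i], start[i] + rl[i] - 1L)
      chars <- seq_to_chars(s)
      n_err <- rbinom(1, rl[i], profile$error_rate)
      if (n_err > 0L) {
        pos <- sample.int(rl[i], n_err)
        chars[pos] <- vapply(
          chars[pos], function(b) sample(setdiff(DNA_BASES, b), 1),
          character(1)
        )
      }
      qv <- pmin(pmax(round(rnorm(rl[i], mean_qv[i], 2)), 2L), 45L)
      list(sequence = paste(chars, collapse = ""), qualities = as.integer(qv),
           n_errors = n_err)
    })
    reads <- tibble(
      read_id = sprintf("%s_r%06d", profile$stage, seq_len(n_reads)),
      sequence = vapply(out, `[[`, character(1), "sequence"),
      qualities = lapply(out, `[[`, "qualities")
    )
    truth <- tibble(
      read_id = reads$read_id,
      family = fam_draw,
      source_ref = vapply(src, function(s) s$ref_id, character(1)),
      start = start,
      n_errors = vapply(out, `[[`, integer(1), "n_errors")
    )
    if (!is.null(out_fastq)) write_fastq(reads, out_fastq)
    if (!is.null(out_truth)) {
      write_report_table(truth, out_truth, json = FALSE)
    }
    list(reads = reads, truth = truth)
  })
}

#' Plant a ground-truth miRNA population with target sites
#'
#' Generates `n_mirna` distinct mature miRNA sequences with per-stage copy
#' numbers following a fixed role pattern (newborn-exclusive,
#' adult-exclusive, and shared miRNAs, the shared ones partly stage-skewed;
#' one low-abundance miRNA per exclusive group exercises the minimum-read
#' filter), and plants each miRNA's exact reverse complement into the 3'-UTRs
#' of `targets_per_mirna` distinct families of the panel.
#'
#' @param panel Panel tibble from [make_references()] (its `utr` column is
#'   rewritten where sites are planted).
#' @param n_mirna Number of distinct mature miRNAs (>= 4).
#' @param mirna_len Mature length in nt (15--40).
#' @param total_reads_newborn,total_reads_adult Approximate per-stage read
#'   totals the copy numbers are scaled to.
#' @param targets_per_mirna Integer vector (recycled) of planted target
#'   transcripts per miRNA; default pattern `2, 2, 1, 0`.
#' @param seed Integer seed.
#' @return A `mirna_truth` list with `mirnas` (tibble: `mirna_id`,
#'   `sequence`, `copies_newborn`, `copies_adult`), `sites` (tibble:
#'   `mirna_id`, `family`, `start`, `end`) and the updated `panel`.
#' @export
mirna_truth <- function(panel, n_mirna = 12, mirna_len = 22,
                        total_reads_newborn = 20000L,
                        total_reads_adult = 20000L,
                        targets_per_mirna = c(2L, 2L, 1L, 0L),
                        seed = 1) {
  stopifnot(n_mirna >= 4)
  if (mirna_len < 15 || mirna_len > 40) {
    abort("mirna_len must be within [15, 40]")
  }
  fams <- unique(panel$family)
  targets_per_mirna <- rep_len(as.integer(targets_per_mirna), n_mirna)
  if (max(targets_per_mirna) > length(fams)) {
    abort("targets_per_mirna exceeds the number of panel families")
  }
  with_seed(seed, {
    seqs <- character(0)
    while (length(seqs) < n_mirna) {
      seqs <- unique(c(seqs, replicate(n_mirna, random_dna(mirna_len))))
    }
    seqs <- seqs[seq_len(n_mirna)]
    ids <- sprintf("M%02d", seq_len(n_mirna))
    # roles: thirds newborn-exclusive / adult-exclusive / shared
    n_excl <- max(1L, n_mirna %/% 4L)
    role <- rep("shared", n_mirna)
    role[seq_len(n_excl)] <- "newborn_only"
    role[n_excl + seq_len(n_excl)] <- "adult_only"
    base <- exp(runif(n_mirna, log(400), log(3000)))
    ratio <- rep(1, n_mirna)
    shared_idx <- which(role == "shared")
    if (length(shared_idx) >= 2L) {
      ratio[shared_idx[1L]] <- 8
      ratio[shared_idx[2L]] <- 1 / 8
    }
    nb_raw <- base * ifelse(role == "adult_only", 0, 1) * sqrt(ratio)
    ad_raw <- base * ifelse(role == "newborn_only", 0, 1) / sqrt(ratio)
    copies_nb <- round(nb_raw * total_reads_newborn / max(sum(nb_raw), 1))
    copies_ad <- round(ad_raw * total_reads_adult / max(sum(ad_raw), 1))
    # designed roles must be realisable above the 100-read abundance
    # filter: expressed miRNAs get at least 150 copies in their stage(s)
    copies_nb[copies_nb > 0L] <- pmax(copies_nb[copies_nb > 0L], 150L)
    copies_ad[copies_ad > 0L] <- pmax(copies_ad[copies_ad > 0L], 150L)
    # ... except one deliberately low-abundance miRNA per exclusive group,
    # pinned below the filter to exercise it
    copies_nb[1L] <- 60L
    copies_ad[n_excl + 1L] <- 60L
    mirnas <- tibble(
      mirna_id = ids, sequence = seqs, role = role,
      copies_newborn = as.integer(copies_nb),
      copies_adult = as.integer(copies_ad)
    )
    # plant sites: exact reverse complements in family UTRs, non-overlapping
    fam_utr <- setNames(
      family_references(panel)$utr, family_references(panel)$family
    )
    occupied <- lapply(fam_utr, function(u) integer(0))
    sites <- list()
    for (i in seq_len(n_mirna)) {
      k <- targets_per_mirna[i]
      if (k == 0L) next
      # least-loaded families first so sites spread across UTRs
      load <- vapply(occupied[fams], length, integer(1))
      fam_pick <- fams[order(load, fams)][seq_len(k)]
      for (fam in fam_pick) {
        site <- revcomp(seqs[i])
        ulen <- nchar(fam_utr[[fam]])
        slot <- find_free_slot(occupied[[fam]], ulen, nchar(site))
        if (is.null(slot)) {
          abort(paste0("UTR of family ", fam,
                       " too short to plant all target sites"))
        }
        substr(fam_utr[[fam]], slot, slot + nchar(site) - 1L) <- site
        occupied[[fam]] <- c(occupied[[fam]], slot:(slot + nchar(site) - 1L))
        sites[[length(sites) + 1L]] <- tibble(
          mirna_id = ids[i], family = fam, start = slot,
          end = slot + nchar(site) - 1L
        )
      }
    }
    panel$utr <- unname(fam_utr[panel$family])
    structure(
      list(
        mirnas = mirnas,
        sites = if (length(sites)) dplyr::bind_rows(sites) else
          tibble(mirna_id = character(0), family = character(0),
                 start = integer(0), end = integer(0)),
        panel = panel
      ),
      class = "mirna_truth"
    )
  })
}

find_free_slot <- function(occupied, ulen, width) {
  starts <- sample(seq_len(max(ulen - width + 1L, 0L)))
  for (s in starts) {
    if (!any((s:(s + width - 1L)) %in% occupied)) return(s)
  }
  NULL
}

#' Simulate adapter-flanked small-RNA reads for one stage
#'
#' Each truth miRNA contributes exactly its per-stage copy number of reads,
#' every read being the mature sequence with the configured 3' adapter
#' appended. Adapter-only reads are injected on top at a binomial rate,
#' emulating the adapter-dimer fraction of small-RNA libraries.
#'
#' @param truth A [mirna_truth()] object.
#' @param stage `"newborn"` or `"adult"`.
#' @param adapter Adapter sequence appended at the 3' end (default: the
#'   23-mer "P1" placeholder).
#' @param adapter_only_rate Expected adapter-only reads per mature read.
#' @param qv Constant per-base quality score.
#' @param seed Integer seed.
#' @param out_fastq,out_truth Optional output paths.
#' @return List with `reads` and `truth` (tibble: `read_id`, `mirna_id`,
#'   with `"adapter_only"` marking injected reads).
#' @export
simulate_mirna_reads <- function(truth, stage = c("newborn", "adult"),
                                 adapter = default_adapters()[["P1"]],
                                 adapter_only_rate = 0.02, qv = 30L,
                                 seed = 1, out_fastq = NULL,
                                 out_truth = NULL) {
  stage <- match.arg(stage)
  copies <- if (stage == "newborn") truth$mirnas$copies_newborn else
    truth$mirnas$copies_adult
  with_seed(seed, {
    mirna_id <- rep(truth$mirnas$mirna_id, copies)
    seqs <- paste0(rep(truth$mirnas$sequence, copies), adapter)
    n_extra <- rbinom(1, length(seqs), adapter_only_rate)
    if (n_extra > 0L) {
      mirna_id <- c(mirna_id, rep("adapter_only", n_extra))
      seqs <- c(seqs, rep(adapter, n_extra))
    }
    ord <- sample.int(length(seqs))
    mirna_id <- mirna_id[ord]
    seqs <- seqs[ord]
    reads <- tibble(
      read_id = sprintf("%s_mir%06d", stage, seq_along(seqs)),
      sequence = seqs,
      qualities = lapply(nchar(seqs), function(n) rep(as.integer(qv), n))
    )
    rt <- tibble(read_id = reads$read_id, mirna_id = mirna_id)
    if (!is.null(out_fastq)) write_fastq(reads, out_fastq)
    if (!is.null(out_truth)) write_report_table(rt, out_truth, json = FALSE)
    list(reads = reads, truth = rt)
  })
}
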