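#' Build and validate a run configuration
#'
#' A run configuration describes one two-stage experiment: either a
#' `simulate` block (the synthetic fixture; the default) or explicit input
#' paths, plus per-module parameter blocks, a global seed and an output
#' directory. Every referenced path is checked at validation time, before
#' any compute.
#'
#' @param x A named list, or a path to a YAML file with the same structure.
#' @return A validated `run_config` list.
#' @export
run_config <- function(x = list()) {
  if (is.character(x) && length(x) == 1L) {
    x <- yaml::read_yaml(x)
  }
  defaults <- list(
    seed = 1L,
    outdir = "venomshift_out",
    simulate = list(
      n_families = 4L, isoforms_per_family = 2L, divergence = 0.15,
      orf_len = 600L, utr_len = 150L, n_mirna = 12L,
      total_long_reads = 4000L, total_mirna_reads = 20000L,
      error_rate = 0.015
    ),
    inputs = NULL,
    qc = list(min_mean_qv = 20, mirna_min_len = 15L, mirna_max_len = 40L,
              min_adapter_overlap = 8L),
    distinctness = list(error_rate = 0.015, alpha = 0.01,
                        min_variant_reads = 3L),
    consensus = list(min_support = 4L, min_variant_reads = 3L),
    pileup = list(min_identity = 0.70, group_max_reads = 400L),
    noiseq = list(k = 0.5, nss = 5L, pnr = 0.2, v = 0.02,
                  prob_threshold = 0.9),
    mirna = list(identity = 0.98, min_reads = 100L),
    scan = list(min_score = 100, max_dg = -19, min_targets_per_mirna = 2L),
    protein_identity = 0.8,
    mirna_reference_fasta = NULL
  )
  cfg <- utils::modifyList(defaults, x)
  if (!is.null(cfg$inputs)) {
    cfg$simulate <- NULL
    required <- c("panel_fasta", "newborn_fastq", "adult_fastq",
                  "newborn_mirna_fastq", "adult_mirna_fastq")
    for (f in required) {
      if (is.null(cfg$inputs[[f]])) {
        abort(paste0("inputs block missing required path: ", f))
      }
      if (!file.exists(cfg$inputs[[f]])) {
        abort(paste0("input path does not exist: ", cfg$inputs[[f]]))
      }
    }
  }
  if (!is.null(cfg$mirna_reference_fasta) &&
      !file.exists(cfg$mirna_reference_fasta)) {
    abort(paste0("mirna reference does not exist: ",
                 cfg$mirna_reference_fasta))
  }
  structure(cfg, class = "run_config")
}

#' Percentage-annotate a counts table
#'
#' Adds `100 * numerator / denominator`, rounded half-to-even at the
#' requested precision, as column `pct`, together with the full-precision
#' value as `pct_full`.
#'
#' @param counts_table A data frame.
#' @param numerator,denominator Column names (strings).
#' @param digits Rendered precision (2 for long-read tables, 1 for the
#'   small-RNA convention).
#' @return The table with `pct` and `pct_full` appended.
#' @export
report_percentages <- function(counts_table, numerator, denominator,
                               digits = 2L) {
  full <- 100 * counts_table[[numerator]] / counts_table[[denominator]]
  full[counts_table[[denominator]] == 0] <- NA_real_
  counts_table$pct <- round(full, digits)
  counts_table$pct_full <- full
  counts_table
}

#' Run the full two-stage pipeline
#'
#' Executes QC, toxin inference, quantification, miRNA profiling and target
#' scanning for a newborn/adult pair and writes the report bundle: a
#' sequencing-statistics table, a per-family expression table with
#' NOISeq-sim differential calls, a per-family minimum-gene-count table with
#' the shared/unique protein clustering, small-RNA statistics and stage
#' comparison, target-scan hits with their alignments, per-stage consensus
#' FASTA files, and a manifest carrying the configuration hash and seed.
#' Outputs are pure functions of (configuration, seed): a re-run writes
#' byte-identical files.
#'
#' @param config A [run_config()] (or a list/YAML path accepted by it).
#' @return Invisibly, a `venomshift_run` list with every table plus the
#'   intermediate objects.
#' @export
run_venomshift <- function(config = run_config()) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  stages <- c("newborn", "adult")

  vs_log("INFO", "stage inputs")
  t0 <- Sys.time()
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    panel <- make_references(
      n_families = sim$n_families,
      isoforms_per_family = sim$isoforms_per_family,
      divergence = sim$divergence, orf_len = sim$orf_len,
      utr_len = sim$utr_len, seed = derive_seed(seed, 1)
    )
    truth <- mirna_truth(
      panel, n_mirna = sim$n_mirna,
      total_reads_newborn = sim$total_mirna_reads,
      total_reads_adult = sim$total_mirna_reads,
      seed = derive_seed(seed, 2)
    )
    panel <- truth$panel
    long_reads <- list()
    mirna_reads <- list()
    for (i in seq_along(stages)) {
      st <- stages[i]
      prof <- stage_profile(
        st, total_long_reads = sim$total_long_reads,
        total_mirna_reads = sim$total_mirna_reads,
        error_rate = sim$error_rate
      )
      long_reads[[st]] <- simulate_long_reads(
        prof, panel, seed = derive_seed(seed, 10 + i)
      )$reads
      mirna_reads[[st]] <- simulate_mirna_reads(
        truth, st, seed = derive_seed(seed, 20 + i)
      )$reads
    }
  } else {
    panel <- read_panel_fasta(config$inputs$panel_fasta,
                              config$inputs$utr_fasta)
    long_reads <- list(
      newborn = read_fastq(config$inputs$newborn_fastq),
      adult = read_fastq(config$inputs$adult_fastq)
    )
    mirna_reads <- list(
      newborn = read_fastq(config$inputs$newborn_mirna_fastq),
      adult = read_fastq(config$inputs$adult_mirna_fastq)
    )
  }
  refs <- family_references(panel)
  qc <- do.call(qc_params, config$qc)
  dparams <- do.call(distinctness_params, config$distinctness)

  # ---- long-read QC + toxin inference + quantification -------------------
  vs_log("INFO", "long-read stages")
  seq_stats <- list()
  fam_counts <- list()
  gene_groups <- list()
  consensus_fastas <- list()
  for (st in stages) {
    raw <- long_reads[[st]]
    qf <- filter_by_mean_quality(raw, qc)
    hits <- annotate_reads(qf$reads, refs, mode = "nucleotide")
    mapped <- 0L
    singleton_total <- 0L
    st_counts <- list()
    st_groups <- list()
    st_cons <- list()
    for (fam in sort(unique(refs$family))) {
      fam_ref <- refs[refs$family == fam, ]
      fam_reads <- qf$reads[qf$reads$read_id %in%
                              hits$read_id[hits$family == fam], ]
      pl <- build_pileup(fam_reads, fam_ref,
                         min_identity = config$pileup$min_identity)
      n_in <- nrow(pl$mat)
      mapped <- mapped + n_in
      singleton_total <- singleton_total + pl$n_excluded
      sub <- pl
      if (n_in > config$pileup$group_max_reads) {
        keep <- order(pl$read_ids)[seq_len(config$pileup$group_max_reads)]
        sub$mat <- pl$mat[keep, , drop = FALSE]
        sub$read_ids <- pl$read_ids[keep]
      }
      gg <- infer_gene_groups(
        sub, dparams,
        min_support = config$consensus$min_support,
        min_variant_reads = config$consensus$min_variant_reads
      )
      st_groups[[fam]] <- gg
      st_counts[[fam]] <- tibble(
        stage = st, family = fam, contigs = gg$n_genes,
        reads = n_in, singletons = pl$n_excluded,
        ref_length_nt = nchar(fam_ref$sequence)
      )
      if (nrow(gg$consensuses) > 0L) {
        st_cons[[fam]] <- tibble(
          id = sprintf("%s_%s_g%d", st, fam, gg$consensuses$group),
          stage = st, family = fam,
          n_reads = gg$consensuses$n_reads,
          sequence = gg$consensuses$aligned
        )
      }
    }
    gene_groups[[st]] <- st_groups
    consensus_fastas[[st]] <- dplyr::bind_rows(st_cons)
    fam_counts[[st]] <- dplyr::bind_rows(st_counts)
    seq_stats[[st]] <- tibble(
      stage = st,
      total_reads = nrow(raw),
      quality_filtered_reads = qf$counts$kept,
      mean_read_length = round(mean(nchar(raw$sequence)), 2),
      max_read_length = max(nchar(raw$sequence)),
      mapped_reads = mapped,
      n_groups = sum(vapply(st_groups, function(g) g$n_genes, integer(1))),
      singletons = singleton_total
    )
  }
  seq_stats <- dplyr::bind_rows(seq_stats) |>
    report_percentages("mapped_reads", "quality_filtered_reads", digits = 2L)
  totals <- setNames(seq_stats$quality_filtered_reads, seq_stats$stage)
  expression <- dplyr::bind_rows(fam_counts) |>
    family_expression(totals) |>
    dplyr::arrange(.data$stage, .data$family)

  vs_log("INFO", "family differential expression")
  wide <- expression |>
    dplyr::select("family", "stage", "reads", "singletons",
                  "ref_length_nt") |>
    dplyr::mutate(n = .data$reads + .data$singletons) |>
    dplyr::select(-"reads", -"singletons") |>
    tidyr::pivot_wider(names_from = "stage", values_from = "n",
                       values_fill = 0L)
  fam_diff <- withCallingHandlers(
    noiseq_sim(
      wide$newborn, wide$adult, lengths = wide$ref_length_nt,
      feature_ids = wide$family,
      k = config$noiseq$k, nss = config$noiseq$nss,
      pnr = config$noiseq$pnr, v = config$noiseq$v,
      prob_threshold = config$noiseq$prob_threshold,
      seed = derive_seed(seed, 30)
    ),
    warning = function(w) {
      vs_log("WARN", conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )

  vs_log("INFO", "protein clustering across stages")
  to_protein <- function(cons_tbl) {
    if (is.null(cons_tbl) || nrow(cons_tbl) == 0L) {
      return(tibble(id = character(0), sequence = character(0),
                    family = character(0)))
    }
    aa <- suppressWarnings(as.character(Biostrings::translate(
      Biostrings::DNAStringSet(gsub("-", "N", cons_tbl$sequence)),
      if.fuzzy.codon = "solve"
    )))
    tibble(id = cons_tbl$id, sequence = unname(aa),
           family = cons_tbl$family)
  }
  prot <- cluster_proteins(
    to_protein(consensus_fastas$newborn),
    to_protein(consensus_fastas$adult),
    identity_threshold = config$protein_identity
  )
  gene_counts <- prot$summary |> dplyr::arrange(.data$family)

  # ---- miRNA stages ------------------------------------------------------
  vs_log("INFO", "small-RNA stages")
  mirna_stats <- list()
  clusters <- list()
  for (st in stages) {
    mq <- qc_mirna(mirna_reads[[st]], qc, stage = st)
    cl <- cluster_mirnas(
      mq$reads, identity = config$mirna$identity, stage = st,
      total_processed = mq$counts$processed_reads
    )
    clusters[[st]] <- cl
    mirna_stats[[st]] <- dplyr::mutate(
      mq$counts,
      total_clusters = nrow(cl),
      clusters_ge_min = nrow(abundance_filter(cl, config$mirna$min_reads))
    )
  }
  filtered <- lapply(clusters, abundance_filter,
                     min_reads = config$mirna$min_reads)
  comparison <- suppressWarnings(compare_stages(
    filtered$newborn, filtered$adult,
    identity = config$mirna$identity,
    prob_threshold = config$noiseq$prob_threshold,
    nss = config$noiseq$nss, pnr = config$noiseq$pnr, v = config$noiseq$v,
    k = config$noiseq$k, seed = derive_seed(seed, 31)
  ))
  mirna_stats <- dplyr::bind_rows(mirna_stats) |>
    dplyr::mutate(
      unique_clusters = c(nrow(comparison$unique_newborn),
                          nrow(comparison$unique_adult)),
      shared_clusters = nrow(comparison$shared)
    )
  annotated <- NULL
  if (!is.null(config$mirna_reference_fasta)) {
    annotated <- dplyr::bind_rows(lapply(filtered, annotate_mirnas,
                                         reference = config$mirna_reference_fasta))
  }

  # ---- target scan -------------------------------------------------------
  vs_log("INFO", "target scan")
  scanp <- do.call(scan_params, config$scan)
  mirna_set <- dplyr::bind_rows(filtered) |>
    dplyr::select(mirna_id = "cluster_id", sequence = "consensus")
  utrs <- refs |>
    dplyr::select(id = "family", "utr") |>
    dplyr::filter(!is.na(.data$utr))
  scan <- if (nrow(mirna_set) > 0L && nrow(utrs) > 0L) {
    scan_targets(mirna_set, utrs, scanp)
  } else {
    list(hits = tibble(), candidates = tibble())
  }

  # ---- reports -----------------------------------------------------------
  vs_log("INFO", "writing report bundle to ", config$outdir)
  out <- function(name) file.path(config$outdir, name)
  write_report_table(seq_stats, out("sequencing_stats.tsv"))
  write_report_table(expression, out("family_expression.tsv"))
  write_report_table(tidy(fam_diff), out("family_diff.tsv"))
  write_report_table(gene_counts, out("gene_counts.tsv"))
  write_report_table(prot$clusters |> dplyr::select(-"sequence"),
                     out("protein_clusters.tsv"))
  write_report_table(mirna_stats, out("mirna_stats.tsv"))
  write_report_table(dplyr::bind_rows(clusters), out("mirna_clusters.tsv"))
  if (nrow(comparison$shared) > 0L) {
    write_report_table(
      dplyr::left_join(comparison$shared, tidy(comparison$diff),
                       by = c(newborn_cluster = "feature")),
      out("mirna_comparison.tsv")
    )
  } else {
    write_report_table(comparison$shared, out("mirna_comparison.tsv"))
  }
  if (!is.null(annotated)) {
    write_report_table(annotated |> dplyr::select(-dplyr::any_of("pairing")),
                       out("mirna_annotation.tsv"))
  }
  hits_flat <- scan$hits |>
    dplyr::select(-dplyr::any_of(c("pairing", "alignment")))
  write_report_table(hits_flat, out("target_hits.tsv"))
  if (nrow(scan$hits) > 0L) {
    writeLines(
      paste0("# ", scan$hits$mirna_id, " -> ", scan$hits$target_id,
             " [", scan$hits$start, "-", scan$hits$end, "] score=",
             scan$hits$score, " dG=", sprintf("%.2f", scan$hits$dg), "\n",
             scan$hits$alignment, "\n"),
      out("target_alignments.txt")
    )
  } else {
    writeLines(character(0), out("target_alignments.txt"))
  }
  for (st in stages) {
    cf <- consensus_fastas[[st]]
    if (!is.null(cf) && nrow(cf) > 0L) {
      write_fasta(
        tibble(id = cf$id, sequence = gsub("-", "N", cf$sequence)),
        out(sprintf("consensus_%s.fasta", st))
      )
    }
  }
  hash_cfg <- unclass(config)
  hash_cfg$outdir <- NULL
  manifest <- list(
    package = "venomshift",
    config_hash = rlang::hash(hash_cfg),
    seed = seed,
    outputs = sort(list.files(config$outdir, pattern = "\\.(tsv|json|txt|fasta)$"))
  )
  manifest$outputs <- setdiff(manifest$outputs, "manifest.json")
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  vs_log("INFO", sprintf("done in %.1f s", as.numeric(
    difftime(Sys.time(), t0, units = "secs")
  )))
  invisible(structure(
    list(
      config = config, panel = panel,
      sequencing_stats = seq_stats, expression = expression,
      family_diff = fam_diff, gene_counts = gene_counts,
      protein_clusters = prot$clusters, mirna_stats = mirna_stats,
      clusters = clusters, comparison = comparison,
      annotation = annotated, targets = scan
    ),
    class = "venomshift_run"
  ))
}

# Panel FASTA reader for file-based runs: family parsed from a
# "family=<label>" token in the header (falling back to the second token);
# UTRs come from an optional companion FASTA keyed by the same ids.
read_panel_fasta <- function(path, utr_path = NULL) {
  fa <- read_fasta(path)
  fam <- stringr::str_match(fa$description, "family=(\\S+)")[, 2]
  fallback <- vapply(strsplit(fa$description, "\\s+"), function(t) {
    if (length(t) >= 2L) t[2] else NA_character_
  }, character(1))
  fam <- dplyr::coalesce(fam, fallback, fa$id)
  panel <- tibble(
    ref_id = fa$id, family = fam,
    isoform = 1L, sequence = fa$sequence,
    utr = NA_character_, length_nt = nchar(fa$sequence)
  )
  if (!is.null(utr_path)) {
    u <- read_fasta(utr_path)
    panel$utr <- u$sequence[match(panel$ref_id, u$id)]
  }
  panel
}

#' @export
print.venomshift_run <- function(x, ...) {
  cat("<venomshift_run>\n")
  cat("  stages: newborn, adult\n")
  cat(sprintf("  families: %d, gene groups: %d\n",
              length(unique(x$expression$family)),
              sum(x$sequencing_stats$n_groups)))
  cat(sprintf("  miRNA clusters (filtered): %d shared, %d + %d unique\n",
              nrow(x$comparison$shared), nrow(x$comparison$unique_newborn),
              nrow(x$comparison$unique_adult)))
  cat(sprintf("  target hits: %d\n", nrow(x$targets$hits)))
  invisible(x)
}

#' Family-share bar chart of an expression table
#'
#' Percentage share of each toxin family within each stage, the tabular
#' counterpart of a transcriptome composition pie chart.
#'
#' @param expression Expression tibble with `family`, `stage`, `pct`.
#' @return A ggplot.
#' @export
plot_family_expression <- function(expression) {
  ggplot2::ggplot(expression,
                  ggplot2::aes(x = stats::reorder(.data$family, -.data$pct),
                               y = .data$pct, fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of stage RPKM") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
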