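test_that("isoforms diverge by the requested number of substitutions", {
  panel <- make_references(1, 2, divergence = 0.05, orf_len = 600, seed = 3)
  a <- strsplit(panel$sequence[1], "")[[1]]
  b <- strsplit(panel$sequence[2], "")[[1]]
  expect_equal(sum(a != b), round(0.05 * panel$length_nt[1]))
})

test_that("degenerate divergence settings behave as specified", {
  p1 <- make_references(1, 1, divergence = 0, seed = 1)
  expect_equal(nrow(p1), 1L)
  expect_error(make_references(1, 2, divergence = 0, seed = 1),
               "100 attempts")
  expect_error(make_references(1, 2, divergence = 0.5, seed = 1),
               "divergence")
})

test_that("the panel generator is a pure function of its seed", {
  p1 <- make_references(3, 2, seed = 11)
  p2 <- make_references(3, 2, seed = 11)
  p3 <- make_references(3, 2, seed = 12)
  expect_identical(p1, p2)
  expect_false(identical(p1$sequence, p3$sequence))
})

test_that("ORFs are codon-clean: start, stop, no internal stops", {
  panel <- make_references(2, 1, seed = 5)
  for (s in panel$sequence) {
    expect_equal(nchar(s) %% 3, 0)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    expect_match(aa, "^M")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
})

test_that("long-read truth labels follow the family weights", {
  panel <- make_references(2, 1, seed = 2)  # SP and PLA2
  prof <- stage_profile("newborn", family_weights = c(SP = 1),
                        total_long_reads = 200)
  sim <- simulate_long_reads(prof, panel, seed = 4)
  expect_equal(nrow(sim$reads), 200L)
  expect_true(all(sim$truth$family == "SP"))
})

test_that("error-free reads are exact substrings of their source isoform", {
  panel <- make_references(2, 2, divergence = 0.1, seed = 6)
  prof <- stage_profile("adult", total_long_reads = 100, error_rate = 0)
  sim <- simulate_long_reads(prof, panel, seed = 7)
  expect_true(all(sim$truth$n_errors == 0))
  src <- setNames(panel$sequence, panel$ref_id)
  ok <- purrr::map2_lgl(sim$reads$sequence, seq_len(100), function(s, i) {
    tr <- sim$truth[i, ]
    substr(src[[tr$source_ref]], tr$start,
           tr$start + nchar(s) - 1L) == s
  })
  expect_true(all(ok))
})

test_that("substitution errors match the binomial error model", {
  panel <- make_references(1, 1, orf_len = 600, seed = 8)
  prof <- stage_profile("newborn", total_long_reads = 1200,
                        error_rate = 0.015)
  sim <- simulate_long_reads(prof, panel, read_len_mean = 500,
                             read_len_sd = 0, seed = 9)
  # truth n_errors equals the realised truth-vs-read Hamming distance
  src <- setNames(panel$sequence, panel$ref_id)
  d <- purrr::map2_int(sim$reads$sequence, seq_len(nrow(sim$reads)),
    function(s, i) {
      tr <- sim$truth[i, ]
      orig <- substr(src[[tr$source_ref]], tr$start,
                     tr$start + nchar(s) - 1L)
      sum(strsplit(orig, "")[[1]] != strsplit(s, "")[[1]])
    })
  expect_equal(d, sim$truth$n_errors)
  # binomial mean: 500 * 0.015 = 7.5 per read; SE of the mean ~ 0.08
  expect_equal(mean(d), 7.5, tolerance = 0.05)
})

test_that("a configurable fraction of reads fails the mean-QV filter", {
  panel <- make_references(1, 1, seed = 10)
  prof <- stage_profile("newborn", total_long_reads = 1000)
  sim <- simulate_long_reads(prof, panel, fail_qv_frac = 0.2, seed = 11)
  qf <- filter_by_mean_quality(sim$reads)
  expect_gt(qf$counts$low_quality, 120)
  expect_lt(qf$counts$low_quality, 280)
})

test_that("miRNA truth invariants hold and sites are exact reverse complements", {
  panel <- make_references(4, 1, seed = 12)
  truth <- mirna_truth(panel, n_mirna = 12, seed = 13)
  expect_true(all(nchar(truth$mirnas$sequence) >= 15))
  expect_true(all(nchar(truth$mirnas$sequence) <= 40))
  utr <- setNames(family_references(truth$panel)$utr,
                  family_references(truth$panel)$family)
  mat <- setNames(truth$mirnas$sequence, truth$mirnas$mirna_id)
  for (i in seq_len(nrow(truth$sites))) {
    s <- truth$sites[i, ]
    expect_equal(substr(utr[[s$family]], s$start, s$end),
                 rc(mat[[s$mirna_id]]))
  }
})

test_that("miRNA read copy numbers are exact and stage-specific", {
  panel <- make_references(4, 1, seed = 14)
  truth <- mirna_truth(panel, n_mirna = 8, total_reads_newborn = 3000,
                       total_reads_adult = 3000, seed = 15)
  sim <- simulate_mirna_reads(truth, "newborn", adapter_only_rate = 0,
                              seed = 16)
  counts <- table(sim$truth$mirna_id)
  for (i in seq_len(nrow(truth$mirnas))) {
    m <- truth$mirnas[i, ]
    observed <- if (m$mirna_id %in% names(counts)) {
      as.integer(counts[[m$mirna_id]])
    } else 0L
    expect_equal(observed, m$copies_newborn)
  }
  # adult-only miRNAs contribute no newborn reads
  expect_true(all(truth$mirnas$copies_newborn[
    truth$mirnas$role == "adult_only"] == 0))
})

test_that("adapter-only reads are injected at the binomial rate", {
  panel <- make_references(4, 1, seed = 17)
  truth <- mirna_truth(panel, n_mirna = 8, total_reads_newborn = 10000,
                       total_reads_adult = 10000, seed = 18)
  sim <- simulate_mirna_reads(truth, "newborn", adapter_only_rate = 0.05,
                              seed = 19)
  n_mature <- sum(sim$truth$mirna_id != "adapter_only")
  n_adapter <- sum(sim$truth$mirna_id == "adapter_only")
  # Binomial(n_mature, 0.05): mean ~ 500, sd ~ 22
  expect_gt(n_adapter, 0.05 * n_mature - 5 * sqrt(0.05 * 0.95 * n_mature))
  expect_lt(n_adapter, 0.05 * n_mature + 5 * sqrt(0.05 * 0.95 * n_mature))
  sim2 <- simulate_mirna_reads(truth, "newborn", adapter_only_rate = 0.05,
                               seed = 19)
  expect_identical(sim$reads, sim2$reads)
})
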