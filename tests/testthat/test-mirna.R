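test_that("identical reads collapse into one cluster with exact counts", {
  reads <- rep(strrep("AC", 11), 100)
  cl <- cluster_mirnas(reads, stage = "newborn", total_processed = 200)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_reads, 100L)
  expect_equal(cl$cpm, 1e6 * 100 / 200)
  expect_equal(cl$consensus, strrep("AC", 11))
})

test_that("one mismatch separates short sequences at the 0.98 threshold", {
  a22 <- strrep("AC", 11)
  b22 <- paste0("GC", substr(a22, 3, 22))   # one substitution: 21/22 < 0.98
  expect_equal(nrow(cluster_mirnas(c(a22, b22))), 2L)

  a40 <- strrep("AG", 20)
  b40 <- paste0("CG", substr(a40, 3, 40))   # 39/40 = 0.975 < 0.98
  expect_equal(nrow(cluster_mirnas(c(a40, b40))), 2L)

  # a permissive threshold merges them and majority vote sets the consensus
  cl <- cluster_mirnas(c(rep(a22, 3), b22), identity = 0.90)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$consensus, a22)
})

test_that("clustering at identity 1.0 equals hash-based deduplication", {
  set.seed(51)
  pool <- replicate(12, rand_dna(sample(18:25, 1)))
  reads <- sample(pool, 400, replace = TRUE)
  cl <- cluster_mirnas(reads, identity = 0.999)
  expect_equal(sort(cl$consensus), sort(unique(reads)))
  expect_equal(sum(cl$n_reads), 400L)
})

test_that("cpm totals scale to clustered over processed reads", {
  set.seed(52)
  reads <- sample(replicate(5, rand_dna(22)), 250, replace = TRUE)
  cl <- cluster_mirnas(reads, total_processed = 1000)
  expect_equal(sum(cl$cpm), 1e6 * 250 / 1000)
  expect_lte(sum(cl$cpm), 1e6)
})

test_that("the abundance filter is inclusive at its threshold", {
  cl <- tibble::tibble(cluster_id = c("a", "b", "c"),
                       consensus = c("x", "y", "z"),
                       n_reads = c(99L, 100L, 1500L),
                       cpm = 1, stage = "newborn")
  expect_equal(abundance_filter(cl)$cluster_id, c("b", "c"))
  expect_equal(abundance_filter(cl, 1000)$cluster_id, "c")
})

test_that("stage comparison splits shared and unique and calls differentials", {
  set.seed(53)
  shared_seqs <- replicate(4, rand_dna(22))
  nb_only <- rand_dna(22)
  ad_only <- rand_dna(22)
  nb <- cluster_mirnas(
    rep(c(shared_seqs, nb_only), c(1000, 500, 400, 300, 1000)),
    stage = "newborn"
  )
  ad <- cluster_mirnas(
    rep(c(shared_seqs, ad_only), c(10, 500, 400, 300, 800)),
    stage = "adult"
  )
  cmp <- suppressWarnings(compare_stages(nb, ad, seed = 1))
  expect_equal(nrow(cmp$shared), 4L)
  expect_equal(cmp$unique_newborn$consensus, nb_only)
  expect_equal(cmp$unique_adult$consensus, ad_only)
  res <- tidy(cmp$diff)
  skewed <- res[res$count_a == 1000 & res$count_b == 10, ]
  expect_true(skewed$called)
  expect_s3_class(autoplot(cmp), "ggplot")

  # disjoint sets share nothing
  cmp2 <- compare_stages(
    cluster_mirnas(rep(rand_dna(22), 5), stage = "newborn"),
    cluster_mirnas(rep(rand_dna(22), 5), stage = "adult")
  )
  expect_equal(nrow(cmp2$shared), 0L)

  # identical sets with equal counts: all shared, nothing called
  eq <- cluster_mirnas(rep(shared_seqs, each = 250), stage = "newborn")
  eq2 <- cluster_mirnas(rep(shared_seqs, each = 250), stage = "adult")
  cmp3 <- suppressWarnings(compare_stages(eq, eq2, seed = 2))
  expect_equal(nrow(cmp3$shared), 4L)
  expect_false(any(tidy(cmp3$diff)$called))
})

test_that("planted stage roles are recovered exactly through the full path", {
  panel <- make_references(4, 1, seed = 54)
  truth <- mirna_truth(panel, n_mirna = 12, total_reads_newborn = 6000,
                       total_reads_adult = 6000, seed = 55)
  cl <- list()
  for (st in c("newborn", "adult")) {
    sim <- simulate_mirna_reads(truth, st, seed = 56)
    q <- qc_mirna(sim$reads, stage = st)
    cl[[st]] <- abundance_filter(cluster_mirnas(
      q$reads, stage = st, total_processed = q$counts$processed_reads
    ))
  }
  cmp <- suppressWarnings(compare_stages(cl$newborn, cl$adult, seed = 3))
  m <- truth$mirnas
  seq_role <- setNames(m$role, m$sequence)
  nb_expected <- m$sequence[m$copies_newborn >= 100]
  ad_expected <- m$sequence[m$copies_adult >= 100]
  expect_setequal(c(cmp$shared$consensus, cmp$unique_newborn$consensus),
                  nb_expected)
  expect_setequal(c(cmp$shared$consensus, cmp$unique_adult$consensus),
                  ad_expected)
  expect_true(all(seq_role[cmp$shared$consensus] == "shared"))
  expect_true(all(seq_role[cmp$unique_newborn$consensus] == "newborn_only"))
  expect_true(all(seq_role[cmp$unique_adult$consensus] == "adult_only"))
})

test_that("mature-reference annotation reports mismatch-bounded best hits", {
  ref_path <- write_mature_reference(n = 20, seed = 57)
  ref <- read_fasta(ref_path, mode = "rna")
  exact <- gsub("U", "T", ref$sequence[1])
  near <- exact
  substr(near, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(near, 3, 3))[1]
  far <- exact
  for (i in c(2, 9, 16)) {
    substr(far, i, i) <- setdiff(c("A", "C", "G", "T"), substr(far, i, i))[1]
  }
  cl <- tibble::tibble(
    cluster_id = c("c1", "c2", "c3"),
    consensus = c(exact, near, far),
    n_reads = c(500L, 300L, 200L), cpm = 1, stage = "newborn"
  )
  ann <- annotate_mirnas(cl, ref_path)
  expect_equal(ann$hit_id[1], ref$id[1])
  expect_equal(ann$mismatches[1], 0L)
  expect_equal(ann$mismatches[2], 1L)
  expect_equal(ann$species[1], "Anolis_carolinensis")
  expect_true(is.na(ann$hit_id[3]))  # 3 mismatches > max 2
})

test_that("species fractions reproduce the reference-annotation arithmetic", {
  ann <- tibble::tibble(
    species = c(rep("Anolis_carolinensis", 22), rep("Gallus_gallus", 26),
                NA)
  )
  s <- species_hit_summary(ann)
  expect_equal(sum(s$n_hits), 48L)
  anolis <- s$pct_of_hits[s$species == "Anolis_carolinensis"]
  expect_equal(round(anolis, 1), 45.8)
})
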