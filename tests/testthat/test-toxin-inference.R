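test_that("an embedded read annotates to its source ORF far below the cutoff", {
  panel <- family_references(make_references(3, 1, seed = 31))
  read <- substr(panel$sequence[panel$family == "PLA2"], 101, 400)
  hit <- annotate_reads(read, panel)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$family, "PLA2")
  expect_lt(hit$e_value, 1e-10)
})

test_that("random reads almost never pass the e-value cutoff", {
  panel <- family_references(make_references(3, 1, seed = 32))
  set.seed(33)
  reads <- replicate(300, rand_dna(300))
  hits <- annotate_reads(reads, panel)
  expect_lte(nrow(hits), 0.03 * 300)
})

test_that("annotation ties break to the lexicographically smaller ref id", {
  seq <- make_references(1, 1, seed = 34)$sequence[1]
  panel <- tibble::tibble(
    ref_id = c("Z_ref", "A_ref"), family = c("Z", "A"),
    sequence = c(seq, seq)
  )
  hit <- annotate_reads(substr(seq, 1, 300), panel)
  expect_equal(hit$ref_id, "A_ref")
})

test_that("pileups place error-free tiling reads and their substitutions", {
  panel <- family_references(make_references(1, 1, orf_len = 600, seed = 35))
  ref <- panel$sequence[1]
  starts <- seq(1, 541, by = 60)
  tiles <- make_reads(substring(ref, starts, starts + 119))
  pl <- build_pileup(tiles, panel)
  depth <- colSums(pl$mat != "-")
  expect_true(all(depth >= 1))
  cc <- call_consensus(pl, min_support = 1L)
  expect_equal(consensus_sequence(cc), ref)

  # empty hit set -> all depths zero
  empty <- build_pileup(tiles[0, ], panel)
  expect_equal(nrow(empty$mat), 0L)
  expect_equal(sum(pileup_counts(empty)), 0)

  # a single substitution lands in its reference column with support 1
  mutated <- ref
  old <- substr(mutated, 100, 100)
  new <- setdiff(c("A", "C", "G", "T"), old)[1]
  substr(mutated, 100, 100) <- new
  pl2 <- build_pileup(make_reads(substr(mutated, 1, 300)), panel)
  expect_equal(unname(pileup_counts(pl2)[new, 100]), 1L)
})

test_that("consensus and variant rules follow the read-support thresholds", {
  # depth 3 < 4 -> undetermined
  cc <- call_consensus(one_column_pileup(c(A = 3)))
  expect_true(is.na(cc$consensus[3]))
  expect_equal(cc$depth[3], 3L)

  # {A:5, G:3}: consensus A, both residues valid variants -> variable
  cc <- call_consensus(one_column_pileup(c(A = 5, G = 3)))
  expect_equal(cc$consensus[3], "A")
  expect_true(cc$is_variable[3])
  expect_equal(cc$variants[[3]], c(A = 5L, G = 3L))

  # {A:5, G:2}: G below the three-read variant rule -> not variable
  cc <- call_consensus(one_column_pileup(c(A = 5, G = 2)))
  expect_equal(cc$consensus[3], "A")
  expect_false(cc$is_variable[3])
  expect_equal(cc$n_variants[3], 1L)

  # the alternative "two total reads" reading is exposed as a knob
  cc <- call_consensus(one_column_pileup(c(A = 5, G = 2)),
                       min_variant_reads = 2L)
  expect_true(cc$is_variable[3])
})

test_that("distinctness calls match the exact binomial quantile", {
  params <- distinctness_params(error_rate = 0.015, alpha = 0.01)
  expect_equal(params$p_mismatch, 1 - (1 - 0.015)^2)

  base <- strrep("A", 300)
  flip <- function(n) {
    s <- base
    substr(s, 1, n) <- strrep("C", n)
    s
  }
  expect_equal(distinctness_test(base, flip(10), params)$call, "same_gene")
  expect_equal(distinctness_test(base, flip(25), params)$call, "distinct")
  expect_equal(distinctness_test(base, base, params)$call, "same_gene")
  expect_error(distinctness_test(strrep("N", 300), base, params),
               "no comparable columns")
  expect_error(distinctness_test(strrep("A", 50), base, params),
               "aligned")
})

test_that("the binomial threshold agrees with a brute-force CDF oracle", {
  # independent oracle: accumulate the CDF by direct term summation
  oracle_q <- function(L, p, alpha) {
    k <- 0:L
    cdf <- cumsum(exp(lchoose(L, k) + k * log(p) + (L - k) * log1p(-p)))
    k[which(cdf >= 1 - alpha)[1]]
  }
  for (e in c(0.005, 0.015, 0.03)) {
    params <- distinctness_params(error_rate = e, alpha = 0.01)
    for (L in c(1, 7, seq(10, 1000, by = 45), 1000)) {
      expect_equal(
        distinctness_threshold(L, params),
        oracle_q(L, params$p_mismatch, params$alpha),
        info = sprintf("L=%d e=%g", L, e)
      )
    }
  }
})

test_that("support masks exclude unsupported differences from d", {
  a <- "AAAAAAAAAA"
  b <- "AAAAACCCCC"
  params <- distinctness_params(error_rate = 0.015)
  plain <- distinctness_test(a, b, params)
  expect_equal(plain$d, 5L)
  masked <- distinctness_test(a, b, params,
                              valid_b = c(rep(TRUE, 7), rep(FALSE, 3)))
  expect_equal(masked$d, 2L)
})

test_that("count_min_genes groups by single linkage and is order-stable", {
  near <- c(x1 = strrep("A", 300), x2 = {
    s <- strrep("A", 300); substr(s, 1, 3) <- "CCC"; s
  }, x3 = {
    s <- strrep("A", 300); substr(s, 5, 6) <- "GG"; s
  })
  expect_equal(count_min_genes(near)$n_genes, 1L)

  far <- c(y1 = strrep("A", 300), y2 = paste0(strrep("C", 150),
                                              strrep("A", 150)))
  expect_equal(count_min_genes(far)$n_genes, 2L)

  shuffled <- count_min_genes(rev(near))
  expect_equal(shuffled$n_genes, 1L)
  expect_equal(count_min_genes(near)$membership$id,
               sort(names(near)))
})

test_that("gene grouping recovers planted isoforms through the full path", {
  panel <- make_references(1, 3, divergence = 0.15, orf_len = 450, seed = 36)
  prof <- stage_profile("newborn", total_long_reads = 120)
  sim <- simulate_long_reads(prof, panel, read_len_mean = 350,
                             read_len_sd = 40, fail_qv_frac = 0, seed = 37)
  pl <- build_pileup(sim$reads, family_references(panel))
  gg <- infer_gene_groups(pl)
  expect_equal(gg$n_genes, 3L)
  # groups are pure: reads in one group share one source isoform
  truth <- setNames(sim$truth$source_ref, sim$truth$read_id)
  purity <- gg$membership |>
    dplyr::mutate(src = truth[.data$id]) |>
    dplyr::summarise(ok = dplyr::n_distinct(.data$src) == 1,
                     .by = "group")
  expect_true(all(purity$ok))
})

test_that("consensus equals the source exactly at zero error and full depth", {
  panel <- make_references(1, 1, orf_len = 450, seed = 38)
  prof <- stage_profile("newborn", total_long_reads = 60, error_rate = 0)
  # full-length reads so every column satisfies the depth >= 4 condition
  sim <- simulate_long_reads(prof, panel, read_len_mean = 450,
                             read_len_sd = 0, fail_qv_frac = 0, seed = 39)
  pl <- build_pileup(sim$reads, family_references(panel))
  cc <- call_consensus(pl)
  expect_true(all(cc$depth >= 4))
  expect_equal(consensus_sequence(cc), panel$sequence[1])
  expect_false(any(cc$is_variable))
})

test_that("protein clustering separates, merges and shares as specified", {
  set.seed(40)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")
  prot <- function(n) paste(sample(aa, n, replace = TRUE), collapse = "")

  # disjoint unrelated sets -> nothing shared
  res <- cluster_proteins(
    tibble::tibble(id = "n1", sequence = prot(100)),
    tibble::tibble(id = "a1", sequence = prot(100))
  )
  expect_equal(res$summary$n_shared, 0L)
  expect_equal(res$summary$n_unique_newborn, 1L)

  # identical sequence in both stages -> one shared cluster
  p <- prot(100)
  res <- cluster_proteins(
    tibble::tibble(id = "n1", sequence = p),
    tibble::tibble(id = "a1", sequence = p)
  )
  expect_equal(res$summary$n_shared, 1L)
  expect_equal(nrow(dplyr::distinct(res$clusters, .data$cluster_id)), 1L)

  # 85% identity straddles the 0.8 threshold from above -> shared
  q <- p
  pos <- sample(100, 15)
  for (i in pos) {
    substr(q, i, i) <- setdiff(aa, substr(p, i, i))[1]
  }
  res <- cluster_proteins(
    tibble::tibble(id = "n1", sequence = p),
    tibble::tibble(id = "a1", sequence = q)
  )
  expect_equal(res$summary$n_shared, 1L)
  # and 70% identity does not merge
  q2 <- p
  for (i in sample(100, 30)) {
    substr(q2, i, i) <- setdiff(aa, substr(p, i, i))[1]
  }
  res <- cluster_proteins(
    tibble::tibble(id = "n1", sequence = p),
    tibble::tibble(id = "a1", sequence = q2)
  )
  expect_equal(res$summary$n_shared, 0L)
})
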