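test_that("a perfect complement scores the closed-form weighted sum", {
  set.seed(61)
  mir <- rand_dna(22)
  utr <- paste0(rand_dna(40), rc(mir), rand_dna(40))
  hits <- scan_pair(mir, utr)
  top <- hits[which.max(hits$score), ]
  # 5' positions 1-11 at weight 2, 12-22 at weight 1, all Watson-Crick +5
  expect_equal(top$score, 5 * (11 * 2 + 11))
  expect_true(top$seed_paired)
  expect_lt(top$dg, -19)
  expect_equal(substr(utr, top$start, top$end), rc(mir))
})

test_that("seed pairing follows the positional rules", {
  set.seed(62)
  mir <- rand_dna(22)
  site <- rc(mir)
  mutate_site_at <- function(mirna_pos) {
    # site position pairing miRNA position p is (length - p + 1)
    j <- nchar(site) - mirna_pos + 1L
    s <- site
    old <- substr(s, j, j)
    # replace with the base equal to the miRNA base (guaranteed mismatch)
    substr(s, j, j) <- substr(mir, mirna_pos, mirna_pos)
    s
  }
  # flank with a base that cannot pair miRNA position 1, so the aligner
  # cannot rescue an end mismatch by pairing a flank base through a gap
  m1 <- substr(mir, 1, 1)
  partners <- c(A = "T", C = "G", G = "C", T = "A")
  flank_base <- setdiff(c("A", "C", "G", "T"),
                        c(partners[[m1]],
                          if (m1 == "G") "T" else if (m1 == "T") "G"))[1]
  utr_for <- function(site) {
    paste0(strrep(flank_base, 30), site, strrep(flank_base, 30))
  }

  ok <- scan_pair(mir, utr_for(site))
  expect_true(any(ok$seed_paired))

  broken4 <- scan_pair(mir, utr_for(mutate_site_at(4L)))
  expect_false(any(broken4$seed_paired[broken4$score > 100]))

  pos1 <- scan_pair(mir, utr_for(mutate_site_at(1L)))
  expect_true(any(pos1$seed_paired & pos1$score > 100))

  # without the position-1 exemption the same site fails
  strict <- scan_params(allow_pos1_mismatch = FALSE)
  pos1s <- scan_pair(mir, utr_for(mutate_site_at(1L)), strict)
  expect_false(any(pos1s$seed_paired[pos1s$score > 100]))
})

test_that("G:U wobble in the seed is rejected unless allowed", {
  set.seed(63)
  mir <- rand_dna(22)
  substr(mir, 5, 5) <- "G"          # seed position 5 is G
  site <- rc(mir)
  j <- nchar(site) - 5L + 1L
  substr(site, j, j) <- "T"          # G:U instead of G:C
  utr <- paste0(strrep("A", 25), site, strrep("A", 25))
  default <- scan_pair(mir, utr)
  expect_false(any(default$seed_paired[default$score > 100]))
  loose <- scan_pair(mir, utr, scan_params(allow_gu_in_seed = TRUE))
  expect_true(any(loose$seed_paired & loose$score > 100))
})

test_that("a miRNA against its own sequence yields no filter-passing hit", {
  set.seed(64)
  params <- scan_params()
  n_pass <- 0L
  for (i in 1:60) {
    mir <- rand_dna(22)
    hits <- scan_pair(mir, paste0(rand_dna(20), mir, rand_dna(20)), params)
    pass <- hits$score > params$min_score & hits$dg < params$max_dg &
      hits$seed_paired
    if (any(pass)) n_pass <- n_pass + 1L
  }
  # isolated chance complements (helped by G:U wobble) pass for on the
  # order of 1% of random pairs; anything more indicates a scoring defect
  expect_lte(n_pass, 2L)
})

test_that("duplex energies come from the shipped stacking table", {
  # independent oracle: direct per-dinucleotide accumulation over the ten
  # published Watson-Crick stack values (+ reverse-complement symmetry)
  stack <- c(AA = -0.93, AU = -1.10, UA = -1.33, CU = -2.08, CA = -2.11,
             GU = -2.24, GA = -2.35, CG = -2.36, GG = -3.26, GC = -3.42)
  rc_rna <- c(A = "U", U = "A", C = "G", G = "C")
  full_stack <- function(xy) {
    if (xy %in% names(stack)) return(stack[[xy]])
    rcxy <- paste0(rc_rna[[substr(xy, 2, 2)]], rc_rna[[substr(xy, 1, 1)]])
    stack[[rcxy]]
  }
  set.seed(65)
  for (rep in 1:5) {
    mir <- rand_dna(20)
    hits <- scan_pair(mir, rc(mir))
    top <- hits[which.max(hits$score), ]
    p <- top$pairing[[1]]
    expect_true(all(p$type == "WC"))
    rna <- chartr("T", "U", mir)
    expected <- 4.09 + sum(vapply(1:19, function(i) {
      full_stack(substr(rna, i, i + 1))
    }, numeric(1)))
    expect_equal(top$dg, expected, tolerance = 1e-9)
  }
})

test_that("duplex energy is additive over separated stack runs", {
  pairing_for <- function(positions, mir_chars) {
    tibble::tibble(
      mirna_pos = positions,
      target_pos = 100L - positions,  # contiguous antiparallel run
      target_base = "A",
      type = "WC",
      mirna_base = mir_chars[positions]
    )
  }
  set.seed(66)
  mchars <- chartr("T", "U", strsplit(rand_dna(22), "")[[1]])
  a <- pairing_for(2:9, mchars)
  b <- pairing_for(12:19, mchars)
  both <- dplyr::bind_rows(a, b)
  expect_equal(duplex_energy(both),
               duplex_energy(a) + duplex_energy(b) - 4.09)
})

test_that("a fully unpaired alignment scores only the initiation penalty", {
  p <- tibble::tibble(
    mirna_pos = 1:10, target_pos = 50:59, target_base = "A",
    type = "MM", mirna_base = "A"
  )
  dg <- duplex_energy(p)
  expect_equal(dg, 4.09)
  expect_false(dg < -19)
})

test_that("reporting filters are strict and monotone", {
  cand <- tibble::tibble(
    mirna_id = c("m1", "m1", "m2", "m3", "m3"),
    target_id = c("t1", "t2", "t1", "t1", "t1"),
    start = c(1L, 5L, 1L, 1L, 40L), end = c(22L, 26L, 22L, 22L, 61L),
    score = c(120, 100, 150, 130, 125),
    dg = c(-25, -30, -22, -18, -26),
    seed_paired = c(TRUE, TRUE, TRUE, TRUE, TRUE)
  )
  params <- scan_params()
  out <- apply_filters(cand, params)
  # m1 loses its second target at score == 100 (strict >) and drops entirely;
  # m2 has one target; m3's -18 fails dG and both sites are on one transcript
  expect_equal(nrow(out), 0L)

  cand$score[2] <- 101
  out <- apply_filters(cand, params)
  expect_setequal(out$mirna_id, "m1")
  expect_equal(nrow(out), 2L)

  # monotonicity: tightening thresholds never adds hits
  tighter_score <- apply_filters(cand, scan_params(min_score = 130))
  expect_true(all(tighter_score$score %in% out$score))
  tighter_dg <- apply_filters(cand, scan_params(max_dg = -28))
  expect_true(nrow(tighter_dg) <= nrow(out))
})

test_that("planted multi-target miRNAs are reported and singletons suppressed", {
  panel <- make_references(4, 1, utr_len = 150, seed = 67)
  truth <- mirna_truth(panel, n_mirna = 8,
                       targets_per_mirna = c(2L, 2L, 1L, 0L), seed = 68)
  expected <- truth$sites |>
    dplyr::count(.data$mirna_id) |>
    dplyr::filter(.data$n >= 2)
  res <- scan_targets(
    truth$mirnas |> dplyr::select("mirna_id", "sequence"),
    family_references(truth$panel) |> dplyr::select(id = "family", "utr")
  )
  got <- res$hits |>
    dplyr::distinct(.data$mirna_id, .data$target_id)
  expect_setequal(unique(got$mirna_id), expected$mirna_id)
  planted <- dplyr::anti_join(
    truth$sites |> dplyr::filter(.data$mirna_id %in% expected$mirna_id),
    got, by = c("mirna_id", family = "target_id")
  )
  expect_equal(nrow(planted), 0L)
  # and the planted window coordinates are recovered exactly
  joined <- dplyr::inner_join(
    res$hits, truth$sites,
    by = c("mirna_id", target_id = "family")
  )
  expect_true(all(joined$start.x == joined$start.y))
  expect_true(all(joined$end.x == joined$end.y))
})

test_that("invalid characters are rejected", {
  expect_error(scan_pair(strrep("AX", 11), "ACGU"), "invalid characters")
  expect_error(scan_pair(strrep("AC", 11), "ACGB"), "invalid characters")
})
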