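test_that("consensus scanning reports offsets, strands and mismatch detail", {
  m0 <- scan_motif(GRHL2_CONSENSUS, max_mismatch = 0)
  expect_equal(nrow(m0), 1)   # palindromic perfect match reported once
  expect_equal(m0$offset, 0L)
  expect_equal(m0$strand, "+")
  expect_equal(m0$mismatch_count, 0L)
  expect_identical(revcomp(GRHL2_CONSENSUS), GRHL2_CONSENSUS)
  # single mismatch: + strand position 3 (C->A), - strand position 6
  m1 <- scan_motif("AAACGGTT", max_mismatch = 1)
  plus <- m1[m1$strand == "+", ]
  minus <- m1[m1$strand == "-", ]
  expect_equal(plus$mismatch_positions[[1]], 3L)
  expect_equal(plus$mismatch_bases[[1]], "A")
  expect_equal(minus$mismatch_positions[[1]], 6L)
  expect_equal(minus$mismatch_bases[[1]], "T")
  expect_error(scan_motif("AANCGGTT"), "non-ACGT")
})

test_that("scanning with full budget tallies windows like brute force", {
  set.seed(21)
  s <- snapspec:::.random_seq(60)
  m <- scan_motif(s, max_mismatch = 8, best_per_window = TRUE)
  expect_equal(nrow(m), 60 - 8 + 1)
  for (i in c(1, 17, 40)) {
    win <- substr(s, i, i + 7)
    expect_equal(m$mismatch_count[m$offset == i - 1L],
                 min(hamming(win, GRHL2_CONSENSUS),
                     hamming(win, revcomp(GRHL2_CONSENSUS))))
  }
})

test_that("mismatch canonicalization folds strand-equivalent descriptions", {
  c1 <- canonicalize_mismatch(6L, "A", "-")
  expect_equal(c1$positions, 3L)
  expect_equal(c1$bases, "T")
  c2 <- canonicalize_mismatch(3L, "T", "+")
  expect_equal(c2$positions, 3L)   # already canonical
  expect_equal(c2$bases, "T")
  c3 <- canonicalize_mismatch(5L, "A", "-")
  expect_equal(c3$positions, 4L)
  expect_equal(c3$bases, "T")
  # idempotent
  c4 <- canonicalize_mismatch(c1$positions, c1$bases, c1$strand)
  expect_equal(c4, c1)
  # the 24 one-mismatch variants fall into 12 strand-equivalence classes
  v1 <- enumerate_mismatch_variants(GRHL2_CONSENSUS, 1)
  keys <- vapply(v1, function(v) {
    m <- scan_motif(v, max_mismatch = 1, best_per_window = TRUE)
    k <- canonicalize_mismatch(m$mismatch_positions[[1]],
                               m$mismatch_bases[[1]], m$strand[1])
    paste(k$positions, k$bases)
  }, character(1))
  expect_equal(length(unique(keys)), 12)
  expect_true(all(table(keys) == 2))
})

test_that("IUPAC scanning expands degenerate codes on both strands", {
  expect_equal(scan_iupac("TTAGGTCATT", "RGGTCA", both_strands = FALSE)$offset, 2L)
  expect_equal(scan_iupac("TTGGGTCATT", "RGGTCA", both_strands = FALSE)$offset, 2L)
  expect_equal(nrow(scan_iupac("TTCGGTCATT", "RGGTCA", both_strands = FALSE)), 0)
  # minus strand: revcomp of AGGTCA is TGACCT
  hit <- scan_iupac("AATGACCTAA", "RGGTCA")
  expect_equal(hit$strand, "-")
  expect_equal(length(expand_iupac("AWTRTTKRYT")), 32)
  expect_equal(sort(expand_iupac("RGGTCA")), c("AGGTCA", "GGGTCA"))
  expect_error(scan_iupac("ACGT", "AXGT"), "IUPAC")
})

test_that("probe ranking bins deterministically with probe-id tie-break", {
  p <- tibble::tibble(probe_id = sprintf("p%02d", 1:4),
                      sequence = strrep("A", 4),
                      intensity = c(9, 7, 5, 3))
  r <- rank_top_probes(p, n = 4, bin_size = 2)
  expect_equal(r$bin, c(1, 1, 2, 2))
  expect_equal(r$intensity, c(9, 7, 5, 3))
  # ties broken lexicographically by probe_id
  pt <- tibble::tibble(probe_id = c("b", "a", "c"),
                       sequence = strrep("A", 3), intensity = c(5, 5, 5))
  rt <- rank_top_probes(pt, n = 3, bin_size = 1)
  expect_equal(rt$probe_id, c("a", "b", "c"))
  expect_warning(rank_top_probes(p, n = 6, bin_size = 2), "full bin")
  expect_error(rank_top_probes(p, n = 5, bin_size = 2), "divisible")
})

test_that("position frequency matrix reflects aligned matches", {
  pfm <- build_pfm(c("TTTTAACCGGTTTTT", "TTTTAACCGGTTTTT"), max_mismatch = 0)
  expect_equal(unname(pfm["A", 1]), 1)
  expect_equal(unname(pfm["C", 3]), 1)
  expect_equal(colSums(pfm), rep(1, 8), ignore_attr = TRUE)
})
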