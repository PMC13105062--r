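test_that("mismatch variant enumeration matches the combinatorial counts", {
  for (k in 0:8) {
    v <- enumerate_mismatch_variants(GRHL2_CONSENSUS, k)
    expect_equal(length(v), choose(8, k) * 3^k)
    expect_false(anyDuplicated(v) > 0)
  }
  expect_identical(enumerate_mismatch_variants(GRHL2_CONSENSUS, 0),
                   GRHL2_CONSENSUS)
  # every variant is at exactly the requested Hamming distance
  for (k in c(1, 2)) {
    v <- enumerate_mismatch_variants(GRHL2_CONSENSUS, k)
    expect_true(all(vapply(v, hamming, numeric(1), b = GRHL2_CONSENSUS) == k))
  }
  expect_error(enumerate_mismatch_variants(GRHL2_CONSENSUS, 9), "between 0 and")
})

test_that("variant counts agree with brute-force Hamming partition of all octamers", {
  all8 <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), 8),
                                      stringsAsFactors = FALSE))
  d <- snapspec:::.window_mismatch_matrix(all8, GRHL2_CONSENSUS)[, 1]
  tab <- table(d)
  expect_equal(sum(tab), 65536)
  for (k in 0:8) {
    expect_equal(unname(tab[as.character(k)]), choose(8, k) * 3^k,
                 ignore_attr = TRUE)
  }
})

test_that("region tiling produces the expected windows and round-trips", {
  spec <- probe_design_spec()
  set.seed(5)
  reg <- snapspec:::.random_seq(102)
  p <- tile_region(reg, "chr1", 1000L, "r1", spec)
  expect_equal(nrow(p), 10)          # floor((102 - 48)/6) + 1
  expect_equal(p$start, 1000L + seq(0L, 54L, by = 6L))
  expect_true(all(p$end - p$start == 48L))
  # round-trip: probe sequence equals the region substring at its offset
  off <- p$start - 1000L
  expect_identical(p$sequence, substring(reg, off + 1, off + 48))
  expect_equal(nrow(tile_region(snapspec:::.random_seq(48), region_id = "x",
                                spec = spec)), 1)
  expect_warning(short <- tile_region(snapspec:::.random_seq(47),
                                      region_id = "s", spec = spec),
                 "shorter than probe length")
  expect_equal(nrow(short), 0)
  expect_warning(big <- tile_region(snapspec:::.random_seq(1200),
                                    region_id = "b", spec = spec),
                 "exceeds max_region_len")
  expect_equal(nrow(big), 0)
})

test_that("dimer spacing library covers the spacing/orientation grid", {
  lib <- build_dimer_spacing_library(spacings = 0:32,
                                     orientations = c("FF", "RF"))
  expect_equal(nrow(lib), 66)
  expect_true(all(nchar(lib$sequence) == 48))
  ff1 <- lib$sequence[lib$orientation == "FF" & lib$spacing == 1]
  expect_match(ff1, "AACCGGTT.AACCGGTT")
  rf3 <- lib$sequence[lib$orientation == "RF" & lib$spacing == 3]
  expect_match(rf3, "TTGGCCAA...AACCGGTT")
  # all probes share flank content outside the motif window
  expect_equal(length(unique(nchar(lib$sequence))), 1)
  expect_error(build_dimer_spacing_library(spacings = 40), "does not fit")
})

test_that("dimer mismatch library enumerates the requested pairings", {
  id1 <- build_dimer_mismatch_library(left_k = 1, right_k = 1,
                                      pairing = "identical")
  expect_equal(nrow(id1), 24)
  # both sites carry the same variant separated by one spacer base
  v <- enumerate_mismatch_variants(GRHL2_CONSENSUS, 1)
  expect_true(all(mapply(function(s, vv) {
    grepl(paste0(vv, ".", vv), s, fixed = FALSE)
  }, id1$sequence, v)))
  id0 <- build_dimer_mismatch_library(left_k = 0, right_k = 0,
                                      pairing = "identical")
  expect_equal(nrow(id0), 1)
  expect_match(id0$sequence, "AACCGGTT.AACCGGTT")
  lo <- build_dimer_mismatch_library(left_k = 2, right_k = 0,
                                     pairing = "left_only")
  expect_equal(nrow(lo), 252)
  expect_true(all(grepl(".AACCGGTT", lo$sequence)))
  expect_error(build_dimer_mismatch_library(left_k = 1, right_k = 2,
                                            pairing = "identical"),
               "identical")
})

test_that("hairpin probes are self-complementary outside the loop", {
  half <- strrep("A", 25)
  hp <- build_hairpin_probe(half)
  expect_equal(nchar(hp$sequence), 53)
  expect_identical(hp$sequence, paste0(strrep("A", 25), "TTT", strrep("T", 25)))
  set.seed(3)
  half2 <- snapspec:::.random_seq(25)
  hp2 <- build_hairpin_probe(half2)$sequence
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ch <- strsplit(hp2, "")[[1]]
  for (i in 1:25) {
    expect_identical(ch[54 - i], unname(comp[ch[i]]))
  }
  # motif on one arm appears (reverse-complemented) on the other
  half3 <- paste0(substr(half2, 1, 5), GRHL2_CONSENSUS, substr(half2, 14, 25))
  hp3 <- build_hairpin_probe(half3)$sequence
  expect_equal(length(gregexpr("AACCGGTT", hp3)[[1]]), 2)
  expect_error(build_hairpin_probe("ACGT"), "25 bases")
})

test_that("peak merging unions overlapping but not adjacent intervals", {
  m <- merge_peak_regions(c("chr1", "chr1", "chr1", "chr2"),
                          c(0L, 40L, 100L, 0L), c(50L, 90L, 101L, 10L))
  expect_equal(nrow(m), 3)
  expect_equal(m$start[1], 0L)
  expect_equal(m$end[1], 90L)
  # book-ended intervals stay separate
  m2 <- merge_peak_regions(c("chr1", "chr1"), c(0L, 50L), c(50L, 80L))
  expect_equal(nrow(m2), 2)
})

test_that("the default constant flank harbours no near-consensus window", {
  d <- snapspec:::.min_motif_distance(strrep(snapspec:::DEFAULT_FLANK, 2),
                                      GRHL2_CONSENSUS)
  expect_gte(d, 3)
})
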