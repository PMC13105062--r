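make_probes <- function(starts, intensity = NULL, chrom = "chr1", width = 48L) {
  tibble::tibble(probe_id = sprintf("p%03d", seq_along(starts)),
                 chrom = chrom, start = as.integer(starts),
                 end = as.integer(starts + width),
                 intensity = if (is.null(intensity)) NULL else intensity)
}

test_that("probes collapse into regions by transitive interval overlap", {
  r <- collapse_to_regions(make_probes(c(0, 6)))
  expect_equal(nrow(r$regions), 1)
  expect_equal(r$regions$start, 0L)
  expect_equal(r$regions$end, 54L)
  r2 <- collapse_to_regions(make_probes(c(0, 100)))
  expect_equal(nrow(r2$regions), 2)
  # chain of 10 probes stepping by 6: one region spanning 48 + 9*6
  r3 <- collapse_to_regions(make_probes(seq(0, 54, by = 6)))
  expect_equal(nrow(r3$regions), 1)
  expect_equal(r3$regions$end - r3$regions$start, 102L)
  expect_equal(r3$regions$n_probes, 10L)
  # every probe lands in exactly one region
  expect_false(anyNA(r3$probes$region_id))
  p <- make_probes(c(0, 6))
  p$chrom[2] <- NA
  expect_warning(r4 <- collapse_to_regions(p), "without coordinates")
  expect_equal(nrow(r4$probes), 1)
})

test_that("direct calls require strictly exceeding the intensity threshold", {
  reg <- tibble::tibble(region_id = c("a", "b", "c"),
                        max_intensity = c(5.2, 3.0, 0.9))
  cl <- classify_regions(reg)
  expect_equal(cl$binding_class, c("direct", "indirect", "indirect"))
  # monotone in threshold: raising it never converts indirect -> direct
  for (thr in c(1, 2, 4, 6)) {
    cl_lo <- classify_regions(reg, thr)
    cl_hi <- classify_regions(reg, thr + 0.5)
    flipped <- cl_lo$binding_class == "indirect" &
      cl_hi$binding_class == "direct"
    expect_false(any(flipped))
  }
})

test_that("distinct sites are above-threshold runs split by low probes", {
  st <- seq(0, by = 6, length.out = 8)
  en <- st + 48
  expect_equal(count_distinct_sites(st, en, c(1, 1, 9, 8, 1, 1, 7, 1), 3), 2L)
  expect_equal(count_distinct_sites(st, en, rep(1, 8), 3), 0L)
  expect_equal(count_distinct_sites(st, en, rep(9, 8), 3), 1L)
  # disjoint windows split even without an intervening low probe
  expect_equal(count_distinct_sites(c(0, 100), c(48, 148), c(9, 9), 3), 2L)
})

test_that("differential association reproduces hand-computed chi-squared", {
  cls <- rep(c("direct", "indirect"), each = 100)
  feat <- rep(c(TRUE, FALSE, TRUE, FALSE), each = 50)
  da <- differential_association(cls, feat)
  expect_equal(da$statistic, 0)
  expect_equal(da$p_value, 1)
  # [[30,10],[10,30]]: all expected cells 20 -> X2 = 4 * 100/20 = 20
  cls2 <- rep(c("direct", "indirect"), each = 40)
  feat2 <- c(rep(TRUE, 30), rep(FALSE, 10), rep(TRUE, 10), rep(FALSE, 30))
  da2 <- differential_association(cls2, feat2)
  expect_equal(da2$statistic, 20)
  expect_lt(da2$p_value, 0.05)
  expect_equal(da2$direction, "direct")
  expect_error(differential_association(rep("direct", 5), rep(TRUE, 5)),
               "non-empty")
})

test_that("pattern presence and peak overlap flag regions correctly", {
  seqs <- c(paste0("TTTT", "AGGTCA", "TTTT"),
            paste0("TTTT", "TGACCT", "TTTT"),   # minus-strand half site
            strrep("T", 14))
  expect_equal(region_has_pattern(seqs, "RGGTCA"), c(TRUE, TRUE, FALSE))
  regions <- tibble::tibble(chrom = "chr1", start = c(0L, 100L), end = c(50L, 150L))
  peaks <- tibble::tibble(chrom = "chr1", start = 49L, end = 60L)
  expect_equal(region_overlaps_peaks(regions, peaks), c(TRUE, FALSE))
})

test_that("indirect fraction reports the printed percentage convention", {
  cls <- c(rep("indirect", 1585), rep("direct", 6151 - 1585))
  expect_equal(indirect_fraction(cls), 25.8)
  expect_equal(indirect_fraction(rep("direct", 10)), 0)
  expect_equal(indirect_fraction(rep("indirect", 3)), 100)
  expect_error(indirect_fraction(character(0)), "no regions")
})
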