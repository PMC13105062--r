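test_that("simulation is deterministic under a fixed seed", {
  cfg <- small_config(seed = 5)
  a <- simulate_regions(cfg)
  b <- simulate_regions(cfg)
  expect_identical(a$regions, b$regions)
  expect_identical(a$truth$site, b$truth$site)
  ra <- simulate_replicates(c(1, 2, 3), cfg)
  rb <- simulate_replicates(c(1, 2, 3), cfg)
  expect_identical(ra, rb)
})

test_that("null genomes contain no window within two mismatches", {
  cfg <- small_config(seed = 9, motif_plant_prob = 0)
  sim <- simulate_regions(cfg)
  d <- vapply(sim$regions$sequence, function(s) {
    snapspec:::.min_motif_distance(s, GRHL2_CONSENSUS)
  }, numeric(1), USE.NAMES = FALSE)
  expect_true(all(d >= 3))
  expect_true(all(!sim$truth$planted))
})

test_that("forced perfect planting makes every region scan positive", {
  cfg <- small_config(seed = 10, motif_plant_prob = 1,
                      mismatch_spectrum = c("0" = 1, "1" = 0, "2" = 0, "3" = 0))
  sim <- simulate_regions(cfg)
  expect_true(all(vapply(sim$regions$sequence, function(s) {
    nrow(scan_motif(s, max_mismatch = 0)) > 0
  }, logical(1))))
  expect_true(all(sim$truth$k == 0))
})

test_that("expected intensity is monotone non-increasing in mismatches", {
  cfg <- simulator_config()
  embed <- function(v) {
    tibble::tibble(probe_id = v, probe_class = "monomer_mismatch",
                   sequence = vapply(v, snapspec:::.embed_in_flank,
                                     character(1), spec = cfg$spec,
                                     USE.NAMES = FALSE))
  }
  i0 <- simulate_probe_intensity(embed(GRHL2_CONSENSUS), cfg)
  bg <- simulate_probe_intensity(embed(strrep("T", 8)), cfg)
  expect_gt(i0 / bg, 1)
  # position 3 penalised more than position 4
  v_pos3 <- "AATCGGTT"   # C->T at position 3
  v_pos4 <- "AACTGGTT"   # C->T at position 4
  ii <- simulate_probe_intensity(embed(c(v_pos3, v_pos4)), cfg)
  expect_lt(ii[1], ii[2])
  # adding a mismatch never raises expected intensity
  set.seed(12)
  for (k in 0:3) {
    vars <- enumerate_mismatch_variants(GRHL2_CONSENSUS, k)
    vk <- if (length(vars) <= 3) vars else sample(vars, 3)
    for (v in vk) {
      pos <- which(strsplit(v, "")[[1]] == strsplit(GRHL2_CONSENSUS, "")[[1]])
      p <- sample(pos, 1)
      v2 <- v
      substr(v2, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                         substr(v, p, p)), 1)
      iv <- simulate_probe_intensity(embed(c(v, v2)), cfg)
      expect_lte(iv[2], iv[1] + 1e-12)
    }
  }
})

test_that("replicate noise matches the configured coefficient of variation", {
  cfg <- simulator_config(seed = 3, noise_cv = 0.2,
                          replicate_scales = c(1, 1, 1))
  x <- simulate_replicates(rep(10, 10000), cfg)
  # pooled over 3e4 draws of known mean: sd/mean estimates the lognormal cv
  expect_equal(sd(x) / mean(x), 0.2, tolerance = 0.05)
  expect_equal(mean(x), 10, tolerance = 0.02)
  # per-probe replicate cv centres on noise_cv (allowing small-n bias)
  cv <- apply(x, 1, sd) / rowMeans(x)
  expect_equal(mean(cv) / 0.8862, 0.2, tolerance = 0.1)
  # noise-free replicates equal the expected value exactly
  cfg0 <- simulator_config(noise_cv = 0, replicate_scales = c(1, 1, 1))
  x0 <- simulate_replicates(c(2, 5), cfg0)
  expect_equal(unname(x0), cbind(c(2, 5), c(2, 5), c(2, 5)))
})

test_that("replicate scale differences vanish through the pipeline", {
  cfg_scaled <- small_config(seed = 6)
  cfg_flat <- small_config(seed = 6, replicate_scales = c(1, 1, 1))
  sim_s <- simulate_snap_experiment(cfg_scaled, include_dimers = FALSE,
                                    control_max_k = 1)
  sim_f <- simulate_snap_experiment(cfg_flat, include_dimers = FALSE,
                                    control_max_k = 1)
  # same expected intensities, same noise draws, different scales
  expect_equal(sim_s$probes$expected, sim_f$probes$expected)
  n_s <- normalize_snap(sim_s$raw)$normalized
  n_f <- normalize_snap(sim_f$raw)$normalized
  expect_equal(n_s, n_f, tolerance = 1e-10)
})

test_that("dimer spacing probes trace the phasing model", {
  cfg <- simulator_config()
  lib <- build_dimer_spacing_library(spacings = 1:20, orientations = "FF")
  inten <- simulate_probe_intensity(lib, cfg)
  pred <- predict_F(1:20, cfg$dimer_params)
  capped <- pmin(pred, exp(cfg$plateau))
  expect_equal(inten, exp(cfg$baseline) * capped)
})
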