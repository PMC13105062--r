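# Synthetic SNAP-array simulator: random genomic regions with planted
# consensus/mismatch motifs and cofactor sites, control probe libraries,
# a position-weighted motif-energy model for expected intensities (the
# phasing model for dimer probes), and triplicate raw intensities with
# per-replicate scale differences and multiplicative lognormal noise.
# Ground truth is recorded for every planted feature so downstream
# recovery can be scored.

#' Simulator configuration
#'
#' Defaults encode the qualitative specificity structure the analysis
#' expects to recover: the steepest intensity penalties for mismatches
#' at octamer positions 3 and 6, the mildest at the central 4-5
#' dinucleotide, intermediate at the edges; a flanking-base bonus; and
#' helically phased dimer probes.
#'
#' @param seed Integer seed; all simulator randomness flows from it.
#' @param n_regions Number of genomic regions.
#' @param region_length_range Min/max region length, bases.
#' @param motif_plant_prob Probability a region carries a planted motif.
#' @param mismatch_spectrum Probabilities over planted mismatch count
#'   k = 0..3 (named `"0".."3"`).
#' @param position_penalties Log-intensity penalty per mismatched
#'   octamer position 1..8.
#' @param plateau Log-intensity gain of a perfect consensus site over
#'   background.
#' @param flank_bonus Log-intensity bonus when the preferred flank base
#'   is present next to a (<=1 mismatch) site.
#' @param flank_pref Named character: preferred base at a flank position
#'   (name `"+1"` means the first base 3' of the octamer).
#' @param cofactor_rates List with `erala_direct`, `erala_indirect`,
#'   `foxa1_direct`, `foxa1_indirect`: per-class planting probabilities
#'   for the ER-alpha half site and the FoxA1 site (FoxA1 enriched in
#'   indirect regions by default).
#' @param dimer_params [phasing_params()] driving dimer-spacing probes.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   lognormal noise.
#' @param replicate_scales Per-replicate global scale factors.
#' @param baseline Background log-intensity (log scale; `exp(baseline)`
#'   is the background intensity).
#' @param direct_threshold Normalized-intensity cutoff defining the true
#'   direct class from noise-free expected intensities.
#' @param spec A [probe_design_spec()].
#' @return An object of class `simulator_config`.
#' @export
simulator_config <- function(seed = 1L,
                             n_regions = 200L,
                             region_length_range = c(120L, 300L),
                             motif_plant_prob = 0.7,
                             mismatch_spectrum = c("0" = 0.55, "1" = 0.25,
                                                   "2" = 0.12, "3" = 0.08),
                             position_penalties = c(1.4, 1.4, 2.9, 0.45,
                                                    0.45, 2.9, 1.4, 1.4),
                             plateau = log(40),
                             flank_bonus = 0.6,
                             flank_pref = c("+1" = "C"),
                             cofactor_rates = list(erala_direct = 0.3,
                                                   erala_indirect = 0.3,
                                                   foxa1_direct = 0.25,
                                                   foxa1_indirect = 0.7),
                             dimer_params = phasing_params(h_r = 5.46,
                                                           K_min = 1,
                                                           s_min = 1,
                                                           sigma_bp = 0.35),
                             noise_cv = 0.1,
                             replicate_scales = c(1, 1.4, 0.6),
                             baseline = 0,
                             direct_threshold = 3.0,
                             spec = probe_design_spec()) {
  stopifnot(motif_plant_prob >= 0, motif_plant_prob <= 1,
            abs(sum(mismatch_spectrum) - 1) < 1e-8,
            all(position_penalties >= 0), noise_cv >= 0,
            all(replicate_scales > 0),
            length(position_penalties) == nchar(spec$consensus))
  structure(as.list(environment()), class = "simulator_config")
}

# Replace any window within `min_dist` mismatches of the consensus by
# fresh random bases until the sequence is clean. Keeps ground truth
# unambiguous: planted sites are the only near-consensus windows.
.scrub_motif <- function(seq, consensus, min_dist = 2L, max_iter = 100L) {
  w <- nchar(consensus)
  for (it in seq_len(max_iter)) {
    if (nchar(seq) < w) return(seq)
    d <- .window_mismatch_matrix(seq, consensus)[1L, ]
    bad <- which(d <= min_dist)
    if (length(bad) == 0L) return(seq)
    i <- bad[1L]
    substr(seq, i, i + w - 1L) <- .random_seq(w)
  }
  stop("failed to scrub near-consensus windows", call. = FALSE)
}

.plant <- function(seq, site, at) {
  substr(seq, at + 1L, at + nchar(site)) <- site
  seq
}

#' Simulate genomic regions with planted features
#'
#' Generates `n_regions` i.i.d.-uniform background sequences, scrubbed
#' of accidental windows within 2 mismatches of the consensus, then
#' plants (per region, per configured probabilities) one consensus/
#' mismatch motif, an optional preferred flank base, and optional
#' ER-alpha / FoxA1 cofactor sites whose rates depend on the region's
#' intended binding class. Regions are laid head-to-tail on a synthetic
#' chromosome with 100-bp gaps.
#'
#' @param config A [simulator_config()].
#' @return List with `regions` (tibble: region_id, chrom, start, end,
#'   sequence) and `truth` (tibble of planted features per region;
#'   `intended_class` is the class implied by the planted site alone and
#'   drives the cofactor planting rates -- the definitive `true_class`,
#'   which also accounts for chance weak sites in the background, is
#'   added by [simulate_snap_experiment()]).
#' @export
simulate_regions <- function(config) {
  set.seed(config$seed)
  sp <- config$spec
  cons <- sp$consensus
  w <- nchar(cons)
  n <- config$n_regions
  lens <- sample(seq.int(config$region_length_range[1L],
                         config$region_length_range[2L]), n, replace = TRUE)
  lens <- pmax(lens, sp$probe_len)
  ks <- as.integer(names(config$mismatch_spectrum))
  region_rows <- vector("list", n)
  truth_rows <- vector("list", n)
  pos_start <- 0L
  for (i in seq_len(n)) {
    L <- lens[i]
    seq <- .scrub_motif(.random_seq(L), cons)
    planted <- stats::runif(1) < config$motif_plant_prob
    k <- NA_integer_; offset <- NA_integer_; site <- NA_character_
    mismatch_pos <- integer(0)
    flank_base <- NA_character_
    if (planted) {
      k <- sample(ks, 1L, prob = config$mismatch_spectrum)
      mismatch_pos <- if (k > 0L) sort(sample.int(w, k)) else integer(0)
      site <- strsplit(cons, "")[[1L]]
      for (p in mismatch_pos) {
        site[p] <- sample(setdiff(DNA_BASES, site[p]), 1L)
      }
      site <- paste(site, collapse = "")
      # margins keep the site >= 10 bases from both region ends so tiled
      # probes can satisfy the flank-eligibility filter
      offset <- sample(seq.int(12L, L - w - 12L), 1L)
      seq <- .plant(seq, site, offset)
      fp <- as.integer(names(config$flank_pref))
      flank_base <- sample(DNA_BASES, 1L)
      if (stats::runif(1) < 0.5) flank_base <- unname(config$flank_pref)
      fpos <- offset + ifelse(fp < 0, fp, w + fp - 1L)
      seq <- .plant(seq, flank_base, fpos)
    }
    # intended class from the noise-free energy model
    exp_log <- .site_log_intensity(k, mismatch_pos, flank_base, config)
    true_direct <- exp(exp_log) > config$direct_threshold
    # cofactor sites at class-dependent rates
    has_er <- stats::runif(1) < (if (true_direct) config$cofactor_rates$erala_direct
                                 else config$cofactor_rates$erala_indirect)
    has_fox <- stats::runif(1) < (if (true_direct) config$cofactor_rates$foxa1_direct
                                  else config$cofactor_rates$foxa1_indirect)
    d0 <- .window_mismatch_matrix(seq, cons)[1L, ]
    base_near <- sum(d0 <= 2L)
    base_min <- min(d0)
    for (co in c("er", "fox")[c(has_er, has_fox)]) {
      pat <- if (co == "er") "RGGTCA" else "AWTRTTKRYT"
      csite <- sample(expand_iupac(pat), 1L)
      for (try in 1:25) {
        cat_at <- sample.int(L - nchar(csite), 1L) - 1L
        if (!is.na(offset) &&
            cat_at < offset + w + 5L && cat_at + nchar(csite) > offset - 5L) next
        cand <- .plant(seq, csite, cat_at)
        dc <- .window_mismatch_matrix(cand, cons)[1L, ]
        # the cofactor site must not add or sharpen near-consensus windows
        if (sum(dc <= 2L) == base_near && min(dc) == base_min) {
          seq <- cand
          break
        }
      }
    }
    region_rows[[i]] <- tibble::tibble(
      region_id = sprintf("sim_%04d", i), chrom = "chrSim",
      start = pos_start, end = pos_start + L, sequence = seq)
    truth_rows[[i]] <- tibble::tibble(
      region_id = sprintf("sim_%04d", i), planted = planted,
      k = k, motif_offset = offset, site = site,
      mismatch_positions = list(mismatch_pos),
      flank_base = flank_base,
      has_erala = has_er, has_foxa1 = has_fox,
      expected_site_intensity = exp(exp_log),
      intended_class = ifelse(true_direct, "direct", "indirect"))
    pos_start <- pos_start + L + 100L
  }
  list(regions = do.call(rbind, region_rows),
       truth = do.call(rbind, truth_rows))
}

# Log-intensity of a planted site (NA k = no site -> baseline).
.site_log_intensity <- function(k, mismatch_pos, flank_base, config) {
  if (is.na(k)) return(config$baseline)
  motif_term <- max(0, config$plateau - sum(config$position_penalties[mismatch_pos]))
  bonus <- if (!is.na(flank_base) && k <= 1L &&
               flank_base == unname(config$flank_pref)) config$flank_bonus else 0
  config$baseline + motif_term + bonus
}

#' Expected (noise-free) intensity of probes under the energy model
#'
#' Genomic / monomer probes: log-intensity is `baseline` plus, when the
#' best motif window lies within 4 mismatches of the consensus, a motif
#' term `max(0, plateau - sum(position_penalties[mismatched positions]))`
#' plus the flank bonus when the preferred flank base is present next to
#' a near-consensus (<=1 mismatch) site. Dimer-spacing probes instead
#' follow the helical phasing model, `K_dimer * predict_F(spacing)`
#' scaled so the spacing-series minimum sits at `K_min`. Adding a
#' mismatch never increases expected intensity.
#'
#' @param probes Probe tibble (needs `sequence`, `probe_class`, and
#'   `spacing`/`orientation` for dimer probes).
#' @param config A [simulator_config()].
#' @return Numeric vector of expected intensities.
#' @export
simulate_probe_intensity <- function(probes, config) {
  cons <- config$spec$consensus
  w <- nchar(cons)
  out <- numeric(nrow(probes))
  is_dimer <- probes$probe_class == "dimer_spacing"
  if (any(!is_dimer)) {
    seqs <- probes$sequence[!is_dimer]
    logi <- vapply(seq_along(seqs), function(j) {
      s <- seqs[j]
      d <- .window_mismatch_matrix(s, cons)[1L, ]
      if (length(d) == 0L || min(d) > 4L) return(config$baseline)
      best <- which.min(d)
      k <- d[best]
      wm <- .seq_matrix(substr(s, best, best + w - 1L))[1L, ]
      mb <- strsplit(cons, "")[[1L]]
      mpos <- which(wm != mb)
      motif_term <- max(0, config$plateau - sum(config$position_penalties[mpos]))
      bonus <- 0
      if (k <= 1L && motif_term > 0) {
        fp <- as.integer(names(config$flank_pref))
        fidx <- (best - 1L) + ifelse(fp < 0, fp + 1L, w + fp)
        if (fidx >= 1L && fidx <= nchar(s) &&
            substr(s, fidx, fidx) == unname(config$flank_pref)) {
          bonus <- config$flank_bonus
        }
      }
      config$baseline + motif_term + bonus
    }, numeric(1))
    out[!is_dimer] <- exp(logi)
  }
  if (any(is_dimer)) {
    sp <- probes$spacing[is_dimer]
    ori <- probes$orientation[is_dimer]
    dp <- config$dimer_params
    f <- rep(NA_real_, sum(is_dimer))
    ok <- sp > 0
    f[ok & ori == "FF"] <- suppressWarnings(
      predict_F(sp[ok & ori == "FF"], dp))
    if (any(ori == "RF")) {
      # reverse-forward probes: same torsional form, shifted phase and
      # heavier damping (the arrangement lacks the strong periodicity)
      dp_rf <- phasing_params(h_r = dp$h_r, K_min = dp$K_min,
                              s_min = dp$s_min + 2.5,
                              sigma_bp = 2 * sigma_bp(dp),
                              ell = dp$ell, T_kelvin = dp$T_kelvin, N = dp$N)
      f[ok & ori == "RF"] <- suppressWarnings(
        predict_F(sp[ok & ori == "RF"], dp_rf))
    }
    f[!ok] <- exp(config$plateau)  # spacing 0: treated as saturated tandem site
    f[!is.finite(f)] <- exp(config$plateau)
    out[is_dimer] <- exp(config$baseline) * pmin(f, exp(config$plateau))
  }
  out
}

#' Triplicate raw intensities from expected values
#'
#' Replicate r of probe i is
#' `replicate_scales[r] * expected[i] * eps`, with `eps` lognormal with
#' mean 1 and coefficient of variation `noise_cv`.
#'
#' @param expected Positive expected intensities.
#' @param config A [simulator_config()].
#' @param seed Optional seed override (defaults to `config$seed + 1`).
#' @return Matrix with `length(expected)` rows and one column per
#'   replicate scale.
#' @export
simulate_replicates <- function(expected, config, seed = config$seed + 1L) {
  stopifnot(all(expected > 0))
  set.seed(seed)
  n_rep <- length(config$replicate_scales)
  sdlog <- sqrt(log(1 + config$noise_cv^2))
  eps <- matrix(stats::rlnorm(length(expected) * n_rep,
                              meanlog = -sdlog^2 / 2, sdlog = sdlog),
                ncol = n_rep)
  out <- outer(expected, config$replicate_scales) * eps
  colnames(out) <- paste0("rep", seq_len(n_rep))
  out
}

#' Simulate a complete SNAP array experiment
#'
#' Regions with planted features, the tiled genomic probe library plus
#' control libraries (monomer mismatch permutations up to
#' `control_max_k` mismatches and the dimer spacing series), expected
#' intensities under the energy model, and triplicate raw intensities.
#'
#' @param config A [simulator_config()].
#' @param control_max_k Largest monomer mismatch class to include.
#' @param include_dimers Include the dimer spacing series?
#' @return List with `probes` (tibble incl. `expected`), `raw` (matrix),
#'   `regions`, `truth`, `config`.
#' @export
simulate_snap_experiment <- function(config = simulator_config(),
                                     control_max_k = 3L,
                                     include_dimers = TRUE) {
  sim <- simulate_regions(config)
  sp <- config$spec
  genomic <- do.call(rbind, lapply(seq_len(nrow(sim$regions)), function(i) {
    r <- sim$regions[i, ]
    tile_region(r$sequence, r$chrom, r$start, r$region_id, sp)
  }))
  controls <- do.call(rbind, lapply(0:control_max_k, function(k) {
    variants <- enumerate_mismatch_variants(sp$consensus, k)
    seqs <- vapply(variants, .embed_in_flank, character(1), spec = sp,
                   USE.NAMES = FALSE)
    .probe_tibble(probe_id = sprintf("mono_k%d_%05d", k, seq_along(seqs)),
                  probe_class = "monomer_mismatch", sequence = seqs,
                  n_mismatch = k)
  }))
  probes <- rbind(genomic, controls)
  if (include_dimers) {
    probes <- rbind(probes, build_dimer_spacing_library(sp$consensus,
                                                        spec = sp))
  }
  probes$expected <- simulate_probe_intensity(probes, config)
  raw <- simulate_replicates(probes$expected, config)
  rownames(raw) <- probes$probe_id
  # the definitive true class comes from the noise-free energy model over
  # the actual tiled probes: chance near-consensus windows in unplanted
  # background are genuine weak sites and count toward direct binding
  gen_region <- sub("_[0-9]+$", "", genomic$probe_id)
  exp_max <- tapply(probes$expected[seq_len(nrow(genomic))], gen_region, max)
  truth <- sim$truth
  truth$expected_max_intensity <- as.numeric(exp_max[truth$region_id])
  truth$true_class <- ifelse(truth$expected_max_intensity >
                               config$direct_threshold, "direct", "indirect")
  list(probes = probes, raw = raw, regions = sim$regions,
       truth = truth, config = config)
}
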