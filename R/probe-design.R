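# Probe-library construction: genomic tiling probes and the combinatorial
# control classes (mismatch permutations, dimer spacing series, dimer
# mismatch combinations, hairpins) used on the SNAP array.

# Constant carrier sequence used for control-probe flanks and spacers.
# Chosen to contain no window within 2 mismatches of the consensus
# octamer on either strand (verified at build time by .check_flank()).
DEFAULT_FLANK <- "GTCTGAGCTCTTACGTGAGATCCAGTGTCTGAGCTCTTACGTGAGATC"

#' Probe design parameters
#'
#' Geometry of the array design: probe length, tiling step, the
#' surface-attachment primer, the consensus motif, and the maximum
#' genomic region length admitted to tiling.
#'
#' @param probe_len Length of the variable (genomic) part of each probe,
#'   in bases.
#' @param tile_step Start-to-start tiling step in bases.
#' @param primer 12-base constant region at the attachment end, used for
#'   primer extension. Not part of `Probe$sequence`.
#' @param consensus Consensus octamer recognised by the factor.
#' @param max_region_len Regions longer than this are excluded from tiling.
#' @param flank Constant carrier sequence for control-probe flanks/spacers.
#' @return An object of class `probe_design_spec`.
#' @export
probe_design_spec <- function(probe_len = 48L, tile_step = 6L,
                              primer = "GTCATAGCTGTT",
                              consensus = GRHL2_CONSENSUS,
                              max_region_len = 1000L,
                              flank = DEFAULT_FLANK) {
  stopifnot(probe_len > 0L, tile_step > 0L, max_region_len >= probe_len)
  .check_acgt(consensus, "consensus")
  .check_acgt(primer, "primer")
  if (nchar(primer) != 12L) stop("primer must be 12 bases", call. = FALSE)
  .check_flank(flank, consensus)
  structure(list(probe_len = as.integer(probe_len),
                 tile_step = as.integer(tile_step),
                 primer = primer, consensus = consensus,
                 max_region_len = as.integer(max_region_len),
                 flank = flank),
            class = "probe_design_spec")
}

# The carrier must not create unintended binding sites: no window within
# 2 mismatches of the consensus (checked on the doubled sequence so any
# substring used as flank or spacer inherits the guarantee).
.check_flank <- function(flank, consensus) {
  .check_acgt(flank, "flank")
  if (nchar(flank) >= nchar(consensus)) {
    d <- .min_motif_distance(strrep(flank, 2L), consensus)
    if (d <= 2) {
      stop("constant flank contains a window within 2 mismatches of the consensus",
           call. = FALSE)
    }
  }
  invisible(flank)
}

.probe_tibble <- function(probe_id, probe_class, sequence,
                          chrom = NA_character_, start = NA_integer_,
                          end = NA_integer_, n_mismatch = NA_integer_,
                          spacing = NA_integer_, orientation = NA_character_,
                          left_k = NA_integer_, right_k = NA_integer_) {
  tibble::tibble(probe_id = probe_id, probe_class = probe_class,
                 sequence = sequence, chrom = chrom,
                 start = as.integer(start), end = as.integer(end),
                 n_mismatch = as.integer(n_mismatch),
                 spacing = as.integer(spacing), orientation = orientation,
                 left_k = as.integer(left_k), right_k = as.integer(right_k))
}

#' Enumerate all k-mismatch variants of a motif
#'
#' Generates every sequence of the same length as `consensus` differing
#' from it at exactly `k` positions. The number of variants is
#' `choose(L, k) * 3^k`; output is lexicographically sorted and free of
#' duplicates. For `k = 0` the consensus itself is returned.
#'
#' @param consensus ACGT motif string.
#' @param k Exact number of mismatching positions, `0 <= k <= nchar(consensus)`.
#' @return Character vector of variant sequences.
#' @examples
#' length(enumerate_mismatch_variants("AACCGGTT", 1)) # 24
#' @export
enumerate_mismatch_variants <- function(consensus, k) {
  .check_acgt(consensus, "consensus")
  L <- nchar(consensus)
  k <- as.integer(k)
  if (is.na(k) || k < 0L || k > L) {
    stop(sprintf("k must be between 0 and %d", L), call. = FALSE)
  }
  ref <- strsplit(consensus, "", fixed = TRUE)[[1L]]
  if (k == 0L) return(consensus)
  pos_sets <- utils::combn(L, k, simplify = FALSE)
  out <- unlist(lapply(pos_sets, function(pos) {
    alt <- lapply(pos, function(p) setdiff(DNA_BASES, ref[p]))
    combos <- as.matrix(expand.grid(alt, stringsAsFactors = FALSE,
                                    KEEP.OUT.ATTRS = FALSE))
    apply(combos, 1L, function(bases) {
      s <- ref
      s[pos] <- bases
      paste(s, collapse = "")
    })
  }), use.names = FALSE)
  sort(out)
}

#' Tile a genomic region with fixed-length probes
#'
#' Windows of `spec$probe_len` bases are taken at offsets
#' `0, step, 2*step, ...` while they fit inside the region. Regions
#' shorter than the probe length are skipped with a warning; regions
#' longer than `spec$max_region_len` are excluded with a warning.
#'
#' @param region_sequence Region sequence (ACGT).
#' @param chrom,start Genomic anchor of the region (0-based start); the
#'   region covers `[start, start + nchar(region_sequence))`.
#' @param region_id Identifier used to derive deterministic probe IDs.
#' @param spec A [probe_design_spec()].
#' @return Tibble of probes (possibly empty).
#' @export
tile_region <- function(region_sequence, chrom = "chrSim", start = 0L,
                        region_id = "region", spec = probe_design_spec()) {
  .check_acgt(region_sequence, "region_sequence")
  L <- nchar(region_sequence)
  if (L > spec$max_region_len) {
    warning(sprintf("region %s (%d bp) exceeds max_region_len (%d bp); excluded",
                    region_id, L, spec$max_region_len))
    return(.probe_tibble(character(0), character(0), character(0)))
  }
  if (L < spec$probe_len) {
    warning(sprintf("region %s (%d bp) shorter than probe length (%d bp); skipped",
                    region_id, L, spec$probe_len))
    return(.probe_tibble(character(0), character(0), character(0)))
  }
  offsets <- seq.int(0L, L - spec$probe_len, by = spec$tile_step)
  seqs <- substring(region_sequence, offsets + 1L, offsets + spec$probe_len)
  .probe_tibble(probe_id = sprintf("%s_%04d", region_id, offsets),
                probe_class = "genomic", sequence = seqs,
                chrom = chrom, start = as.integer(start) + offsets,
                end = as.integer(start) + offsets + spec$probe_len)
}

#' Merge overlapping peak intervals into tiling regions
#'
#' Interval union on sorted intervals (0-based half-open). Intervals that
#' are merely book-ended (1-bp adjacent) are not merged.
#'
#' @param chrom,start,end Parallel vectors describing the peaks.
#' @return Tibble of merged regions (chrom, start, end).
#' @export
merge_peak_regions <- function(chrom, start, end) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  tibble::tibble(chrom = as.character(GenomicRanges::seqnames(red)),
                 start = GenomicRanges::start(red) - 1L,
                 end = GenomicRanges::end(red))
}

# Lay a motif arrangement into the constant carrier, centred-ish: the
# insert replaces carrier bases starting at left_len, so all probes in a
# library share length and flank content outside the motif window.
.embed_in_flank <- function(insert, spec) {
  total <- spec$probe_len
  ins_len <- nchar(insert)
  if (ins_len > total) stop("insert longer than probe length", call. = FALSE)
  left_len <- (total - ins_len) %/% 2L
  carrier <- strrep(spec$flank, ceiling(total / nchar(spec$flank)) + 1L)
  paste0(substr(carrier, 1L, left_len), insert,
         substr(carrier, left_len + ins_len + 1L, total))
}

#' Dimer spacing probe library
#'
#' One probe per (spacing, orientation): two copies of the consensus
#' separated by `s` spacer bases drawn from the constant carrier.
#' Forward-forward (FF) places two forward copies; reverse-forward (RF)
#' places the motif written in reverse orientation first (TTGGCCAA for
#' the consensus octamer -- for a palindromic motif the reversed string
#' equals its complement, and is a distinct sequence from the motif
#' itself, whereas the reverse complement would not be). Spacing is
#' edge-to-edge spacer length; centre-to-centre spacing is `s + nchar(consensus)`.
#'
#' @param consensus Motif string.
#' @param spacings Integer vector of spacer lengths (edge-to-edge).
#' @param orientations Subset of `c("FF", "RF")`.
#' @param spec A [probe_design_spec()].
#' @return Tibble of probes with `spacing` and `orientation` metadata.
#' @export
build_dimer_spacing_library <- function(consensus = GRHL2_CONSENSUS,
                                        spacings = 0:32,
                                        orientations = c("FF", "RF"),
                                        spec = probe_design_spec()) {
  orientations <- match.arg(orientations, c("FF", "RF"), several.ok = TRUE)
  w <- nchar(consensus)
  if (max(spacings) + 2L * w > spec$probe_len) {
    stop("largest spacing does not fit in the probe length", call. = FALSE)
  }
  grid <- expand.grid(spacing = as.integer(spacings),
                      orientation = orientations,
                      stringsAsFactors = FALSE)
  reversed <- paste(rev(strsplit(consensus, "", fixed = TRUE)[[1L]]),
                    collapse = "")
  seqs <- vapply(seq_len(nrow(grid)), function(i) {
    s <- grid$spacing[i]
    left <- if (grid$orientation[i] == "RF") reversed else consensus
    spacer <- substr(spec$flank, 1L, s)
    .embed_in_flank(paste0(left, spacer, consensus), spec)
  }, character(1))
  .probe_tibble(probe_id = sprintf("dimer_%s_s%02d", grid$orientation, grid$spacing),
                probe_class = "dimer_spacing", sequence = seqs,
                spacing = grid$spacing, orientation = grid$orientation)
}

#' Dimer mismatch probe library
#'
#' Dimeric probes (two motif copies separated by `spacer_len` carrier
#' bases) carrying mismatches in one or both sites. With
#' `pairing = "identical"` the same `left_k`-mismatch variant occupies
#' both sites (requires `left_k == right_k`); with `"left_only"` /
#' `"right_only"` the other site is the exact consensus.
#'
#' @param consensus Motif string.
#' @param left_k,right_k Mismatch counts for the left and right sites.
#' @param pairing One of `"identical"`, `"left_only"`, `"right_only"`.
#' @param spacer_len Spacer bases between the two sites.
#' @param spec A [probe_design_spec()].
#' @return Tibble of probes with `left_k`, `right_k` metadata.
#' @export
build_dimer_mismatch_library <- function(consensus = GRHL2_CONSENSUS,
                                         left_k = 1L, right_k = 1L,
                                         pairing = c("identical", "left_only",
                                                     "right_only"),
                                         spacer_len = 1L,
                                         spec = probe_design_spec()) {
  pairing <- match.arg(pairing)
  w <- nchar(consensus)
  left_k <- as.integer(left_k); right_k <- as.integer(right_k)
  if (left_k < 0L || left_k > w || right_k < 0L || right_k > w) {
    stop("mismatch counts must lie within the motif length", call. = FALSE)
  }
  if (pairing == "identical" && left_k != right_k) {
    stop("pairing = 'identical' requires left_k == right_k", call. = FALSE)
  }
  if (pairing == "left_only" && right_k != 0L) {
    stop("pairing = 'left_only' requires right_k = 0", call. = FALSE)
  }
  if (pairing == "right_only" && left_k != 0L) {
    stop("pairing = 'right_only' requires left_k = 0", call. = FALSE)
  }
  spacer <- substr(spec$flank, 1L, spacer_len)
  k <- max(left_k, right_k)
  variants <- enumerate_mismatch_variants(consensus, k)
  pairs <- switch(pairing,
    identical = cbind(variants, variants),
    left_only = cbind(variants, consensus),
    right_only = cbind(consensus, variants))
  seqs <- vapply(seq_len(nrow(pairs)), function(i) {
    .embed_in_flank(paste0(pairs[i, 1L], spacer, pairs[i, 2L]), spec)
  }, character(1))
  .probe_tibble(probe_id = sprintf("dmm_%s_%d_%d_%05d", pairing, left_k,
                                   right_k, seq_along(seqs)),
                probe_class = "dimer_mismatch", sequence = seqs,
                spacing = spacer_len, left_k = left_k, right_k = right_k)
}

#' Hairpin control probe
#'
#' A single strand folding back on itself: 25-base duplex half, a
#' 3-base loop, and the reverse complement of the half. The 53-base
#' product is self-complementary outside the loop.
#'
#' @param duplex_half 25-base ACGT string (one arm of the duplex).
#' @param loop 3-base loop sequence.
#' @param probe_id Identifier.
#' @return One-row probe tibble.
#' @export
build_hairpin_probe <- function(duplex_half, loop = "TTT",
                                probe_id = "hairpin") {
  .check_acgt(duplex_half, "duplex_half")
  .check_acgt(loop, "loop")
  if (nchar(duplex_half) != 25L) {
    stop("duplex_half must be 25 bases", call. = FALSE)
  }
  if (nchar(loop) != 3L) stop("loop must be 3 bases", call. = FALSE)
  .probe_tibble(probe_id = probe_id, probe_class = "hairpin",
                sequence = paste0(duplex_half, loop, revcomp(duplex_half)))
}
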