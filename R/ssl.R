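# Sequence Specificity Landscape: sequences arranged in concentric rings
# by Hamming distance from the consensus, ordered within each ring by
# mismatch position then substituted base, with intensity as height.
# The one-mismatch ring can be flattened to a 2D profile with section
# boundaries at mismatch-position transitions.

#' Ring index of a probe sequence
#'
#' Minimum Hamming distance between the consensus and any window of the
#' sequence, over both strands. A sequence containing a perfect site is
#' ring 0.
#'
#' @param sequences Character vector of ACGT sequences (equal length, or
#'   a single sequence).
#' @param consensus Motif string.
#' @return Integer vector of ring indices.
#' @export
assign_ring <- function(sequences, consensus = GRHL2_CONSENSUS) {
  .check_acgt(sequences)
  if (length(unique(nchar(sequences))) == 1L) {
    as.integer(.min_motif_distance(sequences, consensus))
  } else {
    vapply(sequences, function(s) {
      as.integer(.min_motif_distance(s, consensus))
    }, integer(1), USE.NAMES = FALSE)
  }
}

# Canonical mismatch description (position tuple + substituted bases) of
# the best motif window of a sequence; used for within-ring ordering.
.ring_key <- function(sequence, consensus, canonicalize = TRUE) {
  m <- scan_motif(sequence, consensus, max_mismatch = nchar(consensus),
                  best_per_window = TRUE)
  best <- m[which.min(m$mismatch_count), ]  # smallest offset wins ties
  pos <- best$mismatch_positions[[1L]]
  bas <- best$mismatch_bases[[1L]]
  if (canonicalize && is_palindromic(consensus)) {
    cn <- canonicalize_mismatch(pos, bas, best$strand, nchar(consensus))
    pos <- cn$positions; bas <- cn$bases
  }
  list(positions = pos, bases = bas)
}

#' Lay out a Sequence Specificity Landscape
#'
#' Entries are grouped into rings by mismatch count; within ring `k`
#' they are sorted by (mismatch-position tuple ascending, substituted
#' bases in A<C<G<T order, then sequence) and placed at equal angular
#' spacing, ordinal `i` of `n` at angle `2*pi*i/n`. Ring radii grow by
#' `r0` per populated ring with no gaps for empty rings (when all rings
#' `0..k` are populated the radius is `(k+1)*r0`).
#'
#' @param entries Tibble with `sequence` and `intensity`; if a `ring`
#'   column is absent it is computed with [assign_ring()]. Multiple
#'   entries sharing a sequence are collapsed by median intensity.
#' @param consensus Motif string.
#' @param canonicalize Collapse strand-equivalent mismatch descriptions
#'   (halves the one-mismatch ring from 24 classes to 12)?
#' @param r0 Radial increment per ring.
#' @return Tibble with `sequence`, `ring`, `section`, `ordinal`, `x`,
#'   `y`, `intensity`.
#' @export
layout_rings <- function(entries, consensus = GRHL2_CONSENSUS,
                         canonicalize = FALSE, r0 = 1) {
  stopifnot(all(c("sequence", "intensity") %in% names(entries)))
  entries <- as.data.frame(entries[, intersect(c("sequence", "intensity", "ring"),
                                               names(entries))])
  if (canonicalize) {
    # collapse strand-equivalent duplexes to one representative sequence
    entries$sequence <- pmin(entries$sequence, revcomp(entries$sequence))
  }
  agg <- stats::aggregate(intensity ~ sequence, data = entries, FUN = stats::median)
  if (!"ring" %in% names(entries)) {
    agg$ring <- assign_ring(agg$sequence, consensus)
  } else {
    ringmap <- entries[!duplicated(entries$sequence), c("sequence", "ring")]
    agg$ring <- ringmap$ring[match(agg$sequence, ringmap$sequence)]
  }
  keys <- lapply(agg$sequence, .ring_key, consensus = consensus,
                 canonicalize = canonicalize)
  agg$section <- vapply(keys, function(k) {
    if (length(k$positions) == 0L) "0" else
      paste(sprintf("%02d", k$positions), collapse = ",")
  }, character(1))
  agg$base_key <- vapply(keys, function(k) paste(k$bases, collapse = ""),
                         character(1))
  rings <- sort(unique(agg$ring))
  out <- lapply(seq_along(rings), function(ri) {
    sub <- agg[agg$ring == rings[ri], , drop = FALSE]
    sub <- sub[order(sub$section, sub$base_key, sub$sequence), , drop = FALSE]
    n <- nrow(sub)
    ordinal <- seq_len(n) - 1L
    theta <- 2 * pi * ordinal / n
    radius <- r0 * ri
    tibble::tibble(sequence = sub$sequence, ring = sub$ring,
                   section = sub$section, ordinal = ordinal,
                   x = radius * cos(theta), y = radius * sin(theta),
                   intensity = sub$intensity)
  })
  do.call(rbind, out)
}

#' Flatten the one-mismatch ring to a 2D profile
#'
#' Extracts the ring-1 entries of an SSL layout in ordinal order and
#' reports, alongside each sequence's mismatch position/base and
#' intensity, the ordinal boundaries where the mismatch position
#' changes (the section separators of the flattened plot).
#'
#' @param layout Output of [layout_rings()].
#' @param consensus Motif string.
#' @return List with `entries` (tibble: ordinal, sequence, mismatch
#'   position, mismatch base, x, y, intensity) and `boundaries`
#'   (ordinals at which a new mismatch-position section starts).
#' @export
flatten_one_mismatch_ring <- function(layout, consensus = GRHL2_CONSENSUS) {
  ring1 <- layout[layout$ring == 1L, , drop = FALSE]
  if (nrow(ring1) == 0L) stop("layout has no one-mismatch ring", call. = FALSE)
  ring1 <- ring1[order(ring1$ordinal), , drop = FALSE]
  pos <- as.integer(sub(",.*", "", ring1$section))
  key <- lapply(ring1$sequence, .ring_key, consensus = consensus,
                canonicalize = FALSE)
  entries <- tibble::tibble(
    ordinal = ring1$ordinal, sequence = ring1$sequence,
    mismatch_position = pos,
    mismatch_base = vapply(key, function(k) {
      if (length(k$bases)) k$bases[1L] else NA_character_
    }, character(1)),
    x = ring1$x, y = ring1$y, intensity = ring1$intensity)
  boundaries <- entries$ordinal[c(TRUE, diff(entries$mismatch_position) != 0L)]
  list(entries = entries, boundaries = boundaries)
}

#' Mean intensity per SSL ring
#'
#' @param layout Output of [layout_rings()].
#' @return Tibble with `ring`, `n`, `mean_intensity`.
#' @export
ring_summary <- function(layout) {
  agg <- stats::aggregate(intensity ~ ring, data = layout, FUN = mean)
  cnt <- stats::aggregate(intensity ~ ring, data = layout, FUN = length)
  tibble::tibble(ring = agg$ring, n = cnt$intensity,
                 mean_intensity = agg$intensity)
}
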