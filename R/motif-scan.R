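# Motif scanning: consensus/mismatch matches with strand handling for the
# palindromic octamer, strand canonicalization of mismatch descriptions,
# IUPAC pattern scanning (via Biostrings), probe ranking for motif-
# discovery export, and a simple position-frequency-matrix builder.

#' Scan a sequence for motif matches up to a mismatch budget
#'
#' Reports every window (both strands) whose Hamming distance to the
#' motif is at most `max_mismatch`. Offsets are 0-based; mismatch
#' positions are 1-based within the motif, read 5'->3' in motif
#' orientation, with the observed base on that strand. For a palindromic
#' motif the two strands carry strand-equivalent descriptions of the
#' same physical site: perfect matches are reported once (strand `"+"`),
#' mismatched windows are reported on both strands (use
#' [canonicalize_mismatch()] to collapse them).
#'
#' @param sequence ACGT string to scan.
#' @param consensus Motif string.
#' @param max_mismatch Maximum Hamming distance, `0..nchar(consensus)`.
#' @param best_per_window If `TRUE`, keep only the minimum-mismatch
#'   description per offset (ties resolved to the `+` strand).
#' @return Tibble with columns `offset`, `strand`, `mismatch_count`,
#'   `mismatch_positions` (list), `mismatch_bases` (list).
#' @export
scan_motif <- function(sequence, consensus = GRHL2_CONSENSUS,
                       max_mismatch = 1L, best_per_window = FALSE) {
  .check_acgt(sequence, "sequence")
  .check_acgt(consensus, "consensus")
  w <- nchar(consensus)
  if (max_mismatch < 0L || max_mismatch > w) {
    stop("max_mismatch must be between 0 and the motif length", call. = FALSE)
  }
  L <- nchar(sequence)
  empty <- tibble::tibble(offset = integer(0), strand = character(0),
                          mismatch_count = integer(0),
                          mismatch_positions = list(),
                          mismatch_bases = list())
  if (L < w) return(empty)
  win <- substring(sequence, seq_len(L - w + 1L), seq_len(L - w + 1L) + w - 1L)
  wm <- .seq_matrix(win)
  mb <- strsplit(consensus, "", fixed = TRUE)[[1L]]
  mism_plus <- sweep(wm, 2L, mb, "!=")
  # a minus-strand occurrence is a window matching the reverse-complement
  # of the motif; its motif-frame description maps window position j to
  # motif position w + 1 - j with the complementary observed base
  rcb <- strsplit(revcomp(consensus), "", fixed = TRUE)[[1L]]
  mism_minus <- sweep(wm, 2L, rcb, "!=")
  rows <- list()
  for (i in which(rowSums(mism_plus) <= max_mismatch)) {
    pos <- which(mism_plus[i, ])
    rows[[length(rows) + 1L]] <- list(
      offset = i - 1L, strand = "+", mismatch_count = length(pos),
      mismatch_positions = pos, mismatch_bases = unname(wm[i, pos]))
  }
  for (i in which(rowSums(mism_minus) <= max_mismatch)) {
    posw <- which(mism_minus[i, ])
    # palindromic motif: the minus description duplicates the plus one;
    # report perfect matches once, mismatched windows on both strands
    if (is_palindromic(consensus) && length(posw) == 0L) next
    rows[[length(rows) + 1L]] <- list(
      offset = i - 1L, strand = "-", mismatch_count = length(posw),
      mismatch_positions = sort(w + 1L - posw),
      mismatch_bases = unname(.comp_base(wm[i, posw]))[order(w + 1L - posw)])
  }
  if (length(rows) == 0L) return(empty)
  out <- tibble::tibble(
    offset = vapply(rows, `[[`, integer(1), "offset"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    mismatch_count = vapply(rows, `[[`, integer(1), "mismatch_count"),
    mismatch_positions = lapply(rows, `[[`, "mismatch_positions"),
    mismatch_bases = lapply(rows, `[[`, "mismatch_bases"))
  if (best_per_window) {
    ord <- order(out$offset, out$mismatch_count, out$strand)
    out <- out[ord, ]
    out <- out[!duplicated(out$offset), ]
  }
  out[order(out$offset, out$strand), ]
}

#' Canonical strand representative of a mismatch description
#'
#' For a palindromic motif every mismatched window has two strand-
#' equivalent descriptions: position `i` with base `b` on one strand
#' equals position `w + 1 - i` with the complementary base on the other.
#' The canonical form is the member of the pair with the
#' lexicographically smaller position tuple, reported on the `+` strand.
#' Idempotent; partitions the 24 one-mismatch octamer variants into 12
#' strand-equivalence classes.
#'
#' @param positions Integer vector of 1-based mismatch positions.
#' @param bases Observed bases at those positions.
#' @param strand `"+"` or `"-"` of the input description.
#' @param motif_len Motif length (8 for the octamer).
#' @return List with `positions`, `bases`, `strand` (always `"+"`).
#' @export
canonicalize_mismatch <- function(positions, bases, strand = "+",
                                  motif_len = 8L) {
  stopifnot(length(positions) == length(bases))
  if (strand == "-") {
    ord <- order(motif_len + 1L - positions)
    positions <- (motif_len + 1L - positions)[ord]
    bases <- unname(.comp_base(bases))[ord]
  } else {
    ord <- order(positions)
    positions <- positions[ord]
    bases <- bases[ord]
  }
  alt_pos <- sort(motif_len + 1L - positions)
  alt_bases <- unname(.comp_base(bases))[order(motif_len + 1L - positions)]
  pick_alt <- FALSE
  for (j in seq_along(positions)) {
    if (alt_pos[j] < positions[j]) { pick_alt <- TRUE; break }
    if (alt_pos[j] > positions[j]) break
  }
  if (pick_alt) list(positions = alt_pos, bases = alt_bases, strand = "+")
  else list(positions = positions, bases = bases, strand = "+")
}

#' Scan for a degenerate (IUPAC) pattern
#'
#' Exact matching of an IUPAC-coded pattern (R, W, K, Y, N, ...) on one
#' or both strands, via Biostrings fixed-pattern expansion.
#'
#' @param sequence ACGT string.
#' @param pattern IUPAC pattern string, e.g. `"RGGTCA"`.
#' @param both_strands Scan the reverse complement too?
#' @return Tibble with `offset` (0-based, on the forward sequence) and
#'   `strand`.
#' @export
scan_iupac <- function(sequence, pattern, both_strands = TRUE) {
  .check_acgt(sequence, "sequence")
  ok <- strsplit(pattern, "", fixed = TRUE)[[1L]] %in%
    names(Biostrings::IUPAC_CODE_MAP)
  if (!all(ok)) {
    stop(sprintf("unknown IUPAC code '%s' in pattern",
                 substr(pattern, which(!ok)[1L], which(!ok)[1L])),
         call. = FALSE)
  }
  subj <- Biostrings::DNAString(sequence)
  hit_f <- Biostrings::matchPattern(pattern, subj, fixed = FALSE)
  out <- tibble::tibble(offset = BiocGenerics::start(hit_f) - 1L,
                        strand = rep("+", length(hit_f)))
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(pattern)))
    hit_r <- Biostrings::matchPattern(rc, subj, fixed = FALSE)
    out <- rbind(out, tibble::tibble(offset = BiocGenerics::start(hit_r) - 1L,
                                     strand = rep("-", length(hit_r))))
  }
  out[order(out$offset, out$strand), ]
}

#' Expand an IUPAC pattern to all concrete sequences
#'
#' @param pattern IUPAC pattern string.
#' @return Character vector of every ACGT sequence the pattern matches.
#' @export
expand_iupac <- function(pattern) {
  sets <- Biostrings::IUPAC_CODE_MAP[strsplit(pattern, "", fixed = TRUE)[[1L]]]
  if (anyNA(names(sets))) stop("unknown IUPAC code in pattern", call. = FALSE)
  combos <- expand.grid(lapply(sets, function(s) strsplit(s, "")[[1L]]),
                        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  sort(apply(as.matrix(combos), 1L, paste, collapse = ""))
}

#' Rank probes by normalized intensity into fixed-size bins
#'
#' Probes are sorted by decreasing normalized intensity (ties broken by
#' probe ID, lexicographically, so ranking is deterministic) and the top
#' `n` are split into consecutive bins of `bin_size` for export to
#' external motif-discovery tools.
#'
#' @param probes Tibble with `probe_id`, `sequence` and `intensity`.
#' @param n Total number of probes to keep (multiple of `bin_size`).
#' @param bin_size Probes per bin.
#' @return Tibble of the top probes with `rank` and `bin` columns.
#' @export
rank_top_probes <- function(probes, n = 1200L, bin_size = 300L) {
  if (n %% bin_size != 0L) stop("n must be divisible by bin_size", call. = FALSE)
  ord <- order(-probes$intensity, probes$probe_id)
  ranked <- probes[ord, ]
  if (nrow(ranked) < n) {
    keep <- (nrow(ranked) %/% bin_size) * bin_size
    warning(sprintf("only %d probes available; keeping %d full bin(s)",
                    nrow(ranked), keep %/% bin_size))
    n <- keep
  }
  ranked <- ranked[seq_len(n), , drop = FALSE]
  ranked$rank <- seq_len(n)
  ranked$bin <- ceiling(ranked$rank / bin_size)
  ranked
}

#' Most enriched k-mer among a set of sequences
#'
#' Support counting in the style of motif discovery: each sequence
#' contributes at most one count per k-mer it contains (strand-
#' equivalent k-mers collapsed to the lexicographically smaller of the
#' k-mer and its reverse complement). Used on top-ranked probes, where
#' the binding-site octamer should dominate.
#'
#' @param sequences Character vector of ACGT sequences.
#' @param k K-mer width.
#' @return Tibble with `kmer` and `count` (number of sequences
#'   containing it), sorted by decreasing count.
#' @export
top_enriched_kmer <- function(sequences, k = 8L) {
  kmers <- unlist(lapply(sequences, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    w <- substring(s, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
    unique(pmin(w, revcomp(w)))
  }), use.names = FALSE)
  tab <- sort(table(kmers), decreasing = TRUE)
  tibble::tibble(kmer = names(tab), count = as.integer(tab))
}

#' Position frequency matrix from aligned motif matches
#'
#' Collects all windows within `max_mismatch` of the consensus across
#' the supplied sequences (canonical `+`-strand frame) and tallies base
#' frequencies per motif position.
#'
#' @param sequences ACGT sequences.
#' @param consensus Motif string.
#' @param max_mismatch Match budget for inclusion.
#' @return 4 x L numeric matrix of base frequencies (rows A, C, G, T).
#' @export
build_pfm <- function(sequences, consensus = GRHL2_CONSENSUS,
                      max_mismatch = 1L) {
  w <- nchar(consensus)
  wins <- unlist(lapply(sequences, function(s) {
    m <- scan_motif(s, consensus, max_mismatch, best_per_window = TRUE)
    substring(s, m$offset + 1L, m$offset + w)
  }), use.names = FALSE)
  counts <- matrix(0, nrow = 4L, ncol = w,
                   dimnames = list(DNA_BASES, seq_len(w)))
  if (length(wins)) {
    sm <- .seq_matrix(wins)
    for (b in DNA_BASES) counts[b, ] <- colSums(sm == b)
  }
  sweep(counts, 2L, pmax(colSums(counts), 1), "/")
}
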