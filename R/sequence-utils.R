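# Low-level sequence helpers shared across modules. Sequences are plain
# character vectors over A/C/G/T; heavier lifting (IUPAC matching, FASTA)
# goes through Biostrings.

DNA_BASES <- c("A", "C", "G", "T")

#' GRHL2 consensus octamer
#'
#' The canonical Grainyhead-family recognition motif, 5'-AACCGGTT-3'.
#' The octamer is palindromic: it equals its own reverse complement.
#'
#' @format A length-one character vector.
#' @export
GRHL2_CONSENSUS <- "AACCGGTT"

.check_acgt <- function(x, arg = "sequence") {
  bad <- regexpr("[^ACGT]", x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("%s contains a non-ACGT character at position %d (sequence %d)",
                 arg, bad[i], i), call. = FALSE)
  }
  invisible(x)
}

#' Reverse complement of ACGT strings
#'
#' @param x Character vector of A/C/G/T sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

#' Is a motif palindromic (its own reverse complement)?
#' @param motif An ACGT string.
#' @return Logical scalar.
#' @export
is_palindromic <- function(motif) identical(revcomp(motif), motif)

# Split equal-length sequences into an n x L character matrix.
.seq_matrix <- function(seqs) {
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences must share a common length", call. = FALSE)
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), ncol = L, byrow = TRUE)
}

# Hamming distances between each window of each sequence and a motif.
# Returns an n x n_offsets integer matrix (offsets are 0-based window
# starts). Vectorized across sequences; all sequences must share a length.
.window_mismatch_matrix <- function(seqs, motif) {
  sm <- .seq_matrix(seqs)
  mb <- strsplit(motif, "", fixed = TRUE)[[1L]]
  w <- length(mb)
  L <- ncol(sm)
  if (L < w) return(matrix(integer(0), nrow = nrow(sm), ncol = 0L))
  n_off <- L - w + 1L
  out <- matrix(0L, nrow = nrow(sm), ncol = n_off)
  for (j in seq_len(w)) {
    out <- out + (sm[, j:(j + n_off - 1L), drop = FALSE] != mb[j])
  }
  out
}

# Minimum window Hamming distance to a motif over both strands.
# For a palindromic motif the two strands are identical, so only the
# forward comparison is performed.
.min_motif_distance <- function(seqs, motif) {
  d <- .window_mismatch_matrix(seqs, motif)
  dm <- if (ncol(d)) apply(d, 1L, min) else rep(Inf, length(seqs))
  if (!is_palindromic(motif)) {
    d2 <- .window_mismatch_matrix(seqs, revcomp(motif))
    dm2 <- if (ncol(d2)) apply(d2, 1L, min) else rep(Inf, length(seqs))
    dm <- pmin(dm, dm2)
  }
  dm
}

# Random ACGT sequences (length may vary per element).
.random_seq <- function(lengths) {
  vapply(lengths, function(L) {
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
  }, character(1))
}
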