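# Shared fixtures, built in code at test time.

# Small simulator configuration for fast end-to-end runs.
small_config <- function(seed = 1L, ...) {
  simulator_config(seed = seed, n_regions = 60L,
                   region_length_range = c(100L, 200L), ...)
}

# Probe set for flank analysis: random 48-mers with a perfect consensus
# planted at a safe offset; intensity optionally boosted when the base
# at flank position `boost_pos` (+k = k bases 3' of the octamer) equals
# `boost_base`.
make_flank_dataset <- function(n = 400L, boost_pos = NULL,
                               boost_base = "C", boost = 1) {
  offs <- sample(12:30, n, replace = TRUE)
  seqs <- snapspec:::.random_seq(rep(48L, n))
  seqs <- vapply(seq_len(n), function(i) {
    s <- seqs[i]
    substr(s, offs[i] + 1L, offs[i] + 8L) <- GRHL2_CONSENSUS
    s
  }, character(1))
  inten <- stats::rlnorm(n, 0, 0.3)
  if (!is.null(boost_pos)) {
    idx <- offs + 8L + boost_pos
    hit <- substring(seqs, idx, idx) == boost_base
    inten[hit] <- inten[hit] * exp(boost)
  }
  tibble::tibble(probe_id = sprintf("p%04d", seq_len(n)),
                 sequence = seqs, intensity = inten)
}

# Brute-force Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Independent window-minimum oracle: naive double loop over offsets and
# strands (used to cross-check the vectorized scanner).
oracle_min_distance <- function(seq, motif) {
  w <- nchar(motif)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  best <- Inf
  for (i in seq_len(nchar(seq) - w + 1L)) {
    win <- substr(seq, i, i + w - 1L)
    best <- min(best, hamming(win, motif), hamming(win, rc))
  }
  best
}
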