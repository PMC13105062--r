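# Flanking-base preference analysis: which bases at positions -5..-1 and
# +1..+5 around a single perfect consensus site distinguish the highest
# from the lowest intensity quartile of eligible genomic probes.

#' Filter probes eligible for flank analysis
#'
#' Retains probes that carry exactly one perfect consensus site, no
#' additional site anywhere within one mismatch (to avoid dimeric
#' binding effects), and whose site sits at least `margin` bases from
#' both the primer junction and the distal probe end (to avoid constant-
#' sequence and duplex-terminus effects).
#'
#' @param probes Tibble with `probe_id`, `sequence`, `intensity`.
#' @param consensus Motif string (palindromic octamer by default).
#' @param margin Minimum distance (bases) from the site to either probe end.
#' @return The eligible subset, with `motif_offset` (0-based) added.
#' @export
filter_flank_eligible <- function(probes, consensus = GRHL2_CONSENSUS,
                                  margin = 10L) {
  if (nrow(probes) == 0L) return(cbind(probes, motif_offset = integer(0)))
  w <- nchar(consensus)
  d <- .window_mismatch_matrix(probes$sequence, consensus)
  if (!is_palindromic(consensus)) {
    d <- pmin(d, .window_mismatch_matrix(probes$sequence, revcomp(consensus)))
  }
  n_perfect <- rowSums(d == 0L)
  n_near <- rowSums(d <= 1L)
  offset <- max.col(-d, ties.method = "first") - 1L  # best window, smallest offset
  L <- nchar(probes$sequence)
  keep <- n_perfect == 1L & n_near == 1L &
    offset >= margin & (L - (offset + w)) >= margin
  out <- probes[keep, , drop = FALSE]
  out$motif_offset <- offset[keep]
  out
}

# Flank base matrix for eligible probes: columns -5..-1, +1..+5 relative
# to the motif (motif orientation; the octamer is palindromic so the
# forward frame is canonical).
.flank_matrix <- function(sequences, motif_offset, motif_len = 8L,
                          width = 5L) {
  pos <- c(-(width:1), seq_len(width))
  out <- matrix(NA_character_, nrow = length(sequences), ncol = length(pos),
                dimnames = list(NULL, ifelse(pos > 0, paste0("+", pos), pos)))
  for (j in seq_along(pos)) {
    p <- pos[j]
    idx <- motif_offset + ifelse(p < 0, p + 1L, motif_len + p)
    out[, j] <- substring(sequences, idx, idx)
  }
  out
}

#' Chi-squared test of base counts against background proportions
#'
#' Pearson chi-squared with 3 degrees of freedom comparing an observed
#' base-count 4-vector to expectations `sum(observed) * background`.
#'
#' @param observed Named or unnamed non-negative count 4-vector (A,C,G,T).
#' @param background Background base proportions, summing to 1.
#' @return List with `statistic` and `p_value`.
#' @export
chisq_vs_background <- function(observed, background) {
  stopifnot(length(observed) == 4L, length(background) == 4L)
  if (any(observed < 0)) stop("counts must be non-negative", call. = FALSE)
  if (abs(sum(background) - 1) > 1e-8) {
    stop("background proportions must sum to 1", call. = FALSE)
  }
  expected <- sum(observed) * background
  if (any(expected == 0)) {
    stop("zero expected count; pool categories before testing", call. = FALSE)
  }
  stat <- sum((observed - expected)^2 / expected)
  list(statistic = stat, p_value = stats::pchisq(stat, df = 3L,
                                                 lower.tail = FALSE))
}

# 2x2 top-vs-bottom chi-squared (1 df, no continuity correction) for a
# single base at a single position.
.chisq_2x2 <- function(top_b, top_n, bot_b, bot_n) {
  tab <- matrix(c(top_b, top_n - top_b, bot_b, bot_n - bot_b), nrow = 2L)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(statistic = 0, p_value = 1))
  }
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1L,
                                                 lower.tail = FALSE))
}

#' Quartile flank-enrichment table
#'
#' Splits eligible probes into the highest and lowest `quartile`
#' fraction by normalized intensity (ties broken by rank, then probe
#' ID) and, for every flank position (-5..-1, +1..+5) and base,
#' tabulates frequencies in each quartile, their ratio, the background
#' frequency over all eligible probes, a per-(position, base) 2x2
#' top-versus-bottom chi-squared p-value, and a per-position 3-df
#' chi-squared of the top-quartile counts against background
#' proportions. Benjamini-Hochberg q-values are added across the
#' per-cell tests.
#'
#' @param eligible Output of [filter_flank_eligible()] (needs
#'   `sequence`, `intensity`, `motif_offset`, `probe_id`).
#' @param quartile Fraction in each tail (default 0.25).
#' @param motif_len Motif length.
#' @param width Number of flank positions on each side.
#' @return Tibble with one row per (position, base).
#' @export
quartile_enrichment <- function(eligible, quartile = 0.25, motif_len = 8L,
                                width = 5L) {
  n <- nrow(eligible)
  m <- floor(n * quartile)
  if (n < 8L || m < 1L) stop("need at least 8 eligible probes", call. = FALSE)
  ord <- order(-eligible$intensity, eligible$probe_id)
  top_idx <- ord[seq_len(m)]
  bot_idx <- ord[seq.int(n - m + 1L, n)]
  fm <- .flank_matrix(eligible$sequence, eligible$motif_offset,
                      motif_len = motif_len, width = width)
  positions <- colnames(fm)
  res <- vector("list", length(positions))
  for (j in seq_along(positions)) {
    count4 <- function(x) {
      vapply(DNA_BASES, function(b) sum(x == b), numeric(1))
    }
    top_c <- count4(fm[top_idx, j])
    bot_c <- count4(fm[bot_idx, j])
    all_c <- count4(fm[, j])
    bg_prop <- all_c / sum(all_c)
    pos_test <- if (all(bg_prop > 0)) {
      chisq_vs_background(top_c, bg_prop)
    } else list(statistic = NA_real_, p_value = NA_real_)
    cell <- lapply(seq_along(DNA_BASES), function(b) {
      .chisq_2x2(top_c[b], m, bot_c[b], m)
    })
    res[[j]] <- tibble::tibble(
      position = positions[j], base = DNA_BASES,
      freq_top = top_c / m, freq_bottom = bot_c / m,
      ratio = ifelse(bot_c > 0, (top_c / m) / (bot_c / m),
                     ifelse(top_c > 0, Inf, NA_real_)),
      background = bg_prop,
      chi2 = vapply(cell, `[[`, numeric(1), "statistic"),
      p = vapply(cell, `[[`, numeric(1), "p_value"),
      position_chi2 = pos_test$statistic,
      position_p = pos_test$p_value)
  }
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$p) & out$p < 0.05
  out$stars <- cut(out$p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                   labels = c("***", "**", "*", ""))
  out
}
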