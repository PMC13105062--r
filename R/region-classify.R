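# Region-level analysis: collapse tiled probes into genomic regions by
# interval overlap, classify each region as direct (measurable naked-DNA
# binding) or indirect (ChIP-seq occupancy without array binding), count
# distinct binding sites, and test differential cofactor association.

#' Collapse tiled probes into genomic regions
#'
#' Transitive closure of interval overlap on the same chromosome: every
#' chain of mutually overlapping probes becomes one region spanning
#' their union. Probes without coordinates are dropped with a warning.
#'
#' @param probes Tibble with `probe_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `intensity`.
#' @return List with `regions` (tibble: region_id, chrom, start, end,
#'   n_probes, and max_intensity when intensities are present) and
#'   `probes` (the input with a `region_id` column added).
#' @export
collapse_to_regions <- function(probes) {
  has_coord <- !is.na(probes$chrom) & !is.na(probes$start) & !is.na(probes$end)
  if (any(!has_coord)) {
    warning(sprintf("%d probe(s) without coordinates excluded", sum(!has_coord)))
  }
  pr <- probes[has_coord, , drop = FALSE]
  gr <- GenomicRanges::GRanges(pr$chrom,
                               IRanges::IRanges(pr$start + 1L, pr$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hit <- GenomicRanges::findOverlaps(gr, red)
  pr$region_id <- sprintf("region_%05d", S4Vectors::subjectHits(hit))
  regions <- tibble::tibble(
    region_id = sprintf("region_%05d", seq_along(red)),
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    n_probes = as.integer(table(factor(S4Vectors::subjectHits(hit),
                                       levels = seq_along(red)))))
  if ("intensity" %in% names(pr)) {
    mx <- tapply(pr$intensity, pr$region_id, max)
    regions$max_intensity <- as.numeric(mx[regions$region_id])
  }
  list(regions = regions, probes = pr)
}

#' Classify regions as direct or indirect
#'
#' A region is a direct binding region when its maximal normalized probe
#' intensity strictly exceeds `threshold`; otherwise (including exactly
#' at the threshold) it is indirect.
#'
#' @param regions Tibble with a `max_intensity` column.
#' @param threshold Normalized-intensity cutoff (default 3.0).
#' @return The input with a `binding_class` column (`"direct"` /
#'   `"indirect"`).
#' @export
classify_regions <- function(regions, threshold = 3.0) {
  regions$binding_class <- ifelse(regions$max_intensity > threshold,
                                  "direct", "indirect")
  regions
}

#' Count distinct binding sites along a tiled region
#'
#' Sites are maximal blocks of above-threshold probes in tiling order:
#' two consecutive above-threshold probes belong to the same site when
#' no below-threshold probe lies between them and their windows overlap.
#' An intervening below-threshold probe demonstrates a low-affinity
#' window and splits the run into distinct sites.
#'
#' @param starts,ends Probe intervals (0-based half-open), any order.
#' @param intensities Normalized probe intensities, parallel to `starts`.
#' @param threshold Intensity cutoff (default 3.0).
#' @return Integer count of distinct sites (0 when nothing is above
#'   threshold).
#' @export
count_distinct_sites <- function(starts, ends, intensities, threshold = 3.0) {
  ord <- order(starts, ends)
  above <- intensities[ord] > threshold
  if (!any(above)) return(0L)
  st <- starts[ord]; en <- ends[ord]
  n_sites <- 0L
  prev_above_end <- NULL
  run_open <- FALSE
  for (i in seq_along(above)) {
    if (above[i]) {
      if (!run_open || st[i] >= prev_above_end) {
        n_sites <- n_sites + 1L
      }
      prev_above_end <- en[i]
      run_open <- TRUE
    } else {
      run_open <- FALSE
    }
  }
  n_sites
}

#' Differential cofactor association between region classes
#'
#' Builds the 2x2 contingency table of binding class (direct/indirect)
#' against a per-region boolean feature (cofactor motif present, or
#' ChIP-seq peak overlap) and applies the Pearson chi-squared test of
#' independence (1 df, no continuity correction). When any expected
#' cell is below 1 a warning recommends the exact test, whose p-value
#' is reported alongside.
#'
#' @param binding_class Character vector, `"direct"` / `"indirect"`.
#' @param feature Logical vector, parallel to `binding_class`.
#' @return List with `table`, `statistic`, `p_value`, `fisher_p` (NA
#'   unless expected counts were small), `direction` (which class is
#'   enriched for the feature).
#' @export
differential_association <- function(binding_class, feature) {
  stopifnot(length(binding_class) == length(feature))
  cls <- factor(binding_class, levels = c("direct", "indirect"))
  if (any(is.na(cls))) stop("binding_class must be 'direct' or 'indirect'",
                            call. = FALSE)
  if (nlevels(droplevels(cls)) < 2L) {
    stop("both region classes must be non-empty", call. = FALSE)
  }
  tab <- table(class = cls, feature = factor(feature, levels = c(FALSE, TRUE)))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  fisher_p <- NA_real_
  if (any(e < 1)) {
    warning("expected cell count below 1; reporting Fisher's exact test alongside")
    fisher_p <- stats::fisher.test(tab)$p.value
  }
  prop <- prop.table(tab, margin = 1L)[, "TRUE"]
  direction <- names(prop)[which.max(prop)]
  list(table = tab, statistic = unname(stat), p_value = unname(p),
       fisher_p = fisher_p, direction = direction)
}

#' Region-level presence of an IUPAC pattern
#'
#' @param sequences Region sequences.
#' @param pattern IUPAC pattern (e.g. `"RGGTCA"` for the ER-alpha half
#'   site, `"AWTRTTKRYT"` for FoxA1).
#' @return Logical vector: pattern present on either strand.
#' @export
region_has_pattern <- function(sequences, pattern) {
  vapply(sequences, function(s) nrow(scan_iupac(s, pattern)) > 0L,
         logical(1), USE.NAMES = FALSE)
}

#' Region overlap with ChIP-seq peaks
#'
#' At least 1 bp intersection between each region and any peak
#' (0-based half-open intervals).
#'
#' @param regions Tibble with `chrom`, `start`, `end`.
#' @param peaks Tibble with `chrom`, `start`, `end`.
#' @return Logical vector, one per region.
#' @export
region_overlaps_peaks <- function(regions, peaks) {
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1L, regions$end))
  pk <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L, peaks$end))
  GenomicRanges::countOverlaps(gr, pk) > 0L
}

#' Percentage of indirect regions
#'
#' `100 * n_indirect / n_total`, rounded to one decimal for reporting.
#'
#' @param binding_class Character vector of `"direct"` / `"indirect"`.
#' @return Percentage (one decimal).
#' @export
indirect_fraction <- function(binding_class) {
  if (length(binding_class) == 0L) stop("no regions", call. = FALSE)
  round(100 * mean(binding_class == "indirect"), 1L)
}
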