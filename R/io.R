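# File formats: tab-delimited intensity and probe tables, FASTA
# (Biostrings), BED (rtracklayer). All genomic coordinates are 0-based
# half-open (BED convention).

#' Read an extracted-intensity table
#'
#' Tab-delimited with header; requires `probe_id` and `sequence`
#' columns plus at least one numeric replicate column (every remaining
#' column is treated as a replicate).
#'
#' @param path File path.
#' @return List with `probes` (tibble: probe_id, sequence) and
#'   `intensities` (numeric matrix, probe IDs as rownames).
#' @export
read_intensity_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("probe_id", "sequence")) {
    if (!col %in% names(df)) {
      stop(sprintf("missing required column '%s' in %s", col, path),
           call. = FALSE)
    }
  }
  rep_cols <- setdiff(names(df), c("probe_id", "sequence"))
  if (length(rep_cols) == 0L) {
    stop("no replicate intensity columns found", call. = FALSE)
  }
  for (col in rep_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stop(sprintf("non-numeric intensity in column '%s', line %d",
                   col, bad[1L] + 1L), call. = FALSE)
    }
    df[[col]] <- v
  }
  if (anyDuplicated(df$probe_id)) {
    stop("duplicate probe_id values", call. = FALSE)
  }
  m <- as.matrix(df[rep_cols])
  rownames(m) <- df$probe_id
  list(probes = tibble::tibble(probe_id = df$probe_id,
                               sequence = df$sequence),
       intensities = m)
}

#' Write an intensity table
#'
#' @param probes Tibble with `probe_id` and `sequence`.
#' @param intensities Numeric matrix, rows parallel to `probes`.
#' @param path Output path.
#' @export
write_intensity_table <- function(probes, intensities, path) {
  df <- data.frame(probe_id = probes$probe_id, sequence = probes$sequence,
                   intensities, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write probe library tables
#'
#' Tab-delimited probe tables as produced by the design functions.
#'
#' @param probes Probe tibble.
#' @param path File path.
#' @return `read_probe_table()` returns the probe tibble.
#' @export
write_probe_table <- function(probes, path) {
  utils::write.table(as.data.frame(probes), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_probe_table
#' @export
read_probe_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  tibble::as_tibble(df)
}

#' Read/write FASTA
#'
#' @param path File path.
#' @param sequences Named character vector of sequences.
#' @return `read_fasta()` returns a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read/write BED intervals (3+ columns, 0-based half-open)
#'
#' @param path File path.
#' @param regions Tibble with `chrom`, `start`, `end`, optionally `name`.
#' @return `read_bed()` returns a tibble (chrom, start, end, name).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr) - 1L,
                 end = GenomicRanges::end(gr),
                 name = if (!is.null(gr$name)) gr$name else NA_character_)
}

#' @rdname read_bed
#' @export
write_bed <- function(regions, path) {
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1L,
                                                regions$end))
  if ("name" %in% names(regions)) gr$name <- regions$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Export ranked probe bins as FASTA files
#'
#' One FASTA per bin (`bin1.fa`, `bin2.fa`, ...) under `dir`, for
#' external de novo motif discovery.
#'
#' @param ranked Output of [rank_top_probes()].
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths.
#' @export
export_ranked_fasta <- function(ranked, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vapply(sort(unique(ranked$bin)), function(b) {
    sub <- ranked[ranked$bin == b, ]
    write_fasta(stats::setNames(sub$sequence, sub$probe_id),
                file.path(dir, sprintf("bin%d.fa", b)))
  }, character(1))
}
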