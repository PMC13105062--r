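# Replicate intensity normalization: global median scaling, quantile
# normalization (via limma), and per-probe median collapse. Input and
# output are numeric probes x replicates matrices with probe IDs as
# rownames; intensities are non-negative fluorescence values.

.check_intensity_matrix <- function(x, min_rep = 1L) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("intensities must be a numeric matrix (probes x replicates)",
         call. = FALSE)
  }
  if (ncol(x) < min_rep) {
    stop(sprintf("at least %d replicate column(s) required", min_rep),
         call. = FALSE)
  }
  if (anyNA(x)) stop("missing intensities: drop incomplete rows first",
                     call. = FALSE)
  if (any(x < 0)) stop("negative intensities are not allowed", call. = FALSE)
  invisible(x)
}

#' Global (median) scaling of replicate arrays
#'
#' Rescales each replicate by a single multiplicative factor so that all
#' replicate medians (or totals, with `method = "sum"`) agree. The
#' default target is the mean of the raw replicate medians, which keeps
#' the output on the raw fluorescence scale; a numeric `target` (e.g.
#' 1) instead fixes the common median at that constant, which makes
#' downstream results exactly invariant to rescaling any replicate.
#' Within-replicate rank order is untouched either way.
#'
#' @param x Numeric probes x replicates matrix.
#' @param method `"median"` (default) equalizes medians;
#'   `"sum"` equalizes column totals.
#' @param target `"mean"` (the mean of the raw per-replicate statistics)
#'   or a positive number.
#' @return Matrix of the same shape, with attribute `"scale_factors"`.
#' @export
global_normalize <- function(x, method = c("median", "sum"),
                             target = "mean") {
  method <- match.arg(method)
  .check_intensity_matrix(x, min_rep = 2L)
  stat <- switch(method,
                 median = apply(x, 2L, stats::median),
                 sum = colSums(x))
  if (any(stat <= 0)) {
    bad <- colnames(x)[stat <= 0]
    if (is.null(bad)) bad <- which(stat <= 0)
    stop(sprintf("replicate(s) %s have non-positive %s; cannot scale",
                 paste(bad, collapse = ", "), method), call. = FALSE)
  }
  tgt <- if (identical(target, "mean")) mean(stat) else {
    stopifnot(is.numeric(target), target > 0)
    target
  }
  factors <- tgt / stat
  out <- sweep(x, 2L, factors, "*")
  attr(out, "scale_factors") <- factors
  out
}

#' Quantile normalization of replicate arrays
#'
#' Forces every replicate onto the common reference distribution (the
#' across-replicate mean of sorted columns) while preserving
#' within-replicate ranks. Tied values receive the mean of the reference
#' quantiles they span, so ties stay tied.
#'
#' @param x Numeric probes x replicates matrix.
#' @return Matrix of the same shape.
#' @export
quantile_normalize <- function(x) {
  .check_intensity_matrix(x, min_rep = 2L)
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Median collapse across replicates
#'
#' Per-probe median of the replicate values; with an even replicate
#' count the mean of the two middle values is used (the usual sample
#' median convention).
#'
#' @param x Numeric probes x replicates matrix.
#' @return Named numeric vector, one value per probe.
#' @export
median_collapse <- function(x) {
  .check_intensity_matrix(x, min_rep = 1L)
  out <- if (ncol(x) == 3L) {
    # vectorized median-of-three; apply() is needlessly slow at array scale
    pmax(pmin(x[, 1L], x[, 2L]), pmin(pmax(x[, 1L], x[, 2L]), x[, 3L]))
  } else if (ncol(x) == 1L) {
    x[, 1L]
  } else {
    apply(x, 1L, stats::median)
  }
  names(out) <- rownames(x)
  out
}

#' Full normalization pipeline
#'
#' Global scaling, then quantile normalization, then per-probe median
#' collapse — the final normalized intensity used by every downstream
#' analysis. The global stage uses a unit-median target by default, so
#' the final intensities are expressed in units of the array median and
#' the whole pipeline is exactly invariant to rescaling any replicate
#' (a mean-of-medians target would drift with the rescaled replicate).
#'
#' @param x Numeric probes x replicates matrix (raw intensities).
#' @param global_method Passed to [global_normalize()].
#' @param global_target Passed to [global_normalize()] as `target`.
#' @return List with `normalized` (named vector), `stages` (list of the
#'   intermediate matrices) and `scale_factors`.
#' @export
normalize_snap <- function(x, global_method = "median", global_target = 1) {
  g <- global_normalize(x, method = global_method, target = global_target)
  q <- quantile_normalize(g)
  m <- median_collapse(q)
  list(normalized = m,
       stages = list(raw = x, global = g, quantile = q),
       scale_factors = attr(g, "scale_factors"))
}
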