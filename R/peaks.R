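#' Select DSB-independent RPA reference peaks by coverage slicing
#'
#' Thresholds the strand-summed coverage at `peak_multiplier` times the
#' genome-wide median (zeros included) and returns maximal runs of
#' positions at or above the threshold, implemented with
#' `IRanges::slice()` on run-length-encoded coverage. Runs with widths
#' outside `peak_width_bounds` are discarded, as are runs intersecting
#' the exclusion window around the DSB (reference peaks must be
#' DSB-independent).
#'
#' @param cov A `strand_coverage`.
#' @param cfg A [quant_config()] (threshold multiplier, width bounds,
#'   DSB exclusion window).
#' @param exclude Exclusion interval as
#'   `list(chrom =, start =, end = )` (0-based half-open), or `NULL` to
#'   derive it from the config's DSB locus, or `NA` to disable.
#' @return A `peak_set`: data.frame `chrom`, `start`, `end` (0-based
#'   half-open) with attribute `threshold`.
#' @export
slice_reference_peaks <- function(cov, cfg, exclude = NULL) {
  stopifnot(inherits(cov, "strand_coverage"), inherits(cfg, "quant_config"))
  summed <- lapply(names(cov$chrom_sizes), function(chr) summed_strands(cov, chr))
  names(summed) <- names(cov$chrom_sizes)
  med <- stats::median(unlist(summed, use.names = FALSE))
  if (med == 0)
    stop("degenerate coverage: genome-wide median is 0, threshold undefined")
  threshold <- cfg$peak_multiplier * med

  if (is.null(exclude)) {
    exclude <- list(chrom = cfg$dsb_chrom,
                    start = cfg$dsb_pos - cfg$dsb_exclusion_halfwidth,
                    end = cfg$dsb_pos + cfg$dsb_exclusion_halfwidth)
  } else if (length(exclude) == 1L && is.na(exclude)) {
    exclude <- NULL
  }

  res <- lapply(names(summed), function(chr) {
    sl <- IRanges::slice(S4Vectors::Rle(summed[[chr]]), lower = threshold,
                         rangesOnly = TRUE)
    if (length(sl) == 0L) return(NULL)
    df <- data.frame(chrom = chr,
                     start = IRanges::start(sl) - 1,  # to 0-based half-open
                     end = IRanges::end(sl))
    w <- df$end - df$start
    df <- df[w >= cfg$peak_width_bounds[1] & w <= cfg$peak_width_bounds[2], ,
             drop = FALSE]
    if (!is.null(exclude) && chr == exclude$chrom)
      df <- df[df$end <= exclude$start | df$start >= exclude$end, , drop = FALSE]
    df
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(chrom = character(), start = numeric(),
                                      end = numeric())
  rownames(out) <- NULL
  structure(out, threshold = threshold, class = c("peak_set", "data.frame"))
}

peaks_to_iranges <- function(peaks, chr) {
  p <- peaks[peaks$chrom == chr, , drop = FALSE]
  IRanges::IRanges(start = p$start + 1, end = p$end)
}

#' Retain anchor peaks present in every sample
#'
#' Implements the "overlapping between different samples and replicates"
#' retention rule: peaks of the first (anchor) set are kept when they
#' overlap, by at least 1 bp, a peak in every other set.
#'
#' @param peaksets Non-empty list of `peak_set` objects; the first is
#'   the anchor (typically peaks of the pooled coverage, see
#'   [reference_peaks()]).
#' @return A `peak_set` (subset of the anchor).
#' @export
intersect_across_samples <- function(peaksets) {
  if (!is.list(peaksets) || length(peaksets) == 0L)
    stop("'peaksets' must be a non-empty list")
  anchor <- peaksets[[1]]
  if (length(peaksets) == 1L) return(anchor)
  keep <- rep(TRUE, nrow(anchor))
  for (chr in unique(anchor$chrom)) {
    sel <- anchor$chrom == chr
    a <- peaks_to_iranges(anchor, chr)
    for (other in peaksets[-1]) {
      o <- peaks_to_iranges(other, chr)
      keep[sel] <- keep[sel] & (IRanges::countOverlaps(a, o) > 0)
    }
  }
  out <- anchor[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, threshold = attr(anchor, "threshold"),
            class = c("peak_set", "data.frame"))
}

#' Reference peaks shared across samples
#'
#' Convenience wrapper implementing the full retention rule: the anchor
#' peaks are sliced from the pooled (position-wise summed) coverage of
#' all samples, and anchor peaks overlapping a peak of every individual
#' sample are retained.
#'
#' @param covs Non-empty list of `strand_coverage` objects on the same
#'   genome.
#' @param cfg A [quant_config()].
#' @param exclude Passed to [slice_reference_peaks()].
#' @return A `peak_set`.
#' @export
reference_peaks <- function(covs, cfg, exclude = NULL) {
  if (!is.list(covs) || length(covs) == 0L) stop("'covs' must be a non-empty list")
  pooled <- covs[[1]]
  if (length(covs) > 1L) {
    for (cv in covs[-1]) {
      if (!same_genome(pooled, cv)) stop("genome mismatch between samples")
      for (chr in names(pooled$chrom_sizes)) {
        pooled$data[[chr]]$fwd <- pooled$data[[chr]]$fwd + cv$data[[chr]]$fwd
        pooled$data[[chr]]$rev <- pooled$data[[chr]]$rev + cv$data[[chr]]$rev
      }
    }
  }
  sets <- c(list(slice_reference_peaks(pooled, cfg, exclude)),
            lapply(covs, slice_reference_peaks, cfg = cfg, exclude = exclude))
  intersect_across_samples(sets)
}

#' Normalize RPA coverage to DSB-independent reference peaks
#'
#' Computes a per-sample scale factor — the mean strand-summed coverage
#' over all positions inside the reference peaks — and divides both
#' strands by it, making RPA enrichment at the DSB comparable between
#' samples and replicates.
#'
#' @param cov A `strand_coverage`.
#' @param refpeaks A non-empty `peak_set`.
#' @return List: `track` (a `strand_coverage` of kind `"normalized"`)
#'   and `scale_factor`.
#' @export
rpa_normalize <- function(cov, refpeaks) {
  stopifnot(inherits(cov, "strand_coverage"))
  if (!is.data.frame(refpeaks) || nrow(refpeaks) == 0L)
    stop("reference peak set is empty; cannot normalize")
  tot <- 0; npos <- 0
  for (i in seq_len(nrow(refpeaks))) {
    chr <- refpeaks$chrom[i]
    if (!chr %in% names(cov$chrom_sizes)) stop("peak on unknown chromosome")
    idx <- (refpeaks$start[i] + 1):refpeaks$end[i]
    tot <- tot + sum(summed_strands(cov, chr)[idx])
    npos <- npos + length(idx)
  }
  scale_factor <- tot / npos
  if (scale_factor <= 0) stop("zero coverage inside reference peaks")
  data <- lapply(cov$data, function(d)
    list(fwd = d$fwd / scale_factor, rev = d$rev / scale_factor))
  list(track = strand_coverage(data, cov$chrom_sizes, kind = "normalized"),
       scale_factor = scale_factor)
}
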