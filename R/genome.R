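#' Genome specification with a DSB locus
#'
#' Describes a (small, synthetic) genome: chromosome names and lengths, the
#' position of the site-specific double-strand break (DSB), and optional
#' DSB-independent background peaks used as internal normalization
#' references for RPA-ChIP tracks.
#'
#' Coordinates are 0-based and half-open throughout the package. `dsb_pos`
#' is the coordinate of the break point between two bases: the right-hand
#' broken fragment starts at position `dsb_pos`, the left-hand fragment ends
#' at `dsb_pos - 1`.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp),
#'   all positive, names unique.
#' @param dsb_chrom Name of the chromosome carrying the DSB.
#' @param dsb_pos 0-based break coordinate, strictly inside the chromosome.
#' @param background_peaks Optional data.frame with columns `chrom`,
#'   `center` (bp), `width` (bp, in \[50, 2000\]) and `amplitude`
#'   (fold over the baseline ChIP coverage, > 1). These model ssDNA-prone
#'   loci bound by RPA independently of the DSB.
#' @return An object of class `genome_spec`.
#' @examples
#' gs <- genome_spec(c(chrV = 200000L), "chrV", 100000)
#' @export
genome_spec <- function(chrom_sizes, dsb_chrom, dsb_pos, background_peaks = NULL) {
  chrom_sizes <- as_chrom_sizes(chrom_sizes)
  if (!is.character(dsb_chrom) || length(dsb_chrom) != 1L || !dsb_chrom %in% names(chrom_sizes))
    stop("'dsb_chrom' must name one chromosome in 'chrom_sizes'")
  dsb_pos <- as.numeric(dsb_pos)
  if (length(dsb_pos) != 1L || is.na(dsb_pos) ||
      dsb_pos <= 0 || dsb_pos >= chrom_sizes[[dsb_chrom]])
    stop("'dsb_pos' must satisfy 0 < dsb_pos < length(dsb_chrom)")
  if (!is.null(background_peaks)) {
    background_peaks <- as.data.frame(background_peaks)
    req <- c("chrom", "center", "width", "amplitude")
    if (!all(req %in% names(background_peaks)))
      stop("'background_peaks' needs columns: ", paste(req, collapse = ", "))
    if (!all(background_peaks$chrom %in% names(chrom_sizes)))
      stop("background peak on unknown chromosome")
    if (any(background_peaks$width < 50 | background_peaks$width > 2000))
      stop("background peak widths must lie in [50, 2000] bp")
    if (any(background_peaks$amplitude <= 1))
      stop("background peak amplitudes must exceed 1 (fold over baseline)")
    lens <- chrom_sizes[background_peaks$chrom]
    lo <- background_peaks$center - floor(background_peaks$width / 2)
    hi <- lo + background_peaks$width
    if (any(lo < 0 | hi > lens))
      stop("background peak exceeds chromosome bounds")
  }
  structure(
    list(chrom_sizes = chrom_sizes, dsb_chrom = dsb_chrom, dsb_pos = dsb_pos,
         background_peaks = background_peaks),
    class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("genome_spec:", length(x$chrom_sizes), "chromosome(s),",
      sum(x$chrom_sizes), "bp total\n")
  cat("  DSB at", x$dsb_chrom, ":", format(x$dsb_pos, big.mark = ","), "\n")
  np <- if (is.null(x$background_peaks)) 0L else nrow(x$background_peaks)
  cat(" ", np, "background peak(s)\n")
  invisible(x)
}

#' Coerce to a validated chromosome-size vector
#'
#' @param x A named numeric vector of lengths, or a `genome_spec`.
#' @return Named numeric vector of positive chromosome lengths.
#' @keywords internal
#' @export
as_chrom_sizes <- function(x) {
  if (inherits(x, "genome_spec")) return(x$chrom_sizes)
  if (is.null(names(x)) || any(names(x) == "") || anyDuplicated(names(x)))
    stop("chromosome sizes must be a named vector with unique names")
  x <- stats::setNames(as.numeric(x), names(x))
  if (any(is.na(x)) || any(x <= 0) || any(x != floor(x)))
    stop("chromosome lengths must be positive integers")
  x
}
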