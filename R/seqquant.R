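#' Quantification configuration
#'
#' Window, bin, threshold and filter settings for the strand-specific
#' quantification. Defaults follow the published analysis: a 20-kb
#' window around the DSB divided in 2-kb bins for total-DNA ratios;
#' reference-peak selection at 6x the genome-wide median coverage with
#' peak widths restricted to 100-500 bp; RPA profiles over 25-kb windows
#' on both sides of the DSB.
#'
#' @param dsb_chrom,dsb_pos DSB locus (0-based break coordinate).
#' @param total_halfwidth Half-width (bp) of the total-DNA window
#'   (default 10000, i.e. a 20-kb window).
#' @param total_binwidth Bin width (bp) for the total-DNA window
#'   (default 2000); must divide the half-width so bins align with the
#'   DSB.
#' @param rpa_halfwidth Half-width (bp) of the RPA profile window
#'   (default 25000).
#' @param rpa_binwidth Bin width (bp) for RPA profiles (default 500; the
#'   published curves are near base-resolution, binning exists for
#'   stable small-scale summaries).
#' @param peak_multiplier Reference-peak threshold as a multiple of the
#'   genome-wide median coverage (default 6).
#' @param peak_width_bounds Retained peak widths, bp (default
#'   `c(100, 500)`).
#' @param dsb_exclusion_halfwidth Peaks within this distance of the DSB
#'   are never used as references (default 50000), so DSB-proximal
#'   signal cannot normalize itself.
#' @param min_score Optional minimum read score (set 30 to emulate a
#'   MAPQ > 30 filter); `NULL` disables filtering.
#' @return An object of class `quant_config`.
#' @export
quant_config <- function(dsb_chrom, dsb_pos,
                         total_halfwidth = 10000, total_binwidth = 2000,
                         rpa_halfwidth = 25000, rpa_binwidth = 500,
                         peak_multiplier = 6, peak_width_bounds = c(100, 500),
                         dsb_exclusion_halfwidth = 50000, min_score = NULL) {
  total_halfwidth <- check_count(total_halfwidth, "total_halfwidth", 1)
  total_binwidth <- check_count(total_binwidth, "total_binwidth", 1)
  rpa_halfwidth <- check_count(rpa_halfwidth, "rpa_halfwidth", 1)
  rpa_binwidth <- check_count(rpa_binwidth, "rpa_binwidth", 1)
  if (total_halfwidth %% total_binwidth != 0 || rpa_halfwidth %% rpa_binwidth != 0)
    stop("bin width must divide the window half-width")
  if (length(peak_width_bounds) != 2L || peak_width_bounds[1] <= 0 ||
      peak_width_bounds[1] >= peak_width_bounds[2])
    stop("'peak_width_bounds' must be 0 < width_min < width_max")
  structure(list(
    dsb_chrom = dsb_chrom, dsb_pos = as.numeric(dsb_pos),
    total_halfwidth = total_halfwidth, total_binwidth = total_binwidth,
    rpa_halfwidth = rpa_halfwidth, rpa_binwidth = rpa_binwidth,
    peak_multiplier = check_number(peak_multiplier, "peak_multiplier", 0, strict_min = TRUE),
    peak_width_bounds = as.numeric(peak_width_bounds),
    dsb_exclusion_halfwidth = check_number(dsb_exclusion_halfwidth, "dsb_exclusion_halfwidth", 0),
    min_score = min_score
  ), class = "quant_config")
}

#' Subsample read sets to a common sequencing depth
#'
#' Draws, from every sample, exactly `min(sample sizes)` reads uniformly
#' without replacement, so all samples enter the coverage comparison at
#' equal depth. Outputs are row-subsets of the inputs (original order
#' kept) and are reproducible for a given seed.
#'
#' @param samples Named (or unnamed) list of read data.frames.
#' @param seed Optional integer seed.
#' @return List of read data.frames, each with `min(sizes)` rows.
#' @export
subsample_to_common_depth <- function(samples, seed = NULL) {
  if (!is.list(samples) || length(samples) == 0L)
    stop("'samples' must be a non-empty list of read sets")
  sizes <- vapply(samples, nrow, integer(1))
  if (any(sizes == 0L)) {
    nm <- names(samples)
    lab <- if (!is.null(nm) && nzchar(nm[which(sizes == 0L)[1]]))
      nm[which(sizes == 0L)[1]] else sprintf("#%d", which(sizes == 0L)[1])
    stop(sprintf("sample '%s' has no reads; cannot subsample", lab))
  }
  target <- min(sizes)
  with_seed(seed, lapply(samples, function(s) {
    if (nrow(s) == target) return(s)
    s[sort(sample.int(nrow(s), target)), , drop = FALSE]
  }))
}

#' Bin a ratio or normalized track around the DSB
#'
#' Tiles the window `[dsb_pos - halfwidth, dsb_pos + halfwidth)` with
#' fixed-width bins (left to right) and averages the track's unmasked
#' positions per bin and strand. Bins whose positions are all masked are
#' reported masked.
#'
#' @param track A `strand_coverage` (typically of kind `"ratio"` or
#'   `"normalized"`).
#' @param cfg A [quant_config()].
#' @param halfwidth,binwidth Window geometry; default the total-DNA
#'   settings in `cfg`.
#' @return A `binned_profile` data.frame: `bin_start`, `bin_end`
#'   (bp relative to the DSB), `strand` (`"fwd"`/`"rev"`), `value`,
#'   `masked`.
#' @export
bin_dsb_window <- function(track, cfg, halfwidth = cfg$total_halfwidth,
                           binwidth = cfg$total_binwidth) {
  stopifnot(inherits(track, "strand_coverage"), inherits(cfg, "quant_config"))
  L <- track$chrom_sizes[[cfg$dsb_chrom]]
  if (is.null(L)) stop("DSB chromosome absent from track")
  lo <- cfg$dsb_pos - halfwidth
  hi <- cfg$dsb_pos + halfwidth
  if (lo < 0 || hi > L)
    stop("DSB window exceeds chromosome bounds")
  edges <- seq(-halfwidth, halfwidth, by = binwidth)
  n_bins <- length(edges) - 1L
  out <- lapply(c("fwd", "rev"), function(s) {
    v <- track$data[[cfg$dsb_chrom]][[s]][(lo + 1):hi]
    grp <- rep(seq_len(n_bins), each = binwidth)
    means <- tapply(v, grp, function(x) mean(x, na.rm = TRUE))
    means[is.nan(means)] <- NA_real_
    data.frame(bin_start = edges[-length(edges)], bin_end = edges[-1],
               strand = s, value = as.numeric(means),
               masked = is.na(as.numeric(means)))
  })
  structure(do.call(rbind, out),
            dsb_chrom = cfg$dsb_chrom, dsb_pos = cfg$dsb_pos,
            class = c("binned_profile", "data.frame"))
}

#' RPA enrichment profile over the wide DSB window
#'
#' [bin_dsb_window()] with the RPA window geometry (default +/- 25 kb,
#' 500-bp bins), intended for peak-normalized RPA tracks.
#'
#' @inheritParams bin_dsb_window
#' @return A `binned_profile`.
#' @export
rpa_window_profile <- function(track, cfg) {
  bin_dsb_window(track, cfg, halfwidth = cfg$rpa_halfwidth,
                 binwidth = cfg$rpa_binwidth)
}

#' Resection-front distance from a total-DNA ratio profile
#'
#' Scans the degraded strand's bins outward from the DSB (forward strand
#' on the right side, reverse strand on the left) and returns the first
#' distance at which the linearly interpolated ratio crosses 0.5 — a
#' robust summary of how far half the population has resected. Returns
#' `NA` when the ratio never drops below 0.5 (no detectable loss) or
#' never recovers within the window.
#'
#' @param profile A `binned_profile` from a total-DNA ratio track.
#' @param side `"right"` or `"left"` of the DSB.
#' @return Distance in bp from the DSB, or `NA_real_`.
#' @export
estimate_resection_front <- function(profile, side = c("right", "left")) {
  side <- match.arg(side)
  stopifnot(inherits(profile, "binned_profile"))
  strand <- if (side == "right") "fwd" else "rev"
  p <- profile[profile$strand == strand, , drop = FALSE]
  if (side == "right") {
    p <- p[p$bin_start >= 0, , drop = FALSE]
    p <- p[order(p$bin_start), , drop = FALSE]
  } else {
    p <- p[p$bin_end <= 0, , drop = FALSE]
    p <- p[order(-p$bin_end), , drop = FALSE]
  }
  if (nrow(p) == 0L || all(p$masked)) stop("profile fully masked on this side")
  d <- abs((p$bin_start + p$bin_end) / 2)
  v <- p$value
  keep <- !is.na(v)
  d <- d[keep]; v <- v[keep]
  if (v[1] >= 0.5) return(NA_real_)
  above <- which(v >= 0.5)
  if (length(above) == 0L) return(NA_real_)
  j <- above[1]
  d[j - 1] + (0.5 - v[j - 1]) / (v[j] - v[j - 1]) * (d[j] - d[j - 1])
}
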