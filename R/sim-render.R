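#' Sequencing-library parameters for the coverage renderers
#'
#' The renderers turn a simulated population into per-base expected
#' fragment depth and optionally Poisson-sample it; explicit read-pair
#' simulation is deliberately not modeled because the quantification
#' consumes coverage, not alignments. `fragment_length_range` documents
#' the emulated library (sonicated chromatin fragments of roughly
#' 200-500 bp) but does not enter the per-base model.
#'
#' @param mean_depth Mean fragments per base (> 0) for total-DNA renders.
#' @param fragment_length_range Length-2 numeric, within \[1, 10000\] bp.
#' @param chip_alpha ChIP enrichment: fold-signal of a position that is
#'   RPA-coated ssDNA in every cell, over baseline (> 0).
#' @param chip_beta Baseline ChIP coverage level (>= 0).
#' @param noise `"poisson"` (counts drawn per base) or `"none"`
#'   (expected depth returned exactly).
#' @param seed Default seed used by the renderers when they are not given
#'   one explicitly.
#' @return An object of class `library_params`.
#' @export
library_params <- function(mean_depth, fragment_length_range = c(200, 500),
                           chip_alpha = 25, chip_beta = 2,
                           noise = c("poisson", "none"), seed = NULL) {
  noise <- match.arg(noise)
  if (length(fragment_length_range) != 2L ||
      any(fragment_length_range < 1 | fragment_length_range > 10000) ||
      fragment_length_range[1] > fragment_length_range[2])
    stop("'fragment_length_range' must be an increasing pair within [1, 10000]")
  structure(list(
    mean_depth = check_number(mean_depth, "mean_depth", 0, strict_min = TRUE),
    fragment_length_range = as.numeric(fragment_length_range),
    chip_alpha = check_number(chip_alpha, "chip_alpha", 0, strict_min = TRUE),
    chip_beta = check_number(chip_beta, "chip_beta", 0),
    noise = noise, seed = seed
  ), class = "library_params")
}

# Strand geometry, stated once and used everywhere (0-based, half-open;
# forward = reference strand read 5'->3' with increasing coordinate):
# at a DSB at x0, the right fragment's 5'-terminated strand is the
# forward strand, so 5'->3' resection degrades the FORWARD strand over
# [x0, x0 + right_extent); on the left fragment it degrades the REVERSE
# strand over [x0 - left_extent, x0). The persisting 3' ssDNA — what RPA
# binds — is therefore reverse-strand right of x0 and forward-strand
# left of x0.
#
# Returns, for the DSB chromosome, the per-position fraction of cells in
# which the position is inside a resection tract, split by side.
resected_fraction_tracks <- function(truth, genome) {
  L <- genome$chrom_sizes[[genome$dsb_chrom]]
  x0 <- genome$dsb_pos
  right_d <- seq_len(L - x0) - 1          # distances 0..L-x0-1 for p >= x0
  left_d <- rev(seq_len(x0)) - 1          # distances x0-1..0 for p = 0..x0-1
  list(
    right = resection_survival(truth, right_d, "right"),  # p = x0 .. L-1
    left = resection_survival(truth, left_d, "left")      # p = 0 .. x0-1
  )
}

maybe_poisson <- function(lambda, noise) {
  if (noise == "poisson") as.numeric(stats::rpois(length(lambda), lambda)) else lambda
}

#' Render strand-specific total-DNA sequencing coverage
#'
#' Converts a simulated population into the total-DNA readout: the
#' 5'-terminated strand is degraded by resection, so expected
#' forward-strand coverage at a position right of the DSB is
#' `mean_depth` times the fraction of cells not resected past it (mirror
#' statement for the reverse strand left of the DSB). The persisting 3'
#' strand keeps full expected coverage inside resected zones. With
#' `noise = "poisson"` each base is an independent Poisson draw.
#'
#' @param truth A `resection_truth` from [simulate_population()].
#' @param genome The [genome_spec()] the truth was generated on.
#' @param lib A [library_params()].
#' @param seed Optional seed overriding `lib$seed`.
#' @return A `strand_coverage` of raw counts (or expected depth when
#'   `noise = "none"`).
#' @export
render_total_dna <- function(truth, genome, lib, seed = lib$seed) {
  stopifnot(inherits(truth, "resection_truth"), inherits(genome, "genome_spec"),
            inherits(lib, "library_params"))
  frac <- resected_fraction_tracks(truth, genome)
  with_seed(seed, {
    data <- lapply(names(genome$chrom_sizes), function(chr) {
      L <- genome$chrom_sizes[[chr]]
      fwd <- rep(lib$mean_depth, L)
      rev <- rep(lib$mean_depth, L)
      if (chr == genome$dsb_chrom) {
        x0 <- genome$dsb_pos
        if (x0 < L) fwd[(x0 + 1):L] <- lib$mean_depth * (1 - frac$right)
        if (x0 >= 1) rev[1:x0] <- lib$mean_depth * (1 - frac$left)
      }
      list(fwd = maybe_poisson(fwd, lib$noise), rev = maybe_poisson(rev, lib$noise))
    })
    names(data) <- names(genome$chrom_sizes)
    strand_coverage(data, genome$chrom_sizes)
  })
}

#' Render strand-specific RPA-ChIP sequencing coverage
#'
#' The RPA readout: expected coverage is
#' `chip_beta + chip_alpha * occ(p, strand)` where `occ` is the fraction
#' of cells in which the position is RPA-coated 3' ssDNA — reverse strand
#' right of the DSB, forward strand left of it. DSB-independent
#' background peaks from the [genome_spec()] contribute
#' `chip_beta * (amplitude - 1)` on both strands over their footprint,
#' emulating the unspecific RPA peaks used as normalization references.
#'
#' @inheritParams render_total_dna
#' @return A `strand_coverage`.
#' @export
render_rpa_chip <- function(truth, genome, lib, seed = lib$seed) {
  stopifnot(inherits(truth, "resection_truth"), inherits(genome, "genome_spec"),
            inherits(lib, "library_params"))
  frac <- resected_fraction_tracks(truth, genome)
  with_seed(seed, {
    data <- lapply(names(genome$chrom_sizes), function(chr) {
      L <- genome$chrom_sizes[[chr]]
      fwd <- rep(lib$chip_beta, L)
      rev <- rep(lib$chip_beta, L)
      if (chr == genome$dsb_chrom) {
        x0 <- genome$dsb_pos
        if (x0 < L) rev[(x0 + 1):L] <- lib$chip_beta + lib$chip_alpha * frac$right
        if (x0 >= 1) fwd[1:x0] <- lib$chip_beta + lib$chip_alpha * frac$left
      }
      pk <- genome$background_peaks
      if (!is.null(pk)) {
        pk <- pk[pk$chrom == chr, , drop = FALSE]
        for (i in seq_len(nrow(pk))) {
          lo <- pk$center[i] - floor(pk$width[i] / 2)
          idx <- (lo + 1):(lo + pk$width[i])
          bump <- lib$chip_beta * (pk$amplitude[i] - 1)
          fwd[idx] <- fwd[idx] + bump
          rev[idx] <- rev[idx] + bump
        }
      }
      list(fwd = maybe_poisson(fwd, lib$noise), rev = maybe_poisson(rev, lib$noise))
    })
    names(data) <- names(genome$chrom_sizes)
    strand_coverage(data, genome$chrom_sizes)
  })
}
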