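#' Total-DNA resection quantification
#'
#' The published total-DNA analysis in one call: divide the induced
#' sample's coverage by the uninduced sample, bin the window around the
#' DSB, and summarize the resection front on each side.
#'
#' @param cov_t `strand_coverage` after induction.
#' @param cov_t0 `strand_coverage` of the uninduced sample.
#' @param cfg A [quant_config()].
#' @return List: `profile` (a `binned_profile` of ratios), `front`
#'   (named numeric, `left`/`right` distances in bp, `NA` when no
#'   crossing).
#' @export
quantify_total_dna <- function(cov_t, cov_t0, cfg) {
  ratio <- t0_ratio(cov_t, cov_t0)
  profile <- bin_dsb_window(ratio, cfg)
  front <- c(left = estimate_resection_front(profile, "left"),
             right = estimate_resection_front(profile, "right"))
  list(profile = profile, front = front)
}

#' Peak-normalized RPA enrichment quantification
#'
#' Selects DSB-independent reference peaks shared across the provided
#' samples ([reference_peaks()]), normalizes each sample's coverage to
#' its mean reference-peak coverage, and bins the wide window around the
#' DSB.
#'
#' @param covs Named list of RPA `strand_coverage` samples (all used for
#'   peak selection).
#' @param cfg A [quant_config()].
#' @param refpeaks Optional precomputed `peak_set`; computed from `covs`
#'   when `NULL`.
#' @return List: `profiles` (named list of `binned_profile`),
#'   `scale_factors` (named numeric), `peaks` (the `peak_set` used).
#' @export
quantify_rpa <- function(covs, cfg, refpeaks = NULL) {
  if (!is.list(covs) || length(covs) == 0L) stop("'covs' must be a non-empty list")
  if (is.null(names(covs))) names(covs) <- paste0("sample", seq_along(covs))
  if (is.null(refpeaks)) refpeaks <- reference_peaks(covs, cfg)
  norm <- lapply(covs, rpa_normalize, refpeaks = refpeaks)
  list(profiles = lapply(norm, function(x) rpa_window_profile(x$track, cfg)),
       scale_factors = vapply(norm, `[[`, numeric(1), "scale_factor"),
       peaks = refpeaks)
}

#' Summed RPA enrichment over a window right or left of the DSB
#'
#' Sum of the ssDNA-reporting strand's bin values over `0..window` bp
#' from the DSB (reverse strand on the right side, forward on the left),
#' the discrimination statistic used to compare conditions.
#'
#' @param profile A `binned_profile` of a normalized RPA track.
#' @param side `"right"` or `"left"`.
#' @param window Distance from the DSB (bp) to sum over.
#' @return Numeric scalar.
#' @export
rpa_signal_sum <- function(profile, side = c("right", "left"), window = 15000) {
  side <- match.arg(side)
  strand <- if (side == "right") "rev" else "fwd"
  if (side == "right") {
    sel <- profile$strand == strand & profile$bin_start >= 0 & profile$bin_end <= window
  } else {
    sel <- profile$strand == strand & profile$bin_end <= 0 & profile$bin_start >= -window
  }
  sum(profile$value[sel], na.rm = TRUE)
}

#' End-to-end demonstration on synthetic data
#'
#' Simulates a resecting population on a small genome, renders
#' total-DNA and RPA-ChIP tracks at two time points, runs the full
#' quantification, and estimates a recombination rate from a simulated
#' fluctuation assay. Used by the `demo` CLI subcommand; finishes in
#' seconds.
#'
#' @param outdir Optional directory for the standard output files
#'   (tracks, profiles, peaks, truth, rates); no files written when
#'   `NULL`.
#' @param seed Integer seed driving every stochastic stage.
#' @return List with elements `truth`, `fronts`, `rpa`, `ssdna`,
#'   `fluctuation`.
#' @export
run_demo <- function(outdir = NULL, seed = 1) {
  genome <- demo_genome()
  model <- resection_model(cut_efficiency = 0.9, speed_mean = 4000, speed_cv = 0.3)
  lib <- library_params(mean_depth = 50, noise = "poisson")
  cfg <- quant_config(genome$dsb_chrom, genome$dsb_pos,
                      total_halfwidth = 24000, total_binwidth = 2000,
                      dsb_exclusion_halfwidth = 40000)

  truth <- list(`2h` = simulate_population(genome, model, 2, 2000, seed = seed),
                `4h` = simulate_population(genome, model, 4, 2000, seed = seed + 1))
  t0_truth <- simulate_population(genome, model, 0, 2000, seed = seed + 2)
  cov_t0 <- render_total_dna(t0_truth, genome, lib, seed = seed + 3)
  fronts <- lapply(seq_along(truth), function(i) {
    cov_t <- render_total_dna(truth[[i]], genome, lib, seed = seed + 3 + i)
    quantify_total_dna(cov_t, cov_t0, cfg)
  })
  names(fronts) <- names(truth)

  rpa_cov <- lapply(seq_along(truth), function(i)
    render_rpa_chip(truth[[i]], genome, lib, seed = seed + 10 + i))
  names(rpa_cov) <- names(truth)
  rpa <- quantify_rpa(rpa_cov, cfg)

  qp <- qpcr_sim_params(site_offsets = c(-120, 98, 640, 2500, 5000),
                        ct_noise_sd = 0.1, seed = seed + 20)
  ctab <- simulate_qpcr_resection(truth[["2h"]], genome, qp)
  ssdna <- lapply(qp$site_offsets, function(off)
    ssdna_fraction(ctab, sprintf("site_%+d", off), qp$control_locus))
  names(ssdna) <- sprintf("site_%+d", qp$site_offsets)

  counts <- simulate_fluctuation(mu = 2e-7, nt = 2^23, n_cultures = 8,
                                 seed = seed + 30)
  fit <- estimate_m(counts)
  rate <- mutation_rate(fit, nt = attr(counts, "nt"))

  out <- list(truth = truth, fronts = fronts, rpa = rpa, ssdna = ssdna,
              fluctuation = list(counts = as.numeric(counts), fit = fit, rate = rate))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_chrom_sizes(genome, file.path(outdir, "chrom.sizes"))
    write_tsv(as.data.frame(truth[["2h"]]), file.path(outdir, "truth_2h.tsv"), seed = seed)
    for (tp in names(fronts))
      write_tsv(fronts[[tp]]$profile,
                file.path(outdir, sprintf("profile_totalDNA_%s.tsv", tp)), seed = seed)
    for (tp in names(rpa$profiles))
      write_tsv(rpa$profiles[[tp]],
                file.path(outdir, sprintf("profile_rpa_%s.tsv", tp)), seed = seed)
    write_peaks_bed(rpa$peaks, file.path(outdir, "reference_peaks.bed"), seed = seed)
    write_tsv(data.frame(sample = names(rpa$scale_factors),
                         scale_factor = rpa$scale_factors),
              file.path(outdir, "scale_factors.tsv"), seed = seed)
    write_tsv(data.frame(culture = seq_along(counts), mutants = as.numeric(counts)),
              file.path(outdir, "fluctuation.tsv"), seed = seed)
    write_tsv(data.frame(m = fit$m, rate = rate$rate,
                         ci_low = rate$ci[1], ci_high = rate$ci[2]),
              file.path(outdir, "rates.tsv"), seed = seed)
  }
  out
}

# Small genome used by the demo and the acceptance checks: one 200-kb
# chromosome, central DSB, four DSB-independent RPA background peaks.
demo_genome <- function() {
  genome_spec(
    c(chrSim = 200000),
    dsb_chrom = "chrSim", dsb_pos = 100000,
    background_peaks = data.frame(
      chrom = "chrSim",
      center = c(20000, 35000, 160000, 180000),
      width = c(300, 200, 250, 300),
      amplitude = c(20, 15, 18, 25)))
}
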