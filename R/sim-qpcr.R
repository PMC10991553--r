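#' Parameters for the restriction-protection qPCR simulator
#'
#' The wet assay digests genomic DNA with a restriction enzyme whose site
#' sits at a known distance from the DSB; only templates where the site
#' has become single-stranded (resected) escape digestion and amplify.
#' The simulator counts amplifiable template strands per cell and turns
#' template fractions into Ct values.
#'
#' @param site_offsets Signed distances (bp) of the restriction sites
#'   from the DSB; negative = upstream (left), positive = downstream
#'   (right). Must be nonzero. The assayed distances in the source system
#'   are 120 bp upstream and 98 bp, 640 bp, 2.5 kb and 5 kb downstream.
#' @param control_locus Name of the undigested control amplicon.
#' @param pcr_efficiency Per-cycle amplification efficiency in (0, 1\];
#'   1 means perfect doubling.
#' @param ct_cap Cycle number reported when no template amplifies
#'   (default 40, the run length of the qPCR program).
#' @param ct_noise_sd Gaussian noise (cycles) added to each replicate.
#' @param ct_reference Ct of the undigested, unresected reference
#'   template amount (the "10 ng input" anchor).
#' @param n_replicates Technical replicates per (site, tube).
#' @param seed Default seed for [simulate_qpcr_resection()].
#' @return An object of class `qpcr_sim_params`.
#' @export
qpcr_sim_params <- function(site_offsets, control_locus = "control",
                            pcr_efficiency = 1, ct_cap = 40,
                            ct_noise_sd = 0, ct_reference = 15,
                            n_replicates = 3, seed = NULL) {
  site_offsets <- as.numeric(site_offsets)
  if (length(site_offsets) == 0L || any(site_offsets == 0) || anyDuplicated(site_offsets))
    stop("'site_offsets' must be nonzero, distinct, signed distances in bp")
  structure(list(
    site_offsets = site_offsets, control_locus = control_locus,
    pcr_efficiency = check_number(pcr_efficiency, "pcr_efficiency", 0, 1, strict_min = TRUE),
    ct_cap = check_number(ct_cap, "ct_cap", 0, strict_min = TRUE),
    ct_noise_sd = check_number(ct_noise_sd, "ct_noise_sd", 0),
    ct_reference = check_number(ct_reference, "ct_reference", 0, strict_min = TRUE),
    n_replicates = check_count(n_replicates, "n_replicates", 1),
    seed = seed
  ), class = "qpcr_sim_params")
}

ct_from_fraction <- function(template_fraction, params) {
  params$ct_reference - log2(template_fraction) / log2(1 + params$pcr_efficiency)
}

#' Simulate a restriction-protection qPCR resection experiment
#'
#' For each restriction site, `f` is the fraction of cells whose tract on
#' the relevant side extends past the site. Template strands per cell:
#' undigested tube, 2 for an unresected locus and 1 for a resected one
#' (the 5' strand is gone); digested tube, only resected loci survive
#' with their 1 remaining strand. Ct values follow
#' `ct_reference - log2(template_fraction)/log2(1 + efficiency)` plus
#' Gaussian noise; a site with `f = 0` reports `ct_cap` in the digested
#' tube (no amplification). The control locus has no restriction site and
#' is never degraded.
#'
#' @param truth A `resection_truth`.
#' @param genome The matching [genome_spec()]; sites must fall inside the
#'   DSB chromosome.
#' @param params A [qpcr_sim_params()].
#' @param sample Sample label written to the table.
#' @param seed Optional seed overriding `params$seed`.
#' @return A `ct_table` data.frame with columns `sample`, `target`,
#'   `tube`, `replicate`, `ct` and attribute `ct_cap`. Site targets are
#'   named `site_<offset>` with the signed offset in bp.
#' @export
simulate_qpcr_resection <- function(truth, genome, params, sample = "S1",
                                    seed = params$seed) {
  stopifnot(inherits(truth, "resection_truth"), inherits(genome, "genome_spec"),
            inherits(params, "qpcr_sim_params"))
  L <- genome$chrom_sizes[[genome$dsb_chrom]]
  pos <- genome$dsb_pos + params$site_offsets
  if (any(pos < 0 | pos >= L))
    stop("restriction site beyond chromosome bounds")
  with_seed(seed, {
    rows <- list()
    for (off in params$site_offsets) {
      side <- if (off > 0) "right" else "left"
      f <- resection_survival(truth, abs(off), side)
      target <- sprintf("site_%+d", off)
      # template fraction relative to the 2-strands-per-cell reference
      frac_undig <- (2 - f) / 2
      frac_dig <- f / 2
      ct_undig <- ct_from_fraction(frac_undig, params)
      ct_dig <- if (f == 0) params$ct_cap else ct_from_fraction(frac_dig, params)
      rows[[target]] <- data.frame(
        sample = sample, target = target,
        tube = rep(c("undigested", "digested"), each = params$n_replicates),
        replicate = rep(seq_len(params$n_replicates), 2L),
        ct = c(noisy_ct(ct_undig, params), noisy_ct(ct_dig, params, capped = f == 0)))
    }
    rows$control <- data.frame(
      sample = sample, target = params$control_locus,
      tube = rep(c("undigested", "digested"), each = params$n_replicates),
      replicate = rep(seq_len(params$n_replicates), 2L),
      ct = noisy_ct(rep(ct_from_fraction(1, params), 2L), params))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    ct_table(out, ct_cap = params$ct_cap)
  })
}

noisy_ct <- function(ct, params, capped = FALSE) {
  ct <- rep(ct, each = params$n_replicates)
  if (!capped && params$ct_noise_sd > 0)
    ct <- ct + stats::rnorm(length(ct), 0, params$ct_noise_sd)
  pmin(ct, params$ct_cap)
}

#' Simulate the HO-cutting qPCR readout
#'
#' Generates undigested-tube Ct values for an amplicon spanning the HO
#' cut site (template lost in cut cells) and a control amplicon, before
#' (`t0`) and after (`t`) induction, from a known cut fraction.
#'
#' @param cut_fraction_true True fraction of cut cells in \[0, 1\].
#' @param params A [qpcr_sim_params()] (only the Ct model fields are
#'   used).
#' @param hocut_target,samples Labels for the cut-site amplicon and the
#'   two samples.
#' @param seed Optional seed.
#' @return A `ct_table` with samples `t0` and `t`.
#' @export
simulate_qpcr_cut <- function(cut_fraction_true, params,
                              hocut_target = "HOcs", samples = c("t0", "t"),
                              seed = params$seed) {
  stopifnot(inherits(params, "qpcr_sim_params"))
  cf <- check_number(cut_fraction_true, "cut_fraction_true", 0, 1)
  with_seed(seed, {
    mk <- function(sample, target, frac) data.frame(
      sample = sample, target = target, tube = "undigested",
      replicate = seq_len(params$n_replicates),
      ct = noisy_ct(ct_from_fraction(frac, params), params)[seq_len(params$n_replicates)])
    out <- rbind(
      mk(samples[1], hocut_target, 1), mk(samples[1], params$control_locus, 1),
      mk(samples[2], hocut_target, 1 - cf), mk(samples[2], params$control_locus, 1))
    ct_table(out, ct_cap = params$ct_cap)
  })
}
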