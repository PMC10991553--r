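#' Validated table of qPCR threshold cycles
#'
#' @param df data.frame with columns `sample` (optional, default
#'   `"S1"`), `target`, `tube` (`"digested"`/`"undigested"`),
#'   `replicate`, `ct`. Ct values must lie in `(0, ct_cap]`.
#' @param ct_cap Cycle cap encoding "no amplification" (default 40).
#' @return The data.frame with class `ct_table` and attribute `ct_cap`.
#' @export
ct_table <- function(df, ct_cap = 40) {
  df <- as.data.frame(df)
  if (!"sample" %in% names(df)) df$sample <- "S1"
  req <- c("sample", "target", "tube", "replicate", "ct")
  if (!all(req %in% names(df)))
    stop("Ct table needs columns: ", paste(req, collapse = ", "))
  if (!all(df$tube %in% c("digested", "undigested")))
    stop("tube must be 'digested' or 'undigested'")
  if (any(is.na(df$ct) | df$ct <= 0 | df$ct > ct_cap + 1e-9))
    stop("Ct values must lie in (0, ct_cap]")
  structure(df[, req], ct_cap = ct_cap, class = c("ct_table", "data.frame"))
}

ct_mean_sd <- function(ct, target, tube, sample = NULL) {
  sel <- ct$target == target & ct$tube == tube
  if (!is.null(sample)) sel <- sel & ct$sample == sample
  x <- ct$ct[sel]
  if (length(x) == 0L)
    stop(sprintf("no Ct values for target '%s', tube '%s'%s", target, tube,
                 if (is.null(sample)) "" else sprintf(", sample '%s'", sample)))
  list(mean = mean(x), var_of_mean = stats::var(x) / length(x),
       n = length(x), all_capped = all(x >= attr(ct, "ct_cap") - 1e-9))
}

#' ssDNA fraction from a restriction-protection qPCR table
#'
#' Quantifies the fraction of molecules resected past a restriction site
#' from digested/undigested Ct values. With
#' `dCt = mean Ct(digested) - mean Ct(undigested)` for the site amplicon,
#' the same for a control amplicon lacking the site, and
#' `ddCt = dCt_site - dCt_control`, the fraction is
#'
#'   `f = 2 / (2^ddCt + 1)`
#'
#' This follows from counting amplifiable template strands at 100% PCR
#' efficiency: an unresected locus contributes 2 strands in the
#' undigested tube and 0 after digestion; a resected locus contributes
#' its 1 surviving 3' strand in both tubes. Hence the digested:undigested
#' template ratio is `r = f / (2 - f)`, `r = 2^(-ddCt)`, and inverting
#' gives `f = 2r / (1 + r) = 2 / (2^ddCt + 1)`.
#'
#' A digested-tube Ct at the cap (no amplification) reports `f = 0`.
#' Replicate scatter is propagated to `f` by the first-order delta
#' method. Optionally, `f` can be expressed per cut molecule by dividing
#' by a measured cut fraction (only cut molecules can resect); this
#' correction is off by default.
#'
#' @param ct A [ct_table()].
#' @param target Site amplicon id.
#' @param control_target Control amplicon id (no restriction site).
#' @param sample Optional sample label to subset on.
#' @param cut_fraction Optional HO cut fraction in (0, 1\] used to
#'   correct `f` for incomplete cutting.
#' @return List of class `ssdna_estimate`: `fraction`, `sd`, `ddct`,
#'   `n_replicates`.
#' @export
ssdna_fraction <- function(ct, target, control_target, sample = NULL,
                           cut_fraction = NULL) {
  stopifnot(inherits(ct, "ct_table"))
  dig <- ct_mean_sd(ct, target, "digested", sample)
  und <- ct_mean_sd(ct, target, "undigested", sample)
  cdig <- ct_mean_sd(ct, control_target, "digested", sample)
  cund <- ct_mean_sd(ct, control_target, "undigested", sample)

  if (dig$all_capped) {
    out <- list(fraction = 0, sd = 0, ddct = Inf,
                n_replicates = dig$n)
  } else {
    ddct <- (dig$mean - und$mean) - (cdig$mean - cund$mean)
    f <- 2 / (2^ddct + 1)
    var_ddct <- dig$var_of_mean + und$var_of_mean +
      cdig$var_of_mean + cund$var_of_mean
    dfdx <- -log(2) * 2^ddct * 2 / (2^ddct + 1)^2
    sd_f <- abs(dfdx) * sqrt(var_ddct)
    if (f > 1 + 1e-9 || f < -1e-9)
      stop("assay failure: ssDNA fraction outside [0, 1]")
    out <- list(fraction = min(max(f, 0), 1), sd = if (is.na(sd_f)) NA_real_ else sd_f,
                ddct = ddct, n_replicates = dig$n)
  }
  if (!is.null(cut_fraction)) {
    cut_fraction <- check_number(cut_fraction, "cut_fraction", 0, 1, strict_min = TRUE)
    corrected <- out$fraction / cut_fraction
    if (corrected > 1 + 1e-9)
      stop("assay failure: cut-corrected ssDNA fraction exceeds 1")
    out$fraction <- min(corrected, 1)
    out$sd <- out$sd / cut_fraction
  }
  structure(out, class = "ssdna_estimate")
}

#' @export
print.ssdna_estimate <- function(x, ...) {
  cat(sprintf("ssDNA fraction = %.4f (sd %.4f, %d replicates)\n",
              x$fraction, x$sd, x$n_replicates))
  invisible(x)
}

#' HO cut fraction from undigested qPCR across a cut-site amplicon
#'
#' An amplicon spanning the endonuclease cut site loses its template in
#' cut cells. Relative to the uninduced reference sample and a control
#' amplicon, the surviving-template ratio is `r = 2^(-ddCt)` and the cut
#' fraction `1 - r`, clipped to \[0, 1\].
#'
#' @param ct A [ct_table()] containing undigested Ct values for both
#'   amplicons in both samples.
#' @param hocut_target Amplicon spanning the cut site.
#' @param control_target Control amplicon.
#' @param sample Induced sample label.
#' @param t0_sample Uninduced reference sample label.
#' @return Cut fraction in \[0, 1\].
#' @export
cut_fraction <- function(ct, hocut_target, control_target,
                         sample = "t", t0_sample = "t0") {
  stopifnot(inherits(ct, "ct_table"))
  if (!t0_sample %in% ct$sample)
    stop(sprintf("t0 reference sample '%s' missing from Ct table", t0_sample))
  ho_t <- ct_mean_sd(ct, hocut_target, "undigested", sample)$mean
  ho_0 <- ct_mean_sd(ct, hocut_target, "undigested", t0_sample)$mean
  c_t <- ct_mean_sd(ct, control_target, "undigested", sample)$mean
  c_0 <- ct_mean_sd(ct, control_target, "undigested", t0_sample)$mean
  ddct <- (ho_t - ho_0) - (c_t - c_0)
  min(max(1 - 2^(-ddct), 0), 1)
}

#' Fit a qPCR calibration (standard) curve
#'
#' Least-squares fit of Ct against `log10(quantity)` over a dilution
#' series of a template of known concentration. The amplification
#' efficiency follows from the slope: `efficiency = 10^(-1/slope) - 1`,
#' equal to 1 for perfect doubling (slope -3.3219 cycles per 10-fold).
#'
#' @param quantities Template quantities (> 0), >= 3 distinct values.
#' @param cts Measured Ct values, same length.
#' @return List of class `standard_curve`: `slope`, `intercept`,
#'   `efficiency`, `r_squared`, `ct_range`.
#' @examples
#' q <- 10^(0:-4); fit <- fit_standard_curve(q, 15 - log2(q))
#' all.equal(fit$efficiency, 1)
#' @export
fit_standard_curve <- function(quantities, cts) {
  if (length(quantities) != length(cts)) stop("length mismatch")
  if (any(quantities <= 0)) stop("quantities must be positive")
  if (length(unique(quantities)) < 3L)
    stop("need >= 3 distinct quantities for a calibration curve")
  fit <- stats::lm(cts ~ log10(quantities))
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop("degenerate calibration curve: slope must be negative")
  efficiency <- 10^(-1 / slope) - 1
  if (efficiency <= 0 || efficiency > 1.2)
    stop(sprintf("implausible amplification efficiency %.3f", efficiency))
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 efficiency = efficiency,
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 ct_range = range(cts)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard curve: slope %.4f cycles/log10, efficiency %.3f, R2 %.4f\n",
              x$slope, x$efficiency, x$r_squared))
  invisible(x)
}

curve_quantity <- function(ct_value, curve) 10^((ct_value - curve$intercept) / curve$slope)

#' Relative recombination rate from the gene-conversion qPCR assay
#'
#' Converts Ct values of the recombination-specific amplicon and of a
#' control amplicon (total-DNA reference on another chromosome) into
#' quantities via their per-primer-pair calibration curves, and reports
#' their ratio. Mean Ct across replicates is used (configurable to mean
#' of quantities). Ct values outside a curve's calibrated range are
#' flagged in `warnings` but still quantified.
#'
#' @param ct A [ct_table()] with undigested Ct values for both targets.
#' @param recomb_curve,control_curve [fit_standard_curve()] fits for the
#'   recombination and control amplicons.
#' @param recomb_target,control_target Amplicon ids in `ct`.
#' @param sample Optional sample label to subset on.
#' @param average `"ct"` (mean of Ct, default) or `"quantity"`.
#' @return List of class `recombination_estimate`: `ratio`, `sd`,
#'   `q_recomb`, `q_control`, `warnings`.
#' @export
recombination_ratio <- function(ct, recomb_curve, control_curve,
                                recomb_target = "recombination",
                                control_target = "control",
                                sample = NULL, average = c("ct", "quantity")) {
  stopifnot(inherits(ct, "ct_table"),
            inherits(recomb_curve, "standard_curve"),
            inherits(control_curve, "standard_curve"))
  average <- match.arg(average)
  warnings <- character()
  one <- function(target, curve) {
    s <- ct_mean_sd(ct, target, "undigested", sample)
    sel <- ct$target == target & ct$tube == "undigested"
    if (!is.null(sample)) sel <- sel & ct$sample == sample
    vals <- ct$ct[sel]
    if (any(vals < curve$ct_range[1] - 1e-9 | vals > curve$ct_range[2] + 1e-9))
      warnings <<- c(warnings,
                     sprintf("Ct for '%s' outside calibrated range [%.2f, %.2f]",
                             target, curve$ct_range[1], curve$ct_range[2]))
    if (average == "ct") {
      q <- curve_quantity(s$mean, curve)
      # delta method: Var(log10 Q) = Var(mean Ct) / slope^2
      sd_q <- abs(q * log(10) / curve$slope) * sqrt(s$var_of_mean)
    } else {
      qs <- curve_quantity(vals, curve)
      q <- mean(qs)
      sd_q <- stats::sd(qs) / sqrt(length(qs))
    }
    list(q = q, sd = sd_q)
  }
  r <- one(recomb_target, recomb_curve)
  c_ <- one(control_target, control_curve)
  ratio <- r$q / c_$q
  sd_ratio <- ratio * sqrt((r$sd / r$q)^2 + (c_$sd / c_$q)^2)
  structure(list(ratio = ratio, sd = if (is.na(sd_ratio)) NA_real_ else sd_ratio,
                 q_recomb = r$q, q_control = c_$q, warnings = warnings),
            class = "recombination_estimate")
}

#' @export
print.recombination_estimate <- function(x, ...) {
  cat(sprintf("relative recombination rate = %.4g (sd %.3g)\n", x$ratio, x$sd))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
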