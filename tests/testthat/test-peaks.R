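test_that("slicing matches the worked threshold example", {
  summed <- c(1, 1, 1, 10, 10, 10, 1, 1, 1, 1)
  cov <- cov1(summed / 2, summed / 2, chrom = "chrT")
  cfg_wide <- quant_config("chrT", 5, peak_width_bounds = c(1, 500),
                           dsb_exclusion_halfwidth = 0)
  ps <- slice_reference_peaks(cov, cfg_wide, exclude = NA)
  expect_equal(attr(ps, "threshold"), 6)   # 6 x median(1) = 6
  expect_equal(ps$start, 3)
  expect_equal(ps$end, 6)
  # with the default 100-500 bp width bounds the 3-bp run is discarded
  cfg_def <- quant_config("chrT", 5)
  expect_equal(nrow(slice_reference_peaks(cov, cfg_def, exclude = NA)), 0L)
})

test_that("tracks below threshold yield no peaks and all-zero errors", {
  cov <- cov1(rep(1, 1000), chrom = "chrT")
  cfg <- quant_config("chrT", 500)
  expect_equal(nrow(slice_reference_peaks(cov, cfg, exclude = NA)), 0L)
  zero <- cov1(rep(0, 1000), chrom = "chrT")
  expect_error(slice_reference_peaks(zero, cfg, exclude = NA), "median")
})

test_that("the DSB exclusion window removes DSB-proximal peaks", {
  v <- rep(1, 10000)
  v[2001:2200] <- 50   # far peak
  v[5001:5200] <- 50   # DSB-proximal peak
  cov <- cov1(v / 2, v / 2, chrom = "chrT")
  cfg <- quant_config("chrT", 5100, dsb_exclusion_halfwidth = 500)
  ps <- slice_reference_peaks(cov, cfg)
  expect_equal(ps$start, 2000)
  expect_equal(ps$end, 2200)
})

test_that("slice agrees with the brute-force position scan on random tracks", {
  set.seed(202)
  for (i in 1:200) {
    n <- sample(50:2000, 1)
    v <- rpois(n, 3)
    if (runif(1) < 0.5) {
      # plant a spike so peaks exist often
      w <- sample(5:min(200, n - 10), 1)
      s <- sample(n - w, 1)
      v[s:(s + w - 1)] <- v[s:(s + w - 1)] + rpois(1, 40)
    }
    if (median(v) == 0) next
    wb <- sort(sample(1:300, 2)); if (wb[1] == wb[2]) wb[2] <- wb[2] + 1
    cfg <- quant_config("chrT", max(2, n %/% 2), peak_multiplier = 6,
                        peak_width_bounds = wb)
    cov <- cov1(v, numeric(n), chrom = "chrT")
    got <- slice_reference_peaks(cov, cfg, exclude = NA)
    want <- brute_force_peaks(v, 6 * median(v), wb)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("cross-sample retention keeps anchor peaks seen everywhere", {
  mk <- function(...) {
    d <- data.frame(...)
    structure(cbind(chrom = "chrT", d), class = c("peak_set", "data.frame"))
  }
  a <- mk(start = c(0, 1000), end = c(200, 1300))
  expect_equal(intersect_across_samples(list(a, a, a))$start, a$start)
  disjoint <- mk(start = 5000, end = 5100)
  expect_equal(nrow(intersect_across_samples(list(a, disjoint))), 0L)
  other <- mk(start = 150, end = 250)
  kept <- intersect_across_samples(list(a, other))
  expect_equal(kept$start, 0)
  expect_equal(kept$end, 200)
  expect_error(intersect_across_samples(list()), "non-empty")
})

test_that("normalization scale factor is the mean coverage inside peaks", {
  summed <- c(10, 10, 0, 0, 30, 30)
  cov <- cov1(summed * 0.25, summed * 0.75, chrom = "chrT")
  peaks <- structure(data.frame(chrom = "chrT", start = c(0, 4), end = c(2, 6)),
                     class = c("peak_set", "data.frame"))
  res <- rpa_normalize(cov, peaks)
  expect_equal(res$scale_factor, 20)
  expect_equal(res$track$data$chrT$fwd + res$track$data$chrT$rev,
               c(0.5, 0.5, 0, 0, 1.5, 1.5))
})

test_that("normalized tracks are invariant to global scaling", {
  set.seed(7)
  v <- rpois(1000, 5) + 1
  cov <- cov1(v, rev(v), chrom = "chrT")
  peaks <- structure(data.frame(chrom = "chrT", start = c(10, 500), end = c(60, 700)),
                     class = c("peak_set", "data.frame"))
  base <- rpa_normalize(cov, peaks)
  for (c_ in c(0.1, 3, 1000)) {
    scaled <- cov1(v * c_, rev(v) * c_, chrom = "chrT")
    res <- rpa_normalize(scaled, peaks)
    expect_equal(res$track$data$chrT$fwd, base$track$data$chrT$fwd,
                 tolerance = 1e-12)
    expect_equal(res$scale_factor, base$scale_factor * c_, tolerance = 1e-12)
  }
})

test_that("empty reference peak sets are rejected", {
  cov <- cov1(rep(1, 10), chrom = "chrT")
  empty <- structure(data.frame(chrom = character(), start = numeric(),
                                end = numeric()),
                     class = c("peak_set", "data.frame"))
  expect_error(rpa_normalize(cov, empty), "empty")
})

test_that("pooled-anchor reference peaks survive per-sample retention", {
  peaks <- data.frame(chrom = "chrT", center = c(5000, 15000),
                      width = c(300, 200), amplitude = c(20, 15))
  gs <- tiny_genome(len = 60000, dsb = 40000, peaks = peaks)
  lib <- library_params(mean_depth = 20, chip_beta = 2, noise = "poisson")
  covs <- lapply(1:3, function(i)
    render_rpa_chip(make_truth(0, 0, gs), gs, lib, seed = 300 + i))
  cfg <- quant_config("chrT", 40000, dsb_exclusion_halfwidth = 5000)
  ps <- reference_peaks(covs, cfg)
  expect_equal(nrow(ps), 2L)
  expect_true(any(ps$start <= 5000 & ps$end >= 5000))
  expect_true(any(ps$start <= 15000 & ps$end >= 15000))
})
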