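# Direct Ct-table construction helpers
ct_rows <- function(target, tube, ct, n = 3, sample = "S1")
  data.frame(sample = sample, target = target, tube = tube,
             replicate = seq_len(n), ct = ct)

make_ct <- function(..., ct_cap = 40) ct_table(do.call(rbind, list(...)), ct_cap)

test_that("ssDNA fraction inverts the template-counting formula", {
  # ddCt = 0 -> f = 1
  tab <- make_ct(ct_rows("site", "digested", 20), ct_rows("site", "undigested", 20),
                 ct_rows("ctrl", "digested", 18), ct_rows("ctrl", "undigested", 18))
  expect_equal(ssdna_fraction(tab, "site", "ctrl")$fraction, 1)
  # ddCt = log2(3) -> f = 0.5
  tab <- make_ct(ct_rows("site", "digested", 20 + log2(3)),
                 ct_rows("site", "undigested", 20),
                 ct_rows("ctrl", "digested", 18), ct_rows("ctrl", "undigested", 18))
  expect_equal(ssdna_fraction(tab, "site", "ctrl")$fraction, 0.5)
  # monotone decreasing in ddCt over the assay's domain, bounded in [0, 1]
  fs <- vapply(seq(0, 8, by = 0.5), function(ddct) {
    tab <- make_ct(ct_rows("site", "digested", 20 + ddct),
                   ct_rows("site", "undigested", 20),
                   ct_rows("ctrl", "digested", 18),
                   ct_rows("ctrl", "undigested", 18))
    ssdna_fraction(tab, "site", "ctrl")$fraction
  }, numeric(1))
  expect_true(all(diff(fs) < 0))
  expect_true(all(fs >= 0 & fs <= 1))
})

test_that("capped digested Ct reports zero ssDNA", {
  tab <- make_ct(ct_rows("site", "digested", 40), ct_rows("site", "undigested", 20),
                 ct_rows("ctrl", "digested", 18), ct_rows("ctrl", "undigested", 18))
  est <- ssdna_fraction(tab, "site", "ctrl")
  expect_equal(est$fraction, 0)
})

test_that("missing tubes are reported", {
  tab <- make_ct(ct_rows("site", "digested", 20),
                 ct_rows("ctrl", "digested", 18), ct_rows("ctrl", "undigested", 18))
  expect_error(ssdna_fraction(tab, "site", "ctrl"), "undigested")
})

test_that("simulator round trip recovers the true ssDNA fraction exactly", {
  gs <- tiny_genome(len = 20000, dsb = 10000)
  qp <- qpcr_sim_params(c(-120, 98, 640, 2500), ct_noise_sd = 0)
  for (f in seq(0, 1, by = 0.1)) {
    n <- 10
    k <- round(n * f)
    tr <- make_truth(left = c(rep(5000, k), rep(0, n - k)),
                     right = c(rep(5000, k), rep(0, n - k)), gs)
    tab <- simulate_qpcr_resection(tr, gs, qp)
    for (tg in c("site_-120", "site_+98")) {
      est <- ssdna_fraction(tab, tg, "control")
      expect_equal(est$fraction, f, tolerance = 1e-9)
    }
  }
})

test_that("replicate scatter shrinks the propagated SD as 1/sqrt(n)", {
  gs <- tiny_genome(len = 20000, dsb = 10000)
  tr <- make_truth(left = 0, right = rep(c(5000, 0), 50), gs)
  sds <- vapply(c(3, 12), function(nrep) {
    qp <- qpcr_sim_params(98, ct_noise_sd = 0.3, n_replicates = nrep)
    median(vapply(1:60, function(i) {
      tab <- simulate_qpcr_resection(tr, gs, qp, seed = 1000 + i)
      ssdna_fraction(tab, "site_+98", "control")$sd
    }, numeric(1)))
  }, numeric(1))
  expect_lt(abs(sds[2] / sds[1] - 0.5), 0.15)
})

test_that("cut-fraction correction rescales the reported fraction", {
  tab <- make_ct(ct_rows("site", "digested", 20 + log2(3)),
                 ct_rows("site", "undigested", 20),
                 ct_rows("ctrl", "digested", 18), ct_rows("ctrl", "undigested", 18))
  est <- ssdna_fraction(tab, "site", "ctrl", cut_fraction = 0.8)
  expect_equal(est$fraction, 0.5 / 0.8)
  expect_error(ssdna_fraction(tab, "site", "ctrl", cut_fraction = 0.2),
               "exceeds 1")
})

test_that("cut fraction follows surviving-template arithmetic", {
  mk <- function(ho_t) make_ct(
    ct_rows("HO", "undigested", 20, sample = "t0"),
    ct_rows("ctrl", "undigested", 18, sample = "t0"),
    ct_rows("HO", "undigested", ho_t, sample = "t"),
    ct_rows("ctrl", "undigested", 18, sample = "t"))
  expect_equal(cut_fraction(mk(20), "HO", "ctrl"), 0)
  expect_equal(cut_fraction(mk(21), "HO", "ctrl"), 0.5)
  expect_error(cut_fraction(mk(21), "HO", "ctrl", t0_sample = "nope"), "missing")
})

test_that("simulated 80% cutting is recovered exactly without noise", {
  qp <- qpcr_sim_params(98, ct_noise_sd = 0)
  tab <- simulate_qpcr_cut(0.8, qp)
  expect_equal(cut_fraction(tab, "HOcs", "control"), 0.8, tolerance = 1e-9)
})

test_that("perfect dilution series gives the textbook slope and efficiency", {
  q <- 10^seq(0, -4)
  fit <- fit_standard_curve(q, 25 - log2(q))
  expect_equal(fit$slope, -1 / log10(2), tolerance = 1e-9)
  expect_equal(fit$efficiency, 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
})

test_that("degenerate calibration inputs are rejected", {
  expect_error(fit_standard_curve(10^(0:-4), rep(20, 5)), "slope")
  expect_error(fit_standard_curve(c(1, 1, 1), c(20, 21, 22)), "distinct")
  expect_error(fit_standard_curve(c(1, 0, -1), c(20, 21, 22)), "positive")
})

test_that("noisy calibration recovers efficiency within 5% (Monte Carlo)", {
  q <- 10^seq(0, -4)
  true_ct <- 25 - log2(q)
  set.seed(99)
  eff <- vapply(1:1000, function(i)
    fit_standard_curve(q, true_ct + rnorm(5, 0, 0.1))$efficiency, numeric(1))
  expect_lt(abs(median(eff) - 1), 0.05)
})

test_that("recombination ratio is a calibrated quantity ratio", {
  q <- 10^seq(0, -4)
  curve <- fit_standard_curve(q, 25 - log2(q))
  mk <- function(ct_r, ct_c) make_ct(ct_rows("recombination", "undigested", ct_r),
                                     ct_rows("control", "undigested", ct_c))
  # equal quantities by construction
  expect_equal(recombination_ratio(mk(27, 27), curve, curve)$ratio, 1,
               tolerance = 1e-9)
  # Q_recomb = 0.2 * Q_control
  res <- recombination_ratio(mk(27 - log2(0.2), 27), curve, curve)
  expect_equal(res$ratio, 0.2, tolerance = 1e-9)
  # global dilution cancels
  res2 <- recombination_ratio(mk(29 - log2(0.2), 29), curve, curve)
  expect_equal(res2$ratio, res$ratio, tolerance = 1e-9)
})

test_that("Ct values outside the calibrated range are flagged, not dropped", {
  q <- 10^seq(0, -4)
  curve <- fit_standard_curve(q, 25 - log2(q))
  tab <- make_ct(ct_rows("recombination", "undigested", 39),
                 ct_rows("control", "undigested", 27))
  res <- recombination_ratio(tab, curve, curve)
  expect_gt(length(res$warnings), 0)
  expect_true(is.finite(res$ratio))
})
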