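lib0 <- library_params(mean_depth = 20, noise = "none")

test_that("an uncut population renders flat total-DNA coverage", {
  gs <- tiny_genome(len = 5000, dsb = 2500)
  tr <- make_truth(0, 0, gs)
  cov <- render_total_dna(tr, gs, lib0)
  expect_equal(cov$data$chrT$fwd, rep(20, 5000))
  expect_equal(cov$data$chrT$rev, rep(20, 5000))
})

test_that("a single resected cell removes exactly its tract", {
  gs <- tiny_genome(len = 5000, dsb = 2000)
  tr <- make_truth(left = 0, right = 300, gs)
  cov <- render_total_dna(tr, gs, lib0)
  fwd <- cov$data$chrT$fwd
  # tract [dsb, dsb + 300) on the forward strand (0-based positions)
  expect_equal(fwd[2001:2300], rep(0, 300))
  expect_equal(fwd[c(1:2000, 2301:5000)], rep(20, 4700))
  expect_equal(cov$data$chrT$rev, rep(20, 5000))
})

test_that("noiseless loss is confined to the 5'-terminated strands", {
  gs <- tiny_genome(len = 20000, dsb = 10000)
  tr <- simulate_population(gs, resection_model(0.8, 1000, 0.4), 2, 200, seed = 9)
  cov <- render_total_dna(tr, gs, lib0)
  expect_equal(cov$data$chrT$fwd[1:10000], rep(20, 10000))       # fwd left intact
  expect_equal(cov$data$chrT$rev[10001:20000], rep(20, 10000))   # rev right intact
  expect_true(any(cov$data$chrT$fwd[10001:20000] < 20))          # fwd right degraded
  expect_true(any(cov$data$chrT$rev[1:10000] < 20))              # rev left degraded
})

test_that("deterministic symmetric tracts mirror about the DSB", {
  gs <- tiny_genome(len = 20000, dsb = 10000)
  tr <- simulate_population(gs, resection_model(1, 1000, 0), 3, 50, seed = 1)
  cov <- render_total_dna(tr, gs, lib0)
  expect_equal(rev(cov$data$chrT$rev[1:10000]), cov$data$chrT$fwd[10001:20000])
})

test_that("noiseless ratio encodes the truth survival exactly", {
  gs <- tiny_genome(len = 40000, dsb = 20000)
  tr <- simulate_population(gs, resection_model(0.9, 2000, 0.5), 2, 400, seed = 13)
  cov_t <- render_total_dna(tr, gs, lib0)
  cov_0 <- render_total_dna(make_truth(0, 0, gs), gs, lib0)
  ratio <- t0_ratio(cov_t, cov_0)
  for (d in c(0, 500, 2000, 4000, 10000)) {
    expect_equal(1 - ratio$data$chrT$fwd[20000 + d + 1],
                 mean(tr$right_extent > d))
    expect_equal(1 - ratio$data$chrT$rev[20000 - d],
                 mean(tr$left_extent > d))
  }
})

test_that("Poisson renders thin coverage by the resected fraction", {
  gs <- tiny_genome(len = 30000, dsb = 10000)
  # half the cells resected 5 kb rightward: survival at p in the tract is 0.5
  tr <- make_truth(left = 0, right = rep(c(5000, 0), 5000), gs)
  lib <- library_params(mean_depth = 50, noise = "poisson")
  cov <- render_total_dna(tr, gs, lib, seed = 21)
  p <- 12500  # inside the tract
  expect_lt(abs(cov$data$chrT$fwd[p + 1] - 25), 3 * sqrt(25))
  # and averaged over the tract the thinning is tight
  expect_lt(abs(mean(cov$data$chrT$fwd[10001:15000]) - 25), 3 * sqrt(25 / 5000))
})

test_that("RPA render is flat baseline without ssDNA or peaks", {
  gs <- tiny_genome(len = 4000, dsb = 2000)
  cov <- render_rpa_chip(make_truth(0, 0, gs), gs, lib0)
  expect_equal(cov$data$chrT$fwd, rep(lib0$chip_beta, 4000))
  expect_equal(cov$data$chrT$rev, rep(lib0$chip_beta, 4000))
})

test_that("RPA enrichment sits on the persisting 3' strand", {
  gs <- tiny_genome(len = 8000, dsb = 3000)
  tr <- make_truth(left = 0, right = 1200, gs)   # every cell resected 1.2 kb right
  cov <- render_rpa_chip(tr, gs, lib0)
  a <- lib0$chip_alpha; b <- lib0$chip_beta
  expect_equal(cov$data$chrT$rev[3001:4200], rep(b + a, 1200))
  expect_equal(cov$data$chrT$rev[c(1:3000, 4201:8000)], rep(b, 6800))
  expect_equal(cov$data$chrT$fwd, rep(b, 8000))  # forward untouched right of DSB
})

test_that("background peaks are recoverable at the 6x-median threshold", {
  peaks <- data.frame(chrom = "chrT", center = 10000, width = 300, amplitude = 20)
  gs <- tiny_genome(len = 50000, dsb = 40000, peaks = peaks)
  lib <- library_params(mean_depth = 20, chip_beta = 2, noise = "none")
  cov <- render_rpa_chip(make_truth(0, 0, gs), gs, lib)
  cfg <- quant_config("chrT", 40000, dsb_exclusion_halfwidth = 5000)
  ps <- slice_reference_peaks(cov, cfg)
  expect_equal(nrow(ps), 1L)
  w <- ps$end - ps$start
  expect_true(w >= 100 && w <= 500)
  expect_true(ps$start <= 10000 && ps$end >= 10000)  # contains the center
})

test_that("renders are reproducible under a fixed seed", {
  gs <- tiny_genome(len = 10000, dsb = 5000)
  tr <- simulate_population(gs, resection_model(0.9, 1000, 0.3), 2, 100, seed = 2)
  lib <- library_params(mean_depth = 30, noise = "poisson")
  expect_identical(render_total_dna(tr, gs, lib, seed = 5),
                   render_total_dna(tr, gs, lib, seed = 5))
  expect_identical(render_rpa_chip(tr, gs, lib, seed = 5),
                   render_rpa_chip(tr, gs, lib, seed = 5))
})
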