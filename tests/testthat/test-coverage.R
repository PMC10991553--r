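test_that("single-read pileup places one count over its interval", {
  reads <- data.frame(chrom = "c", start = 10, end = 15, strand = "+")
  cov <- coverage_from_reads(reads, c(c = 100))
  expected <- numeric(100); expected[11:15] <- 1
  expect_equal(cov$data$c$fwd, expected)
  expect_equal(cov$data$c$rev, numeric(100))
})

test_that("empty read sets give all-zero coverage", {
  reads <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), strand = character())
  cov <- coverage_from_reads(reads, c(c = 50))
  expect_equal(sum(cov$data$c$fwd) + sum(cov$data$c$rev), 0)
})

test_that("overlapping reads sum as a hand-computed pileup", {
  reads <- data.frame(chrom = "c", start = c(0, 5), end = c(10, 15),
                      strand = "+")
  cov <- coverage_from_reads(reads, c(c = 20))
  expect_equal(cov$data$c$fwd,
               c(rep(1, 5), rep(2, 5), rep(1, 5), rep(0, 5)))
})

test_that("score filtering drops low-quality reads", {
  reads <- data.frame(chrom = "c", start = c(0, 10, 20), end = c(5, 15, 25),
                      strand = "+", score = c(10, 30, 50))
  cov <- coverage_from_reads(reads, c(c = 100), min_score = 30)
  expect_equal(sum(cov$data$c$fwd), 10)  # two retained reads of 5 bp
})

test_that("out-of-bounds reads are reported with their record", {
  reads <- data.frame(chrom = "c", start = 95, end = 105, strand = "+")
  expect_error(coverage_from_reads(reads, c(c = 100)), "c:95-105")
})

test_that("t0 ratio is exact division with masked zero-denominator positions", {
  t0 <- cov1(c(10, 10, 0, 5), c(2, 2, 2, 2), chrom = "c")
  tt <- cov1(c(5, 10, 7, 5), c(2, 1, 0, 2), chrom = "c")
  r <- t0_ratio(tt, t0)
  expect_equal(r$data$c$fwd, c(0.5, 1, NA, 1))
  expect_equal(r$data$c$rev, c(1, 0.5, 0, 1))
  expect_false(any(is.infinite(unlist(r$data))))
})

test_that("ratio of identical tracks is 1 wherever defined", {
  cov <- cov1(c(3, 0, 7), chrom = "c")
  r <- t0_ratio(cov, cov)
  expect_equal(r$data$c$fwd, c(1, NA, 1))
})

test_that("genome mismatch is rejected", {
  a <- cov1(c(1, 2), chrom = "c")
  b <- cov1(c(1, 2, 3), chrom = "c")
  expect_error(t0_ratio(a, b), "mismatch|length")
})

test_that("subsampling equalizes depth at the minimum sample size", {
  mk <- function(n) data.frame(chrom = "c", start = seq_len(n) - 1,
                               end = seq_len(n), strand = "+")
  out <- subsample_to_common_depth(list(a = mk(100), b = mk(60), c = mk(80)),
                                   seed = 1)
  expect_equal(vapply(out, nrow, integer(1)), c(a = 60, b = 60, c = 60))
  # subset property: every output row exists in its input
  expect_true(all(out$a$start %in% (0:99)))
  expect_true(!is.unsorted(out$a$start))  # original order kept
})

test_that("a single sample passes through unchanged", {
  s <- data.frame(chrom = "c", start = 0:9, end = 1:10, strand = "+")
  out <- subsample_to_common_depth(list(s), seed = 3)
  expect_identical(out[[1]], s)
})

test_that("subsampling is deterministic in the seed", {
  mk <- function(n) data.frame(chrom = "c", start = seq_len(n) - 1,
                               end = seq_len(n), strand = "+")
  samples <- list(x = mk(500), y = mk(200))
  a <- subsample_to_common_depth(samples, seed = 5)
  b <- subsample_to_common_depth(samples, seed = 5)
  expect_identical(a, b)
  d <- subsample_to_common_depth(samples, seed = 6)
  expect_false(identical(a$x$start, d$x$start))
  expect_equal(nrow(d$x), 200)
})

test_that("empty samples are reported by name", {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), strand = character())
  full <- data.frame(chrom = "c", start = 0, end = 1, strand = "+")
  expect_error(subsample_to_common_depth(list(ok = full, bad = empty)), "bad")
})
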