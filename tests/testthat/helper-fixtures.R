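# Shared fixtures and independent oracles.

tiny_genome <- function(len = 200000, dsb = len / 2, peaks = NULL)
  genome_spec(c(chrT = len), "chrT", dsb, background_peaks = peaks)

# Hand-built ground truth: explicit per-cell extents, bypassing the sampler.
make_truth <- function(left, right, genome, time = 2) {
  n <- max(length(left), length(right))
  left <- rep_len(left, n); right <- rep_len(right, n)
  structure(
    data.frame(cell = seq_len(n), cut = left > 0 | right > 0,
               left_extent = left, right_extent = right),
    time = time, genome = genome,
    class = c("resection_truth", "data.frame"))
}

# Build a strand_coverage from explicit per-strand vectors on one chromosome.
cov1 <- function(fwd, rev = fwd, chrom = "chrT", kind = "coverage") {
  cs <- stats::setNames(length(fwd), chrom)
  strand_coverage(stats::setNames(list(list(fwd = fwd, rev = rev)), chrom),
                  cs, kind = kind)
}

# Independent brute-force peak scan: position-by-position thresholding of the
# strand-summed coverage, then width and exclusion filters. The production
# path goes through run-length encoding and IRanges::slice; this one never
# does.
brute_force_peaks <- function(summed, threshold, width_bounds, exclude = NULL) {
  above <- summed >= threshold
  peaks <- list()
  i <- 1L
  n <- length(above)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      peaks[[length(peaks) + 1L]] <- c(i - 1L, j)  # 0-based half-open
      i <- j + 1L
    }
    i <- i + 1L
  }
  if (length(peaks) == 0L) return(data.frame(start = numeric(), end = numeric()))
  df <- as.data.frame(do.call(rbind, peaks))
  names(df) <- c("start", "end")
  w <- df$end - df$start
  df <- df[w >= width_bounds[1] & w <= width_bounds[2], , drop = FALSE]
  if (!is.null(exclude))
    df <- df[df$end <= exclude[1] | df$start >= exclude[2], , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Vectorized-over-m MSS recursion in plain R, for the grid-search oracle:
# returns an (length(m) x (r_max+1)) matrix of probabilities.
ld_pmf_grid <- function(m, r_max) {
  p <- matrix(0, length(m), r_max + 1)
  p[, 1] <- exp(-m)
  for (r in seq_len(r_max)) {
    w <- 1 / (r - (0:(r - 1)) + 1)
    p[, r + 1] <- m / r * as.vector(p[, 1:r, drop = FALSE] %*% w)
  }
  p
}

# Brute-force grid-search MLE of m over a fixed grid.
grid_search_m <- function(counts, grid = seq(1e-4, 50, by = 1e-3)) {
  p <- ld_pmf_grid(grid, max(counts))
  ll <- rowSums(log(pmax(p[, counts + 1, drop = FALSE], 1e-300)))
  grid[which.max(ll)]
}

quiet <- function(expr) suppressMessages(expr)
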