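#' Stochastic model of DSB induction and 5'-to-3' resection
#'
#' Parameters of the per-cell resection process used by
#' [simulate_population()]. Each cell carries the DSB with probability
#' `cut_efficiency` (endonuclease cutting is incomplete in a real
#' population). In a cut cell, each end is resected independently; the
#' tract length at time `t` is drawn from a lognormal distribution with
#' mean `speed_mean * max(0, t - init_delay)` and coefficient of variation
#' `speed_cv`. `speed_cv = 0` collapses to a deterministic tract length.
#'
#' @param cut_efficiency Fraction of cells in which the DSB is induced,
#'   in \[0, 1\].
#' @param speed_mean Mean resection speed per end (nt/h), > 0.
#' @param speed_cv Coefficient of variation of the tract length, >= 0.
#' @param init_delay Lag (h) before resection initiates, >= 0.
#' @param timepoints Optional numeric vector of sampling times (h).
#' @return An object of class `resection_model`.
#' @examples
#' resection_model(cut_efficiency = 0.9, speed_mean = 4000, speed_cv = 0.3)
#' @export
resection_model <- function(cut_efficiency, speed_mean, speed_cv,
                            init_delay = 0, timepoints = NULL) {
  structure(list(
    cut_efficiency = check_number(cut_efficiency, "cut_efficiency", 0, 1),
    speed_mean = check_number(speed_mean, "speed_mean", 0, strict_min = TRUE),
    speed_cv = check_number(speed_cv, "speed_cv", 0),
    init_delay = check_number(init_delay, "init_delay", 0),
    timepoints = timepoints
  ), class = "resection_model")
}

#' Simulate a resecting cell population
#'
#' Draws the per-cell ground truth at one time point: whether the cell's
#' DSB was cut, and how far each end has been resected. Tract lengths are
#' lognormal (see [resection_model()]) and are clipped to the chromosome
#' bounds (`left_extent <= dsb_pos`,
#' `right_extent <= chrom_length - dsb_pos`). Uncut cells have both
#' extents 0.
#'
#' @param genome A [genome_spec()].
#' @param model A [resection_model()].
#' @param t Time after induction (h), >= 0.
#' @param n_cells Number of cells, >= 1.
#' @param seed Optional integer seed; identical seeds reproduce the
#'   population exactly.
#' @return A data.frame of class `resection_truth` with columns `cell`,
#'   `cut` (logical), `left_extent` and `right_extent` (nt), and
#'   attributes `time` and `genome`.
#' @examples
#' gs <- genome_spec(c(chrV = 200000L), "chrV", 100000)
#' mod <- resection_model(1, 4000, 0)
#' tr <- simulate_population(gs, mod, t = 2, n_cells = 3, seed = 1)
#' stopifnot(all(tr$right_extent == 8000))
#' @export
simulate_population <- function(genome, model, t, n_cells, seed = NULL) {
  stopifnot(inherits(genome, "genome_spec"), inherits(model, "resection_model"))
  t <- check_number(t, "t", 0)
  n_cells <- check_count(n_cells, "n_cells", 1)

  mu_t <- model$speed_mean * max(0, t - model$init_delay)
  max_left <- genome$dsb_pos
  max_right <- genome$chrom_sizes[[genome$dsb_chrom]] - genome$dsb_pos

  with_seed(seed, {
    cut <- stats::runif(n_cells) < model$cut_efficiency
    draw <- function(n) {
      if (n == 0L) return(numeric(0))
      if (mu_t == 0) return(rep(0, n))
      if (model$speed_cv == 0) return(rep(mu_t, n))
      sdlog <- sqrt(log(1 + model$speed_cv^2))
      meanlog <- log(mu_t) - sdlog^2 / 2
      stats::rlnorm(n, meanlog, sdlog)
    }
    left <- right <- numeric(n_cells)
    left[cut] <- pmin(draw(sum(cut)), max_left)
    right[cut] <- pmin(draw(sum(cut)), max_right)
    structure(
      data.frame(cell = seq_len(n_cells), cut = cut,
                 left_extent = left, right_extent = right),
      time = t, genome = genome,
      class = c("resection_truth", "data.frame"))
  })
}

# Fraction of cells whose tract on `side` extends strictly beyond each
# distance in `d` (nt from the break). Uncut cells count with extent 0.
# This survival curve is the simulator's bridge to coverage: the expected
# fraction of molecules lost at distance d on the degraded strand is
# exactly resection_survival(truth, d, side).
#' Survival function of resection extents
#'
#' For each distance `d`, the fraction of cells (cut or not) whose
#' resection tract on the given side extends strictly beyond `d` nt.
#'
#' @param truth A `resection_truth` from [simulate_population()].
#' @param d Numeric vector of distances from the DSB (nt).
#' @param side `"left"` or `"right"`.
#' @return Numeric vector, same length as `d`, values in \[0, 1\].
#' @export
resection_survival <- function(truth, d, side = c("right", "left")) {
  side <- match.arg(side)
  ext <- sort(if (side == "right") truth$right_extent else truth$left_extent)
  1 - findInterval(d, ext) / length(ext)
}
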