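#' Simulate a Luria-Delbruck fluctuation experiment
#'
#' Grows `n_cultures` parallel cultures from `n0` to at least `nt` cells
#' and returns the final number of mutant (recombinant) cells in each.
#'
#' Two growth models are available. The default, `"division"`, treats
#' each of the `nt - n0` cell divisions as an independent mutation
#' opportunity: the number of mutations per culture is
#' `Binomial(nt - n0, mu)`, each mutation is assigned to a uniformly
#' drawn division (i.e. the population size `s` at which it arose), and
#' the mutant clone then grows deterministically with the culture to
#' `floor(nt / s)` cells. This reproduces the classic Luria-Delbruck
#' clone-size law `P(clone size = j) = 1/(j(j+1))` and hence the
#' Ma-Sandri-Sarkar distribution targeted by [estimate_m()], with
#' `P(0 mutants) = (1 - mu)^(nt - n0)` (approximately `exp(-mu * nt)`).
#' The `"synchronous"` variant instead doubles the whole culture in
#' discrete generations, drawing `Binomial(new cells, mu)` mutants per
#' generation; it shares the same zero-class probability but puts clone
#' sizes on powers of two.
#'
#' @param mu Mutation probability per cell division, in \[0, 1) and
#'   realistically << 1.
#' @param nt Final population size per culture (> `n0`); rounded up to
#'   the next power-of-two multiple of `n0` under `"synchronous"` growth.
#' @param n_cultures Number of parallel cultures (the source experiments
#'   used 7-8 per strain per replicate).
#' @param n0 Initial cells per culture (default 1).
#' @param growth `"division"` (default) or `"synchronous"`; see Details.
#' @param seed Optional seed; identical seeds reproduce counts exactly.
#' @return Numeric vector of per-culture mutant counts with attributes
#'   `nt` (realized final population size), `mu` and
#'   `m_expected = mu * (nt - n0)`.
#' @examples
#' counts <- simulate_fluctuation(mu = 2e-6, nt = 2^20, n_cultures = 8, seed = 1)
#' @export
simulate_fluctuation <- function(mu, nt, n_cultures, n0 = 1,
                                 growth = c("division", "synchronous"),
                                 seed = NULL) {
  growth <- match.arg(growth)
  mu <- check_number(mu, "mu", 0, 1)
  if (mu >= 1) stop("'mu' must be < 1")
  n0 <- check_count(n0, "n0", 1)
  nt <- check_number(nt, "nt", 0, strict_min = TRUE)
  if (nt <= n0) stop("'nt' must exceed 'n0'")
  n_cultures <- check_count(n_cultures, "n_cultures", 1)

  with_seed(seed, {
    if (growth == "division") {
      nt <- floor(nt)
      divisions <- nt - n0
      k <- stats::rbinom(n_cultures, divisions, mu)
      counts <- vapply(k, function(ki) {
        if (ki == 0L) return(0)
        s <- n0 + ceiling(stats::runif(ki) * divisions)  # pop size after the mutant division
        sum(floor(nt / s))
      }, numeric(1))
      nt_final <- nt
    } else {
      gens <- ceiling(log2(nt / n0))
      nonmut <- rep(n0, n_cultures)
      mut <- numeric(n_cultures)
      for (g in seq_len(gens)) {
        newmut <- stats::rbinom(n_cultures, nonmut, mu)
        mut <- 2 * mut + newmut
        nonmut <- 2 * nonmut - newmut
      }
      counts <- mut
      nt_final <- n0 * 2^gens
    }
    structure(counts, nt = nt_final, mu = mu, m_expected = mu * (nt_final - n0))
  })
}
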