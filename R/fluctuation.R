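#' Luria-Delbruck probability mass function (MSS recursion)
#'
#' Probabilities of observing `0..r_max` mutants per culture when the
#' expected number of mutations per culture is `m`, computed by the
#' Ma-Sandri-Sarkar recursion
#' `p_0 = exp(-m)`, `p_r = (m/r) * sum_{i=0}^{r-1} p_i / (r - i + 1)`.
#'
#' The distribution is heavy-tailed (`p_r ~ m / (r (r+1))` for large
#' `r`), so the truncated mass falls short of 1 by approximately
#' `m / (r_max + 1)`; [ld_tail_mass()] gives that analytic remainder,
#' which the likelihood uses as a final "r >= r_max" bin.
#'
#' @param m Expected mutations per culture, >= 0.
#' @param r_max Largest count to evaluate, >= 0.
#' @return Numeric vector of length `r_max + 1` with `p_0 .. p_r_max`.
#' @examples
#' p <- ld_pmf(1, 5)
#' all.equal(p[1], exp(-1))
#' all.equal(p[2], exp(-1) / 2)
#' @export
ld_pmf <- function(m, r_max) {
  m <- check_number(m, "m", 0)
  r_max <- check_count(r_max, "r_max", 0)
  if (m == 0) return(c(1, rep(0, r_max)))
  .ld_pmf_cpp(m, as.integer(r_max))
}

#' Analytic tail mass of the Luria-Delbruck distribution
#'
#' First-order approximation `P(R > r_max) ~ m / (r_max + 1)` from the
#' asymptotic tail `p_r ~ m / (r (r+1))`; used to check truncated-mass
#' convergence and to bound the tail bin.
#'
#' @inheritParams ld_pmf
#' @return Approximate tail probability.
#' @export
ld_tail_mass <- function(m, r_max) m / (r_max + 1)

# Log-likelihood of per-culture counts under the MSS distribution.
# Counts at or above r_max share a tail bin P(R >= r_max) = 1 - sum(p_<r_max),
# which keeps jackpot cultures from forcing unbounded recursions.
ld_loglik <- function(counts, m, r_max = 10000) {
  if (m <= 0) return(if (all(counts == 0)) 0 else -Inf)
  cap <- min(r_max, max(counts) + 1)
  p <- ld_pmf(m, cap)
  ll <- 0
  in_tail <- counts >= r_max
  if (any(in_tail)) {
    tail_p <- max(1 - sum(p[seq_len(r_max)]), 1e-300)
    ll <- ll + sum(in_tail) * log(tail_p)
  }
  obs <- counts[!in_tail]
  ll + sum(log(pmax(p[obs + 1], 1e-300)))
}

#' Maximum-likelihood estimate of mutations per culture (MSS method)
#'
#' Estimates `m`, the expected number of mutation events per culture,
#' from the distribution of mutant counts across parallel cultures by
#' maximizing the Ma-Sandri-Sarkar likelihood. Optimization is
#' one-dimensional on `log m` (golden-section/Brent), with the boundary
#' case handled explicitly: all-zero counts give the boundary MLE
#' `m = 0` with a one-sided confidence interval. The 95% interval is the
#' likelihood-ratio interval (log-likelihood drop of 1.92).
#'
#' @param counts Non-negative integer vector of mutant counts, one per
#'   culture (>= 2 cultures).
#' @param r_max Truncation bound: counts >= `r_max` are pooled into a
#'   tail bin `P(R >= r_max)`.
#' @param conf_level Confidence level for the likelihood-ratio interval.
#' @return List of class `mss_fit`: `m`, `loglik`, `ci` (length 2),
#'   `n_cultures`, `counts`.
#' @examples
#' fit <- estimate_m(c(0, 0, 1, 0, 3, 0, 27, 1))
#' fit$m
#' @export
estimate_m <- function(counts, r_max = 10000, conf_level = 0.95) {
  counts <- as.numeric(counts)
  if (length(counts) < 2L) stop("need at least 2 cultures to estimate m")
  if (any(is.na(counts) | counts < 0 | counts != floor(counts)))
    stop("'counts' must be non-negative integers")
  n <- length(counts)
  crit <- stats::qchisq(conf_level, df = 1) / 2   # 1.92 at 95%

  if (all(counts == 0)) {
    # L(m) = exp(-m n): maximized at the m = 0 boundary
    upper <- crit / n
    return(structure(list(m = 0, loglik = 0, ci = c(0, upper),
                          n_cultures = n, counts = counts),
                     class = "mss_fit"))
  }

  nll <- function(logm) -ld_loglik(counts, exp(logm), r_max)
  opt <- stats::optimize(nll, interval = log(c(1e-6, 1e4)), tol = 1e-9)
  m_hat <- exp(opt$minimum)
  ll_max <- -opt$objective

  drop_fun <- function(m) ld_loglik(counts, m, r_max) - (ll_max - crit)
  lo_end <- 1e-8
  ci_lo <- if (drop_fun(lo_end) >= 0) 0
           else stats::uniroot(drop_fun, c(lo_end, m_hat), tol = 1e-8)$root
  hi_end <- max(m_hat * 100, 10)
  ci_hi <- if (drop_fun(hi_end) >= 0) Inf
           else stats::uniroot(drop_fun, c(m_hat, hi_end), tol = 1e-8)$root

  structure(list(m = m_hat, loglik = ll_max, ci = c(ci_lo, ci_hi),
                 n_cultures = n, counts = counts),
            class = "mss_fit")
}

#' @export
print.mss_fit <- function(x, ...) {
  cat(sprintf("MSS maximum-likelihood fit (%d cultures)\n", x$n_cultures))
  cat(sprintf("  m = %.4g  (95%% CI %.4g - %.4g), logL = %.3f\n",
              x$m, x$ci[1], x$ci[2], x$loglik))
  invisible(x)
}

#' Convert mutations per culture to a per-division rate
#'
#' The fluctuation-assay rate convention: `rate = m / Nt`, mutations per
#' cell per division, with the confidence interval scaled identically.
#' An optional plating dilution divides the effective `Nt` (off by
#' default: apply it only when a known fraction of each culture was
#' plated).
#'
#' @param fit An `mss_fit` from [estimate_m()] (or a single number `m`).
#' @param nt Final population size per culture, > 0.
#' @param plating_fraction Fraction of the culture plated, in (0, 1\].
#' @return List of class `mutation_rate`: `rate`, `ci`, `m`, `nt`.
#' @examples
#' mutation_rate(estimate_m(c(0, 1, 0, 5)), nt = 1e8)
#' @export
mutation_rate <- function(fit, nt, plating_fraction = 1) {
  nt <- check_number(nt, "nt", 0, strict_min = TRUE)
  plating_fraction <- check_number(plating_fraction, "plating_fraction", 0, 1,
                                   strict_min = TRUE)
  if (is.numeric(fit)) fit <- list(m = fit, ci = c(NA_real_, NA_real_))
  nt_eff <- nt * plating_fraction
  structure(list(rate = fit$m / nt_eff, ci = fit$ci / nt_eff,
                 m = fit$m, nt = nt_eff),
            class = "mutation_rate")
}

#' @export
print.mutation_rate <- function(x, ...) {
  cat(sprintf("rate = %.3g per cell per division (m = %.4g, Nt = %.3g)\n",
              x$rate, x$m, x$nt))
  invisible(x)
}
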