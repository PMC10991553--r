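---
title: "Quantifying DNA end resection: models and methods"
author: "resectquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DNA end resection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resectquant)
```

## The measurement problem

A site-specific double-strand break (DSB) — induced, for example, by the HO
endonuclease at the budding-yeast *MAT* locus — is processed by nucleolytic
5'→3' resection: one strand of each broken end is degraded, leaving a 3'
single-stranded overhang that is immediately coated by the ssDNA-binding
complex RPA. Two sequencing readouts report this process:

* **Total-DNA strand-specific sequencing.** The degraded (5'-terminated)
  strand loses coverage; dividing each post-induction sample by the
  uninduced sample turns coverage into a per-position retention ratio.
* **RPA ChIP strand-specific sequencing.** The persisting 3' strand gains
  RPA occupancy; enrichment on a strand reports ssDNA of that strand.

Two orthogonal wet-lab assays complete the picture: restriction-protection
qPCR (ssDNA across a restriction site survives digestion and amplifies)
and gene-conversion / fluctuation assays that measure the downstream
recombination outcome. `resectquant` implements the computations for all
four, plus a generative model of the whole experiment so that each stage
can be validated against known ground truth.

## Strand geometry

Coordinates are 0-based and half-open everywhere. The forward strand is
the reference strand read 5'→3' with increasing coordinate. At a break at
`x0`, the right-hand fragment's 5'-terminated strand is the *forward*
strand, so resection removes forward-strand signal over
`[x0, x0 + right_extent)`; on the left-hand fragment it removes
reverse-strand signal over `[x0 - left_extent, x0)`. The RPA-bound 3'
ssDNA is the complement: reverse strand right of the break, forward strand
left of it. This single convention is stated here once and asserted by
tests throughout the package.

## The generative model

`simulate_population()` draws, for each of `n` cells, a Bernoulli cut
indicator (probability `cut_efficiency`; endonuclease cutting is
incomplete in real populations) and, for cut cells, independent left and
right tract lengths. Tract lengths are lognormal with mean
`speed_mean * max(0, t - init_delay)` and coefficient of variation
`speed_cv`; the lognormal was chosen because it is positive, has a
tunable tail, and collapses to a deterministic length at `speed_cv = 0`.
No per-cell tract-length distribution has been measured for this system,
so these are free knobs of the simulator, not estimates of any
experimental value.

`render_total_dna()` and `render_rpa_chip()` convert a population into
per-base *expected fragment depth* and optionally Poisson-sample each
base. Read-pair geometry (the emulated libraries carry roughly 200–500 bp
fragments) is deliberately not modeled: the quantification consumes
coverage, not alignments, and a per-base Poisson model keeps every
downstream check analytically tractable. The RPA model is
`beta + alpha * occ(p, strand)` where `occ` is the fraction of cells in
which the position is RPA-coated ssDNA; DSB-independent background peaks
(rectangular footprints with an amplitude expressed as fold over
baseline) are added on both strands to emulate the unspecific RPA peaks
used as normalization references.

Defaults used by the demonstration pipeline and the end-to-end checks
are the study conditions encoded once in the package: a 200-kb
chromosome with a central DSB, 2,000 cells, cut efficiency 0.9, resection
speed 4,000 nt/h with CV 0.3, sequencing depth 50×, and sampling at 2 h
and 4 h after induction.

## Sequencing quantification

The published analysis steps are implemented as small composable
operations:

* `subsample_to_common_depth()` — every sample is reduced to the minimum
  sample size by uniform sampling without replacement, so samples are
  compared at equal depth.
* `t0_ratio()` — position-wise division by the uninduced sample.
  Positions with zero t0 coverage are **masked** (`NA`), never infinite
  and never pseudocounted: pseudocounts would bias loss estimates near
  unmappable or repetitive positions.
* `bin_dsb_window()` — a 20-kb window around the DSB divided in 2-kb
  bins (defaults; both configurable). A bin's value is the mean of its
  unmasked positions; a fully masked bin stays masked.
* `slice_reference_peaks()` — reference peaks are maximal runs of
  strand-summed coverage at or above 6× the genome-wide median
  (zeros included), restricted to widths of 100–500 bp. The run
  extraction uses `IRanges::slice()` on run-length-encoded coverage; an
  independent brute-force position scan exists in the test suite and the
  two are required to agree exactly. The median is computed on
  strand-summed coverage because RPA binding is strand-resolved only
  near the DSB. A degenerate median of zero is an error rather than a
  silent threshold of zero.
* `intersect_across_samples()` / `reference_peaks()` — peaks must be
  present in every sample. The retention rule needs an anchor, which the
  published description leaves open; the package slices the pooled
  (summed) coverage of all samples as the anchor and keeps anchor peaks
  overlapping (≥ 1 bp) a peak of every individual sample. Pooling
  maximizes stability; the overlap rule follows the published wording
  literally.
* A DSB **exclusion window** (default ±50 kb, configurable) prevents
  DSB-proximal RPA signal from being selected as a normalization
  reference — reference peaks must be DSB-independent.
* `rpa_normalize()` — the scale factor is the *mean* strand-summed
  coverage over all reference-peak positions. The published analysis
  does not name its statistic; the mean is the simplest
  scale-equivariant choice, and scale invariance of the normalized track
  is asserted to 1e-12.
* `rpa_window_profile()` — ±25-kb windows around the DSB, 500-bp bins by
  default. The published curves are near base-resolution; binning exists
  to give stable desk-scale summaries.
* `estimate_resection_front()` — a summary statistic for
  parameter-recovery tests: scanning the degraded strand's bins outward
  from the DSB, the first linear-interpolation crossing of ratio 0.5.
  With cut efficiency `c` and tract CDF `F`, the ratio at distance `d`
  is `1 - c + c * F(d)`, so the 0.5 crossing equals the *median tract
  length over all cells including uncut ones* — which is exactly the
  quantity the recovery tests compare against. If the ratio never drops
  below 0.5 there is no front to report and the estimate is `NA`.

## qPCR computations

**Restriction protection.** An unresected locus contributes 2
amplifiable strands in the undigested tube and none after digestion; a
locus whose restriction site has become ssDNA contributes its 1
surviving 3' strand in both tubes. With
`ddCt = (Ct_dig - Ct_undig)_site - (Ct_dig - Ct_undig)_control`, the
digested:undigested template ratio is `r = 2^(-ddCt) = f / (2 - f)`,
giving

```
f = 2 / (2^ddCt + 1)
```

The formula is derived, not copied: the original protocol defers to its
own methodological reference and never prints it. A digested-tube Ct at
the cycle cap (no amplification) reports `f = 0`. Replicate scatter is
propagated by the first-order delta method, which makes the reported SD
shrink as `1/sqrt(replicates)` — a property the tests verify by
simulation. An optional division by the measured HO cut fraction (only
cut molecules can resect) is provided but **off by default**, because
whether that correction was applied in the source analysis is not
stated.

**Cut efficiency.** An amplicon spanning the HO site loses template in
cut cells; relative to the uninduced sample and a control amplicon, the
surviving fraction is `2^(-ddCt)` and the cut fraction its complement,
clipped to [0, 1].

**Gene conversion.** Each primer pair gets a least-squares calibration
of Ct against `log10(quantity)`; the amplification efficiency follows
from the slope (`10^(-1/slope) - 1`, exactly 1 at the textbook slope of
−3.3219 cycles per 10-fold dilution). The relative recombination rate is
the ratio of the calibrated quantity of the recombination-specific
amplicon to that of a control amplicon on another chromosome. Replicates
are averaged on the Ct scale (the common convention; averaging on the
quantity scale is available as an option), and Ct values outside a
curve's calibrated range are flagged but still quantified.

## Fluctuation analysis

The Luria–Delbrück experiment estimates a per-division recombination
rate from the distribution of recombinant counts across parallel
cultures (7–8 per strain in the motivating experiments). The package
implements the Ma–Sandri–Sarkar (MSS) recursion

```
p_0 = exp(-m)
p_r = (m / r) * sum_{i=0}^{r-1} p_i / (r - i + 1)
```

and maximizes the resulting likelihood over `log m` (Brent-style
one-dimensional optimization), with an explicit boundary case: all-zero
counts give `m = 0` with a one-sided likelihood-ratio interval.
Confidence intervals come from the likelihood-ratio bound (log-likelihood
drop of 1.92 at 95%). Counts at or above `r_max` (default 10⁴) are
pooled into a tail bin `P(R >= r_max)`, which keeps jackpot cultures
from forcing unbounded recursions. The recursion is O(r_max²) and is the
one numerical kernel implemented in C++.

Two numerical facts matter and are asserted by tests. First, the
distribution is heavy-tailed, `p_r ≈ m / (r (r + 1))`, so a truncated
sum falls short of 1 by approximately `m / (r_max + 1)`
(`ld_tail_mass()`); completeness of probability mass is therefore
checked as *truncated sum + analytic tail*, which closes to 1 within
1e-6 at `r_max = 10⁴`, rather than as the raw truncated sum, which
cannot. Second, the rate is `m / Nt` with the interval scaled
identically; no plating-fraction correction is applied by default (the
original analysis plated dilutions but the tool settings are unknown),
though a plating fraction can be supplied.

**Simulator growth model.** `simulate_fluctuation()` defaults to a
per-division model: mutations are `Binomial(nt - n0, mu)` over the
culture's divisions, each mutation is assigned a uniformly drawn
division (the population size `s` at which it arose), and the clone then
grows deterministically to `floor(nt / s)` cells. This mechanistic model
reproduces the classic clone-size law `P(size = j) = 1/(j (j + 1))` and
hence exactly the MSS distribution that `estimate_m()` assumes, with
`P(0 mutants) = (1 - mu)^(nt - n0) ≈ exp(-mu nt)`. A synchronous-doubling
variant (whole-culture doublings with binomial mutation among new cells)
is kept as an option; it shares the zero-class probability but places
clone sizes on powers of two, so it is *not* MSS-distributed and is
inappropriate for calibration checks — the default was chosen so that
the simulator and the estimator refer to the same distribution, which a
chi-squared goodness-of-fit test in the suite confirms at 10⁵ cultures.

## Numerical choices and degenerate inputs

* All randomness flows through explicit `seed` arguments; the caller's
  RNG state is saved and restored, and identical seeds are bit-identical.
* Masked ratio positions propagate as `NA` through binning; a fully
  masked bin is masked, and front estimation drops masked bins.
* `IRanges::slice()` thresholds are inclusive (`coverage >= 6 × median`),
  matching the brute-force oracle's `>=`.
* The thinned-Poisson closed-form check renders the uninduced
  denominator noiselessly: with a Poisson denominator the ratio
  estimator carries an `E[1/Y]` bias of order `1/depth` (~2% at 50×)
  that the 3-SD budget of the check does not include; with an exact
  denominator, `1 - ratio` is an unbiased thinned-Poisson estimate of
  the truth's survival function.
* Out-of-range Ct, non-doubling calibration slopes, empty peak sets,
  all-zero coverage and out-of-bounds intervals all raise immediate
  errors naming the offending record.

## Problem sizes

The validation suite runs entirely on synthetic data built at call time:
200-kb genomes, populations of 10–10,000 cells, 20 seeded pipeline
replicates for the coverage checks, 1,000 random tracks for the
peak-finder equivalence, 10⁴–10⁵ cultures for the fluctuation checks.
These sizes were chosen so each property is measured with comfortable
statistical margin while the whole suite stays desk-scale.

## What the simulator does and does not emulate

It emulates incomplete cutting, per-cell tract-length heterogeneity,
strand-specific coverage loss and RPA gain, DSB-independent background
peaks, Poisson counting noise, qPCR template counting with Gaussian Ct
noise and a no-amplification cap, and Luria–Delbrück culture growth. It
does **not** emulate mappability structure, GC or fragment-length bias,
ChIP pull-down variability, chromatin context, repair of the break, or
resection-speed changes over time. Passing the recovery tests therefore
demonstrates that the *computations* are correct and internally
consistent at realistic signal-to-noise — not that real libraries are
free of the biases the model omits; on real data those biases are
partially absorbed by the t0 division and the reference-peak
normalization, but not measured here.

## Known limitations

* The resection front is a population summary; it does not identify
  bimodal resection subpopulations.
* The MSS likelihood ignores differential fitness of recombinants and
  phenotypic lag; rates from strains where those matter will be biased
  in the same way as any MSS-based tool.
* BED score filtering stands in for mapping-quality filtering because
  alignment is out of scope; the two agree only if the upstream aligner
  wrote MAPQ into the score column.
* qPCR delta-Ct arithmetic assumes the site and control amplicons share
  amplification efficiency (the calibration-curve path handles the case
  where they do not).
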