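---
title: "Estimating mosaic loss-of-Y cell fractions from array intensities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mosaic loss-of-Y cell fractions from array intensities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mloycf)
```

## The problem

Mosaic loss of the Y chromosome (mLOY) is the most common age-related
chromosomal mosaicism in men: a fraction of circulating leukocytes loses
chrY entirely while the rest keep it. Two array-intensity signals can
reveal it. The B-allele frequency (BAF) of heterozygous variants in the
PAR1 pseudoautosomal region — diploid in males, one copy each from chrX
and chrY — splits symmetrically around 0.5 when a cell subpopulation has
lost the Y haplotype. And the Log2 R ratio (LRR) of probes in the
male-specific Y region (MSY) drops as Y copy number falls below one.

Phase-aware BAF analysis is the more sensitive route, but it needs enough
PAR1 heterozygotes; several widely deployed arrays carry fewer than 35
PAR1 SNPs, of which a handful are heterozygous in any one man. This
package implements the intensity route that works on those platforms —
the MSY median LRR — together with a phase-free BAF-deviation estimator
so the two can be compared wherever both regions are covered.

## Model and conversions

LRR relates observed to expected copy number. A one-copy loss from the
diploid state should give LRR = log2(1/2) = −1, but on real arrays it
registers around −0.45, so LRR is rescaled by that empirical factor:

$$\mathrm{CN}_{obs} = \mathrm{CN}_{exp}\cdot 2^{\mathrm{LRR}/0.45}$$

For the MSY of a normal male, $\mathrm{CN}_{exp}=1$; with a fraction $CF$
of cells lacking the Y the observed copy number is $1-CF$, so the median
LRR over MSY probes (written mLRR_Y) converts as

$$CF = 1 - 2^{\mathrm{mLRR\_Y}/0.45}.$$

In PAR1, a heterozygote's BAF deviates from 0.5 by
$Bdev = \tfrac{CF}{4-2\,CF}$, inverted as $CF = \tfrac{4\,Bdev}{1+2\,Bdev}$.
`cn_from_lrr()`, `cf_from_mlrry()`, `mlrry_from_cf()`, `cf_from_bdev()`
and `bdev_from_cf()` implement these maps; `reference_table()` tabulates
the CF curve (default grid 0 to −4.5 in 0.01 steps — any grid reproduces
the published lookup table functionally, since the curve is closed-form).

The scale factor is a parameter defaulting to 0.45 rather than a hard
constant, because that value is an empirical approximation of the
one-copy-deletion mean, not an identity. `cf_from_mlrry()` deliberately
returns the raw value — negative when mLRR_Y is positive — because the
caller uses the sign to exclude samples whose LRR shows no loss;
`cf_from_mlrry_clamped()` truncates to $[0,1]$ for reporting.

## The caller

Per sample, `call_sample()`:

* computes mLRR_Y as the median of non-missing LRR over MSY probes,
  withheld below `min_msy_probes` (default 30: below roughly that
  coverage the median is no longer a stable summary);
* calls mLOY when mLRR_Y ≤ −0.15, inclusive at the boundary. The
  threshold corresponds to a detection floor of
  $1-2^{-0.15/0.45}\approx 20.6\%$ CF — losses below it are invisible to
  the LRR route in expectation;
* reports the clamped CF when mLRR_Y ≤ 0, and flags `positive_mlrry`
  otherwise (a sample whose LRR indicates no loss has no meaningful
  LRR-route CF; we include the boundary because a CF of exactly 0 is a
  valid estimate);
* estimates Bdev as the median of |BAF − 0.5| over PAR1 probes genotyped
  AB, withheld below `min_par1_het` (default 30). This is a phase-free
  surrogate for the phased-haplotype deviation statistic: it reads the
  split between the two heterozygote BAF bands directly, which is the
  quantity a reviewer reads off a BAF plot. It cannot detect the very
  low fractions phased analysis can, and it is biased low once genotype
  miscalling truncates the bands (see below);
* computes QC metrics applied as flags, never as silent drops: call rate
  (non-missing genotype fraction; flag below 0.97), the lag-1
  autocorrelation of autosomal BAF deviations in genomic order (flag
  above 0.03 — white-noise BAF gives values near zero while wave
  artifacts induce serial correlation; this is a stated surrogate for
  the upstream pipeline's `baf_auto` statistic, whose exact definition
  is not published, and precomputed values can be used instead), and the
  relative PAR1 copy number $2\cdot 2^{\mathrm{medLRR}_{PAR1}/0.45}$
  (flag at ≥ 2.5). The published event-size filter (> 2 MB) is satisfied
  by construction for whole-chromosome Y loss.

Heterozygosity is taken from the genotype column rather than re-derived
from BAF, precisely because genotype miscalling at high CF is a failure
mode the package must reproduce, not mask. Absence of an estimate
is always distinct from a negative call, with an enumerated reason.

## Method agreement

`pair_samples()` keeps samples with both CF estimates and mLRR_Y < 0
(positive values would imply a negative LRR-route CF), logging exclusion
counts by reason. `r_squared()` is the squared Pearson correlation of the
raw pairs — the statistic behind the published scatter plots; whether
those were Pearson or regression $R^2$ is unstated, and Pearson-squared
is used here and documented. `bin_summaries()` sorts pairs by mLRR_Y
(ties broken by sample ID for determinism), splits them into equal-size
bins (sizes differing by at most one, remainder distributed from the
first bin), and summarises min/max/median/mean of both estimates per
bin. Correlating bin medians suppresses independent per-sample noise, so
the binned-median R² systematically exceeds the pairwise R² — the
motivation for binning in cohort comparisons.

## The simulator

`simulate_cohort()` generates probe-level cohorts with known truth. Its
defaults are the study conditions of the platforms that motivate the
method: 397 MSY probes (the coverage of the PAR1-poor array the LRR
route rescues) and 434 PAR1 probes (the coverage of the denser platform
used for the method comparison). Per sample with true fraction $CF$:

* MSY LRR ~ Normal$(0.45\log_2\max(1-CF,\ \texttt{cn\_floor}),\ \sigma_{LRR})$;
* PAR1 probes are heterozygous with probability `het_fraction` (0.3, a
  typical SNP-array heterozygosity); true-het BAF is
  $0.5\pm Bdev(CF)$ plus Normal$(0,\sigma_{BAF})$ noise with equiprobable
  band sign; homozygote BAF sits near 0/1 plus noise; everything is
  clipped to $[0,1]$; the reported genotype is AB iff observed BAF falls
  in `het_call_band` (default $[0.15, 0.85]$), else AA/BB by proximity;
* autosomal probes (default 10,000) carry LRR noise around 0 and BAF
  bands at 0/0.5/1 under Hardy–Weinberg proportions; only QC reads them,
  and the count is large enough that the autocorrelation statistic's
  $1/\sqrt{n}$ sampling noise sits well inside its 0.03 cutoff, as on a
  real array;
* females are simulated at CF 1 with Y copy number `cn_floor` and no Y
  genotype calls; their PAR1 is ordinary diploid X–X territory with no
  BAF deviation, so the truth table reports `expected_bdev = NA` for
  them (the male formula would nonsensically give 0.5);
* `cn_floor` models residual background intensity at zero Y copies. The
  default 0.005 puts a noiseless female at mLRR_Y ≈ −3.44, inside the
  observed female range (−3.3 to −4.11 across platforms); it is
  configurable, and 0.0062 reproduces the −3.3 platform median exactly.

Noise magnitudes for the source arrays are not published;
$\sigma_{LRR}=0.15$ and $\sigma_{BAF}=0.03$ are calibration knobs chosen
to give realistic-looking signal (MSY median s.e. ≈ 0.0094 at 397
probes), not measured values. LRR noise is Gaussian and
probe-independent — real arrays show GC waves, but the method consumes
only the MSY median, which is robust to symmetric noise, so passing
simulation tests demonstrates correctness of the estimator arithmetic
and its asymmetries, not robustness to structured artifacts. BAF on MSY
probes is not simulated (hemizygous BAF is unstable on real arrays and
the method never reads it).

`miscall_rate()` gives the closed-form Gaussian-tail probability that a
true heterozygote is called homozygous, against which the simulator's
empirical miscall frequency is verified. This mechanism reproduces the
two documented failure regimes: below the 20.6% floor the LRR call
misses while Bdev still registers; at CF ≥ 0.9 the BAF bands leave the
AB window, the BAF route starves (too few AB calls), and the LRR route
alone recovers the fraction.

## Numerical choices

Medians use the midpoint of the two central order statistics for even
counts. Display rounding is half-even to 3 decimals; internal math is
full precision. The reference-table grid is built by index
(`max − step·k`, rounded at the 12th decimal) so printed grid values are
exact. Degenerate inputs error early: empty grids, `cf = 1` in the
log-inverse, out-of-domain Bdev, non-finite LRR. `r_squared()` refuses
fewer than 3 pairs or zero variance rather than returning NaN.

## Problem sizes used in validation

The shipped tests exercise: cohort recovery at 397 MSY probes,
$\sigma_{LRR}=0.15$, 100 samples per CF level over the grid
$\{0, 0.1, \ldots, 0.9\}$, 20 replicate seeds (mean CF per level within
±0.02 of truth); the binning advantage over 50 replicate cohorts of 150
samples at 100 probes per region; and the failure regimes on cohorts of
40–60 samples at full probe counts. These sizes give comfortably
powered checks of the properties at stake; the estimators themselves are
O(probes) and run on cohorts of any size.

## Limitations

The phase-free Bdev estimator is not the phased statistic: it cannot see
sub-percent cell fractions and underestimates once band truncation sets
in, exactly as the plot-read values it mimics. Only GRCh38 region
coordinates ship built in (PAR2's published X-labelled coordinates match
the chrY PAR2 interval and are applied to chrY; a region file overrides
this). No liftover, no idat parsing, no haplotype phasing, and no
segmentation of partial-chromosome events: the caller targets
whole-chromosome Y loss.
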