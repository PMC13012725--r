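---
title: "Detecting nucleation barriers in DAmFRET data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting nucleation barriers in DAmFRET data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(damfret)
```

## The measurement and the two regimes

Distributed amphifluoric FRET (DAmFRET) expresses a protein of interest as a
fusion to a photoconvertible fluorophore in a population of cells, partially
photoconverts the fluorophore so every cell carries donor and acceptor
forms, and records for each cell the acceptor intensity (a proxy for
concentration, in procedure-defined units, p.d.u.) and the ratiometric FRET
value AmFRET = FRET intensity / acceptor intensity, which reports
self-association. Because expression varies log-normally over orders of
magnitude across cells, one sample traces out an entire
concentration-response curve of self-assembly.

Two physical regimes produce qualitatively different AmFRET-versus-
expression relationships. A protein that assembles as soon as it exceeds
its saturation concentration (`C_sat`) shows a *continuous* relationship:
every cell sits on one curve. A protein whose assembly is limited by a
sequence-encoded nucleation barrier remains soluble (low AmFRET) well above
`C_sat` until a stochastic nucleation event, after which the cell jumps to
the assembled branch; across a population this produces a *discontinuous*,
bimodal relationship in the supersaturated concentration window. Detecting
that bimodality, and quantifying how far the soluble state persists above
`C_sat`, is the purpose of this package.

## The assembled-branch model

The mean AmFRET of assembled cells as a function of concentration `c` is
modeled as a stretched exponential (Weibull) saturation curve,

$$\mathrm{AmFRET}(c) = Amp\left[1 - e^{-\ln 2\,(c/C50)^a}\right],$$

with plateau `Amp` (dimensionless AmFRET units), half-plateau concentration
`C50` (p.d.u.) and steepness `a` (dimensionless, constrained to
[0.1, 10]). By construction `AmFRET(C50) = Amp/2` exactly; the `ln 2`
factor makes `C50` the *median* rather than a rate parameter. Fitted to a
seeded sample — in which a constitutive template removes the nucleation
barrier so every cell assembles at its thermodynamic threshold — `C50`
approximates `C_sat`. Fitted to an unseeded sample of a nucleation-limited
protein, `C50` instead tracks the median spontaneous-nucleation
concentration. The ratio `C50_stochastic / C50_seeded` ("fold reduction of
C50 by seeding") quantifies supersaturability; it is computed only within
one batch because the acceptor scale is instrument-run specific.

## Pipeline stages and their parameters

**Gating and binning.** Events pass a singlet gate (FSC-A vs SSC-A and
FSC-H vs FSC-W; doublets have roughly twice the singlet width) and an
expression gate (donor above an autofluorescence-conditional boundary).
Gating-space coordinates may be viewed under a logicle transform
(defaults T = 262144, W = 0.5, M = 4.5, A = 0, the conventional cytometry
values; an arcsinh alternative is provided) — but binning, medians and all
fits operate on raw intensities; the transform is display/gating geometry
only. Profiles use 64 logarithmically spaced acceptor bins (constant log10
step) over a range fixed per experiment; the default range spans the 1st
to 99.9th percentile of the pooled control-plus-sample acceptor values.
Bins are half-open `[lo, hi)`, so a cell exactly on an interior edge
belongs to the upper bin. Cells with non-positive acceptor are flagged and
excluded (AmFRET is undefined and log bins require positivity).

**The fgate statistic.** A monomer control (the fluorophore alone) defines
the no-assembly region: in each bin, the 99th percentile of the control's
AmFRET (linear-interpolation quantiles, R type 7 — pinned so the gate is
reproducible). Sample cells strictly above their bin's threshold are
FRET-positive; `fgate` is the fraction of binned cells above the gate. By
construction a control measured against its own gate yields roughly 1%
positives, so `fgate` values at or below ~0.02 are indistinguishable from
no assembly.

**Continuity classification.** Per sample: (1) log10-acceptor is re-binned
by Scott's rule (width `3.49 s n^{-1/3}`); (2) bins are kept only with at
least 20 cells, density (count / AmFRET IQR) at least 500, and at most 25%
Tukey-fence outliers (fences at 1.5 IQR — "outlier" needed a concrete
pinned definition and this is the standard one); (3) per-bin median AmFRET
is bootstrap-resampled 100 times within bins (resampling cells, not bins,
preserves the expression design), each replicate is denoised with a
zero-phase forward-backward 2nd-order Butterworth low-pass at normalized
critical frequency 0.1, and the final curve is the pointwise mean of
replicates; (4) the transition point is the argmax of the first
finite-difference derivative, the transition range is bounded by the
second-derivative extrema before/after it, with per-bootstrap landmarks
summarized by medians; (5) Hartigan & Hartigan's dip test is applied to
the raw per-cell AmFRET of all cells with acceptor inside the transition
range. `p < 0.05` classifies the sample as discontinuous. Otherwise the
spline's minimum and ending values are compared with a reference AmFRET
level to sub-classify continuous profiles as low (both below), high (both
above) or low-to-high. Replicates combine by majority vote.

Choices worth spelling out:

* *Dip-test calibration.* The null distribution is simulated: dips of
  uniform(0, 1) samples of the same size (10,000 draws by default for the
  standalone test; 1,000 inside the classifier, where the p-value only
  needs to resolve the 0.05 boundary). Monte-Carlo calibration is exact at
  any n and reproducible under a seed, unlike interpolation tables. Sorted
  uniform samples are generated directly from normalized cumulative
  exponential spacings. The dip statistic itself is computed in compiled
  code by the classical iterative convex-minorant/concave-majorant
  algorithm and is validated in the test suite against closed-form values
  (two equal point masses give dip 0.25; a uniform grid attains the
  1/(2n) lower bound) and against an independent slow oracle that bisects
  the feasibility of a unimodal CDF within a sup-norm band of the
  empirical CDF.
* *Dip on raw cells.* The test uses raw per-cell AmFRET within the window,
  not bin aggregates: bimodality is a per-cell property and aggregation
  would discard it.
* *Low-pass filter.* Only "zero-phase forward-backward" is contractual;
  the 2nd-order Butterworth at 0.1 is a pinned constant of this pipeline.
  The series is extended by odd-periodic reflection (100 samples each
  side) before filtering so that constants and linear trends pass through
  unchanged and start-up transients never reach the data.
* *Reference AmFRET.* The low/high boundary is the AmFRET level where a
  high-FRET state begins. In real experiments this comes from a control
  construct's transition start. The synthetic monomer control has no
  transition, so its analogue is a robust upper bound of the control's
  AmFRET distribution, median + 4 MAD (about 0.2 with the default noise
  SD of 0.05).
* *Derivative ties and flat curves.* Ties in the argmax (within
  floating-point jitter) break to the smallest index and are flagged; a
  flat fitted curve has no transition and is classified continuous by its
  level alone.

**C50 fitting.** The average DAmFRET curve takes the mean AmFRET of bins
holding at least 100 cells. Because curve tails are dominated by noise and
compensation artifacts, the fit uses a window. Analysts often choose such
windows by eye; here an automated surrogate performs that step so the fit
is reproducible: the window starts one bin before the curve first exceeds
the baseline (median of the first three bins) by 3 MAD, and ends where the
Gaussian-smoothed slope falls below 5% of its peak. All window parameters
are pinned constants, and the heuristic is validated by parameter-recovery
tests rather than by any claim of equivalence to visual inspection.
Initial values come from a Gaussian-smoothed curve; `Amp` and `C50` are
bounded within twofold of their guesses, `a` within [0.1, 10]; the loss is
plain least squares. Parameter errors come from Monte-Carlo refits of the
fitted curve plus resampled residuals (100 by default) — residual
resampling was chosen over a parametric noise model because no noise model
is part of the contract.

**Screen hit-calling.** Records failing quality control (fewer than 2500
mEos-positive events, or mean acceptor below 3.5 p.d.u.) are dropped, then
any DFD or seed retaining under 25% of its original instances is removed
entirely. C50 and fgate are standardized per experimental batch (mean 0,
variance 1, sample SD); directional outlier degrees are computed per DFD
as IQRs below the median (C50) or above it (fgate); seedability is their
mean; hits are records at or above mean + 3 SD of all seedability values
(global threshold — a per-DFD option exists). Replicate consistency is the
percentage of pairs with concordant hit flags, with a Wald binomial CI
(the Wald form reproduces the reported interval arithmetic; Wilson is
available), and a Pearson correlation of seedability in which
double-negative pairs can be excluded. Seedability matrices cluster with
Ward's variance-minimization linkage on log10(max(x, 0) + 1), rows and
columns independently; missing cells impute as zero seedability (absence
of evidence of seeding) before the transform.

**Morphology.** Objects classify by pixel-intensity CV (= 100 SD/mean) and
aspect ratio with strict-inequality threshold rules, applied in order
fibrillar, punctate, diffuse. The thresholds leave gaps (exact
boundary values; CV below threshold with high AR) and a sliver of overlap
(AR between 1.159 and 1.16); rather than invent a rule, uncovered
combinations stay "unclassified" and are reported separately, and the
overlap resolves by rule order. Group-versus-pooled-frequency association
uses an exact multinomial test (full enumeration of compositions up to
n = 200, seeded Monte-Carlo beyond, ties counted into the tail) with
Bonferroni adjustment across groups. Expected counts are reported at one
decimal using round-half-even.

**Networks and lifespan.** Physical-interaction subnetworks keep edges
with STRING-style scores of 900 or higher, deduplicated and loop-free;
proteins with several DFDs are discontinuous/seedable if any DFD is.
Degree centrality is degree/(n-1); betweenness is normalized shortest-path
betweenness with even splitting over equal-length paths (undirected
normalization 2/((n-1)(n-2)) — the common library default, pinned here).
Group comparisons use the Mann-Whitney U test (exact for small untied
samples, tie-corrected normal approximation otherwise). The
supersaturation-lifespan analysis computes, per cell type, each adaptor's
transcript/C_sat ratio, takes the geometric mean across the five adaptors
(non-positive proxies drop the cell type with a warning — a declared
choice, since zero-transcript handling is not contractual), and fits
lifespan against the proxy by ordinary least squares in log10-log10 space
(a power law) with a 95% confidence band, plus a Spearman rank correlation
(exact p for small n without ties via the standard R implementation, t
approximation otherwise).

## What the synthetic generators emulate — and what they do not

All validation runs on synthetic data with planted ground truth, because
raw screen cytometry is not redistributable at package scale. The
generators encode the statistical structure the analysis assumes:

* `simulate_events()` draws log10-normal expression (default mean 2,
  SD 0.6 — several decades of spread centered near the transition, as the
  assay is designed to achieve) and one of four AmFRET regimes: monomer
  (Gaussian noise at zero), continuous (hyperbolic rise,
  `amp·c/(K + c)`), discontinuous (per-cell nucleation with probability
  `1 − exp(−ln2 (c/c50_stochastic)^a)`, nucleated cells on the Weibull
  assembled branch — the same branch seeded cells follow, so seeded and
  stochastic datasets share one assembled manifold), and seeded (all cells
  on the branch). The default discontinuous condition plants
  `c50_stochastic = 4 × c50_seeded`, a fourfold supersaturation window.
* The four-member study panel (`damfret_panel_models()`) fixes the
  conditions used throughout validation: monomer noise SD 0.05;
  continuous with plateau 0.3 and noise SD 0.1 (a gradual, low-plateau
  rise — the regime where continuous and discontinuous data are hardest
  to tell apart without being degenerate); discontinuous with plateau
  0.6, `C50_seeded` 100, `C50_stochastic` 400, steepness 2; and a deeply
  seeded construct with `C50_seeded = 1`, below the observable expression
  range, so that every expressing cell sits on the assembled branch and
  the profile reads "continuous high". 50,000 cells per dataset matches
  the scale of a typical well after gating.
* `simulate_screen()` draws per-DFD baselines with additive batch shifts
  on the standardized scale (the simplest structure that exercises
  per-batch standardization) and plants hits as shifts of C50 down and
  fgate up in units of the baseline IQR; two negative-control seeds per
  DFD are always present.
* Morphology objects draw CV and AR from truncated normals that must sit
  strictly inside one decision region; interaction graphs plant hub nodes
  on an Erdős–Rényi background plus sub-threshold decoy edges; the
  expression-lifespan table applies multiplicative log-normal scatter
  around an exact power law, with transcript levels and C_sat stored
  separately so the proxy must be computed downstream.

What the generators do *not* emulate: instrument-specific spectral
spillover and compensation error, autofluorescence structure beyond a
log-normal channel, acceptor-dependent noise (noise SD is constant in
AmFRET units), cell-cycle or viability substructure, batch drift within a
run, or the unknown true shape of the cellular expression distribution
(log-normal is an assumption of convenience, not a fidelity claim).
Passing tests therefore demonstrate that the algorithms recover the truth
under the assumed statistical structure — not that the structure matches
any particular instrument.

## Numerical choices and degenerate inputs

One quantile definition (linear interpolation, type 7) is used everywhere
a quantile appears — control gates, IQRs, Tukey fences, screen outlier
degrees — so every threshold is reproducible to the digit. Zero IQR counts
as a density pass in the bin filter (a zero-spread bin is maximally dense)
but makes outlier degrees undefined (flagged, not silently zero).
Hit-calling with zero seedability spread is degenerate: no hits, flagged.
Weibull fits that fail to converge report their parameters with
`converged = FALSE` rather than erroring; supersaturability warns when
built from them. Fewer than 4 quality bins, an empty transition window, or
fewer than 4 window cells yield an explicit "insufficient data"
classification. All generator and analysis randomness flows through
explicit integer seeds; fixing the seed fixes every output byte.

## Problem sizes used in validation

The bundled validation (test suite and `scripts/acceptance.R`) uses the
study conditions directly: 20 independent seeds of the four-model panel at
50,000 cells each for classifier accuracy and type-I error; 20 seed pairs
of seeded/unseeded datasets for C50 and fold-reduction recovery; one
100 × 100 screen with 20 planted six-IQR hits plus fifty 20 × 20 null
screens for the hit-caller's operating characteristics; 1,000 uniform
samples of size 500 against a 10,000-draw null for dip-test calibration;
and exhaustive small-n enumeration for the exact-test oracles. The
end-to-end demonstration pipeline (`run_pipeline()`) defaults to 5,000
cells per dataset, which preserves every qualitative behavior at a few
seconds' runtime.

## Known limitations

* FCS 3.0 files are not read directly; events are consumed as CSV tables
  (the interchange schema is documented in `load_events()`).
* The automated fit window is a surrogate for expert curve inspection;
  on pathological curves (non-monotone plateaus, double rises) it may
  bracket the wrong feature — fits carry their window so this is
  auditable.
* The dip test's Monte-Carlo null makes classification p-values
  seed-dependent at the resolution of `1/n_mc`; at the 0.05 decision
  boundary this is negligible for the defaults but users comparing
  p-values across runs should fix the seed.
* `C_sat` and supersaturability are reported in procedure-defined units;
  no absolute molar calibration is attempted.
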