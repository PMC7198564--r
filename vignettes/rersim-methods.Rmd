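---
title: "Models and methods behind rersim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rersim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rersim)
```

## The question the simulation answers

A rapid event-related (rER) design switches conditions on a timescale
comparable to, or faster than, the hemodynamic response itself. Under
the linear-systems view of fMRI, the measured regressor for any
stimulus schedule $s(t)$ is $(s * h)(t)$ sampled at the TR, so the
impulse response $h$ acts as a temporal filter: effect energy at
stimulus frequency $f$ is transmitted in proportion to $|H(f)|^2$.
The BOLD kernel is fast but small; the MION (iron-oxide blood-volume)
kernel is roughly 1.8 times taller at its peak but much wider, hence a
stronger low-pass filter. Whether MION's amplitude advantage survives
its temporal smoothing at event-related frequencies is a quantitative
question about $|H(f)|^2$, and `rersim` answers it per frequency bin.

## Impulse-response models

All kernels are gamma-family, sampled at `dt = 0.1` s over 60 s (which
contains more than 99.9% of both responses' mass) and represented
magnitude-only: the physically negative MION signal change is stored
as a positive response, since only squared amplitude enters every
comparison.

- **BOLD** (`boldBoynton()`): $h(t) = ((t-\delta)/\tau)^{n-1}
  e^{-(t-\delta)/\tau}$ with defaults $n = 3$, $\tau = 1.2$ s,
  $\delta = 0$, peak-normalized to 1. The analytic mode is
  $\delta + (n-1)\tau = 2.4$ s and the argmax of the sampled kernel is
  required (and tested) to match it within one grid step.
- **MION** (`mionModel()`): a gamma density with mean lag 6 s and SD
  4.5 s, amplitude-scaled so the peak equals the configurable ratio
  `peakRatio` (default 1.8, the conventional MION/BOLD peak-amplitude
  assumption at equal noise). The shape constraints that define a
  credible MION kernel — peaking later than BOLD, wider at half
  maximum, taller at the default ratio — are asserted in the test
  suite rather than hard-coded.
- **Macaque HRF** (`gammaHRF()`): gamma density parameterized by its
  first moment (3 s) and SD (1.5 s), i.e. shape $(m/s)^2 = 4$ and
  scale $s^2/m = 0.75$ s, reflecting the faster macaque BOLD response
  used in the GLM stage.

**Calibrating the MION shape.** The MION literature gives the kernel's
qualitative shape but no single canonical parameterization, so the
mean/SD pair here is a deliberate calibration choice. The spectral
tail of a gamma density falls as $|H(f)| \sim f^{-k}$ with
$k = (m/s)^2$, so the SD controls how much high-frequency energy the
kernel transmits relative to its area. With mean 6 s, an SD of 4 s
($k = 2.25$) loses per-bin dominance at the top of the evaluated band
already at a peak ratio of 1.6, while an SD of 4.5 s ($k \approx 1.78$,
a heavier spectral tail) keeps the kernel later and wider than BOLD
and sustains dominance down to a ratio of 1.3 — reproducing the
published robustness margin of 1.5 for this class of simulation. The
default is therefore mean 6 s / SD 4.5 s, both overridable.

**Onset surgery.** Two transforms make the comparison conservative
with respect to MION:

- `spliceSmoothOnset()` replaces the MION rise with the BOLD rising
  limb, time-rescaled so its peak lands at the MION peak time and
  amplitude-rescaled to the MION peak. Among the possible readings of
  "replace the onset" this one guarantees continuity at the splice
  point, preserves the peak exactly, and is idempotent.
- `smoothOnsetVariant()` convolves with a unit-sum raised-cosine
  (Hann) kernel of total width `width` (default 1 s in the packaged
  workflows), supported on $[0, \mathrm{width}]$ so the smoothed
  kernel stays causal and exactly zero at $t = 0$, then renormalizes
  the peak. The same width is always applied to both kernels when they
  are compared; the induced half-width delay is common to both and
  does not affect power spectra. The Hann kernel was chosen for its
  compact support and smooth spectral roll-off; the width is a free
  parameter and the dominance threshold is tested as an inequality
  (≤ 1.5), not an equality, precisely because the published analyses
  do not pin the smoothing width down.

Peak metadata uses the earliest maximal sample as the tie-break.

## Designs and convolution

`rapidERSchedule()` emits one trial per image (48 by default, 0.5 s
stimulus + 2.5 s ISI) plus 30 null trials in a seeded random
permutation. The per-run arithmetic (117 volumes at TR 2 s, i.e.
234 s) is consistent with 48 × 3 s stimulus slots only if a null trial
occupies a 3 s slot; the generator therefore defaults to
`nullSlot = 3.0` s — read as 2.5 s of blank null trial inheriting the
0.5 s slot padding of the trial grid — and exposes the parameter. Runs
are padded with trailing blank up to a whole number of TRs.

`convolveSchedule()` builds the (possibly ±1 contrast-weighted) boxcar
on the kernel's fine grid, convolves, and samples at the *end* of each
TR ($t = \mathrm{TR}, 2\mathrm{TR}, \dots$); slice-timing conventions
are out of scope. Convolution is a plain discrete sum, so a single
event one grid-step long returns the kernel itself — a convenient
identity for testing and for the Featquery-style regressor height used
by `percentSignalChange()`.

The alternating fast-switch design (2 s per condition, 4 s period,
0.25 Hz) is the hardest case for a wide kernel: all contrast energy
sits at the Nyquist frequency of a 2 s TR.

## Spectral comparison

`periodogram()` folds the two-sided DFT power into one-sided bins
under the convention $\sum_k P_k = \sum_t x_t^2$ (Parseval, tested to
1e-9), so zero-padding — used to refine the grid to 1/120 Hz —
preserves total power. `fullSpectrumDominance()` compares per-bin
power over $0 < f \le 0.25$ Hz: DC is excluded because mean signal is
not an effect of interest, 0.25 Hz is the Nyquist frequency of the
2 s TR, and ties count as dominance (the claim concerns transmitted
effect energy, not strict ordering). `peakRatioSweep()` exploits that
power scales as the ratio squared, so dominance is monotone in the
ratio; the default granularity of 0.1 matches the reported sweep and
is exposed. When dominance fails even at the largest ratio the sweep
returns an NA sentinel rather than raising.

`contrastSE()` implements $\sigma\sqrt{c^\top (X^\top X)^{-1} c}$ for
i.i.d. additive noise — the "equal additive noise" ground rule of the
comparison. Temporally correlated noise is deliberately not modelled
(see Limitations).

## GLM with behavioural censoring

- **Fixation rule** (`censorBrokenFixation()`): a volume is excluded
  iff strictly more than half of its eye samples (more than 1 s at
  20 Hz / TR 2 s, i.e. > 20 of 40) fall outside the ±5° window.
  Exactly half keeps the volume; the strictness follows the "> 1 s"
  reading and is pinned by a boundary test at 20/40 vs 21/40.
- **Motion rule** (`flagMotionOutliers()`): a volume is flagged iff
  its motion variance strictly exceeds the mean + 2 SD of the series.
  Moments are computed over the run by default (the per-run vs
  per-session choice is ambiguous in practice and exposed to the
  caller by what is passed in). A constant series flags nothing.
- **Design** (`buildDesignMatrix()`): one HRF-convolved column per
  image; events overlapping a fixation-censored volume are removed
  from their condition's boxcar ("not modelled"), whereas motion
  outliers get one-hot nuisance columns — two deliberately different
  mechanisms, mirroring common FSL practice. A condition whose every
  event is censored yields an all-zero column that is flagged, dropped
  from the fit, and reported as NA. High-pass filtering of real data
  is replaced by polynomial drift regressors (default order 1), since
  the synthetic data carry configurable linear drift.
- **Statistics**: OLS per voxel; $t = \beta/\mathrm{SE}$ with SE from
  residual variance; `tToZ()` converts via two-sided sign-preserving
  tail matching computed in log-tail space, so $|t|$ up to 40 maps to
  a finite z (tested against numerical quadrature of the t density).
- **ROI geometry** (`sphericalROIMask()`): all voxels whose centres
  lie within the radius, inclusive; on the 1.5 mm grid a 2 mm sphere
  is the centre plus 6 face neighbours (7 voxels) and a 5 mm sphere is
  tested against brute-force enumeration.

## Crossnobis RSA

Per-fold, the estimator is
$(b_{k,A}-b_{j,A})\,\Sigma_A^{-1}\,(b_{k,B}-b_{j,B})^\top$ with
$\Sigma_A = \frac{1}{T} R^\top R$ from the training half's
concatenated residuals only. Design choices where the procedure is
genuinely open:

- **Within-half aggregation**: available per-condition betas are
  averaged across the half's runs (one GLM per run is fixed; the
  alternative — refitting a concatenated GLM per half — is not
  implemented).
- **Folds**: 50 seeded random split-halves, one random run dropped
  when the count is odd. A condition missing from either half of a
  fold removes its pairs from that fold only; a pair available in no
  fold is NA. Fold assignment is bit-reproducible from the seed.
- **Shrinkage**: with ~150 voxels in a 5 mm sphere and limited
  training volumes, $\Sigma$ can be ill-conditioned, so the default
  blends 10% of the diagonal ($\lambda = 0.1$); $\lambda = 0$
  reproduces the literal formula and raises a clear singularity error
  when the inverse does not exist. With zero-noise data the residual
  matrix is numerically zero, so the packaged workflow switches to the
  identity whitener, under which the RDM reduces to planted squared
  Euclidean distances — the basis of the exact-recovery tests.
- **Units**: distances are not divided by the voxel count; entries are
  squared whitened amplitudes, negative values allowed (unbiased
  estimator). RDM averaging across sessions/hemispheres is entrywise,
  NA-ignoring.

## Synthetic data: what it emulates and what it does not

`generateSession()` draws condition patterns with category structure
(4 categories × exemplars, mimicking a 48-image set of faces, body
parts, objects and places; within-category similarity is controlled by
the ratio of category-level to exemplar-level SD), forms signal as
design × patterns under the macaque HRF, and adds baseline (default
100), optional linear drift, and spatially correlated Gaussian noise
($\mathrm{cov}_{ij} = \sigma^2 e^{-|i-j|/\ell}$, default $\ell = 2$
voxel indices). Broken-fixation volumes are planted at 16.3% and
motion outliers at 3.0% — the mean per-session rates for the
best-sampled animal in the study setting this package emulates — and
the eye traces / motion series are constructed so the censoring
operations recover the planted flags *exactly* (the motion generator
includes a deterministic repair pass for small-sample false positives
and validates itself post hoc). All randomness flows through one
top-level seed from which per-run, per-purpose substreams are derived
with a Lehmer step, so changing one stage's parameters does not
perturb another stage's draws.

What the generator does **not** emulate — and hence what passing tests
do not establish about real data: temporal autocorrelation
(deliberately omitted to match the OLS assumptions), saccade
kinematics and oculomotor dynamics, scanner drift beyond a linear
term, spatial structure beyond exponential falloff in voxel index, and
any nonlinearity or saturation of the hemodynamic response. The
default pattern SDs (0.15 signal units per unit regressor against
noise SD 1) are test-bed calibrations, not empirical claims about
cortical pattern strength.

## Numerical choices and problem sizes

Tolerances: Parseval and convolution identities at 1e-9..1e-12;
zero-noise beta recovery at 1e-8; zero-noise RDM recovery at 1e-6;
Monte-Carlo checks at 3% (10,000 draws) or 3 standard errors;
parameter-recovery smoke tests use 10 runs × 12 conditions × 12 voxels
over 5 seeds with a unit peak-to-noise ratio, and the recovery
correlation threshold (median r > 0.7) is a calibration of this test
bed. The dominance analyses use the 0.1 s grid zero-padded to 120 s.
The packaged GLM→RSA workflow defaults (10 runs, 48 conditions, 60
voxels, 50 folds) run in seconds; tests use smaller sessions chosen to
keep the full suite under a minute while leaving every statistical
check well-powered.

## Known limitations

- The MION kernel is one calibrated gamma shape, not a fit to
  measured blood-volume responses; conclusions are robustness
  statements over the exposed parameters, not kernel estimates.
- OLS with i.i.d. noise throughout; no prewhitening, no AR models.
- Trial censoring interacts with the single-presentation design: a
  censored trial removes that image from the run entirely, which the
  fold-skipping policy absorbs but which reduces effective run counts
  at high censoring rates.
- The percent-signal-change scaling follows the Featquery convention
  (peak of an isolated-event regressor); other conventions rescale
  results by a constant.
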