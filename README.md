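# rersim

Rapid event-related (rER) fMRI in non-human primates is caught between
two contrast mechanisms. The endogenous BOLD signal has a fast impulse
response but low amplitude; the iron-oxide contrast agent MION
(blood-volume weighted) responds with roughly 1.8 times the peak
amplitude but is temporally much wider, which smooths away
high-temporal-frequency effect energy — exactly the frequencies a
fast event-related design lives on. `rersim` provides the
linear-systems machinery to settle this trade-off quantitatively, and
a matching GLM + representational-similarity pipeline for the
condition-rich rER experiments the answer matters for.

The package is aimed at NHP neuroimagers planning event-related
designs, and at methodologists who want a fully synthetic, seeded
test bed for crossnobis RSA with realistic trial censoring.

## What it computes

**Sensitivity simulation.** Hemodynamic impulse responses are modelled
as gamma-family kernels h(t). For BOLD, h(t) = ((t−δ)/τ)^(n−1)
e^(−(t−δ)/τ) (defaults n = 3, τ = 1.2 s), peak-normalized to 1. The
MION kernel is a gamma density (mean lag 6 s, SD 4.5 s) scaled so its
peak equals a configurable ratio r (default 1.8), with its sharp onset
replaced by the BOLD rising limb and, optionally, an additional
raised-cosine onset smoothing applied identically to both kernels
(conservative "smooth onset" variants). A linear time-invariant system
maps any stimulus schedule s(t) to a regressor x = (s ∗ h) sampled at
the TR. Sensitivity is compared three ways:

- effect energy Σ x², of the ±1 contrast time course of a 2 s-switch
  alternating design (TR 2 s);
- the analytic contrast standard error σ·sqrt(cᵀ(XᵀX)⁻¹c) at equal
  additive noise;
- per-frequency-bin periodogram dominance over the band (0, 0.25 Hz]
  (the TR Nyquist), with a sweep that lowers the MION peak ratio in
  0.1 steps until dominance is lost.

**GLM + crossnobis RSA.** Per-run ordinary-least-squares GLMs use one
regressor per image convolved with a macaque gamma HRF (3 s mean lag,
1.5 s SD), one-hot nuisance regressors for head-motion outliers
(variance > mean + 2 SD), and censoring of trials whose volumes show
broken fixation (gaze outside a ±5° window for more than half the
volume, i.e. > 20 of 40 samples at 20 Hz / TR 2 s). Pattern
dissimilarity uses the cross-validated squared Mahalanobis distance

    crossnobis(k, j) = (b_k,A − b_j,A) Σ_A⁻¹ (b_k,B − b_j,B)ᵀ

with Σ_A = (1/T) RᵀR estimated from training-half residuals
(optionally shrunk toward its diagonal), averaged over 50 random
split-half folds (one run dropped when the count is odd). A seeded
synthetic-data module generates every input — ROI voxel time series
with planted condition patterns, eye traces, motion series — with
ground truth the analysis operations recover exactly.

## Worked example

```r
library(rersim)

rep <- runSensitivity()
rep$effect_energy
#> $bold
#> [1] 4152.193
#> $mion
#> [1] 10870.62
rep$contrast_se
#> $bold
#> [1] 0.01552352
#> $mion
#> [1] 0.009601310
rep$threshold_ratio
#> [1] 1.3
```

Even for the fastest design a 2 s TR can carry, the smooth-onset MION
contrast time course carries about 2.6× the effect energy of BOLD, so
the contrast standard error at equal noise is about 0.62× the BOLD
value, and per-bin spectral dominance survives lowering the MION/BOLD
peak ratio from 1.8 down to 1.3 — comfortably below the 1.5 robustness
margin reported for this class of simulation.

```r
res <- runGlmRsa(list(seed = 11, synth = list(nRuns = 6, nVoxels = 20)))
res$rdm
#> RDM: 48 conditions, 50 folds; off-diagonal mean 3.62 (0 NA)
res$qc$censored_fraction
#> [1] 0.1680912
```

The QC fraction is the realized share of censored volumes (planted
rate 16.3%, matching the broken-fixation rates the pipeline is
designed around); the RDM is the fold-averaged crossnobis matrix for
the 48 planted image patterns.

## Package tour

- `boldBoynton()`, `mionModel()`, `gammaHRF()`, `spliceSmoothOnset()`,
  `smoothOnsetVariant()` — impulse-response models and onset surgery.
- `alternatingDesign()`, `rapidERSchedule()`, `blockSchedule()`,
  `convolveSchedule()` — schedules and volume-sampled regressors.
- `periodogram()`, `effectEnergy()`, `contrastSE()`,
  `fullSpectrumDominance()`, `peakRatioSweep()` — sensitivity analysis.
- `censorBrokenFixation()`, `flagMotionOutliers()`,
  `buildDesignMatrix()`, `fitGLM()`, `tToZ()`,
  `percentSignalChange()`, `sphericalROIMask()` — GLM stage.
- `noiseCovariance()`, `crossnobis()`, `splitHalfRDM()`,
  `averageRDMs()` — RSA stage.
- `generateSession()`, `generateEyeTrace()`, `generateMotionSeries()`
  — synthetic data with planted truth.
- `runSensitivity()`, `runGlmRsa()` — end-to-end workflows from a
  single config (list or YAML/JSON file).

See `vignettes/rersim-methods.Rmd` for the modelling assumptions,
parameter calibration and known limitations.
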