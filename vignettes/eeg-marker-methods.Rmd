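---
title: "Methods: resting-state EEG source and connectivity markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resting-state EEG source and connectivity markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(eegmarkers)
```

This vignette documents the models, conventions and numerical choices
behind the pipeline, in the spirit of a methods section: what is computed,
under which assumptions, which knobs matter, and what the synthetic test
bed does and does not establish about real data.

## The analysis model

The pipeline targets a classical question in clinical neurophysiology: how
well do spectral and connectivity features of eyes-closed resting EEG
separate Alzheimer's patients from age-matched controls at the level of a
*single individual*? The core quantities are:

**Band power with shared boundary bins.** Spectra are estimated with the
Welch method on consecutive artifact-screened 2-s epochs, Hann taper,
no overlap and no sub-segmentation. A 2-s epoch gives a 0.5 Hz grid
natively, which is the entire reason for the 2-s choice; sub-segmenting
would destroy that resolution, so the screened epochs *are* the Welch
segments. Band power is the *mean* PSD over a band's bins (a density, so
bands of different widths remain comparable), and a bin on a band boundary
(4, 8, 10.5, 13, 20, 30 Hz) belongs to both neighbours — neighbouring
rhythms genuinely overlap at their borders, and the shared-bin convention
keeps the seven bands contiguous without arbitrary half-open intervals.

**Individual alpha frequency.** The argmax of the across-signal mean PSD
in 7–14 Hz, ties broken toward the lower frequency so the detector is
deterministic. Whether a posterior-only channel subset would be
preferable is genuinely open; the all-channel mean is a declared choice,
not an inference.

**Weighted minimum-norm source inverse.** The gain matrix `K` (channels ×
3·voxels) is centred to the common-average reference (`H = I − 11ᵀ/n`).
Per-voxel 3×3 weights start at the identity and iterate

    W_v ← [ K_vᵀ (K W⁻¹ Kᵀ + αH)⁺ K_v ]^{1/2}

until the maximal elementwise change drops below `tol` (default 1e-6,
`max_iter` 100; non-convergence warns and returns the flagged last
iterate). The operator is `M = W⁻¹ Kᵀ (K W⁻¹ Kᵀ + αH)⁺`. This weighting is
what buys the method's defining property — exact localization of noiseless
point sources even in the underdetermined 19-channel setting — and the
package tests that property exhaustively over all voxels of its toy
leadfield. `α` is specified *relative* to the mean eigenvalue of
`K W⁻¹ Kᵀ`, recomputed at each weight iteration (default 0.05; 0 disables
regularization), so its meaning does not depend on the gain's scale.

**Current density.** Per voxel and frequency bin, the Welch power of the
three moment components combined across components. "Combined" is
ambiguous in the field's usual phrasing (mean of the three vectors); the
default is the arithmetic mean of the component powers
(`combine = "mean"`), with the sum (`combine = "sum"`, the squared moment
magnitude) available, and the choice recorded in the output object. Values
are normalized by the grand mean over all voxels and all bins in
0.5–45 Hz, so 1 means "equal to the average activity"; the normalization
is idempotent, scale-free, and cancels exactly in every ratio marker.
Voxel values are then averaged over each of six macro-ROIs (hemispheres
pooled), whose conventional Brodmann memberships ship with the package
(`roi_brodmann_map()`) for users supplying atlas-labelled leadfields.

**Lagged linear connectivity.** Volume conduction makes any two scalp-level
or smeared source-level signals instantaneously coherent, so only the
coherence that *survives removal of the zero-lag component* is
physiologically interpretable. For a cross-spectrum `S`:

    LagC(f) = Im(S_ij)² / (S_ii S_jj − Re(S_ij)²)

This is 0 for identical signals, 0 for independent signals, bounded in
[0, 1], symmetric, and — the motivating property — at the estimator's null
level for arbitrary instantaneous mixtures of one common source while
staying bounded away from 0 for a genuinely lagged shared component. A
degenerate denominator (perfect instantaneous coherence) is defined as 0
with a warning. Since lagged coherence is a scalar-pair quantity, each
voxel's three-component series is reduced to its first principal
orientation (maximal-power moment direction); a fixed component can be
selected instead. ROI-pair LLC averages over all voxel pairs (one voxel
per side) and then over band bins — bins innermost, though the two orders
are equivalent for linear averaging; above `max_voxel_pairs` (default 500)
a seeded uniform subsample is taken and recorded.

**Markers, screen, ROC.** The default registry holds 12 composite
current-density ratios (slow band over alpha band at one ROI) and 6
composite LLC ratios; a simple (non-ratio) alpha 1 connectivity candidate
can be added. The gate into ROC analysis is a one-tailed two-sample Welch
t-test per marker at `alpha = 0.05`, deliberately uncorrected — its role
is to prune candidates, not to establish differences. The tail comes from
each marker's registered AD-abnormal direction ("greater" for all
slow/alpha ratios), which keeps the null selection rate at the nominal
level; a data-driven tail (`direction = "auto"`) is available but runs at
twice the nominal rate under the null, which the documentation states
rather than hides. Covariate residualization (pooled OLS) is available but
off by default: the composite-marker gate is a plain t-test, and pooled
residualization on a covariate that itself differs between groups (IAF
slowing is part of the disease) would remove genuine group signal.

ROC curves place thresholds at midpoints between adjacent distinct pooled
values with ±∞ sentinels; a subject exactly at the threshold counts
positive, matching the boundary-inclusive AD+ rule. Orientation is chosen
so AUROC ≥ 0.5 and the flip recorded. The trapezoidal area then equals the
tie-adjusted pairwise-comparison (rank-sum) probability *exactly*, which
the tests verify against a brute-force oracle, exhaustively for small
cohorts. The reported operating point maximizes the Youden index
`J = sens + spec − 1`; ties break toward higher specificity, then lower
threshold — a balanced criterion consistent with defining accuracy as the
mean of sensitivity and specificity. Markers with AUROC strictly above
0.70 ("moderate" classification) are flagged. No cross-validation is
performed by default: reported rates are apparent rates on the analysis
sample, as is conventional for this marker-screening design.

**Stratification.** AD subjects are AD+ when their (abnormal-high
oriented) marker value is ≥ the Nold mean plus one sample SD; abnormal-low
markers are sign-flipped first, so "positive" always means abnormal. For a
normal reference this threshold leaves ≈ 15.9 % of held-out controls
positive (Φ(−1)), which the tests verify by Monte Carlo. Subgroup
contrasts (MMSE, normalized GM/WM/CSF volumes — each compartment divided
by the GM+WM+CSF total) use one-tailed Welch tests; a subgroup smaller
than two is flagged not-testable rather than raising an error.

## The synthetic cohort generator

Each voxel's source signal is a sum of resonant AR(2) band oscillators
(pole radius `exp(−π·bw/fs)`, centre frequency per band; the alpha 1
oscillator is centred on the subject's drawn IAF). AR(2) resonators were
chosen over filtered noise because two parameters (centre, bandwidth) give
reproducible, controllable spectral peaks. Scalp data are the leadfield
projection of the sources through fixed per-voxel orientations, rescaled
to a target RMS (default 8 µV) plus white sensor noise (default 2 µV);
artifact epochs receive 200 µV half-second transients on a random channel,
so the rejection path is exercised deterministically.

Group structure follows the direction of the clinical contrast: the AD
profile multiplies delta/theta source power by 2 and alpha by 0.5 in every
ROI, IAF means are 10.0 (Nold) vs 8.5 Hz (AD), inter-hemispheric occipital
alpha 1 coupling is stronger in controls (0.6 vs 0.2 shared-power
fraction, lag 3 samples), and a per-AD-subject severity scalar
(geometrically interpolating each power between the two profiles) also
drives MMSE downward and shifts volumes (GM down, CSF up). All magnitudes
are invented — the source literature reports p-values, not source-level
effect sizes — and are exposed in `sim_config()`. Between-subject
variability is a log-normal jitter per (ROI, band) cell; its default SD of
0.8 was chosen so that default cohorts show substantial between-subject
overlap rather than trivially separable groups. Demographics (age,
education) are drawn from the same distributions for both groups, matching
the design of an age/education-matched study.

For quantitative checks the package provides
`separation_study_config()`, which programs a group contrast *only* in
occipital delta (× 2) and alpha 1 (× 0.5) and calibrates the jitter SD
analytically so the occipital delta/alpha 1 marker attains a prescribed
standardized log-scale separation `d` after the full pipeline. The
calibration accounts for inverse-solution crosstalk: the estimated
occipital value is a known linear mixture (computable from `M` and the
gain) of every ROI's source power, which dilutes both the programmed
offset and the jitter variance; lognormal moments with a delta-method
variance and one root-find recover the SD that delivers the target `d`.
Under this (log-)normal marker model the expected AUROC is `Φ(d/√2)`, the
link the acceptance tests check at `d = 1.2` (expected ≈ 0.80).

What the generator does *not* emulate: realistic anatomy (the toy
leadfield is a homogeneous-conductor dipole model with 12–36 voxels, not a
6000-voxel boundary-element head model), ocular/muscle artifact
morphology, drowsiness drift, non-stationarity, and 1/f background.
Passing tests therefore demonstrate the *correctness and calibration of
the estimators and decision rules*, not clinical performance; the clinical
numbers of any particular study are not reproducible without its data.

## Numerical and format details

- Pseudo-inverses use a symmetric eigendecomposition with relative
  tolerance 1e-12; 3×3 weight square roots clamp negative eigenvalues at 0
  and raise an error naming the voxel if a block is rank-deficient.
- All FFT work is done once per epoch; one-sided scaling puts
  `sum(PSD)·Δf` equal to the window-compensated mean square exactly
  (verified to 1e-10), so a unit sinusoid carries total power 0.5 µV².
- All randomness flows through explicit seeds (`withr::with_seed`
  internally); per-subject seeds derive deterministically from the cohort
  seed, so cohorts, pipelines and file outputs are bit-reproducible.
- Recordings are read/written as delimited matrix + JSON sidecar or as a
  minimal 16-bit EDF subset (one-second records, common sampling rate;
  written with the same affine quantization used on decode, so round-trip
  error is at most half a quantization step). The EDF reader targets the
  files this package writes; arbitrary third-party EDF(+) features
  (annotations, mixed rates) are out of scope. Leadfields are a delimited
  gain matrix plus a JSON voxel table; every pipeline stage writes a TSV
  and a JSON provenance record naming the configuration digest.
- Degenerate inputs have defined behaviour throughout: no accepted epochs,
  empty ROIs, zero ratio denominators, constant markers (p = 1 with a
  warning), zero reference SD, single-member stratification subgroups, and
  all-control cohorts each produce a specific error, warning or flag
  rather than silent propagation.

## Problem sizes used by the test suite

The suite runs on a 19-channel leadfield with one voxel per ROI and
hemisphere (12 voxels). Structural checks use 4–8 subjects at 10–30 s;
sign-recovery uses 30 + 30 subjects at 20 s; the calibrated separation
study uses ten replicates of 60 + 60 subjects at 60 s and 128 Hz;
screening calibration uses 1000 label permutations of a 60 + 60 null
cohort; stratification calibration uses 10⁴ reference and 10⁴ held-out
values. These sizes keep the full suite in the minutes range on a single
core while leaving every statistical assertion comfortably inside its
tolerance.

## Known limitations

- The inverse is tested for zero localization error, not for spatial
  resolution; with 19 channels the ROI estimates are strongly smeared, and
  the LLC of reconstructed sources is correspondingly attenuated relative
  to the true source coupling (the tests show the contrast, not absolute
  recovery).
- The bivariate lagged form is implemented; multivariate lagged dependence
  measures, directed measures and graph summaries are out of scope.
- The t-screen's covariate adjustment is pooled OLS residualization — a
  transparent but blunt instrument; covariates collinear with group will
  absorb group signal, which is why adjustment is opt-in.
- Apparent (resubstitution) classification rates are reported by design;
  users wanting generalization estimates should wrap the pipeline in their
  own resampling.
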