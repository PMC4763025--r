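# eegmarkers

Resting-state EEG markers of Alzheimer's disease (AD) versus normal elderly
(Nold) individuals, as a reproducible, fully tested R pipeline. The package
is aimed at researchers in clinical neurophysiology who want to screen
spectral and connectivity biomarkers of cortical sources — and at
methodologists who need a deterministic synthetic test bed for such
pipelines, since clinical resting-state EEG cohorts are rarely shareable.

## What it computes

Starting from 19-channel eyes-closed recordings (10–20 montage, 128 or
256 Hz), the pipeline:

1. **Preprocesses**: re-references to the common average, cuts consecutive
   2-s epochs, and flags artifact epochs by amplitude (> 100 µV) and
   flatline rules.
2. **Estimates spectra**: Welch PSD with Hann tapering on the 2-s epochs
   (0.5 Hz resolution), band powers for delta (2–4 Hz), theta (4–8),
   alpha 1 (8–10.5), alpha 2 (10.5–13), beta 1 (13–20), beta 2 (20–30) and
   gamma (30–40) with shared boundary bins, and the individual alpha
   frequency (IAF), the argmax of power in 7–14 Hz.
3. **Inverts to cortical sources**: a weighted minimum-norm (eLORETA-style)
   inverse with iterated voxel weights
   `W_v ← [K_vᵀ (K W⁻¹ Kᵀ + αH)⁺ K_v]^{1/2}`, which localizes noiseless
   point sources with zero error; voxel current density is normalized by
   its grand mean over 0.5–45 Hz and all voxels ("1" = average activity)
   and averaged within six regions of interest (frontal, central, parietal,
   occipital, temporal, limbic).
4. **Measures lagged linear connectivity (LLC)** between ROI pairs — six
   homologous inter-hemispheric pairs and fifteen intra-hemispheric pairs
   per hemisphere — using the zero-lag-excluded coherence
   `LagC(f) = Im(S_ij)² / (S_ii S_jj − Re(S_ij)²)`, which is immune to
   instantaneous volume-conduction mixing.
5. **Builds and evaluates markers**: 12 composite current-density ratios
   (e.g. occipital delta/alpha 1) and 6 composite LLC ratios; a one-tailed
   t-screen gates markers into ROC analysis; sensitivity, specificity,
   accuracy = (sensitivity + specificity)/2 and AUROC are reported at the
   Youden operating point, with AUROC > 0.70 as the "moderate"
   classification floor.
6. **Stratifies patients**: AD subjects with marker values at or above the
   Nold mean + 1 SD are "AD+"; MMSE and normalized GM/WM/CSF brain volumes
   are compared between AD+ and AD− by one-tailed Welch tests.

A seeded synthetic-cohort generator (band-limited AR(2) source oscillators
projected through a configurable toy leadfield) provides group-structured
data — AD profiles with elevated delta/theta, reduced alpha, slower IAF and
weaker lagged alpha coupling — so that every stage is testable end to end
without any clinical data.

## Worked example

Simulate a cohort whose occipital delta/alpha 1 marker has a programmed
standardized separation d = 1.2 (expected AUROC Φ(1.2/√2) ≈ 0.80), then run
the whole analysis:

```r
library(eegmarkers)

lf     <- make_toy_leadfield(19, 1, seed = 7)
op     <- compute_inverse(lf, alpha = 0.05)
cfg    <- separation_study_config(lf, inverse = op, d = 1.2,
                                  n_per_group = 60, seed = 1)
cohort <- simulate_cohort(cfg, lf)
study  <- analyze_cohort(cohort, lf, inverse = op)
study
#> <eeg_study> 120 subjects, 18 markers, 3 screened, 2 above AUROC threshold
#>   best: occipital_delta_alpha1 (AUROC 0.825, sens 60.0%, spec 93.3%, acc 76.7%)

tibble::as_tibble(study$roc)[1:3, c("marker", "auroc", "sensitivity", "specificity", "accuracy")]
#>                   marker auroc sensitivity specificity accuracy
#> 1 occipital_delta_alpha1 0.825       0.600       0.933    0.767
#> 2 occipital_delta_alpha2 0.755       0.617       0.850    0.733
#> 3  parietal_delta_alpha1 0.605       0.600       0.617    0.608
```

The programmed marker ranks first with an AUROC close to the analytic 0.80;
its sensitivity/specificity are those of the Youden point, and accuracy is
their mean. Stratifying the patients on that marker against the control
reference:

```r
study$strat
#> <eeg_strat> occipital_delta_alpha1: Nold ref 0.4703 +/- 0.2176,
#>   threshold 0.6878; AD+ 39, AD- 21
```

With the severity-linked default generator (disease severity drives both
the spectral burden and MMSE/volumes), the AD+ subgroup shows the expected
clinical pattern — lower MMSE and higher normalized CSF:

```r
#>   outcome mean_pos mean_neg n_pos n_neg       p
#> 1    mmse   20.884   23.118    43    17 0.00501
#> 2      gm    0.389    0.396    43    17 0.05745
#> 3      wm    0.342    0.350    43    17 0.09393
#> 4     csf    0.269    0.255    43    17 0.00103
```

`run_pipeline(pipeline_config(out_dir = "run1", seed = 1))` performs the
same analysis from a (YAML-serializable) configuration and writes every
stage's table as tab-delimited text with JSON provenance records;
re-running an identical configuration reproduces all outputs byte for
byte. `autoplot()` methods cover ROC curves, spectra and marker summaries;
`tidy()`/`glance()` methods return tibbles for all result types.

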