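# ecogfmri

Spatial correlation of ECoG and fMRI activity via Gaussian kernel
weighting.

## The problem

Electrocorticography (ECoG) electrodes record neuronal activity from the
cortex directly under each contact; BOLD fMRI measures the hemodynamic
response to the same activity, spatially smeared by the vasculature.
Integrating the two modalities — for pre-surgical mapping, multimodal
cognitive studies, or electrode placement for brain–computer interfaces —
requires knowing *how far around an electrode* the BOLD signal should be
averaged. `ecogfmri` estimates that scale from paired recordings of the
same block-design motor task:

1. **ECoG**: per-electrode band-power z-scores (movement vs rest, pooled
   two-sample t over 2 s Hanning-tapered windows) in the high-frequency
   broadband (65–95 Hz), alpha (8–12 Hz) and beta (13–30 Hz) bands;
2. **fMRI**: a gray-matter-restricted voxelwise GLM z-map (boxcar ⊗
   double-gamma HRF regressor, 45 s Gaussian running-line high-pass);
3. **Kernel sweep**: for each width σ on a 1–20 mm grid, the fMRI z-score
   at each electrode is the Gaussian-weighted average
   `w_i ∝ exp(−d_i²/2σ²)` of the gray-matter voxel z-scores, and the
   explained variance r²(σ) of ECoG z across electrodes is recorded.

Two kernel widths summarize the curve: the **peak width** (σ maximizing
r²) and the **concavity width** — the σ at the most negative second
derivative of r²(σ), where the gain from further smoothing tapers off.
The concavity width is the spatial-specificity measure: an ordinal
estimate of the BOLD point-spread scale.

A seeded synthetic generator produces paired ECoG + BOLD datasets with a
known ground-truth point-spread width (focal hotspots on a broad
activation strip, 1/f ECoG with controlled band modulation, spatially
correlated physiological BOLD noise, tangential electrode-localization
error), so the full pipeline runs and is tested without any clinical
data. See the methods vignette (`vignettes/kernel-width-estimation.Rmd`)
for the model and every default.

## Worked example

One synthetic subject at the default study conditions (8×8 grid at 10 mm
pitch, 512 Hz ECoG, TR 0.608 s, 4 mm voxels, ground-truth point spread
4 mm), analysed fully in memory:

```r
library(ecogfmri)
res <- run_synthetic_subject(default_config(), seed = 1)
res$zmap
#> GM z-map: 1250 voxels, z range [-1.95, 6.12], 51.0% with |z| > 1.96
res$curves$hfb
#> Kernel-width correlation curve (band: hfb)
#>   56 electrodes, sigma 1-20 mm (77 widths), pearson correlation
#>   peak:      sigma =  11.00 mm, r2 = 0.683
#>   concavity: sigma =   5.50 mm, r2 = 0.623
round(coef(res$curves$hfb), 3)
#>      peak_sigma         peak_r2      peak_slope concavity_sigma    concavity_r2
#>          11.000           0.683           0.403           5.500           0.623
```

Reading: 56 electrodes showed a significant HFB response and entered the
sweep. Explained variance between ECoG and kernel-weighted fMRI z-scores
keeps improving with smoothing up to σ = 11 mm (r² = 0.68, positive
slope: more HFB power, more BOLD), but the gain tapers off after
σ = 5.5 mm — the concavity width, reflecting the 4 mm ground-truth blur
plus localization error. `plot(res$curves$hfb)` draws the curve and its
second derivative.

For file-based runs, `run_subject(root, "sub-01", config)` executes the
staged pipeline (simulate → ecog → fmri → kernel) over a BIDS-like
subject directory and writes electrode responses, the z-map NIfTI and
per-band kernel summaries under `derivatives/`; `aggregate_group()`
combines subjects. `inst/scripts/ecogfmri-pipeline.R` wraps these as a
command-line tool with `simulate/ecog/fmri/kernel/all/group` stages.

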