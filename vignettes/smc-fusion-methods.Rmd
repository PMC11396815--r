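---
title: "Methods: soil moisture from fused multispectral and thermal features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soil moisture from fused multispectral and thermal features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smcfusion)
```

## 1. The estimation problem

The package estimates plot-level soil moisture content (SMC, a mass
fraction) in three depth layers (0–20, 20–40, 40–60 cm) from two airborne
observations per plot: a six-band reflectance raster
(490/555/680/720/800/900 nm, reflectance in [0, 1]) and a thermal-infrared
raster (°C). Ground truth comes from gravimetric sampling,
`W = (M1 − M2)/M1` with wet mass `M1` and oven-dry mass `M2`
(`gravimetric_smc()`; the conventional dry-basis form `(M1 − M2)/M2` is
available via `basis = "dry"`), averaged over sampling points per plot.

The estimation chain is:

1. **Masking.** Per-pixel NDVI > 0.3 separates canopy from soil background
   (`canopy_mask()`). The threshold suits a dense canopy; it is a
   configuration parameter (`vi_threshold`).
2. **Vegetation indices (VIs).** Band means over the canopy mask feed 15
   band-arithmetic indices (`compute_vi()`, `VI_CATALOG`). Each index is
   evaluated with both NIR bands (800 and 900 nm); per depth layer, the band
   whose index correlates more strongly (|Pearson r|) with SMC **on the
   training split only** is kept (`select_nir_band()`; ties go to 800 nm).
3. **Texture features (TF).** Each band is min–max quantized to `G = 32`
   gray levels; for every interior pixel a 3×3 window yields a symmetric
   gray-level co-occurrence matrix at distance 1 in each of four directions
   (0°, 45°, 90°, 135°), and the eight statistics (mean, variance,
   homogeneity, contrast, dissimilarity, entropy, second moment,
   correlation) are direction-averaged (`band_texture_image()`, implemented
   in C++). Plot-level features average each statistic over valid masked
   pixels: 6 bands × 8 statistics = 48 features.
4. **Texture indices (TIs).** Six two-feature forms —
   `NDTI = (T1−T2)/(T1+T2)`, `DTI = T1−T2`, `RTI = T1/T2`,
   `NTI = (T1²−T2)/(T1²+T2)`, `RDTI = 1/T1 − 1/T2`, `RATI = 1/T1 + 1/T2` —
   are optimized by exhaustive search over all ordered pairs of the 48
   texture identities, including identical pairs
   (`search_texture_indices()`), keeping the pair with the largest |r|
   against the layer's SMC.
5. **Thermal indices (TVIs).** The thermal raster is calibrated by
   ordinary least squares against leaf/water reference points
   (`calibrate_thermal()`, `reference = a·image + b`). Four indices follow
   (`thermal_indices()`): `TcD = Tc − Tair`,
   `NRCT = (Tc − Tc,min)/(Tc,max − Tc,min)` with field-wide canopy extremes,
   `CRTD = (Tc,max − Tc,min)/(Tc,max + Tc,min)`, and `SRTD` from within-plot
   soil extremes.
6. **Screening.** Every feature is tested against the layer's SMC with the
   exact two-sided Pearson t-test (`screen_features()`); features with
   `p < 0.01` enter the models. At `n = 96` this is equivalent to
   `|r| > 0.2617` (`critical_r(96, 0.01)`).
7. **Models.** Ten input combinations of the four families, three learners
   (XGBoost, random forest, GA-BP), three layers; training on a seeded
   random 2/3 split (64 of 96 plots) and reporting validation R², RMSE (in
   percent SMC), and mean relative error (`evaluate_combinations()`).

## 2. The synthetic experiment generator

Real campaigns cannot ship with the package, so `generate_experiment()`
renders a field whose statistical structure contains exactly the couplings
the chain is designed to detect. All randomness flows from one seed;
output is bit-reproducible.

For plot *p* with surface-layer SMC `s_p ~ U(0.09, 0.25)`:

- **Reflectance.** Band *b* of the canopy is
  `base_b + w_b · k_r · (s_p − s̄) + δ_b + scale_b (A·S + η_p·W)`,
  where `k_r = 0.5` per SMC unit at 800 nm, band weights
  `w = (0, 0.2, −0.3, 0.5, 1.0, 0.9)` make NIR rise and red fall with
  moisture, `δ_b` is per-plot Gaussian noise, `S` a smooth unit-variance
  structure field of amplitude `A = 0.05`, and `W` unit white noise whose
  per-plot amplitude `η_p = 0.04 − 0.15 (s_p − s̄)` *decreases* with SMC —
  this is the planted texture signal. Per-pixel sensor noise is added on
  top, and values are clipped to [0, 1].
- **Thermal.** Canopy temperature is
  `(Tair − 2) − 40 (s_p − s̄) + noise` (°C): wetter plots run cooler. The
  generator emits *raw* sensor values `(T − offset)/gain`
  (gain 1.05, offset −1.5) plus noisy leaf/water calibration points, so the
  calibration stage does real work.
- **Depth.** Deeper layers are noisy copies of the layer above with
  correlation 0.8, so layer 3 correlates with the surface at about 0.64 and
  planted signal decays with depth.
- **Soil background.** Deterministic inter-row strips (20% of pixels) carry
  a distinct spectral/thermal profile (low NDVI, warmer than canopy), so
  masking is exercised rather than trivial.

### Noise calibration

The reflectance noise default (`noise_sd_reflectance = 0.045`) was set so
that the strongest single-feature correlations with surface SMC land near
`|r| ≈ 0.65` across seeds — the signal-to-noise regime typical of
plot-scale UAV studies, and the regime in which feature fusion is
informative at all. Substantially cleaner scenes make the vegetation-index
family alone nearly sufficient; substantially noisier ones leave nothing
for any family to recover in the deepest layer. This calibration was fixed
against the feature-correlation target, and then frozen, before the
package's end-to-end fusion property was evaluated.

### What the generator does *not* model

Radiative transfer, BRDF and illumination geometry, row orientation versus
flight lines, mixed pixels at canopy edges, treatment-by-moisture
interactions (the 16 treatment labels are inert by default;
`treatment_effect` can activate them), spatially correlated sensor noise,
and any nonlinearity in the SMC couplings. Model rankings obtained on
synthetic scenes characterize the software, not crop physiology.

## 3. Numerical choices

- **GLCM entropy** is the Shannon form `−Σ P ln P` with `0 ln 0 = 0`,
  guaranteeing `Ent ≥ 0`; a sign-free transcription sometimes seen in print
  would make entropy non-positive and is not used.
- **GLCM correlation** returns the sentinel 0 with a `degenerate_cor`
  attribute when a marginal variance is zero (constant window), keeping
  sliding-window images finite.
- **Quantization** maps a constant raster to bin 0 rather than dividing by
  a zero range.
- **Metrics** are the standard `R² = 1 − SSE/SST`,
  `RMSE = √(mean(err²))`, `MRE = 100 · mean(|err|/y)`.
  `regression_metrics(..., printed_variants = TRUE)` additionally exposes
  two defective transcription variants occasionally found in the applied
  literature — an R² that is a ratio of sums (can exceed 1) and an "RMSE"
  that does not depend on the predictions — strictly for comparison.
- **Undefined values** (zero denominators in indices) raise errors in
  scalar use and become NA (excluded candidates) inside the vectorized
  search and table builders; degenerate screening columns are warned about
  and dropped, never silently imputed.
- **GA-BP** is a from-scratch single-hidden-layer network (5 sigmoid units,
  linear output) on min–max-scaled inputs and target. A small GA
  (population 5, 50 generations, arithmetic crossover 0.4, per-gene
  Gaussian mutation 0.05, elitism 1) searches initial weights, scoring each
  individual after a 20-epoch gradient refinement (a Lamarckian scheme);
  the winner is trained by full-batch gradient descent with momentum 0.9
  and learning rate 0.2 up to 1000 epochs or a training MSE of 1e-6.
  Deterministic per seed; on a noiseless linear target it reaches
  validation R² > 0.999.

## 4. Design decisions worth knowing

- **CRTD is constant per field.** With field-wide canopy extremes, CRTD
  takes one value for all plots in a scene set; the screening stage detects
  the zero-variance column and drops it with a warning. The thermal family
  that reaches the models is effectively {TcD, NRCT, SRTD}.
- **Screening and the texture-index search use the full sample**, matching
  common practice in the application domain; this leaks validation
  information into feature selection, and validation R² should be read as
  evaluating the *modelling* stage given that protocol. The NIR-band
  selection, by contrast, is restricted to the training split.
- **SMC is modelled in percent** (fractions × 100), so RMSE is in percent
  SMC and MRE is scale-free.
- **Rasters are stored as multi-page 32-bit float TIFF** (one page per
  band) with temperatures affinely mapped into [0, 1]; the mapping lives in
  the accompanying `manifest.json`. No geospatial referencing is attached —
  plots are abstract grids.
- **Evaluation rows never abort the matrix:** a combination with no
  surviving screened features yields an NA row with an explanatory note.

## 5. The fusion property

The package's acceptance suite asserts the structural finding it exists to
reproduce: over 20 seeded default experiments, the fused VIs+TIs+TVIs input
achieves a 0–20 cm validation R² at least as high as the best single
family's in at least 70% of seeds (combination score = mean over the three
learners), and mean fused R² does not increase with depth. Measured at the
frozen defaults, the win fraction is 0.80 and the model-averaged fused R²
by layer is about 0.49 / 0.37 / 0.33 at seed 1 (individual learners vary;
random forest shows the fusion gain most consistently).

## 6. Limitations

Synthetic validation bounds what can be claimed: the generator's couplings
are linear with Gaussian noise, so learners face no distribution shift, no
label noise beyond the planted kind, and no confounding between families
beyond their shared SMC driver. Results on real campaigns will differ; the
package's value there is the audited, deterministic feature chain and
evaluation harness rather than any transferred performance number.
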