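# thzvol

Tumor volumetry for terahertz (THz) transmission imaging.

Subcutaneous breast tumors absorb THz radiation more strongly than the fatty
tissue around them (higher water content), so a raster scan of transmitted
power through a glass-sandwiched tissue slab carries endogenous contrast: no
stain, no exogenous marker. `thzvol` implements the full analysis that turns
such scans into a tumor volume, and a synthetic tissue phantom that makes
every stage testable against known ground truth:

1. **Phantom simulation** — a skin/fat/tumor tissue stack on a pixel grid
   (default 10 × 10 mm at configurable pitch), scanned with the Beer-Lambert
   forward model `I_s = I_b · exp(−τ_skin − α·d)` plus multiplicative
   detector noise of relative SD `1/snr`, with replicate scans.
2. **Absorbance inversion** — per pixel, `α = ln(I_b / I_s) / d` (mm⁻¹),
   replicate scans averaged in α-space.
3. **Skin calibration** — skin attenuation is uniform and
   position-independent, so it is removed as a scalar background
   `τ_skin / d`, either supplied or estimated from a skin-only reference
   region.
4. **Segmentation** — pure thresholding on α: fatty background in
   [1.400, 1.450) mm⁻¹, cancer in [1.450, 1.600) mm⁻¹, saturation at
   ≥ 1.600 mm⁻¹. The region summary yields the absorption change
   Δα = mean(cancer ∪ saturated) − mean(background).
5. **Volumetry** — the absorption-cross-section model. A single cancer cell
   of volume `V_cell` has cross-section `σ = α_ref · V_cell`; the observed Δα
   implies a cell density `N′ = Δα / σ`, and the total cancer volume is

   ```
   V = N′ · V_cell · V_eff = (Δα / α_ref) · V_eff
   ```

   with default calibration `α_ref = 1.5 mm⁻¹` (midpoint of the 1.400–1.600
   display band) and `V_eff = 8 mm³`. `V_cell` cancels: it affects only the
   auxiliary σ and N′ outputs. Detection-limit and penetration-depth
   (`ln(dynamic range)/α`) calculators round out the module, and a
   spectroscopy module aggregates per-animal absorption spectra over
   108–143 GHz with a tissue-separability statistic.

## Worked example

Simulate three replicate scans of a phantom carrying a 1.5 mm-radius tumor
with absorption excess 0.160 mm⁻¹ over a 1.42 mm⁻¹ fatty background, and run
the whole analysis:

```r
library(thzvol)

cfg <- pipeline_config(
  subject_id  = "mouse2",
  phantom     = phantom_spec(
    skin_optical_depth = 0.05,
    tumor_regions      = tumor_disc(5, 5, 1.5, 0.160)),
  acquisition = acquisition_config(snr = 1e4, n_replicates = 3),
  skin        = skin_fixed(0.05),
  rng_seed    = 33L)

run_pipeline(cfg)$report[, c("subject_id", "delta_alpha", "n_cancer_pixels",
                             "volume_mm3")]
#> # A tibble: 1 × 4
#>   subject_id delta_alpha n_cancer_pixels volume_mm3
#>   <chr>            <dbl>           <int>      <dbl>
#> 1 mouse2           0.160             716      0.853
```

The recovered Δα matches the generating excess of 0.160 mm⁻¹, the 716 cancer
pixels at 0.1 mm pitch are exactly the ground-truth disc pixels
(π·1.5² ≈ 7.07 mm²), and the volumetry converts
Δα into 0.853 mm³ of cancer tissue. Volumetry alone is a one-liner:

```r
estimate_volume(c(0.090, 0.160, 0.132))
#>   delta_alpha    sigma n_prime volume_mm3
#> 1       0.09  0.000003  30000       0.48
#> 2       0.16  0.000003  53333.      0.853
#> 3       0.132 0.000003  44000       0.704
```

All three volumes are below 1 mm³ — the regime this technique is built to
resolve. `autoplot()` renders absorbance maps with the clamped blue→red
scale, `tidy()`/`glance()` give tabular views of every result, and
`exec/thzvol` exposes `run` and `volumetry` subcommands for shell use.

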