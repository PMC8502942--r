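---
title: "THz transmission imaging tumor volumetry: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{THz transmission imaging tumor volumetry: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thzvol)
```

`thzvol` estimates the volume of a subcutaneous tumor from a terahertz (THz)
transmission raster scan. This vignette explains the physical and statistical
model behind each stage, the parameters that matter, and the design choices
made where the method leaves genuine freedom. Nothing here asserts an
empirical result that the package's tests do not themselves compute.

## The measurement model

A fiber-scanned THz beam at 108 GHz passes through a tissue slab of thickness
$d$ held between two cover glasses; a detector records the transmitted power
$I_s$ at each scan position, and $I_b$ is the background power through the
bare cover glass. Scattering and reflection inside the slab are assumed
negligible at these wavelengths (0.003–3 mm, much longer than cellular
structure), so attenuation is pure Beer-Lambert:

$$I_s = I_b \, e^{-\tau_\text{skin} - \alpha d},$$

where $\alpha$ (mm⁻¹) is the absorption coefficient of the sub-skin tissue
and $\tau_\text{skin}$ is the dimensionless optical depth of the overlying
skin. Inverting,

$$\alpha = \frac{1}{d}\ln\frac{I_b}{I_s} - \frac{\tau_\text{skin}}{d}.$$

Two conventions are worth making explicit:

* **Sign.** The package computes $\alpha = \ln(I_b/I_s)/d$, which is positive
  for an attenuating sample. The formula is sometimes written with the ratio
  inverted; since every absorption coefficient in this domain is reported
  positive, we treat that form as a sign slip and document our orientation.
* **Skin as an optical depth.** Skin thickness is not measured separately;
  only the product of its thickness and absorption enters the data, and it is
  uniform across the field. Parameterising skin by a single dimensionless
  $\tau_\text{skin}$ (rather than a thickness × coefficient pair) matches
  exactly what is identifiable. Calibration subtracts the scalar
  $\tau_\text{skin}/d$ from the α map — after division by $d$, so units stay
  mm⁻¹ — and a map can be corrected exactly once (`skin_corrected` flag).
  When $\tau_\text{skin}$ is unknown, `estimate_skin_background()` recovers
  it from a reference region known to hold only skin over fat, as
  $d \cdot (\bar\alpha_\text{mask} - \alpha_\text{fat})$, floored at zero.

Replicate scans (three per subject by default) are averaged pixelwise in
α-space, matching the presentation of repeat scans as a mean
absorption-coefficient image. Because $\ln$ is applied per replicate before
averaging, this equals power-space averaging only in the noiseless limit;
the difference is second-order in the noise and irrelevant at the SNRs in
play. Averaging and skin correction commute (both are affine in α), which
the test suite checks explicitly.

## The synthetic phantom

No raw scans are publicly deposited, so the package ships a first-class
phantom generator that emulates the study conditions:

* **Field**: 10 × 10 mm, the standard scan extent; pitch configurable
  (default 0.1 mm → 100 × 100 pixels). The scan step of the real system is
  not published, so pitch is a free parameter — 0.1 mm was chosen once as a
  plausible fiber-scan step that resolves millimetre lesions with ~700
  pixels.
* **Tissue**: uniform fatty background at $\alpha = 1.42$ mm⁻¹ (inside the
  published fatty band 1.400–1.450 mm⁻¹), one or more tumor discs adding a
  uniform absorption excess (overlaps take the maximum, not the sum), and a
  uniform skin optical depth (default 0.05, i.e. a 0.1 mm⁻¹ offset at
  $d = 0.5$ mm — comfortably detectable but small against fat attenuation).
* **Geometry**: a pixel belongs to a disc when its center — at
  $((j-\tfrac12)p, (i-\tfrac12)p)$, origin top-left, row-major — lies inside
  it (distance ≤ radius). Discs keep the lesion area analytically checkable:
  the tests compare rasterised pixel counts against an independent
  brute-force enumeration and against $\pi r^2/p^2$.
* **Thickness**: the in-vivo sandwich thickness is not published; the
  phantom defaults to $d = 0.5$ mm but the absorbance module requires $d$
  explicitly and never defaults it silently.
* **Noise**: the real detection chain reports only a system SNR (~10⁸:1).
  We model detector noise as i.i.d. multiplicative Gaussian on power with
  relative standard deviation $1/\text{snr}$, clipped to keep power
  positive. This is the simplest positive-preserving model whose single
  parameter maps directly onto the quoted figure; the package default
  snr = 10⁴ is deliberately far noisier so that tests exercise visible
  noise. The clip never activates above snr ≈ 10.
* **Spectroscopy panel**: per-animal true α values per tissue and frequency
  are drawn from a normal law truncated at zero and pushed through the
  forward model. The frequency grid defaults to 108–143 GHz in 5 GHz steps
  (8 points); only the band endpoints are published, and 5 GHz gives a
  readable spectrum without pretending to unpublished resolution.

What the phantom does **not** emulate: diffraction and lens focusing, fiber
coupling losses, spatially correlated noise, irregular lesion shapes,
partial-volume effects at lesion edges, or skin-thickness variation. Passing
the recovery tests therefore demonstrates the correctness of the analysis
chain under the stated model, not robustness to every artefact of real
scans.

## Segmentation

Classification is pure per-pixel thresholding on the skin-corrected α map,
with the published false-color bands as defaults: background (fat) in
$[1.400, 1.450)$, cancer in $[1.450, 1.600)$, saturation at $\ge 1.600$, and
`below_range` otherwise. Intervals are half-open so the four classes
partition the grid; a pixel at exactly 1.450 classifies as cancer — the
conservative choice for a detection method. No morphological cleanup is
applied by default, because the method as described is thresholding alone;
an optional minimum-component-size filter (`min_component_px`) exists for
noisy regimes but defaults to off.

The region summary reports the absorption change

$$\Delta\alpha = \overline{\alpha}_{\text{cancer} \cup \text{saturated}}
               - \overline{\alpha}_{\text{background}}.$$

The scalar Δα is reported per subject without a published definition; a
difference of region means was chosen because (a) it matches the "absorption
change" language, (b) saturated pixels are genuinely lesion tissue whose
display is merely clamped, and (c) a difference of means is invariant to any
uniform offset left by an imperfect skin calibration — a property the tests
assert. Alternatives (peak α, mode-to-mode distance) would be more
noise-sensitive and are not implemented. An image with no background pixels
has no reference level and errors; one with no lesion pixels reports
$\Delta\alpha = 0$ with `cancer_detected = FALSE` and a warning.

Rendering clamps the display scale to $[1.400, 1.600]$ mm⁻¹ on a continuous
blue→red ramp — saturated tissue renders as the same red as 1.600 — but
never modifies stored α values.

## The absorption-cross-section volumetry

A confluent cancer-cell mass with bulk absorption coefficient
$\alpha_\text{ref}$ and cell number density $N = 1/V_\text{cell}$ assigns
each cell an absorption cross-section

$$\sigma = \frac{\alpha_\text{ref}}{N} = \alpha_\text{ref} V_\text{cell}.$$

An observed regional excess Δα then implies a cancer-cell density
$N' = \Delta\alpha/\sigma$ in the interrogated tissue volume
$V_\text{eff}$, and the total cancer volume is

$$V = N' V_\text{cell} V_\text{eff}
    = \frac{\Delta\alpha}{\alpha_\text{ref}} V_\text{eff}.$$

$V_\text{cell}$ cancels algebraically; the implementation computes $V$ from
the simplified form so the cancellation is exact to the bit, and
$V_\text{cell}$ (default $2\times10^{-6}$ mm³, the order of magnitude of a
~15 µm MDA-MB-231 cell) matters only for the auxiliary σ and N′ outputs.

**Calibration.** Neither $\alpha_\text{ref}$ nor $V_\text{eff}$ is published
directly, but the three reference (Δα, V) pairs —
(0.090, 0.480), (0.160, 0.853), (0.132, 0.704) — share a constant ratio
$V/\Delta\alpha = 5.333$ mm³ per mm⁻¹ to within 0.03%, which pins down only
the quotient $V_\text{eff}/\alpha_\text{ref}$. We fix
$\alpha_\text{ref} = 1.5$ mm⁻¹, the midpoint of the 1.400–1.600 mm⁻¹
display band, giving $V_\text{eff} = 8$ mm³. Both are plain configuration
values in `volumetry_calibration()`; only their ratio is identified by the
data, and $V_\text{eff}$ is treated as an opaque constant — no claim is made
that it equals scan area × thickness.

```{r volumes}
estimate_volume(c(0.090, 0.160, 0.132))
```

The detection limit is the same map applied to the smallest resolvable
absorption change; with the default calibration, any
$\Delta\alpha_\text{min} \le 0.1875$ mm⁻¹ corresponds to sub-1 mm³ volumes.
The penetration-depth helper, $\text{depth} = \ln(DR)/\alpha$ for dynamic
range $DR$, is the depth at which transmitted power reaches the noise floor;
it is a closed-form utility, and no published penetration figure is
reproduced because the tissue α assumed for such estimates is unstated.

## Reporting conventions and numerical choices

* Volumes and Δα are formatted to 3 decimal places in written reports,
  rounding half away from zero (`round_half_up()`); R's banker's rounding
  would print 0.8535 as 0.854 vs 0.853 unpredictably across values.
* All randomness is seeded. `run_mouse_panel()` derives each subject's
  stream as master seed + subject index, so adding a subject never perturbs
  the others, and identical configs give byte-identical written reports.
* The noiseless forward/inverse round trip is exact to floating-point
  rounding (tested at ≤ 10⁻¹² relative); no iterative numerics are involved
  anywhere in the chain.
* Degenerate inputs fail loudly: non-positive powers name the offending
  pixel, double skin-correction errors, unordered band edges error, and
  pipeline stage failures are re-raised with the subject id and stage name.

## Problem sizes in the test suite

The tests run the default 100 × 100 phantom throughout: the stochastic
recovery suite uses 20 seeded runs at snr = 10⁴ (median volume error and an
18-of-20 within-5% criterion), the noise-contract checks use single scans of
10⁴ pixels, and the spectroscopy flag stability uses 20 seeds × 20 animals
× 8 frequencies. These sizes make the whole suite run in a few seconds while
leaving Monte-Carlo tolerances (10% on SD ratios, 5% on recovered Δα and V)
comfortably above sampling error.

## Known limitations

* The calibration ratio $V_\text{eff}/\alpha_\text{ref}$ is inherited, not
  derived from first principles; volumes are only as meaningful as that
  constant.
* Δα as a difference of region means depends on the segmentation bands;
  lesions whose α never leaves the fatty band are invisible by
  construction.
* The phantom's uniform-excess discs cannot probe sensitivity to
  heterogeneous lesions or partial-volume edge effects.
* Spectroscopy is exercised on synthetic panels only; no published spectral
  values exist to compare against.
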