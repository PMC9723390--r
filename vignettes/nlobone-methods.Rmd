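---
title: "Quantifying bone collagen architecture and composition from multimodal NLO images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bone collagen architecture and composition from multimodal NLO images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlobone)
```

## The measurement problem

Bone is a composite of mineral and a collagen-rich organic matrix whose
amount and spatial organization set its mechanical properties. Multimodal
nonlinear optical microscopy reads several of these properties label-free
from one section: second-harmonic generation (SHG) arises only in
non-centrosymmetric structures — in practice collagen fibre bundles — and its
intensity scales linearly with scatterer density; stimulated Raman scattering
(SRS) at 2850 and 2920 cm⁻¹ is proportional to the local concentration of
CH₂ (lipid) and CH₃ (protein) groups; two-photon fluorescence reports
NADH/FAD metabolism. Given co-registered channels and a per-pixel tissue
label map (cortical bone, trabecular bone, marrow, growth plate,
background), three quantities summarize a vertebral section:

* mean raw SHG intensity over mineralized bone — relative collagen density;
* the distribution of pixel-wise fibre orientations and its decomposition
  into an aligned and an isotropic component;
* bone:marrow mean-intensity ratios of the SRS channels — compartmental
  lipid/protein contrast.

This vignette describes the models and the numerical and design choices
behind each stage, what the synthetic-scene generator emulates, and what the
passing test suite does and does not establish about real data.

## Orientation from Sobel gradients

`sobel_gradients()` cross-correlates the image with the classical 3×3
kernels (Gx for horizontal, Gy for vertical derivatives) — unflipped kernels,
i.e. cross-correlation rather than convolution, with reflect padding so the
output keeps the image size. The gradient direction `atan2(gy, gx)` points
across intensity edges, perpendicular to the local fibre axis, so
`fibre_angle_map()` reports the fibre angle as the gradient direction plus
90°, folded to [0°, 180°). With this convention a structure elongated along
the vertical image axis — anatomically the craniocaudal axis — reads 90°.
The full-quadrant arctangent is used instead of the textbook `arctan(Gy/Gx)`
to avoid division by zero; after folding to the axial range the two agree.

Two practical gates matter on noisy data:

* **Validity gate ε.** Pixels with gradient magnitude below ε carry no
  orientation information and are masked (not errors). The permissive
  default (10⁻⁶ × max magnitude) counts essentially every pixel with any
  gradient. For images with additive detector noise the pipeline instead
  estimates the noise floor from background-class pixels
  (`noise_floor_epsilon()`, 3 × median background magnitude): near-zero
  stencils dominated by zero-clipped noise otherwise contribute spurious
  angle mass concentrated at multiples of 45° (a single nonzero pixel in the
  stencil forces |gx| and |gy| into small-integer ratios).
* **ROI erosion.** At pixels whose 3×3 stencil straddles a tissue-class
  boundary, the gradient measures the compartment interface — an edge
  parallel to the boundary — rather than fibre texture. `erode_mask()`
  removes this one-pixel boundary layer; the pipeline default is 1 px (the
  stencil radius). Histograms built directly from the raw class masks are
  available by setting `erode_px = 0`.

`orientation_histogram()` bins valid ROI pixels into 180 left-closed 1° bins
and normalizes to percent of analyzable pixels, so the bins always sum
to 100.

## The baseline-plus-Gaussian model and the alignment ratio

Orientation histograms of bone show a peak around the craniocaudal axis on
top of a flat floor. `fit_orientation_model()` fits

$$f(\theta) = B + A\,e^{-\left(\frac{\theta-\theta_0}{2\sigma}\right)^2}$$

by bounded least squares (Levenberg–Marquardt via `minpack.lm`), with
A, B ≥ 0, θ0 ∈ [0°, 180°], σ ∈ (0.5°, 90°]. Note the exponent's `2σ`
denominator: this σ equals a standard Gaussian's standard deviation divided
by √2. The package reports σ in this parameterization throughout — fitted
values are only comparable to each other (and to published tables using this
form) under the same convention.

Numerical choices:

* **Initialization** from the data: B₀ = min, A₀ = max − min, θ0₀ at the
  modal bin, σ₀ from the half-width at half prominence (h = 2σ√ln 2).
* **Guard grid.** A profiled grid over (θ0, σ) at 2° spacing — with the
  conditionally linear (A, B) solved in closed form at every node, clamped
  at zero — always runs alongside the LM fit; the better solution (after LM
  polish from the grid optimum) wins, with ties broken toward smaller σ. The
  returned fit is therefore never worse than a dense brute-force search,
  including on misspecified inputs such as bimodal histograms where a single
  local search can stall.
* **R²** is 1 − SS_res/SS_tot; a constant histogram (SS_tot = 0) is assigned
  R² = 1 exactly when the fit is exact.
* **No circular fitting.** The model is a plain Gaussian on the finite
  domain; peaks within ~2σ of 0°/180° wrap around the axial boundary and are
  outside the model's intended range.

The alignment ratio is `AR = 100·A_G/(A_G + A_B)` where A_G integrates the
Gaussian term (offset zero) over the data domain [0°, 180°] — numerically,
to 10⁻¹⁰ relative tolerance — and A_B = 180·B. The truncated domain is a
documented convention: for σ ≤ 45° it differs negligibly from the full-line
integral, and the finite axial domain is what the histogram actually
measures. AR is 0 for purely random fibres (A = 0), 100 for a pure peak
(B = 0), strictly increasing in A and strictly decreasing in B.

`summarize_fits()` arranges fits as a per-polarization table (rows =
parameters, columns = genotype × compartment cells) and appends the
arithmetic mean across cells. Cells are rounded half-up at the printed
precision of such tables (A, B, R², AR to 2 decimals, θ0 to whole degrees,
σ to 0.1°), means to 2 decimals; half-up rounding is required for the means
of table-precision values (e.g. 0.385 → 0.39) that banker's rounding would
print differently.

## ROI intensity statistics and composition ratios

`roi_mean_intensity()` averages raw intensities — deliberately no
flat-field, background subtraction, or rescaling — over the union of the
selected classes; SD/SEM use the sample (n − 1) convention to match
mean ± SEM reporting. `bone_marrow_ratio()` divides the mineralized-bone
mean (cortical ∪ trabecular) by the marrow mean, excluding growth plate and
background from both; the marrow mean must be positive. Both are exactly
scale-equivariant: multiplying an image by c > 0 multiplies means by c and
leaves ratios unchanged. "Mineralized bone" = cortical ∪ trabecular is used
for whole-bone collagen readouts, while per-class results are also emitted
because cortical and trabecular compartments differ systematically in fibre
alignment.

## Group statistics

Two test families are implemented because both are standard in this setting:
the exact Mann–Whitney U (the package default) and Student/Welch t tests.
For pooled sizes ≤ 12 the Mann–Whitney null is enumerated over all
`choose(n, n_a)` rank assignments with mid-ranked ties, and the two-sided p
is the null probability of a U at least as far from its mean as observed;
larger samples use the normal approximation with tie and continuity
correction. Zero-variance t-test inputs are handled explicitly (equal
constants → t = 0, p = 1; unequal constants → flagged degenerate).
`compare_groups()` reports mean ± SEM per group and flags significance
strictly below the configured α; the pipeline default is α = 0.1, a
deliberately liberal screening threshold appropriate to n = 3-per-group
histology studies, and configurable because it is unusual as a general
default.

## The synthetic scene generator

No public image data accompanies this analysis chain, so the package treats
scene synthesis as a first-class, tested module. A `scene_spec()` fixes
everything: geometry (background frame, rectangular cortical band,
growth-plate band, vertical trabecular struts, marrow interior), the fibre
population, polarization response, compartment contrasts, noise, and the
seed (the sole randomness source; identical specs give bit-identical
scenes).

* **Fibre orientations** follow the axial mixture
  `aligned_fraction · WrappedGaussian(θ0_true, σ_true) +
  (1 − aligned_fraction) · Uniform[0°, 180°)`, sampling an unwrapped normal
  and folding modulo 180. σ_true is specified in the fit model's
  parameterization (underlying normal sd = √2·σ_true) so that fitted σ
  estimates σ_true directly.
* **Polarization.** Each fibre's amplitude is scaled by
  `floor + (1 − floor)·cos⁴(θ − polarization angle)` — the SHG emission
  power law — with a configurable floor so perpendicular fibres are not
  fully dark. The same seeded fibre population is rendered under any
  polarization, so parallel/perpendicular channel pairs share geometry, and
  rotating both the orientation distribution and the polarization leaves
  the image statistics unchanged.
* **Rendering.** Fibres are straight segments with a Gaussian cross-section
  (sd = width/2, truncated at 2 sd) rather than hard-edged lines: the Sobel
  direction of a smooth profile is accurate to ~1° at every pixel, whereas
  kinked profiles scatter it by tens of degrees, and the tight truncation
  keeps fibre footprints small so overlapping fibres rarely contaminate each
  other's gradients. The truncation ring runs parallel to the fibre and adds
  no angular distortion. Fibre intensity is clipped to zero outside bone
  classes.
* **SRS/TPEF channels** are piecewise-constant per compartment with the
  bone:marrow mean ratio equal to the spec's value exactly before noise.
* **Noise** is additive Gaussian clipped at zero — one knob, matching the
  near-additive behaviour of balanced-detection/PMT images — not Poisson.

Default study conditions (chosen once; none are published values): 512 × 512
px at 1 µm/px, cortical band 48 px, six 28-px struts, 600 fibres of length
12–28 px and width 4 px at amplitude 100, marrow level 100, noise sd 2, SRS
bone:marrow ratios 1.3 (lipid) and 1.2 (protein) — qualitatively "ratios
above one" with a lipid contrast exceeding the protein one, polarization
floor 0.1. Two sizing choices deserve their rationale:

* *Compartments thick relative to fibre length.* Fibres clipped at
  compartment boundaries couple orientation to compartment shape (vertical
  fibres survive whole inside vertical struts; diagonal ones are
  truncated), biasing the measured orientation distribution. With 48-px
  cortex and 28-px struts against ≤ 28-px fibres the coupling is small.
* *600 fibres.* The fitted θ0's sampling error scales as
  √2·σ_true/√(aligned fibres) ≈ 2° at 300 aligned fibres — the scale needed
  for a meaningful ±3° recovery benchmark — while fibre density beyond
  ~1 fibre footprint per bone pixel makes overlaps shrink fitted σ toward
  θ0. 600 fibres in ~140k bone pixels balance the two.

## What the tests do and do not show

The suite verifies, among others: bit-exact agreement of the Sobel stage
with a brute-force double loop; histogram partition (Σ = 100%); 90°-rotation
equivariance of the angle map; exact recovery (< 1%) of model parameters
from noiseless model-generated histograms and of compartment ratios from
noiseless scenes; the fit never losing to a 2° grid search; Mann–Whitney
agreement with full enumeration; and, on stochastic scenes at the default
conditions with a half-aligned mixture (θ0 = 90°, σ = 25°), recovery of θ0
within ±3° in ≥ 15 of 20 seeds and a median relative σ error ≤ 20%.

These scenes emulate fibrous SHG texture, the cos⁴ polarization response,
compartment contrast, and additive noise. They do **not** model real SHG
speckle, lamellar sub-structure, fibre curvature, partial-volume mixing at
1 µm pixels, uneven illumination, or segmentation error in the (manual)
tissue labels. Passing recovery tests therefore establishes the correctness
and statistical behaviour of the *analysis chain*, not the accuracy of any
particular biological estimate from real images: on real data the fitted σ
reflects visibility-weighted orientation (misaligned fibres are dimmed by
cos⁴ and contribute fewer analyzable pixels), so parallel- and
perpendicular-polarization results should be compared within, not across,
illumination conditions.

## Degenerate inputs and failure modes

Empty ROIs (no labelled or no valid pixels) raise errors naming the stage
and sample; zero-gradient pixels are masked, never errors; flat histograms
fit as pure baseline (A ≈ 0, AR ≈ 0); fit non-convergence across both the
LM start and the guard grid raises a diagnostic error rather than returning
a silent fallback; marrow means ≤ 0 make ratios an error rather than an
infinity. Peaks adjacent to the 0°/180° axial boundary are the known
unsupported case of the plain-Gaussian model.
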