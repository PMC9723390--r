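# nlobone

Quantitative analysis of multimodal nonlinear optical (NLO) microscopy images
of bone: co-registered second-harmonic generation (SHG), two-photon excited
fluorescence (TPEF), and stimulated Raman scattering (SRS) channels of murine
vertebral sections, with per-pixel tissue labels (cortical bone, trabecular
bone, marrow, growth plate, background).

The package answers three questions about a labelled multichannel image:

1. **How much collagen is there?** SHG intensity scales linearly with the
   density of collagen scatterers, so the mean raw SHG pixel intensity over
   the mineralized-bone ROI (cortical ∪ trabecular) is a relative collagen
   density readout (`roi_mean_intensity()`).

2. **How aligned are the collagen fibres?** Pixel-wise fibre orientation Θ is
   computed from Sobel gradients,

   ```
   Gx = [ +1 0 -1 ]        Gy = [ +1 +2 +1 ]
        [ +2 0 -2 ]             [  0  0  0 ]       Θ = atan2(Gy, Gx) + 90°  (mod 180°)
        [ +1 0 -1 ]             [ -1 -2 -1 ]
   ```

   (cross-correlation, reflect-padded borders; the +90° maps structures
   elongated along the craniocaudal/vertical axis to Θ = 90°). Orientations
   over an ROI are binned into a 180 × 1° percentage histogram and fitted
   with a baseline-plus-Gaussian model

   ```
   f(θ) = B + A · exp( −((θ − θ0) / 2σ)² )
   ```

   where B is the isotropic (randomly oriented) fibre fraction, A the
   peak-minus-baseline amplitude, θ0 the preferential orientation and σ its
   spread (`sobel_gradients()`, `fibre_angle_map()`,
   `orientation_histogram()`, `fit_orientation_model()`). The degree of
   orientation is summarized by the alignment ratio
   `AR = 100 · A_G / (A_G + A_B)`, with A_G the area under the Gaussian term
   on [0°, 180°] and A_B = 180·B (`alignment_ratio()`): ≈0% for random
   fibres, →100% for perfect alignment.

3. **How do bone and marrow differ in composition?** SRS at 2850 cm⁻¹
   (CH₂, lipids) and 2920 cm⁻¹ (CH₃, proteins) is proportional to scatterer
   concentration; `bone_marrow_ratio()` reports the bone:marrow
   mean-intensity ratio per channel.

Group differences (e.g. wild type vs. a bone-loss knockout) are tested with
an exact Mann–Whitney U test (full enumeration with mid-ranked ties for
pooled n ≤ 12) or Student/Welch t tests, with mean ± SEM summaries and a
configurable significance threshold (`mann_whitney_u()`, `two_sample_t()`,
`compare_groups()`).

Because SHG fibre orientation is polarization-sensitive (emitted power
scales as cos⁴ of the angle between pump polarization and fibre axis), every
analysis is tagged by pump polarization (parallel/perpendicular to the
craniocaudal axis), and the package ships a **synthetic vertebra-scene
generator** (`scene_spec()`, `make_region_labels()`, `render_scene()`) whose
ground truth — fibre orientation mixture, cos⁴ polarization response,
compartment intensity ratios, noise — is fully known, so the complete
pipeline is testable without raw microscope data.

## Worked example

```r
library(nlobone)

spec   <- scene_spec(aligned_fraction = 0.7, theta0_true = 90,
                     sigma_true = 25, seed = 42)
labels <- make_region_labels(spec)
shg    <- render_shg_channel(spec, labels)$image

grad   <- sobel_gradients(shg)
angles <- fibre_angle_map(grad, epsilon = noise_floor_epsilon(grad, labels))
hist   <- orientation_histogram(angles, labels, c("cortical", "trabecular"),
                                erode_px = 1)
fit    <- fit_orientation_model(hist)
fit
#> <fibre_fit> A=0.773, theta0=90.2 deg, sigma=19.9 deg, B=0.253
#>   R^2=0.9669, alignment ratio=54.5% (cortical+trabecular, NA)

roi_mean_intensity(shg, labels, c("cortical", "trabecular"))
#> # A tibble: 1 × 7
#>   sample_id channel_id roi                 n_pixels mean_intensity    sd   sem
#>   <chr>     <chr>      <chr>                  <int>          <dbl> <dbl> <dbl>
#> 1 sample    SHG_PAR    cortical+trabecular   140736           27.6  40.2 0.107

bone_marrow_ratio(render_intensity_channel(spec, labels, "SRS_2850"), labels)
#> # A tibble: 1 × 5
#>   sample_id channel_id bone_mean marrow_mean ratio
#>   <chr>     <chr>          <dbl>       <dbl> <dbl>
#> 1 sample    SRS_2850        130.        100.  1.30
```

The fitted θ0 ≈ 90° recovers the generating preferential orientation (the
craniocaudal axis); the fitted σ reads a little below the generating 25°
because fibres nearly perpendicular to the pump polarization are dimmed by
the cos⁴ response (see the methods vignette). The SRS ratio 1.30 matches the
scene's ground-truth lipid bone:marrow contrast of 1.3.

`autoplot(hist, fit = fit)` overlays the fitted model on the histogram;
`generics::tidy(fit)` / `glance(fit)` give the parameters as tibbles.

End-to-end runs over sample groups — scene generation or TIFF stacks from
disk, ROI metrics, orientation fits, per-polarization summary tables, group
statistics, CSV reports and a JSON-lines log — go through `run_config()` +
`run_pipeline()`, or the thin command-line driver:

```sh
Rscript inst/cli/nlobone all --config run.yml --out results/ --seed 7 --test both
```

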