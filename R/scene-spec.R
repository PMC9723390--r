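#' Parameterize a synthetic vertebra scene
#'
#' A `scene_spec` fully determines a synthetic multimodal scene: the label
#' geometry (cortical band, trabecular struts, growth-plate band), the
#' collagen-fibre population rendered into the SHG channels, the SHG
#' polarization response, the SRS/TPEF compartment contrasts, the noise
#' level and the random seed. Identical specs produce bit-identical scenes,
#' so every downstream stage can be tested against known ground truth.
#'
#' Fibre orientations are drawn from the axial mixture
#' `aligned_fraction * WrappedGaussian(theta0_true, sigma_true) +
#' (1 - aligned_fraction) * Uniform[0, 180)`, in degrees, where the wrapped
#' Gaussian is an unwrapped normal folded modulo 180. Each fibre's rendered
#' amplitude is scaled by the polarization response
#' `polarization_floor + (1 - polarization_floor) * cos^4(theta - polarization_angle)`,
#' the squared-intensity form of the SHG dipole emission pattern. Angles
#' follow the image convention that 0 degrees is the horizontal image axis
#' and 90 degrees the vertical (craniocaudal) axis.
#'
#' @param image_height,image_width Scene size in pixels.
#' @param pixel_size Pixel side, micrometres.
#' @param margin Background frame width around the vertebra, pixels.
#' @param cortical_thickness Thickness of the cortical band, pixels.
#' @param n_struts Number of vertical trabecular struts.
#' @param strut_width Width of each strut, pixels.
#' @param growth_plate_rows Rows of the growth-plate band under the upper
#'   cortex (0 disables it).
#' @param n_fibres Number of collagen fibres rendered into SHG channels.
#' @param fibre_length_range Two-element range of fibre lengths, pixels.
#' @param fibre_width Fibre width, pixels.
#' @param fibre_amplitude Peak intensity of a fully co-polarized fibre,
#'   intensity units.
#' @param aligned_fraction Fraction of fibres drawn from the peaked
#'   (wrapped-Gaussian) orientation component, in `[0, 1]`.
#' @param theta0_true Centre of the peaked component, degrees in `[0, 180)`.
#' @param sigma_true Spread of the peaked component, degrees, `> 0`, in the
#'   [orientation_model()] parameterization (the underlying normal has sd
#'   `sqrt(2) * sigma_true`), so fitted `sigma` estimates `sigma_true`.
#' @param polarization_angle Pump polarization direction, degrees
#'   (90 = craniocaudal/vertical).
#' @param polarization_floor Fraction in `[0, 1]` added to the cos^4
#'   response so fibres perpendicular to the pump are not fully dark.
#' @param marrow_level Mean marrow intensity of SRS/TPEF channels,
#'   intensity units.
#' @param srs_bone_marrow_ratio_lipid,srs_bone_marrow_ratio_protein
#'   Bone:marrow mean-intensity ratio of the SRS 2850 / 2920 channels,
#'   dimensionless `> 0`.
#' @param tpef_bone_marrow_ratio Bone:marrow ratio of the TPEF channel.
#' @param bf_level Bright-field base intensity.
#' @param noise_sd Standard deviation of the additive Gaussian detector
#'   noise (clipped at zero), intensity units.
#' @param seed Integer seed; the sole source of randomness for the scene.
#'
#' @return An object of class `scene_spec` (a validated named list).
#' @seealso [make_region_labels()], [render_shg_channel()],
#'   [render_intensity_channel()], [render_scene()]
#' @export
#' @examples
#' spec <- scene_spec(image_height = 128, image_width = 128, n_fibres = 50)
#' spec$theta0_true
scene_spec <- function(image_height = 512, image_width = 512,
                       pixel_size = 1.0,
                       margin = 16,
                       cortical_thickness = 48,
                       n_struts = 6,
                       strut_width = 28,
                       growth_plate_rows = 40,
                       n_fibres = 600,
                       fibre_length_range = c(12, 28),
                       fibre_width = 4,
                       fibre_amplitude = 100,
                       aligned_fraction = 0.7,
                       theta0_true = 90,
                       sigma_true = 25,
                       polarization_angle = 90,
                       polarization_floor = 0.1,
                       marrow_level = 100,
                       srs_bone_marrow_ratio_lipid = 1.3,
                       srs_bone_marrow_ratio_protein = 1.2,
                       tpef_bone_marrow_ratio = 1.0,
                       bf_level = 200,
                       noise_sd = 2,
                       seed = 1L) {
  spec <- list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    pixel_size = pixel_size,
    margin = as.integer(margin),
    cortical_thickness = as.integer(cortical_thickness),
    n_struts = as.integer(n_struts),
    strut_width = as.integer(strut_width),
    growth_plate_rows = as.integer(growth_plate_rows),
    n_fibres = as.integer(n_fibres),
    fibre_length_range = as.numeric(fibre_length_range),
    fibre_width = as.numeric(fibre_width),
    fibre_amplitude = as.numeric(fibre_amplitude),
    aligned_fraction = as.numeric(aligned_fraction),
    theta0_true = as.numeric(theta0_true),
    sigma_true = as.numeric(sigma_true),
    polarization_angle = as.numeric(polarization_angle),
    polarization_floor = as.numeric(polarization_floor),
    marrow_level = as.numeric(marrow_level),
    srs_bone_marrow_ratio_lipid = as.numeric(srs_bone_marrow_ratio_lipid),
    srs_bone_marrow_ratio_protein = as.numeric(srs_bone_marrow_ratio_protein),
    tpef_bone_marrow_ratio = as.numeric(tpef_bone_marrow_ratio),
    bf_level = as.numeric(bf_level),
    noise_sd = as.numeric(noise_sd),
    seed = as.integer(seed)
  )
  class(spec) <- "scene_spec"
  validate_scene_spec(spec)
}

validate_scene_spec <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with(spec, {
    if (image_height < 8 || image_width < 8)
      abort("image must be at least 8x8 pixels")
    if (aligned_fraction < 0 || aligned_fraction > 1)
      abort("aligned_fraction must lie in [0, 1]")
    if (sigma_true <= 0) abort("sigma_true must be > 0")
    if (theta0_true < 0 || theta0_true >= 180)
      abort("theta0_true must lie in [0, 180)")
    if (polarization_floor < 0 || polarization_floor > 1)
      abort("polarization_floor must lie in [0, 1]")
    if (srs_bone_marrow_ratio_lipid <= 0 || srs_bone_marrow_ratio_protein <= 0 ||
        tpef_bone_marrow_ratio <= 0)
      abort("bone:marrow intensity ratios must be > 0")
    if (noise_sd < 0) abort("noise_sd must be >= 0")
    if (length(fibre_length_range) != 2 || any(fibre_length_range <= 0) ||
        fibre_length_range[1] > fibre_length_range[2])
      abort("fibre_length_range must be an increasing positive pair")
    inner_h <- image_height - 2L * margin - 2L * cortical_thickness
    inner_w <- image_width - 2L * margin - 2L * cortical_thickness
    if (margin < 0 || cortical_thickness < 1 || inner_h < 1 || inner_w < 1)
      abort("label geometry does not fit inside the image")
    if (growth_plate_rows < 0 || growth_plate_rows >= inner_h)
      abort("growth-plate band does not fit inside the vertebra interior")
    if (n_struts < 0 || strut_width < 1 && n_struts > 0 ||
        n_struts * strut_width > inner_w)
      abort("trabecular struts do not fit inside the vertebra interior")
  })
  spec
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec> %dx%d px (%.3g um/px), seed %d\n",
              x$image_height, x$image_width, x$pixel_size, x$seed))
  cat(sprintf("  fibres: n=%d, aligned %.2f @ theta0=%.1f deg, sigma=%.1f deg\n",
              x$n_fibres, x$aligned_fraction, x$theta0_true, x$sigma_true))
  cat(sprintf("  polarization: %.1f deg, floor %.2f; noise sd %.3g\n",
              x$polarization_angle, x$polarization_floor, x$noise_sd))
  cat(sprintf("  SRS bone:marrow ratios lipid %.3g, protein %.3g\n",
              x$srs_bone_marrow_ratio_lipid, x$srs_bone_marrow_ratio_protein))
  invisible(x)
}

#' Serialize a scene spec to a flat YAML file
#'
#' The spec is stored as a flat key/value mapping so a scene written to disk
#' always carries its own ground truth.
#'
#' @param spec A [scene_spec()].
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_scene_spec <- function(spec, path) {
  stopifnot(inherits(spec, "scene_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_scene_spec
#' @return `read_scene_spec()` returns the validated `scene_spec`.
#' @export
read_scene_spec <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(scene_spec, vals)
}
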