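#' Sample fibre orientations from the axial mixture model
#'
#' Draws `n` orientations (degrees, axial on `[0, 180)`) from
#' `aligned_fraction * WrappedGaussian(theta0, sigma) +
#' (1 - aligned_fraction) * Uniform[0, 180)`. The wrapped Gaussian is an
#' unwrapped normal folded modulo 180, matching the undirected nature of
#' fibre orientation. `sigma` uses the [orientation_model()]
#' parameterization (exponent `((theta - theta0) / (2 sigma))^2`), so the
#' underlying normal has standard deviation `sqrt(2) * sigma`; fitting the
#' model to orientations drawn here recovers `sigma` itself. Uses the
#' current RNG state.
#'
#' @param n Number of draws.
#' @param aligned_fraction Mixture weight of the peaked component.
#' @param theta0,sigma Centre and spread of the peaked component, degrees
#'   (model parameterization).
#' @return Numeric vector of `n` angles in `[0, 180)`.
#' @export
sample_fibre_orientations <- function(n, aligned_fraction, theta0, sigma) {
  stopifnot(aligned_fraction >= 0, aligned_fraction <= 1, sigma > 0)
  from_peak <- runif(n) < aligned_fraction
  ang <- runif(n, 0, 180)
  k <- sum(from_peak)
  if (k > 0) ang[from_peak] <- (rnorm(k, theta0, sqrt(2) * sigma)) %% 180
  ang
}

#' CDF of the axial orientation mixture
#'
#' Distribution function of the mixture sampled by
#' [sample_fibre_orientations()], used for goodness-of-fit checks against
#' generated scenes.
#'
#' @param x Angles in `[0, 180]`, degrees.
#' @inheritParams sample_fibre_orientations
#' @return `P(angle <= x)` for each element of `x`.
#' @export
orientation_mixture_cdf <- function(x, aligned_fraction, theta0, sigma) {
  # folded-normal CDF on [0,180): sum the normal mass of every 180-degree
  # period; +/-6 sd windows cover all non-negligible terms
  s <- sqrt(2) * sigma  # sd of the unwrapped normal (model parameterization)
  kmax <- ceiling((6 * s + 180) / 180)
  ks <- -kmax:kmax
  fw <- function(xx) {
    sum(pnorm((xx + 180 * ks - theta0) / s) -
        pnorm((180 * ks - theta0) / s))
  }
  vapply(x, function(xx) {
    xx <- min(max(xx, 0), 180)
    aligned_fraction * fw(xx) + (1 - aligned_fraction) * xx / 180
  }, numeric(1))
}

# internal: additive Gaussian detector noise, clipped at zero
add_noise <- function(img, sd) {
  if (sd > 0) img <- img + matrix(rnorm(length(img), 0, sd), nrow(img))
  img[img < 0] <- 0
  img
}

# internal: draw one anti-aliased line segment into img (adds intensity).
# The cross-section is a Gaussian of sd = width/2, truncated at 2 sd: a
# smooth profile keeps the discrete Sobel gradient direction accurate at
# every pixel of the fibre (a hard-edged line does not), while the tight
# truncation limits the footprint so co-located fibres rarely overlap.
# The truncation ring runs parallel to the fibre axis, so it adds no
# angular distortion of its own.
draw_segment <- function(img, r0, c0, theta_deg, len, width, amplitude) {
  th <- theta_deg * pi / 180
  # x = column, y = row (y increases caudally); axial, so sign is arbitrary
  dx <- cos(th); dy <- sin(th)
  half <- len / 2
  sw <- width / 2
  x0 <- c0 - half * dx; y0 <- r0 - half * dy
  x1 <- c0 + half * dx; y1 <- r0 + half * dy
  pad <- 2 * sw + 1
  rr <- max(1L, floor(min(y0, y1) - pad)):min(nrow(img), ceiling(max(y0, y1) + pad))
  cc <- max(1L, floor(min(x0, x1) - pad)):min(ncol(img), ceiling(max(x0, x1) + pad))
  if (!length(rr) || !length(cc)) return(img)
  py <- matrix(rr, length(rr), length(cc))
  px <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  # squared distance from pixel centres to the segment
  vx <- x1 - x0; vy <- y1 - y0
  l2 <- vx^2 + vy^2
  tt <- ((px - x0) * vx + (py - y0) * vy) / l2
  tt[tt < 0] <- 0; tt[tt > 1] <- 1
  d2 <- (px - (x0 + tt * vx))^2 + (py - (y0 + tt * vy))^2
  cov <- exp(-d2 / (2 * sw^2))
  cov[d2 > (2 * sw)^2] <- 0
  img[rr, cc] <- img[rr, cc] + amplitude * cov
  img
}

#' Render an SHG channel of a synthetic scene
#'
#' Renders `n_fibres` anti-aliased line segments whose centres fall on bone
#' pixels (cortical or trabecular) and whose orientations follow the spec's
#' axial mixture. Each fibre's amplitude is modulated by the polarization
#' response `floor + (1 - floor) * cos^4(theta_fibre - polarization_angle)`,
#' so fibres parallel to the pump polarization radiate most strongly.
#' Fibre intensity outside bone classes is clipped to zero, then additive
#' Gaussian noise (clipped at zero) is applied. All randomness derives from
#' `spec$seed`, so the same spec gives the same fibre population regardless
#' of the polarization the channel is rendered under.
#'
#' @param spec A [scene_spec()].
#' @param labels Label map from [make_region_labels()] for the same spec.
#' @param polarization_angle Pump polarization, degrees; defaults to the
#'   spec's value. 90 is the craniocaudal (vertical) axis.
#' @return A list with `image` (a [channel_image()], id `SHG_PAR` when the
#'   polarization is within 45 degrees of vertical, else `SHG_PERP`) and
#'   `truth` (a `scene_truth` list carrying the spec, the per-fibre
#'   orientations in degrees, and per-class noiseless mean intensities).
#' @export
render_shg_channel <- function(spec, labels,
                               polarization_angle = spec$polarization_angle) {
  validate_scene_spec(spec)
  stopifnot(nrow(labels) == spec$image_height,
            ncol(labels) == spec$image_width)
  codes <- label_codes()
  bone <- labels == codes[["cortical"]] | labels == codes[["trabecular"]]
  if (!any(bone)) abort("scene has no bone pixels to host fibres")
  bone_idx <- which(bone)
  h <- spec$image_height; w <- spec$image_width

  withr::with_seed(spec$seed, {
    centres <- sample(bone_idx, spec$n_fibres, replace = TRUE)
    thetas <- sample_fibre_orientations(spec$n_fibres, spec$aligned_fraction,
                                        spec$theta0_true, spec$sigma_true)
    lens <- runif(spec$n_fibres, spec$fibre_length_range[1],
                  spec$fibre_length_range[2])
    img <- matrix(0, h, w)
    delta <- (thetas - polarization_angle) * pi / 180
    amp <- spec$fibre_amplitude *
      (spec$polarization_floor + (1 - spec$polarization_floor) * cos(delta)^4)
    for (i in seq_len(spec$n_fibres)) {
      r0 <- (centres[i] - 1L) %% h + 1L
      c0 <- (centres[i] - 1L) %/% h + 1L
      img <- draw_segment(img, r0, c0, thetas[i], lens[i],
                          spec$fibre_width, amp[i])
    }
    img[!bone] <- 0
    clean <- img
    img <- add_noise(img, spec$noise_sd)
  })

  pol_par <- abs(((polarization_angle - 90) + 90) %% 180 - 90) <= 45
  ch <- channel_image(img, if (pol_par) "SHG_PAR" else "SHG_PERP",
                      pixel_size = spec$pixel_size)
  truth <- structure(list(
    spec = spec,
    fibre_orientations = thetas,
    class_means = class_mean_table(clean, labels)
  ), class = "scene_truth")
  list(image = ch, truth = truth)
}

# internal: per-class mean intensities of a (noiseless) image
class_mean_table <- function(img, labels) {
  codes <- label_codes()
  vapply(codes, function(k) {
    px <- img[labels == k]
    if (length(px)) mean(px) else NA_real_
  }, numeric(1))
}

#' Render a compartment-contrast channel (SRS or TPEF) of a synthetic scene
#'
#' SRS signal is proportional to the concentration of the probed molecular
#' species, so these channels are modelled as piecewise-constant compartment
#' intensities: marrow (and growth plate) at `marrow_level`, bone (cortical
#' and trabecular) at `ratio * marrow_level`, background at zero, plus
#' additive Gaussian noise clipped at zero. Before noise, the bone:marrow
#' mean-intensity ratio equals the spec's ratio for the channel exactly.
#'
#' @inheritParams render_shg_channel
#' @param channel One of `"SRS_2850"` (lipid, CH2), `"SRS_2920"` (protein,
#'   CH3), `"TPEF"`.
#' @return A [channel_image()].
#' @export
render_intensity_channel <- function(spec, labels, channel) {
  validate_scene_spec(spec)
  channel <- match.arg(channel, c("SRS_2850", "SRS_2920", "TPEF"))
  ratio <- switch(channel,
                  SRS_2850 = spec$srs_bone_marrow_ratio_lipid,
                  SRS_2920 = spec$srs_bone_marrow_ratio_protein,
                  TPEF = spec$tpef_bone_marrow_ratio)
  if (ratio <= 0) abort("bone:marrow ratio must be > 0")
  codes <- label_codes()
  img <- matrix(0, nrow(labels), ncol(labels))
  img[labels == codes[["marrow"]]] <- spec$marrow_level
  img[labels == codes[["growth_plate"]]] <- spec$marrow_level
  img[labels == codes[["cortical"]] |
      labels == codes[["trabecular"]]] <- ratio * spec$marrow_level
  # channel-specific seed stream so channels are independent but reproducible
  ch_seed <- (spec$seed + 7L * match(channel, channel_ids())) %% .Machine$integer.max
  withr::with_seed(ch_seed, img <- add_noise(img, spec$noise_sd))
  channel_image(img, channel, pixel_size = spec$pixel_size)
}

#' Render a complete multimodal synthetic scene
#'
#' Builds the label map and all six channels (bright field, TPEF, SHG under
#' parallel and perpendicular pump polarization, SRS lipid and protein) of a
#' synthetic vertebra. The two SHG channels share the identical fibre
#' population and differ only in the polarization response.
#'
#' @inheritParams render_shg_channel
#' @param sample_id,genotype Metadata stored in the stack.
#' @return A list with `stack` (a [multimodal_stack()]), `labels`, and
#'   `truth` (per-fibre orientations and noiseless class means of the
#'   parallel SHG channel).
#' @export
render_scene <- function(spec, sample_id = "synthetic", genotype = "WT") {
  labels <- make_region_labels(spec)
  shg_par <- render_shg_channel(spec, labels, polarization_angle = 90)
  shg_perp <- render_shg_channel(spec, labels, polarization_angle = 0)
  shg_perp$image$channel_id <- "SHG_PERP"
  codes <- label_codes()
  bf <- matrix(spec$bf_level, spec$image_height, spec$image_width)
  bf[labels != codes[["background"]]] <- spec$bf_level * 0.6
  withr::with_seed(spec$seed + 13L, bf <- add_noise(bf, spec$noise_sd))
  channels <- list(
    channel_image(bf, "BF", spec$pixel_size),
    render_intensity_channel(spec, labels, "TPEF"),
    shg_par$image,
    shg_perp$image,
    render_intensity_channel(spec, labels, "SRS_2850"),
    render_intensity_channel(spec, labels, "SRS_2920")
  )
  stack <- multimodal_stack(channels, sample_id = sample_id,
                            genotype = genotype)
  list(stack = stack, labels = labels, truth = shg_par$truth)
}
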