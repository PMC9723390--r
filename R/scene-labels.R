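#' Build the tissue label map of a synthetic vertebra scene
#'
#' Rasterizes a stylized vertebral cross-section: a background frame, a
#' connected rectangular cortical band of the requested thickness, a
#' growth-plate band directly under the upper cortex, evenly spaced vertical
#' trabecular struts, and marrow filling the remaining interior. Every pixel
#' receives exactly one class from [label_codes()]. The construction is
#' deterministic (no randomness).
#'
#' @param spec A [scene_spec()].
#' @return An integer matrix (`image_height` x `image_width`) of class
#'   `region_label_map`, with values from [label_codes()].
#' @export
#' @examples
#' labels <- make_region_labels(scene_spec(image_height = 64, image_width = 64,
#'   margin = 4, cortical_thickness = 4, growth_plate_rows = 4,
#'   n_struts = 3, strut_width = 3))
#' table(labels)
make_region_labels <- function(spec) {
  validate_scene_spec(spec)
  codes <- label_codes()
  h <- spec$image_height; w <- spec$image_width
  m <- spec$margin; t <- spec$cortical_thickness

  labels <- matrix(codes[["background"]], h, w)

  # vertebra body -> cortical, then carve the interior out of it
  vr <- (m + 1L):(h - m); vc <- (m + 1L):(w - m)
  labels[vr, vc] <- codes[["cortical"]]
  ir <- (m + t + 1L):(h - m - t)
  ic <- (m + t + 1L):(w - m - t)
  labels[ir, ic] <- codes[["marrow"]]

  # growth-plate band: top rows of the interior, full interior width
  if (spec$growth_plate_rows > 0L) {
    gp <- ir[seq_len(spec$growth_plate_rows)]
    labels[gp, ic] <- codes[["growth_plate"]]
  }

  # trabecular struts: vertical bands in the marrow rows, evenly spaced
  if (spec$n_struts > 0L) {
    mrows <- ir[labels[ir, ic[1]] == codes[["marrow"]]]
    wi <- length(ic)
    centers <- ic[1] - 1 + (seq_len(spec$n_struts) - 0.5) * wi / spec$n_struts
    half <- spec$strut_width / 2
    for (ctr in centers) {
      cols <- max(ic[1], ceiling(ctr - half)):min(ic[length(ic)],
                                                  ceiling(ctr + half) - 1L)
      labels[mrows, cols] <- codes[["trabecular"]]
    }
  }

  class(labels) <- c("region_label_map", class(labels))
  labels
}

#' @export
print.region_label_map <- function(x, ...) {
  codes <- label_codes()
  counts <- vapply(codes, function(k) sum(x == k), integer(1))
  cat(sprintf("<region_label_map> %dx%d px\n", nrow(x), ncol(x)))
  print(counts)
  invisible(x)
}
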