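#' Sobel image gradients
#'
#' Cross-correlates the image with the 3x3 Sobel kernels
#' `Gx = [[+1,0,-1],[+2,0,-2],[+1,0,-1]]` and
#' `Gy = [[+1,+2,+1],[0,0,0],[-1,-2,-1]]` (cross-correlation, not
#' convolution: the kernels are applied unflipped). Borders are handled by
#' reflect padding (the edge row/column is mirrored outward), so the output
#' has the input's shape.
#'
#' @param image A [channel_image()] or a plain numeric matrix, at least 3x3.
#' @return A `gradient_field`: list with matrices `gx`, `gy`, `magnitude`
#'   (`sqrt(gx^2 + gy^2)`).
#' @export
sobel_gradients <- function(image) {
  img <- if (inherits(image, "channel_image")) image$pixels else image
  stopifnot(is.matrix(img))
  nr <- nrow(img); nc <- ncol(img)
  if (nr < 3L || nc < 3L) abort("image must be at least 3x3 for Sobel kernels")
  p <- img[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc)]  # reflect pad
  s <- function(di, dj) p[(1L + di):(nr + di), (1L + dj):(nc + dj)]
  gx <- (s(0, 0) - s(0, 2)) + 2 * (s(1, 0) - s(1, 2)) + (s(2, 0) - s(2, 2))
  gy <- (s(0, 0) + 2 * s(0, 1) + s(0, 2)) - (s(2, 0) + 2 * s(2, 1) + s(2, 2))
  structure(list(gx = gx, gy = gy, magnitude = sqrt(gx^2 + gy^2)),
            class = "gradient_field")
}

#' Pixel-wise collagen fibre angle from a gradient field
#'
#' The gradient direction `phi = atan2(gy, gx)` (full-quadrant, folded to
#' `[0, 180)`) points across intensity edges, i.e. perpendicular to the
#' local fibre axis; the reported fibre angle is `(phi + 90) mod 180`, so a
#' structure elongated along the vertical (craniocaudal) image axis reads
#' 90 degrees. Pixels whose gradient magnitude falls below the validity gate
#' carry no orientation information and are masked out, not treated as
#' errors.
#'
#' @param grad A `gradient_field` from [sobel_gradients()].
#' @param epsilon Absolute magnitude gate; pixels with
#'   `magnitude < epsilon` are flagged invalid. Default
#'   `1e-6 * max(magnitude)`: effectively every pixel with any gradient
#'   counts.
#' @param epsilon_quantile Alternative percentile gate in `[0, 1)`; when
#'   given, `epsilon` is set to that quantile of the nonzero magnitudes
#'   (useful for noisy data).
#' @return List with `angle` (degrees in `[0, 180)`, `NA` where invalid)
#'   and `valid` (logical matrix).
#' @export
fibre_angle_map <- function(grad, epsilon = NULL, epsilon_quantile = NULL) {
  stopifnot(inherits(grad, "gradient_field"))
  mag <- grad$magnitude
  if (!is.null(epsilon_quantile)) {
    stopifnot(epsilon_quantile >= 0, epsilon_quantile < 1)
    epsilon <- stats::quantile(mag[mag > 0], epsilon_quantile, names = FALSE)
  }
  if (is.null(epsilon)) epsilon <- 1e-6 * max(mag)
  valid <- mag >= epsilon & mag > 0
  phi <- (atan2(grad$gy, grad$gx) * 180 / pi) %% 180
  angle <- (phi + 90) %% 180
  angle[!valid] <- NA_real_
  list(angle = angle, valid = valid)
}

#' Erode a binary ROI mask
#'
#' Shrinks a mask by `px` pixels (binary erosion with a 3x3 box, applied
#' `px` times). Used before orientation histogramming to drop the
#' boundary layer of an ROI: at pixels whose 3x3 Sobel stencil straddles a
#' tissue-class boundary, the gradient reflects the compartment interface
#' (an edge parallel to the boundary), not fibre texture.
#'
#' @param mask Logical matrix.
#' @param px Erosion depth in pixels (0 returns the mask unchanged).
#' @return Logical matrix of the same shape.
#' @export
erode_mask <- function(mask, px = 1L) {
  stopifnot(is.logical(mask), is.matrix(mask), px >= 0)
  nr <- nrow(mask); nc <- ncol(mask)
  for (i in seq_len(px)) {
    p <- rbind(FALSE, cbind(FALSE, mask, FALSE), FALSE)
    s <- function(di, dj) p[(1L + di):(nr + di), (1L + dj):(nc + dj)]
    mask <- s(0, 0) & s(0, 1) & s(0, 2) & s(1, 0) & s(1, 1) & s(1, 2) &
      s(2, 0) & s(2, 1) & s(2, 2)
  }
  mask
}

#' Noise-floor orientation validity gate from background pixels
#'
#' Estimates the gradient-magnitude level produced by detector noise alone
#' as the median Sobel magnitude over background-class pixels, and returns
#' `k` times it as the validity gate for [fibre_angle_map()]. Gradients at
#' or below the noise floor carry no orientation information; gating them
#' out removes the spurious structure that near-zero clipped-noise stencils
#' add to orientation histograms.
#'
#' @param grad A `gradient_field`.
#' @param labels Label map of the same shape.
#' @param k Multiple of the background median magnitude (default 3; for a
#'   Rayleigh-distributed noise magnitude this passes only ~0.2% of pure
#'   noise pixels).
#' @return The gate value, or `NULL` when the map has no background pixels
#'   or the background is exactly constant (callers then fall back to the
#'   [fibre_angle_map()] default).
#' @export
noise_floor_epsilon <- function(grad, labels, k = 3) {
  stopifnot(inherits(grad, "gradient_field"))
  bg <- labels == label_codes()[["background"]]
  if (!any(bg)) return(NULL)
  med <- median(grad$magnitude[bg])
  if (med <= 0) return(NULL)
  k * med
}

#' Orientation histogram over an ROI
#'
#' Bins the valid fibre angles of the selected tissue classes into 180
#' one-degree bins on `[0, 180)` (left-closed, right-open) and normalizes
#' to percentage of analyzable pixels, so the bins sum to 100.
#'
#' @param angle_map Result of [fibre_angle_map()].
#' @param labels Label map of the same shape.
#' @param classes Tissue classes defining the ROI (names or codes).
#' @param sample_id,polarization Provenance tags copied into the result.
#' @param erode_px Erode the ROI mask by this many pixels first (see
#'   [erode_mask()]); 0 uses the classes' pixels exactly.
#' @return A tibble of class `orientation_histogram` with columns
#'   `bin_center` (0.5, 1.5, ..., 179.5 degrees) and `counts_pct`, plus
#'   attributes `n_analyzable`, `roi`, `sample_id`, `polarization`.
#' @export
orientation_histogram <- function(angle_map, labels, classes,
                                  sample_id = "sample",
                                  polarization = NA_character_,
                                  erode_px = 0L) {
  stopifnot(identical(dim(angle_map$angle), dim(labels)[1:2]))
  codes <- resolve_classes(classes)
  roi_mask <- matrix(labels %in% codes, nrow(angle_map$angle))
  if (erode_px > 0L) roi_mask <- erode_mask(roi_mask, erode_px)
  sel <- angle_map$valid & roi_mask
  n <- sum(sel)
  if (n == 0L) abort("empty ROI: no valid-orientation pixels in the selected classes")
  a <- angle_map$angle[sel]
  bin <- pmin(floor(a), 179)  # angles are in [0,180); guard fp edge
  counts <- tabulate(bin + 1L, nbins = 180L)
  roi <- paste(sort(names(label_codes())[match(codes, label_codes())]),
               collapse = "+")
  out <- tibble(bin_center = seq(0.5, 179.5, by = 1),
                counts_pct = 100 * counts / n)
  attr(out, "n_analyzable") <- n
  attr(out, "roi") <- roi
  attr(out, "sample_id") <- sample_id
  attr(out, "polarization") <- polarization
  class(out) <- c("orientation_histogram", class(out))
  out
}

#' @export
#' @rdname orientation_histogram
#' @param x,... An `orientation_histogram`; unused extras.
#' @details `glance()` summarizes the histogram: analyzable pixel count,
#'   ROI, and the modal bin.
glance.orientation_histogram <- function(x, ...) {
  tibble(n_analyzable = attr(x, "n_analyzable"),
         roi = attr(x, "roi"),
         mode_deg = x$bin_center[which.max(x$counts_pct)],
         max_pct = max(x$counts_pct))
}

#' Plot an orientation histogram (and optionally a fitted model)
#'
#' @param object An `orientation_histogram`.
#' @param fit Optional `fibre_fit` whose curve is overlaid.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.orientation_histogram <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_center,
                                            y = .data$counts_pct)) +
    ggplot2::geom_col(width = 1, fill = "grey60") +
    ggplot2::labs(x = "fibre orientation (degrees)",
                  y = "pixel counts (%)",
                  title = attr(object, "roi")) +
    ggplot2::scale_x_continuous(breaks = seq(0, 180, 45), limits = c(0, 180))
  if (!is.null(fit)) {
    curve <- tibble(bin_center = seq(0, 180, by = 0.5))
    curve$counts_pct <- orientation_model(curve$bin_center, fit$A,
                                          fit$theta0, fit$sigma, fit$B)
    p <- p + ggplot2::geom_line(data = curve, color = "#c0392b",
                                linewidth = 0.8)
  }
  p
}
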