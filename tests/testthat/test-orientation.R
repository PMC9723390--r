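test_that("Sobel gradients vanish on constant images", {
  g <- sobel_gradients(matrix(5, 7, 9))
  expect_true(all(g$gx == 0) && all(g$gy == 0) && all(g$magnitude == 0))
})

test_that("Sobel of a horizontal ramp gives gx = -8, gy = 0 in the interior", {
  img <- outer(1:8, 1:10, function(r, c) c)  # I(r, c) = c
  g <- sobel_gradients(img)
  expect_true(all(g$gx[2:7, 2:9] == -8))
  expect_true(all(g$gy[2:7, 2:9] == 0))
})

test_that("gy of an image equals the transposed gx of its transpose", {
  withr::with_seed(5, img <- matrix(stats::runif(12 * 15), 12, 15))
  g <- sobel_gradients(img)
  gt <- sobel_gradients(t(img))
  expect_equal(g$gy, t(gt$gx))
})

test_that("Sobel matches the brute-force double loop bit-exactly", {
  withr::with_seed(99, {
    for (dims in list(c(3, 3), c(5, 9), c(16, 16))) {
      img <- matrix(stats::runif(prod(dims)) * 50, dims[1], dims[2])
      g <- sobel_gradients(img)
      bf <- sobel_bruteforce(img)
      expect_identical(g$gx, bf$gx)
      expect_identical(g$gy, bf$gy)
    }
  })
  expect_error(sobel_gradients(matrix(1, 2, 5)), "3x3")
})

test_that("fibre angles follow the axis convention", {
  gf <- function(gx, gy) structure(
    list(gx = matrix(gx, 3, 3), gy = matrix(gy, 3, 3),
         magnitude = matrix(sqrt(gx^2 + gy^2), 3, 3)),
    class = "gradient_field")
  # vertical stripe: horizontal gradient -> fibre along the vertical = 90
  expect_equal(fibre_angle_map(gf(1, 0))$angle[1, 1], 90)
  # horizontal stripe: vertical gradient -> fibre angle 0
  expect_equal(fibre_angle_map(gf(0, 1))$angle[1, 1], 0)
  # diagonal gradient at 45 -> fibre at 135
  expect_equal(fibre_angle_map(gf(1, 1))$angle[1, 1], 135)
  # zero-gradient pixels are masked, not errors
  am <- fibre_angle_map(gf(0, 0))
  expect_true(all(!am$valid))
  expect_true(all(is.na(am$angle)))
})

test_that("raising the validity gate monotonically shrinks the valid set", {
  spec <- small_spec(seed = 8)
  labels <- make_region_labels(spec)
  g <- sobel_gradients(render_shg_channel(spec, labels)$image)
  eps <- c(1e-6, 1, 5, 20, 100)
  n <- vapply(eps, function(e) sum(fibre_angle_map(g, epsilon = e)$valid),
              integer(1))
  expect_true(all(diff(n) <= 0))
  # quantile gate: higher quantile, fewer valid pixels
  n50 <- sum(fibre_angle_map(g, epsilon_quantile = 0.5)$valid)
  n90 <- sum(fibre_angle_map(g, epsilon_quantile = 0.9)$valid)
  expect_lt(n90, n50)
})

test_that("histogram bins partition [0,180) and sum to 100%", {
  withr::with_seed(17, {
    angle <- matrix(stats::runif(400, 0, 180), 20, 20)
    valid <- matrix(stats::runif(400) < 0.8, 20, 20)
  })
  angle[!valid] <- NA
  labels <- matrix(1L, 20, 20)
  h <- orientation_histogram(list(angle = angle, valid = valid),
                             labels, "cortical")
  expect_equal(nrow(h), 180L)
  expect_equal(sum(h$counts_pct), 100, tolerance = 1e-9)
  expect_equal(attr(h, "n_analyzable"), sum(valid))
  expect_true(all(h$counts_pct >= 0))
  expect_equal(h$bin_center, seq(0.5, 179.5, 1))
})

test_that("a delta distribution lands entirely in its 1-degree bin", {
  angle <- matrix(90.2, 5, 5); valid <- matrix(TRUE, 5, 5)
  h <- orientation_histogram(list(angle = angle, valid = valid),
                             matrix(1L, 5, 5), "cortical")
  expect_equal(h$counts_pct[h$bin_center == 90.5], 100)
  expect_equal(sum(h$counts_pct != 0), 1L)
})

test_that("empty ROI for the histogram raises an error", {
  angle <- matrix(NA_real_, 4, 4); valid <- matrix(FALSE, 4, 4)
  expect_error(orientation_histogram(list(angle = angle, valid = valid),
                                     matrix(1L, 4, 4), "cortical"),
               "empty ROI")
})

test_that("vertically aligned scenes put the histogram mode at 90 degrees", {
  spec <- small_spec(aligned_fraction = 1, theta0_true = 90, sigma_true = 2,
                     n_fibres = 80, seed = 21)
  labels <- make_region_labels(spec)
  am <- fibre_angle_map(sobel_gradients(render_shg_channel(spec, labels)$image))
  h <- orientation_histogram(am, labels, c("cortical", "trabecular"))
  mode_bin <- h$bin_center[which.max(h$counts_pct)]
  expect_true(mode_bin >= 90 - 0.5 && mode_bin <= 90 + 0.5)
})

test_that("rotating the image by 90 degrees shifts fibre angles by 90", {
  spec <- small_spec(seed = 33, aligned_fraction = 0.7, theta0_true = 40,
                     sigma_true = 10, noise_sd = 0)
  labels <- make_region_labels(spec)
  img <- render_shg_channel(spec, labels)$image$pixels
  rot <- rot90ccw(img)
  am <- fibre_angle_map(sobel_gradients(img))
  am_rot <- fibre_angle_map(sobel_gradients(rot))
  nr <- nrow(img); nc <- ncol(img)
  interior <- 3:(nr - 2)
  mism <- 0L; checked <- 0L
  for (i in interior) for (j in interior) {
    # rot[i, j] corresponds to img[j, nc + 1 - i]
    a_r <- am_rot$angle[i, j]; a_o <- am$angle[j, nc + 1 - i]
    if (!is.na(a_r) && !is.na(a_o)) {
      checked <- checked + 1L
      if (axial_diff(a_r, (a_o + 90) %% 180) > 1e-6) mism <- mism + 1L
    }
  }
  expect_gt(checked, 1000L)
  expect_equal(mism, 0L)
})

test_that("mask erosion removes exactly the boundary layer", {
  m <- matrix(FALSE, 10, 10); m[3:8, 3:8] <- TRUE
  e1 <- erode_mask(m, 1)
  expect_equal(sum(e1), 16)          # 6x6 block -> 4x4
  expect_true(all(which(e1) %in% which(m)))
  expect_identical(erode_mask(m, 0), m)
  expect_equal(sum(erode_mask(m, 3)), 0)  # erosion exhausts the block
})

test_that("background noise floor gate scales with the noise level", {
  spec_lo <- small_spec(noise_sd = 1, seed = 2)
  spec_hi <- small_spec(noise_sd = 4, seed = 2)
  labels <- make_region_labels(spec_lo)
  g_lo <- sobel_gradients(render_shg_channel(spec_lo, labels)$image)
  g_hi <- sobel_gradients(render_shg_channel(spec_hi, labels)$image)
  e_lo <- noise_floor_epsilon(g_lo, labels)
  e_hi <- noise_floor_epsilon(g_hi, labels)
  expect_gt(e_hi, 2 * e_lo)
  # noiseless background gives no estimate
  g0 <- sobel_gradients(render_shg_channel(small_spec(noise_sd = 0),
                                           labels)$image)
  expect_null(noise_floor_epsilon(g0, labels))
})
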