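test_that("scene_spec validates its invariants", {
  expect_s3_class(small_spec(), "scene_spec")
  expect_error(small_spec(aligned_fraction = 1.2), "aligned_fraction")
  expect_error(small_spec(sigma_true = 0), "sigma_true")
  expect_error(small_spec(srs_bone_marrow_ratio_lipid = 0), "ratios")
  expect_error(small_spec(cortical_thickness = 200), "geometry")
  expect_error(small_spec(n_struts = 50, strut_width = 20), "struts")
})

test_that("scene spec round-trips through its YAML serialization", {
  spec <- small_spec(theta0_true = 42.5, noise_sd = 0.7)
  path <- withr::local_tempfile(fileext = ".yml")
  write_scene_spec(spec, path)
  expect_equal(read_scene_spec(path), spec)
})

test_that("label map partitions the frame into the five classes", {
  spec <- small_spec()
  labels <- make_region_labels(spec)
  counts <- table(factor(as.vector(labels), levels = label_codes()))
  expect_equal(sum(counts), spec$image_height * spec$image_width)
  expect_true(all(counts[c("0", "1", "2", "3", "4")] > 0))
})

test_that("zero trabecular struts yields no trabecular pixels", {
  labels <- make_region_labels(small_spec(n_struts = 0))
  expect_equal(sum(labels == label_codes()[["trabecular"]]), 0L)
})

test_that("cortical band pixel count matches independent rasterization", {
  spec <- small_spec(image_height = 200, image_width = 200, margin = 20,
                     cortical_thickness = 10)
  labels <- make_region_labels(spec)
  # independent count: pixels inside the vertebra rectangle but not inside
  # the rectangle inset by the band thickness
  in_band <- 0L
  for (r in 1:200) for (c in 1:200) {
    outer_rect <- r > 20 && r <= 180 && c > 20 && c <= 180
    inner_rect <- r > 30 && r <= 170 && c > 30 && c <= 170
    if (outer_rect && !inner_rect) in_band <- in_band + 1L
  }
  expect_identical(sum(labels == label_codes()[["cortical"]]), in_band)
})

test_that("uniform mixture produces a flat fibre-orientation distribution", {
  withr::with_seed(2024, {
    ang <- sample_fibre_orientations(2000, aligned_fraction = 0,
                                     theta0 = 90, sigma = 25)
  })
  counts <- tabulate(floor(ang / 10) + 1L, nbins = 18L)
  gof <- suppressWarnings(stats::chisq.test(counts))
  expect_gt(gof$p.value, 0.01)
})

test_that("collapsed aligned component concentrates orientations at the peak", {
  withr::with_seed(7, {
    ang <- sample_fibre_orientations(2000, aligned_fraction = 1,
                                     theta0 = 90, sigma = 0.25)
  })
  expect_true(all(ang >= 88 & ang <= 92))
  expect_lt(max(abs(ang - 90)), 2)
})

test_that("drawn orientations follow the mixture CDF (KS, multiple seeds)", {
  pass <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      ang <- sample_fibre_orientations(5000, aligned_fraction = 0.6,
                                       theta0 = 90, sigma = 25)
    })
    ks <- suppressWarnings(stats::ks.test(
      ang, function(q) orientation_mixture_cdf(q, 0.6, 90, 25)))
    ks$p.value > 0.01
  }, logical(1))
  expect_gte(sum(pass), 9L)
})

test_that("scene rendering is deterministic for identical specs", {
  spec <- small_spec(seed = 55)
  labels <- make_region_labels(spec)
  a <- render_shg_channel(spec, labels)
  b <- render_shg_channel(spec, labels)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$fibre_orientations, b$truth$fibre_orientations)
  s1 <- render_scene(spec)
  s2 <- render_scene(spec)
  for (ch in names(s1$stack$channels))
    expect_identical(s1$stack$channels[[ch]]$pixels,
                     s2$stack$channels[[ch]]$pixels)
})

test_that("a fibre perpendicular to the pump renders dark at zero floor", {
  # cos^4(90 deg) = 0: with no floor, the polarization factor vanishes
  spec <- small_spec(aligned_fraction = 1, theta0_true = 90,
                     sigma_true = 0.25, polarization_floor = 0,
                     noise_sd = 0)
  labels <- make_region_labels(spec)
  perp <- render_shg_channel(spec, labels, polarization_angle = 0)
  par <- render_shg_channel(spec, labels, polarization_angle = 90)
  # fibres are all within ~1 degree of vertical; amplitudes are ~cos^4 of
  # the offset, so the perpendicular image is essentially empty
  expect_lt(max(perp$image$pixels), 1e-3 * max(par$image$pixels))
})

test_that("SHG energy is maximal when polarization matches the fibre axis", {
  spec <- small_spec(aligned_fraction = 0.8, theta0_true = 60,
                     sigma_true = 15, polarization_floor = 0.1,
                     noise_sd = 0)
  labels <- make_region_labels(spec)
  co <- render_shg_channel(spec, labels, polarization_angle = 60)
  cross <- render_shg_channel(spec, labels, polarization_angle = 150)
  expect_gt(sum(co$image$pixels), sum(cross$image$pixels))
})

test_that("compartment-contrast channels honor the bone:marrow ratio", {
  spec0 <- small_spec(noise_sd = 0, srs_bone_marrow_ratio_lipid = 1,
                      marrow_level = 80)
  labels <- make_region_labels(spec0)
  ch <- render_intensity_channel(spec0, labels, "SRS_2850")
  codes <- label_codes()
  bone_px <- ch$pixels[labels == codes[["cortical"]] |
                       labels == codes[["trabecular"]]]
  marrow_px <- ch$pixels[labels == codes[["marrow"]]]
  expect_equal(mean(bone_px), mean(marrow_px))  # unit ratio, exact
  # noiseless image is piecewise constant per class
  for (k in codes) {
    px <- ch$pixels[labels == k]
    if (length(px)) expect_equal(diff(range(px)), 0)
  }

  spec15 <- small_spec(noise_sd = 0.5, srs_bone_marrow_ratio_lipid = 1.5)
  ch15 <- render_intensity_channel(spec15, make_region_labels(spec15),
                                   "SRS_2850")
  r <- bone_marrow_ratio(ch15, make_region_labels(spec15))$ratio
  expect_lt(abs(r - 1.5) / 1.5, 0.02)  # law of large numbers over the ROI
})

test_that("fibres are confined to bone classes", {
  spec <- small_spec(noise_sd = 0)
  labels <- make_region_labels(spec)
  img <- render_shg_channel(spec, labels)$image$pixels
  codes <- label_codes()
  outside <- img[!(labels == codes[["cortical"]] |
                   labels == codes[["trabecular"]])]
  expect_true(all(outside == 0))
})

test_that("per-fibre truth orientations lie in [0, 180)", {
  spec <- small_spec(n_fibres = 200, aligned_fraction = 0.5)
  labels <- make_region_labels(spec)
  th <- render_shg_channel(spec, labels)$truth$fibre_orientations
  expect_length(th, 200)
  expect_true(all(th >= 0 & th < 180))
})
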