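test_that("model evaluation matches its closed form", {
  expect_equal(orientation_model(85, A = 0.6, theta0 = 85, sigma = 25.4,
                                 B = 0.33), 0.93)      # peak = B + A
  expect_equal(orientation_model(c(0, 60, 120), A = 0, theta0 = 90,
                                 sigma = 10, B = 0.4), rep(0.4, 3))
  # exponent ((20)/(2*10))^2 = 1
  expect_equal(orientation_model(110, A = 1, theta0 = 90, sigma = 10, B = 0),
               exp(-1))
  expect_error(orientation_model(90, 1, 90, 0, 0), "sigma")
})

test_that("noiseless model histograms are refit to within 1 percent", {
  cases <- expand.grid(A = c(0.1, 0.6, 2), theta0 = c(20, 90, 160),
                       sigma = c(5, 25, 45), B = c(0.1, 0.5))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    fit <- fit_orientation_model(model_histogram(cs$A, cs$theta0, cs$sigma,
                                                 cs$B))
    expect_lt(abs(fit$A - cs$A) / cs$A, 0.01)
    expect_lt(abs(fit$theta0 - cs$theta0) / cs$theta0, 0.01)
    expect_lt(abs(fit$sigma - cs$sigma) / cs$sigma, 0.01)
    expect_lt(abs(fit$B - cs$B) / cs$B, 0.01)
    expect_gte(fit$r_squared, 0.99)
  }
})

test_that("a flat histogram fits as pure baseline", {
  flat <- data.frame(bin_center = seq(0.5, 179.5, 1),
                     counts_pct = rep(100 / 180, 180))
  fit <- fit_orientation_model(flat)
  expect_lt(fit$A, 1e-4)
  expect_equal(fit$B, 100 / 180, tolerance = 1e-3)
  expect_lt(fit$alignment_ratio, 0.1)
})

test_that("the fit is never worse than a coarse grid search", {
  th <- seq(0.5, 179.5, 1)
  hists <- list(
    withr::with_seed(10, orientation_model(th, 0.8, 70, 20, 0.3) +
                       stats::rnorm(180, 0, 0.05)),
    withr::with_seed(11, stats::runif(180, 0.2, 0.6)),
    orientation_model(th, 0.5, 30, 10, 0.2) +
      orientation_model(th, 0.5, 150, 10, 0)  # two peaks, misspecified
  )
  for (y in hists) {
    y <- pmax(y, 0)
    fit <- fit_orientation_model(data.frame(bin_center = th, counts_pct = y))
    oracle <- grid_search_rss(th, y)
    expect_lte(fit$rss, oracle + 1e-9)
  }
})

test_that("mixture-scene histograms recover the generating peak position", {
  th <- seq(0.5, 179.5, 1)
  withr::with_seed(77, {
    ang <- sample_fibre_orientations(10000, aligned_fraction = 0.5,
                                     theta0 = 90, sigma = 20)
  })
  counts <- tabulate(pmin(floor(ang), 179) + 1L, nbins = 180L)
  hist <- data.frame(bin_center = th, counts_pct = 100 * counts / sum(counts))
  fit <- fit_orientation_model(hist)
  expect_lt(abs(fit$theta0 - 90), 3)
  rss_grid <- grid_search_rss(th, hist$counts_pct)
  expect_lte(fit$rss, rss_grid + 1e-9)
})

test_that("alignment ratio matches a trapezoid integration oracle", {
  # A_G approximately equal to A_B: AR near 50%
  sigma <- 20
  fit <- list(A = 1, theta0 = 90, sigma = sigma,
              B = 2 * sigma * sqrt(pi) / 180)
  ar <- alignment_ratio(fit)
  a_g <- gauss_area_trapz(1, 90, sigma)
  a_b <- 180 * fit$B
  expect_equal(ar, 100 * a_g / (a_g + a_b), tolerance = 1e-6)
  expect_equal(ar, 50, tolerance = 0.5)

  # degenerate extremes
  expect_equal(alignment_ratio(list(A = 0, theta0 = 90, sigma = 10, B = 1)), 0)
  expect_equal(alignment_ratio(list(A = 2, theta0 = 90, sigma = 10, B = 0)),
               100)
  expect_error(alignment_ratio(list(A = 0, theta0 = 90, sigma = 10, B = 0)),
               "degenerate")
})

test_that("alignment ratio is monotone in amplitude and baseline", {
  base <- list(theta0 = 90, sigma = 25, B = 0.4)
  ars_A <- vapply(c(0.1, 0.3, 0.6, 1, 2), function(a)
    alignment_ratio(c(list(A = a), base)), numeric(1))
  expect_true(all(diff(ars_A) > 0))
  ars_B <- vapply(c(0.1, 0.3, 0.6, 1), function(b)
    alignment_ratio(list(A = 0.6, theta0 = 90, sigma = 25, B = b)),
    numeric(1))
  expect_true(all(diff(ars_B) < 0))
  ar <- alignment_ratio(list(A = 0.6, theta0 = 85, sigma = 25.4, B = 0.33))
  expect_true(ar >= 0 && ar <= 100)
})

test_that("fit accessors expose parameters tidily", {
  fit <- fit_orientation_model(model_histogram(0.6, 85, 25.4, 0.33))
  td <- generics::tidy(fit)
  expect_equal(td$term, c("A", "theta0", "sigma", "B"))
  expect_equal(td$estimate[3], 25.4, tolerance = 1e-3)
  gl <- generics::glance(fit)
  expect_equal(gl$r_squared, 1, tolerance = 1e-6)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})

test_that("summary tables average parameter cells at printed precision", {
  tab <- par_pol_fit_table()
  fits <- purrr::pmap(tab, function(genotype, roi, A, theta0, sigma, B) {
    f <- fit_orientation_model(model_histogram(A, theta0, sigma, B))
    f$roi <- roi; f$polarization <- "par"
    f
  })
  summ <- summarize_fits(fits, genotypes = tab$genotype)
  expect_equal(summ$mean[summ$parameter == "B"], 0.39)
  expect_equal(summ$mean[summ$parameter == "sigma"], 27.58)
  expect_equal(unname(summ$`WT.cortical`[summ$parameter == "A"]), 0.60)
  expect_equal(unname(summ$`KO.trabecular`[summ$parameter == "theta0"]), 91)

  # a single fit summarizes to its own values
  one <- summarize_fits(fits[1], genotypes = "WT")
  expect_equal(one$mean[one$parameter == "sigma"],
               round(25.4, 2))
  expect_error(summarize_fits(list()), "no fits")
})
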