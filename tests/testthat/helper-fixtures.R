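# Small scene used throughout: fast to render, all five classes present.
small_spec <- function(...) {
  args <- utils::modifyList(
    list(image_height = 192, image_width = 192, margin = 8,
         cortical_thickness = 20, n_struts = 3, strut_width = 14,
         growth_plate_rows = 14, n_fibres = 60, fibre_length_range = c(10, 24),
         seed = 101L),
    list(...))
  do.call(scene_spec, args)
}

# Brute-force Sobel cross-correlation with reflect padding: independent
# double-loop oracle.
sobel_bruteforce <- function(img) {
  kx <- matrix(c(1, 2, 1, 0, 0, 0, -1, -2, -1), 3, 3)  # column-major
  ky <- t(kx)
  nr <- nrow(img); nc <- ncol(img)
  refl <- function(i, n) min(max(i, 1L), n)  # mirror edge pixel outward
  gx <- gy <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    sx <- sy <- 0
    for (i in -1:1) for (j in -1:1) {
      v <- img[refl(r + i, nr), refl(c + j, nc)]
      sx <- sx + kx[i + 2, j + 2] * v
      sy <- sy + ky[i + 2, j + 2] * v
    }
    gx[r, c] <- sx; gy[r, c] <- sy
  }
  list(gx = gx, gy = gy)
}

# Trapezoid-rule oracle for the Gaussian-component area on [0, 180].
gauss_area_trapz <- function(A, theta0, sigma, n = 20001) {
  t <- seq(0, 180, length.out = n)
  y <- A * exp(-((t - theta0) / (2 * sigma))^2)
  sum((y[-1] + y[-n]) / 2) * (180 / (n - 1))
}

# Noiseless model histogram at the standard bin centers.
model_histogram <- function(A, theta0, sigma, B) {
  th <- seq(0.5, 179.5, by = 1)
  data.frame(bin_center = th,
             counts_pct = orientation_model(th, A, theta0, sigma, B))
}

# Independent grid-search least squares: profile (A, B) by a direct 2x2
# normal-equation solve at each (theta0, sigma) node.
grid_search_rss <- function(theta, y, theta0_step = 2, sigma_step = 2) {
  best <- Inf
  for (t0 in seq(0, 180, by = theta0_step)) {
    for (sg in seq(1, 89, by = sigma_step)) {
      g <- exp(-((theta - t0) / (2 * sg))^2)
      n <- length(y)
      sg_ <- sum(g); sgg <- sum(g * g); sy <- sum(y); sgy <- sum(g * y)
      det <- n * sgg - sg_^2
      if (abs(det) < 1e-12) next
      A <- (n * sgy - sg_ * sy) / det
      B <- (sy * sgg - sg_ * sgy) / det
      if (A < 0) { A <- 0; B <- mean(y) }
      if (B < 0) { B <- 0; A <- max(sgy / sgg, 0) }
      rss <- sum((y - B - A * g)^2)
      if (rss < best) best <- rss
    }
  }
  best
}

# Rotate a matrix 90 degrees counterclockwise: out[i, j] = m[j, nc+1-i].
rot90ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# Smallest circular difference between two axial angles (degrees, mod 180).
axial_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# Parameter rows of the parallel-polarization orientation-fit table
# (genotype x bone compartment), used for refit self-consistency checks.
par_pol_fit_table <- function() {
  tibble::tribble(
    ~genotype, ~roi,          ~A,   ~theta0, ~sigma, ~B,
    "WT",     "cortical",    0.60, 85,      25.4,   0.33,
    "WT",     "trabecular",  0.30, 89,      27.6,   0.44,
    "KO",     "cortical",    0.46, 91,      29.0,   0.37,
    "KO",     "trabecular",  0.39, 91,      28.3,   0.40
  )
}
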