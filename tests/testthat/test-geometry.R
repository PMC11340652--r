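# Contour normalization and geometric primitives, checked against closed
# forms and independent oracles.

test_that("area and perimeter match closed forms for canonical shapes", {
  sq <- contour_from_points(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_lt(abs(polygon_area(sq) - 1), 0.01)
  expect_lt(abs(polygon_perimeter(sq) - 4) / 4, 0.01)

  disc <- contour_from_points(ellipse_points(5, 5, n = 720))
  expect_lt(abs(polygon_area(disc) / (pi * 25) - 1), 0.01)

  ell <- contour_from_points(ellipse_points(2, 1, n = 720))
  expect_lt(abs(polygon_perimeter(ell) /
                  ellipse_perimeter_ramanujan(2, 1) - 1), 0.01)
})

test_that("circularity is 1 for discs and pi/4 for squares (rasterized)", {
  cd <- contour_from_silhouette(silhouette(disc_mask(50), 0.1))
  circ <- 4 * pi * polygon_area(cd) / polygon_perimeter(cd)^2
  expect_lt(abs(circ - 1), 0.02)
  cs <- contour_from_silhouette(silhouette(square_mask(120), 0.1))
  circ_s <- 4 * pi * polygon_area(cs) / polygon_perimeter(cs)^2
  expect_lt(abs(circ_s / (pi / 4) - 1), 0.02)
})

test_that("rasterized disc areas converge to pi r^2 within 2% for r >= 30", {
  for (r in c(30, 50, 80)) {
    cd <- contour_from_silhouette(silhouette(disc_mask(r), 0.1))
    expect_lt(abs(polygon_area(cd) / (pi * (r / 10)^2) - 1), 0.02)
  }
})

test_that("tilted rasterized 2:1 ellipse normalizes to height/width 2", {
  n <- 260
  xx <- outer(rep(1, n), seq_len(n)); yy <- t(xx)
  ang <- 30 * pi / 180
  X <- (xx - n / 2) * cos(ang) + (yy - n / 2) * sin(ang)
  Y <- -(xx - n / 2) * sin(ang) + (yy - n / 2) * cos(ang)
  m <- (X / 100)^2 + (Y / 50)^2 <= 1
  cal <- caliper_dimensions(contour_from_silhouette(silhouette(m, 0.1)))
  expect_lt(abs(cal$height / cal$width - 2), 0.04)
})

test_that("resampling resolution barely changes area", {
  p <- ellipse_points(3, 1.5, n = 2048)
  a256 <- polygon_area(contour_from_points(p, n_points = 256))
  a1024 <- polygon_area(contour_from_points(p, n_points = 1024))
  expect_lt(abs(a256 / a1024 - 1), 0.005)
})

test_that("caliper dimensions and width profile behave as defined", {
  cn <- contour_from_points(ellipse_points(2, 1, n = 720))  # normalizes apex-up
  cal <- caliper_dimensions(cn)
  expect_equal(cal$height, 4, tolerance = 0.01)
  expect_equal(cal$width, 2, tolerance = 0.01)
  expect_equal(cal$width_profile(cal$width_position), cal$width,
               tolerance = 1e-6)
  sq <- contour_from_points(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  prof <- caliper_dimensions(sq)$profile
  mid <- prof$chord[prof$h > 0.05 & prof$h < 0.95]
  expect_lt(diff(range(mid)) / max(mid), 0.02)
})

test_that("direct ellipse fit recovers exact and noisy ellipses", {
  f <- fit_ellipse(ellipse_points(2, 1, n = 256, angle = 0.4, center = c(3, -2)))
  expect_equal(f$a, 2, tolerance = 1e-6)
  expect_equal(f$b, 1, tolerance = 1e-6)
  expect_lt(f$rms_residual, 1e-6)
  fc <- fit_ellipse(ellipse_points(1, 1, n = 128))
  expect_equal(fc$a, 1, tolerance = 1e-6)
  expect_equal(fc$b, 1, tolerance = 1e-6)

  # Monte-Carlo: radial noise sigma = 0.01 mm, recovery within 1%
  errs <- sapply(1:20, function(sd_) {
    set.seed(sd_)
    th <- runif(256, 0, 2 * pi)
    r_noise <- 1 + rnorm(256, sd = 0.01)
    p <- cbind(2 * cos(th) * r_noise, 1 * sin(th) * r_noise)
    f <- fit_ellipse(p)
    max(abs(f$a - 2) / 2, abs(f$b - 1))
  })
  expect_lt(max(errs), 0.01)
  expect_error(fit_ellipse(cbind(1:10, 2 * (1:10))), "degenerate")
})

test_that("curvature matches closed forms and scales like 1/length", {
  disc <- contour_from_points(ellipse_points(2, 2, n = 720))
  k <- curvature_profile(disc)
  expect_lt(abs(mean(k$kappa) - 0.5) / 0.5, 0.05)

  ell <- contour_from_points(ellipse_points(2, 1, n = 720))
  kap <- curvature_profile(ell)$kappa
  apex <- locate_landmarks(ell)$apex_index
  side <- which.max(ell$points[, 1])
  expect_lt(abs(kap[apex] / kap[side] - 8) / 8, 0.10)

  big <- contour_from_points(2 * ellipse_points(2, 1, n = 720))
  kap2 <- curvature_profile(big)$kappa
  expect_lt(abs(kap2[locate_landmarks(big)$apex_index] / (kap[apex] / 2) - 1),
            0.01)
  expect_error(curvature_profile(ell, window = 400), "window")
})

test_that("landmarks sit at the vertical extremes, half a contour apart", {
  ell <- contour_from_points(ellipse_points(1, 2, n = 512))
  lm <- locate_landmarks(ell)
  expect_equal(ell$points[lm$apex_index, 2], max(ell$points[, 2]))
  set.seed(42)
  for (i in 1:20) {
    p <- shape_params("fruit",
                      height_mm = runif(1, 15, 28), width_mm = runif(1, 10, 18),
                      taper = runif(1, 0, 0.2),
                      apex_sharpness = runif(1, 1, 1.4))
    cn <- contour_from_params(p)
    lm <- locate_landmarks(cn)
    gap <- abs(lm$apex_index - lm$base_index)
    gap <- min(gap, cn$n_points - gap)
    expect_lt(abs(gap - cn$n_points / 2), 0.1 * cn$n_points)
  }
})

test_that("symmetry measures: mirror shapes, ellipses and planted eggs", {
  ell <- contour_from_points(ellipse_points(1.5, 3, n = 720))
  sym <- symmetry_measures(ell)
  expect_lt(sym$transversal_asymmetry, 0.01)
  expect_equal(sym$vertical_symmetry, 0.5, tolerance = 0.02)

  # taper > 0 moves the widest section toward the base
  egg <- shape_params("fruit", 20, 15, taper = 0.25)
  truth <- oliveshape:::shape_truth(egg)
  sy <- symmetry_measures(contour_from_params(egg))
  expect_equal(sy$vertical_symmetry, truth$widest_height, tolerance = 0.02)
  expect_lt(truth$widest_height, 0.5)
})

test_that("normalized descriptors are rotation-invariant", {
  p0 <- oliveshape:::fine_polygon(shape_params("fruit", 20, 14, taper = 0.15))
  ref <- contour_from_points(p0)
  for (ang in c(0.7, 2.1, 4.4)) {
    rot <- oliveshape:::rotate_pts(p0, ang)
    cn <- contour_from_points(rot)
    expect_lt(abs(polygon_area(cn) / polygon_area(ref) - 1), 0.01)
    c1 <- caliper_dimensions(cn); c0 <- caliper_dimensions(ref)
    expect_lt(abs(c1$height / c0$height - 1), 0.01)
    expect_lt(abs(c1$width / c0$width - 1), 0.01)
  }
})

test_that("scale equivariance: k x lengths, k^2 x areas, kappa / k", {
  base <- silhouette(disc_mask(40), 0.1)
  scaled <- silhouette(disc_mask(40), 0.2)
  c1 <- contour_from_silhouette(base); c2 <- contour_from_silhouette(scaled)
  expect_lt(abs(polygon_perimeter(c2) / polygon_perimeter(c1) - 2), 0.02)
  expect_lt(abs(polygon_area(c2) / polygon_area(c1) - 4), 0.04)
  k1 <- mean(curvature_profile(c1)$kappa)
  k2 <- mean(curvature_profile(c2)$kappa)
  expect_lt(abs(k2 / (k1 / 2) - 1), 0.01)
})

test_that("polygon area agrees with foreground pixel count", {
  for (seed in 1:5) {
    p <- shape_params("fruit", 18 + seed, 13, taper = 0.1, noise_amp = 0.015,
                      seed = seed)
    s <- generate_shape(p, mm_per_px = 0.05)
    cn <- contour_from_silhouette(s)
    px_area <- sum(s$mask) * 0.05^2
    expect_lt(abs(polygon_area(cn) / px_area - 1), 0.03)
  }
})

test_that("contour CSV export writes points and metadata", {
  cn <- contour_from_points(ellipse_points(2, 1))
  path <- file.path(withr::local_tempdir(), "c.csv")
  write_contour_csv(cn, path, meta = list(sample_id = "x1"))
  lines <- readLines(path)
  expect_match(lines[1], "sample_id: x1")
  df <- read.csv(path, comment.char = "#")
  expect_identical(nrow(df), cn$n_points)
})
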