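# Organ descriptor catalogs.

test_that("descriptor catalogs have the declared sizes and stable order", {
  expect_length(feature_names("fruit"), 24)
  expect_length(feature_names("leaf"), 16)
  expect_length(feature_names("endocarp"), 22)
  expect_length(feature_names("endocarp", extended = TRUE), 25)
  expect_identical(feature_names("fruit"), feature_names("fruit"))
  expect_error(feature_names("stem"), "unknown organ")
})

test_that("a pure 2:1 ellipse fruit yields its closed-form descriptors", {
  p <- shape_params("fruit", height_mm = 4, width_mm = 2)
  cA <- contour_from_params(p); cB <- contour_from_params(p)
  fv <- fruit_features(cA, cB)
  expect_length(fv, 24)
  expect_identical(names(fv), feature_names("fruit"))
  expect_equal(unname(fv[["A_shape_index"]]), 2, tolerance = 0.01)
  circ_expected <- 4 * pi * (pi * 2 * 1) / ellipse_perimeter_ramanujan(2, 1)^2
  expect_equal(unname(fv[["A_circularity"]]), circ_expected, tolerance = 0.01)
  expect_identical(unname(fv[["A_nipple_index"]]), 0)
  expect_identical(unname(fv[["A_nipple_size"]]), 0)
  expect_lt(fv[["A_trans_asymmetry"]], 0.01)
  expect_equal(unname(fv[["A_ellipse_a"]]), 2, tolerance = 0.01)
  expect_equal(unname(fv[["A_ellipse_b"]]), 1, tolerance = 0.01)
})

test_that("nipple detection fires above its floor and sizes the bump", {
  p5 <- shape_params("fruit", 20, 15, nipple_amplitude = 0.05)
  d5 <- detect_nipple(contour_from_params(p5))
  expect_identical(d5$index, 1)
  truth <- oliveshape:::shape_truth(p5)$bump_area
  expect_lt(abs(d5$size - truth) / truth, 0.25)

  d05 <- detect_nipple(contour_from_params(
    shape_params("fruit", 20, 15, nipple_amplitude = 0.005)))
  expect_identical(d05$index, 0)
  expect_identical(d05$size, 0)

  # detected in both viewing positions
  pB <- p5; pB$width_mm <- pB$width_mm * 0.93
  fv <- fruit_features(contour_from_params(p5), contour_from_params(pB))
  expect_identical(unname(fv[["A_nipple_index"]]), 1)
  expect_identical(unname(fv[["B_nipple_index"]]), 1)
})

test_that("nipple detection rate is monotone in bump amplitude", {
  amps <- c(0, 0.01, 0.02, 0.05, 0.10)
  rate <- sapply(amps, function(a) {
    mean(sapply(1:15, function(seed) {
      p <- shape_params("fruit", 20, 15, nipple_amplitude = a,
                        noise_amp = 0.01, seed = seed)
      detect_nipple(contour_from_params(p))$index
    }))
  })
  expect_true(all(diff(rate) >= -1e-9))
  expect_lt(rate[1], 0.2)
  expect_gt(rate[5], 0.8)
})

test_that("leaf descriptors recover blade and petiole geometry", {
  # circular blade: circularity and convexity 1
  pc <- shape_params("leaf", 30, 30)
  lf <- leaf_features(contour_from_params(pc))
  expect_length(lf, 16)
  expect_equal(unname(lf[["circularity"]]), 1, tolerance = 0.02)
  expect_equal(unname(lf[["convexity"]]), 1, tolerance = 0.01)
  expect_identical(unname(lf[["petiole_length"]]), 0)

  # lanceolate blade, no petiole
  pl <- shape_params("leaf", 50, 10)
  lf2 <- leaf_features(contour_from_params(pl))
  expect_equal(unname(lf2[["shape_index"]]), 5, tolerance = 0.1)

  # full silhouette path with a 10 x 1 mm petiole
  ps <- shape_params("leaf", 50, 12, petiole_length_mm = 10,
                     petiole_width_mm = 1)
  s <- generate_leaf(ps, mm_per_px = 0.1)
  lf3 <- leaf_features_from_silhouette(s)
  expect_lt(abs(lf3[["petiole_length"]] - 10) / 10, 0.10)
  expect_lt(abs(lf3[["petiole_thickness_upper"]] - 1), 0.15)
  expect_lt(abs(lf3[["petiole_thickness_lower"]] - 1), 0.15)
})

test_that("petiole splitting partitions the mask and finds the split point", {
  ps <- shape_params("leaf", 48, 13, petiole_length_mm = 9,
                     petiole_width_mm = 1.2)
  s <- generate_leaf(ps, mm_per_px = 0.1)
  sp <- split_petiole(s)
  expect_false(is.null(sp$petiole))
  expect_identical(sp$blade$mask | sp$petiole$mask, s$mask)
  expect_false(any(sp$blade$mask & sp$petiole$mask))
  total_len <- 48 + 9
  expect_lt(abs(sp$info$length - 9) / total_len, 0.05)

  # ellipse-only mask: no petiole
  s0 <- generate_shape(shape_params("leaf", 40, 15), mm_per_px = 0.1,
                       organ = "leaf")
  sp0 <- split_petiole(s0)
  expect_null(sp0$petiole)
  expect_identical(sp0$info$length, 0)
})

test_that("endocarp descriptors include the mucro signal and extras", {
  pe <- shape_params("endocarp", 15, 10)
  cA <- contour_from_params(pe)
  pB <- pe; pB$width_mm <- 9
  cB <- contour_from_params(pB)
  ev <- endocarp_features(cA, cB)
  expect_length(ev, 22)
  expect_identical(names(ev), feature_names("endocarp"))
  expect_lt(ev[["A_apex_curve_area"]], 0.01 * ev[["A_area"]])

  ex <- endocarp_features(cA, cB, extended = TRUE)
  expect_length(ex, 25)
  expect_identical(unname(ex[["mucro_index"]]), 0)
  expect_equal(unname(ex[["width_ratio_AB"]]), 10 / 9, tolerance = 0.02)
  expect_equal(unname(ex[["mean_circularity"]]),
               mean(c(ex[["A_circularity"]], ex[["B_circularity"]])),
               tolerance = 1e-9)

  pm <- shape_params("endocarp", 15, 10, mucro_amplitude = 0.05)
  cm <- contour_from_params(pm)
  em <- endocarp_features(cm, cm, extended = TRUE)
  expect_identical(unname(em[["mucro_index"]]), 1)
  expect_gt(em[["A_apex_curve_area"]], ev[["A_apex_curve_area"]])
})

test_that("unitless descriptors are scale-invariant", {
  p <- shape_params("fruit", 20, 15, taper = 0.1, nipple_amplitude = 0.05)
  s1 <- generate_shape(p, mm_per_px = 0.05)
  s2 <- generate_shape(p, mm_per_px = 0.1)
  f1 <- fruit_features(contour_from_silhouette(s1), contour_from_silhouette(s1))
  f2 <- fruit_features(contour_from_silhouette(s2), contour_from_silhouette(s2))
  for (d in c("A_shape_index", "A_circularity")) {
    expect_lt(abs(f1[[d]] / f2[[d]] - 1), 0.01)
  }
  # curvature-based descriptors are second derivatives of the boundary and
  # carry a little more resolution sensitivity
  expect_lt(abs(f1[["A_apex_pointedness"]] / f2[["A_apex_pointedness"]] - 1),
            0.03)
})

test_that("feature tables validate, order rows and round-trip via CSV", {
  co <- cached_cohort("separable3", n_per_organ = 3, years = 1L, seed = 7)
  tab <- co$fruit
  expect_identical(dim(tab), c(9L, 4L + 24L))
  expect_identical(tab$cultivar, sort(tab$cultivar))

  rows <- lapply(seq_len(3), function(i) list(
    sample_id = "dup", cultivar = "a", year = 1L,
    features = structure(setNames(rnorm(24), feature_names("fruit")),
                         organ = "fruit")))
  expect_error(build_feature_table(rows, "fruit"), "duplicate")

  path <- file.path(withr::local_tempdir(), "t.csv")
  write_feature_table(tab, path)
  tab2 <- read_feature_table(path)
  expect_equal(as.data.frame(tab), as.data.frame(tab2), tolerance = 1e-12)
  expect_identical(attr(tab2, "feature_names"), attr(tab, "feature_names"))
})
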