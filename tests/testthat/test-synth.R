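# Synthetic generator: analytic ground truth and cohort structure.

test_that("the ellipse limit of the curve family is exact", {
  p <- shape_params("fruit", height_mm = 24, width_mm = 12)
  tr <- oliveshape:::shape_truth(p)
  expect_equal(tr$height, 24, tolerance = 1e-6)
  expect_equal(tr$width, 12, tolerance = 1e-3)
  expect_equal(tr$area, pi * 12 * 6, tolerance = 0.001 * tr$area)
  cn <- contour_from_params(p)
  expect_equal(caliper_dimensions(cn)$height /
                 caliper_dimensions(cn)$width, 2, tolerance = 0.01)
})

test_that("rasterized area matches the quadrature oracle within 2%", {
  for (seed in 1:5) {
    p <- shape_params("fruit", 17 + seed, 12 + seed / 2, taper = 0.08,
                      apex_sharpness = 1.2, noise_amp = 0.01, seed = seed)
    s <- generate_shape(p, mm_per_px = 0.05)
    truth <- attr(s, "truth")
    expect_lt(abs(sum(s$mask) * 0.05^2 / truth$area - 1), 0.02)
  }
})

test_that("generation is seed-deterministic", {
  p <- shape_params("fruit", 20, 15, noise_amp = 0.02, seed = 11)
  s1 <- generate_shape(p, mm_per_px = 0.1)
  s2 <- generate_shape(p, mm_per_px = 0.1)
  expect_identical(s1$mask, s2$mask)
  co1 <- generate_cohort(preset_cohorts("separable3"), 3, years = 1L, seed = 5)
  co2 <- generate_cohort(preset_cohorts("separable3"), 3, years = 1L, seed = 5)
  expect_identical(co1$fruit, co2$fruit)
  expect_identical(co1$truth, co2$truth)
})

test_that("extraction round-trips generator ground truth", {
  rel_err <- function(a, b) abs(a - b) / abs(b)
  errs0 <- sapply(1:10, function(seed) {
    set.seed(seed)
    p <- shape_params("fruit", runif(1, 16, 26), runif(1, 11, 17),
                      taper = runif(1, 0, 0.15))
    s <- generate_shape(p, mm_per_px = 0.05)
    tr <- attr(s, "truth")
    cal <- caliper_dimensions(contour_from_silhouette(s))
    max(rel_err(cal$height, tr$height), rel_err(cal$width, tr$width),
        rel_err(cal$height / cal$width, tr$shape_index))
  })
  expect_lt(median(errs0), 0.02)

  errs2 <- sapply(1:10, function(seed) {
    set.seed(seed)
    p <- shape_params("fruit", runif(1, 16, 26), runif(1, 11, 17),
                      taper = runif(1, 0, 0.15), noise_amp = 0.02, seed = seed)
    s <- generate_shape(p, mm_per_px = 0.05)
    tr <- attr(s, "truth")
    cn <- contour_from_silhouette(s)
    cal <- caliper_dimensions(cn)
    max(rel_err(cal$height, tr$height), rel_err(cal$width, tr$width),
        rel_err(polygon_area(cn), tr$area))
  })
  expect_lt(median(errs2), 0.05)
})

test_that("leaf generator round-trips the petiole within 5% of total length", {
  errs <- sapply(1:5, function(seed) {
    set.seed(seed)
    pl <- runif(1, 7, 12)
    p <- shape_params("leaf", runif(1, 40, 60), runif(1, 10, 16),
                      petiole_length_mm = pl, petiole_width_mm = runif(1, 0.8, 1.4))
    s <- generate_leaf(p, mm_per_px = 0.1)
    sp <- split_petiole(s)
    abs(sp$info$length - pl) / (p$height_mm + pl)
  })
  expect_lt(median(errs), 0.05)
})

test_that("lanceolate leaves reproduce their planted shape index", {
  p <- shape_params("leaf", 55, 11, petiole_length_mm = 0)
  s <- generate_leaf(p, mm_per_px = 0.1)
  lf <- leaf_features_from_silhouette(s)
  expect_equal(unname(lf[["shape_index"]]), 5, tolerance = 0.15)
})

test_that("cohorts have the promised structure", {
  co <- cached_cohort("separable3", n_per_organ = 5, years = c(1L, 2L), seed = 1)
  expect_identical(nrow(co$fruit), 3L * 5L * 2L)
  expect_identical(nrow(co$leaf), 30L)
  expect_identical(nrow(co$endocarp), 30L)
  expect_setequal(unique(co$fruit$cultivar),
                  c("elongata", "sphaerica", "papillata"))
  # fruit and endocarp share sample ids; leaves do not
  expect_setequal(co$fruit$sample_id, co$endocarp$sample_id)
  expect_false(any(co$leaf$sample_id %in% co$fruit$sample_id))
  # year-2 fruits are larger on average (positive year effect)
  m1 <- mean(co$fruit$A_height[co$fruit$year == 1])
  m2 <- mean(co$fruit$A_height[co$fruit$year == 2])
  expect_gt(m2, m1)
})

test_that("fruit and endocarp sizes are coupled through the latent factor", {
  co <- cached_cohort("separable3", n_per_organ = 8, years = c(1L, 2L), seed = 2)
  merged <- merge(co$fruit[, c("sample_id", "cultivar", "A_height")],
                  co$endocarp[, c("sample_id", "A_height")], by = "sample_id")
  centered <- do.call(rbind, lapply(split(merged, merged$cultivar), function(d)
    data.frame(f = d$A_height.x - mean(d$A_height.x),
               e = d$A_height.y - mean(d$A_height.y))))
  expect_gt(cor(centered$f, centered$e), 0.4)
})

test_that("image-mode and fast-mode agree on scale-free descriptors", {
  spec <- preset_cohorts("separable3")[2]   # round, noise-tolerant
  spec[[2]] <- spec[[1]]; spec[[2]]$name <- "b"  # need >= 2 cultivars
  fast <- generate_cohort(spec, n_per_organ = 5, years = 1L, seed = 9,
                          mode = "fast")
  img <- generate_cohort(spec, n_per_organ = 5, years = 1L, seed = 9,
                         mode = "image", mm_per_px = 0.1)
  for (d in c("A_shape_index", "A_circularity")) {
    expect_lt(max(abs(fast$fruit[[d]] - img$fruit[[d]]) / img$fruit[[d]]), 0.05)
  }
})

test_that("presets are well formed and frozen", {
  expect_length(preset_cohorts("overlap14"), 14)
  expect_length(preset_cohorts("complementary"), 3)
  expect_error(preset_cohorts("nonexistent"))
  s1 <- preset_cohorts("kalamon_leaf"); s2 <- preset_cohorts("kalamon_leaf")
  expect_identical(s1, s2)
  # kalamon_leaf: organs other than leaf share identical means
  expect_identical(s1[[1]]$fruit, s1[[2]]$fruit)
  expect_identical(s1[[1]]$endocarp, s1[[3]]$endocarp)
  expect_false(identical(s1[[1]]$leaf, s1[[2]]$leaf))
})

test_that("parameter validation rejects out-of-range inputs", {
  expect_error(shape_params("fruit", height_mm = -1), "height_mm")
  expect_error(shape_params("fruit", noise_amp = 0.1), "noise_amp")
  expect_error(shape_params("fruit", taper = 0.7), "taper")
  expect_error(shape_params("fruit", apex_sharpness = 0.5), "apex_sharpness")
})
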