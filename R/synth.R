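# Synthetic silhouette and cohort generator.
#
# Shapes come from a star-shaped polar curve family: an ellipse radius
# modulated by an egg taper, an apex-sharpening term, a Gaussian angular bump
# at the apex (fruit nipple / endocarp mucro) and band-limited Fourier noise.
# Because the radius stays positive the polygon is simple by construction, and
# area/height/width ground truth comes from numeric quadrature of the curve
# itself, independent of rasterization and of the measurement pipeline.

FINE_THETA_N <- 4096L

#' Parameters of a synthetic organ shape
#'
#' @param organ `"fruit"`, `"leaf"` or `"endocarp"`.
#' @param height_mm,width_mm overall extent of the base ellipse (mm).
#' @param taper egg asymmetry in \[-0.5, 0.5\]; the widest section moves toward
#'   the base for `taper > 0`.
#' @param apex_sharpness >= 1; 1 is the pure ellipse, larger values pinch the
#'   apex half into a more pointed tip.
#' @param nipple_amplitude protrusion height of the apex bump as a fraction of
#'   `height_mm` (fruit nipple; use `mucro_amplitude` for endocarps).
#' @param nipple_width angular half-width (radians) of the bump.
#' @param mucro_amplitude endocarp apex bump, same units as `nipple_amplitude`.
#' @param petiole_length_mm,petiole_width_mm leaf petiole dimensions (0 = no
#'   petiole).
#' @param noise_amp band-limited boundary noise amplitude as a fraction of
#'   width (< 0.05).
#' @param seed integer seed for the noise draw.
#' @return a `shape_params` list.
#' @export
shape_params <- function(organ = "fruit", height_mm = 20, width_mm = 15,
                         taper = 0, apex_sharpness = 1,
                         nipple_amplitude = 0, nipple_width = 0.18,
                         mucro_amplitude = 0,
                         petiole_length_mm = 0, petiole_width_mm = 0,
                         noise_amp = 0, seed = 0L) {
  stopifnot(height_mm > 0, width_mm > 0, apex_sharpness >= 1,
            taper >= -0.5, taper <= 0.5, noise_amp >= 0, noise_amp < 0.05,
            nipple_amplitude >= 0, mucro_amplitude >= 0)
  structure(list(organ = organ, height_mm = height_mm, width_mm = width_mm,
                 taper = taper, apex_sharpness = apex_sharpness,
                 nipple_amplitude = nipple_amplitude,
                 nipple_width = nipple_width,
                 mucro_amplitude = mucro_amplitude,
                 petiole_length_mm = petiole_length_mm,
                 petiole_width_mm = petiole_width_mm,
                 noise_amp = noise_amp, seed = as.integer(seed)),
            class = "shape_params")
}

# Radius of the curve family at angles th (apex at th = pi/2).
shape_radius <- function(p, th, with_bump = TRUE) {
  a <- p$width_mm / 2; b <- p$height_mm / 2
  r <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  r <- r * (1 - p$taper * sin(th))            # widest toward base for taper > 0
  ks <- 0.5 * (1 - 1 / p$apex_sharpness)      # pinch the apex-half shoulders
  up <- sin(th) > 0
  r[up] <- r[up] * (1 - ks * (sin(2 * th[up]))^2)
  amp <- (p$nipple_amplitude + p$mucro_amplitude) * p$height_mm
  if (with_bump && amp > 0) {
    d <- atan2(sin(th - pi / 2), cos(th - pi / 2))
    r <- r + amp * exp(-0.5 * (d / p$nipple_width)^2)
  }
  if (p$noise_amp > 0) {
    rng <- local_rng(p$seed)
    orders <- 6:12
    cf <- rng$rnorm(length(orders)) / sqrt(length(orders))
    ph <- rng$runif(length(orders), 0, 2 * pi)
    for (j in seq_along(orders))
      r <- r + p$noise_amp * p$width_mm * cf[j] * cos(orders[j] * th + ph[j])
  }
  r
}

# Analytic-quadrature ground truth for a parameter set.
shape_truth <- function(p) {
  th <- seq(0, 2 * pi, length.out = FINE_THETA_N + 1L)[-(FINE_THETA_N + 1L)]
  r <- shape_radius(p, th)
  if (any(r <= 0)) stop("self-intersecting curve: noise/bump amplitude too large")
  dth <- 2 * pi / FINE_THETA_N
  area <- sum(r^2) * dth / 2
  r0 <- shape_radius(p, th, with_bump = FALSE)
  bump_area <- sum(r^2 - r0^2) * dth / 2
  pts <- cbind(r * cos(th), r * sin(th))
  ys <- pts[, 2]
  height <- diff(range(ys))
  # width profile of the analytic polygon
  cal <- caliper_dimensions(new_contour(pts, 1), n_levels = 512L)
  list(area = area, height = height, width = cal$width,
       shape_index = height / cal$width,
       widest_height = cal$width_position,
       bump_area = bump_area,
       params = p)
}

fine_polygon <- function(p) {
  th <- seq(0, 2 * pi, length.out = FINE_THETA_N + 1L)[-(FINE_THETA_N + 1L)]
  r <- shape_radius(p, th)
  if (any(r <= 0)) stop("self-intersecting curve: noise/bump amplitude too large")
  cbind(r * cos(th), r * sin(th))
}

#' Generate a synthetic organ silhouette with ground truth
#'
#' Rasterizes the polar curve at the requested scale. The returned object
#' carries the analytic ground truth (area by quadrature, height, width,
#' widest-section height, bump area) as the `truth` attribute.
#'
#' @param p a [shape_params()].
#' @param mm_per_px rasterization scale.
#' @param organ,position,sample_id,cultivar,year silhouette metadata.
#' @return an [silhouette()] with attribute `truth`.
#' @export
generate_shape <- function(p, mm_per_px = 0.05, organ = p$organ,
                           position = "none", sample_id = "s1",
                           cultivar = NA, year = NA) {
  truth <- shape_truth(p)
  pts <- fine_polygon(p)
  mask <- rasterize_star(p, pts, mm_per_px)
  s <- silhouette(mask, mm_per_px, organ = organ, position = position,
                  sample_id = sample_id, cultivar = cultivar, year = year)
  attr(s, "truth") <- truth
  s
}

# Rasterize a star-shaped polar curve: a pixel center is foreground iff its
# radius is below the curve radius at its angle.
rasterize_star <- function(p, pts, mm_per_px, extra = NULL) {
  pad <- 3 * mm_per_px
  xr <- range(pts[, 1]); yr <- range(pts[, 2])
  if (!is.null(extra)) {
    xr <- range(xr, extra[, 1]); yr <- range(yr, extra[, 2])
  }
  xs <- seq(xr[1] - pad, xr[2] + pad, by = mm_per_px)
  ys <- seq(yr[2] + pad, yr[1] - pad, by = -mm_per_px)   # row 1 = top
  gx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  gy <- matrix(ys, length(ys), length(xs))
  th <- atan2(gy, gx)
  rr <- sqrt(gx^2 + gy^2)
  thg <- seq(-pi, pi, length.out = 2049L)
  # curve radius lookup over [-pi, pi]
  rg <- shape_radius(p, thg)
  mask <- rr <= approx(thg, rg, xout = th, rule = 2)$y
  if (!is.null(extra)) {
    inrect <- gx >= extra[1, 1] & gx <= extra[2, 1] &
      gy >= extra[1, 2] & gy <= extra[2, 2]
    mask <- mask | inrect
  }
  mask
}

#' Generate a synthetic leaf silhouette (blade + petiole)
#'
#' The blade comes from the same polar-curve family; the petiole is an
#' axis-aligned rectangle attached at the blade base. Ground truth includes
#' the petiole length and width.
#'
#' @inheritParams generate_shape
#' @return an [silhouette()] with attribute `truth`.
#' @export
generate_leaf <- function(p, mm_per_px = 0.05, sample_id = "s1",
                          cultivar = NA, year = NA) {
  truth <- shape_truth(p)
  truth$petiole_length <- p$petiole_length_mm
  truth$petiole_width <- p$petiole_width_mm
  pts <- fine_polygon(p)
  extra <- NULL
  if (p$petiole_length_mm > 0) {
    y0 <- min(pts[, 2])
    w <- p$petiole_width_mm / 2
    # overlap 1 mm into the blade so the union is connected
    extra <- rbind(c(-w, y0 - p$petiole_length_mm), c(w, y0 + 1))
  }
  mask <- rasterize_star(p, pts, mm_per_px, extra = extra)
  s <- silhouette(mask, mm_per_px, organ = "leaf", sample_id = sample_id,
                  cultivar = cultivar, year = year)
  attr(s, "truth") <- truth
  s
}

# Contour of the analytic curve via the standard normalization (fast path:
# no rasterization). Leaves pass the petiole attachment as the base hint.
contour_from_params <- function(p, n_points = DEFAULT_N_POINTS) {
  pts <- fine_polygon(p)
  base_point <- if (p$organ == "leaf") c(0, min(pts[, 2])) else NULL
  contour_from_points(pts, mm_per_px = 1, n_points = n_points,
                      base_point = base_point)
}

# --- cohorts -----------------------------------------------------------------

#' Specification of a synthetic cultivar
#'
#' Per-organ mean shape parameters plus within-cultivar variation and a
#' between-year size shift. Per-sample parameters are drawn as lognormal
#' perturbations of the means (lengths stay positive); fruit and endocarp of
#' the same sample share a latent size factor, emulating the observed
#' coupling of fruit and endocarp size.
#'
#' @param name cultivar name.
#' @param fruit,leaf,endocarp mean [shape_params()] per organ.
#' @param width_B_frac width of viewing position B relative to position A
#'   (fruits and endocarps are photographed in two orthogonal positions).
#' @param rel_sd within-cultivar relative standard deviation of size/shape
#'   parameters.
#' @param year_effect multiplicative size shift applied to all lengths in the
#'   second sampling year (environmental effect).
#' @return a `cultivar_spec` list.
#' @export
cultivar_spec <- function(name, fruit, leaf, endocarp,
                          width_B_frac = 0.93, rel_sd = 0.06,
                          year_effect = 1.07) {
  stopifnot(rel_sd >= 0, year_effect > 0)
  structure(list(name = name, fruit = fruit, leaf = leaf, endocarp = endocarp,
                 width_B_frac = width_B_frac, rel_sd = rel_sd,
                 year_effect = year_effect),
            class = "cultivar_spec")
}

# Draw per-sample parameters for one cultivar/year. Returns a list with
# fruit/leaf/endocarp shape_params (fruit & endocarp share the latent size).
draw_sample_params <- function(spec, year, rng, sample_seed) {
  ymul <- if (year == 2L) spec$year_effect else 1
  rs <- spec$rel_sd
  latent <- exp(rng$rnorm(1) * rs)           # shared fruit/endocarp size factor
  jit <- function() exp(rng$rnorm(1) * rs * 0.5)
  perturb <- function(p, size_mul) {
    p$height_mm <- p$height_mm * size_mul * jit()
    p$width_mm <- p$width_mm * size_mul * jit()
    p$taper <- max(-0.5, min(0.5, p$taper + rng$rnorm(1) * 0.02))
    p$apex_sharpness <- max(1, p$apex_sharpness * jit())
    if (p$nipple_amplitude > 0) p$nipple_amplitude <- p$nipple_amplitude * exp(rng$rnorm(1) * rs)
    if (p$mucro_amplitude > 0) p$mucro_amplitude <- p$mucro_amplitude * exp(rng$rnorm(1) * rs)
    if (p$petiole_length_mm > 0) p$petiole_length_mm <- p$petiole_length_mm * size_mul * jit()
    if (p$petiole_width_mm > 0) p$petiole_width_mm <- p$petiole_width_mm * jit()
    p$seed <- sample_seed
    p
  }
  fr <- perturb(spec$fruit, latent * ymul)
  # endocarp dimensions follow the same latent fruit size plus small noise
  en <- perturb(spec$endocarp, latent * ymul * exp(rng$rnorm(1) * 0.03))
  lf <- perturb(spec$leaf, ymul)
  list(fruit = fr, leaf = lf, endocarp = en)
}

position_params <- function(p, position, width_B_frac) {
  if (position == "B") p$width_mm <- p$width_mm * width_B_frac
  p
}

#' Generate a synthetic cohort as per-organ feature tables
#'
#' For each cultivar, year and sample, draws shape parameters from the
#' cultivar specification and computes the organ descriptor vectors, either
#' directly from the analytic boundary curve (`mode = "fast"`, the default) or
#' through rasterization, segmentation-grade masks and contour extraction
#' (`mode = "image"`). Fruit and endocarp rows of the same sample share their
#' `sample_id`.
#'
#' @param specs list of [cultivar_spec()]s (>= 2).
#' @param n_per_organ samples per cultivar per year.
#' @param years sampling years, subset of `c(1, 2)`.
#' @param seed master seed.
#' @param mode `"fast"` (analytic boundary) or `"image"` (rasterize +
#'   contour extraction).
#' @param mm_per_px rasterization scale for image mode.
#' @param extended_endocarp add the 3 extra endocarp descriptors.
#' @param n_points contour resolution.
#' @return list with `fruit`, `leaf`, `endocarp` feature tables
#'   ([build_feature_table()]) and `truth`, a data frame of per-sample ground
#'   truth (fruit shape): analytic height, width, shape index, area,
#'   widest-section height and bump area.
#' @export
generate_cohort <- function(specs, n_per_organ = 20, years = c(1L, 2L),
                            seed = 0L, mode = c("fast", "image"),
                            mm_per_px = 0.05, extended_endocarp = FALSE,
                            n_points = DEFAULT_N_POINTS) {
  mode <- match.arg(mode)
  if (length(specs) < 2) stop("need at least 2 cultivar specs")
  nm <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate cultivar names")
  rows <- list(fruit = list(), leaf = list(), endocarp = list())
  truth <- list()
  for (spec in specs) {
    rng <- local_rng(derive_seed(seed, paste0("cohort:", spec$name)))
    for (yr in as.integer(years)) {
      for (i in seq_len(n_per_organ)) {
        sid <- sprintf("%s_y%d_%03d", spec$name, yr, i)
        sseed <- derive_seed(seed, paste0(sid, ":noise"))
        ps <- draw_sample_params(spec, yr, rng, sseed)
        feats <- tryCatch(
          sample_features(ps, spec, mode, mm_per_px, extended_endocarp,
                          n_points),
          error = function(e) e)
        if (inherits(feats, "error")) {
          message("sample ", sid, " failed: ", conditionMessage(feats))
          next
        }
        for (org in names(rows)) {
          rows[[org]][[length(rows[[org]]) + 1L]] <-
            list(sample_id = if (org == "leaf") paste0(sid, "_L") else sid,
                 cultivar = spec$name, year = yr, features = feats[[org]])
        }
        tr <- shape_truth(ps$fruit)
        truth[[length(truth) + 1L]] <- data.frame(
          sample_id = sid, cultivar = spec$name, year = yr,
          height = tr$height, width = tr$width, shape_index = tr$shape_index,
          area = tr$area, widest_height = tr$widest_height,
          bump_area = tr$bump_area)
      }
    }
  }
  list(fruit = build_feature_table(rows$fruit, "fruit"),
       leaf = build_feature_table(rows$leaf, "leaf"),
       endocarp = build_feature_table(rows$endocarp, "endocarp"),
       truth = do.call(rbind, truth))
}

sample_features <- function(ps, spec, mode, mm_per_px, extended_endocarp,
                            n_points) {
  two_positions <- function(p) {
    pa <- position_params(p, "A", spec$width_B_frac)
    pb <- position_params(p, "B", spec$width_B_frac)
    if (mode == "fast") {
      list(A = contour_from_params(pa, n_points),
           B = contour_from_params(pb, n_points))
    } else {
      list(A = contour_from_silhouette(generate_shape(pa, mm_per_px), n_points),
           B = contour_from_silhouette(generate_shape(pb, mm_per_px), n_points))
    }
  }
  fr <- two_positions(ps$fruit)
  en <- two_positions(ps$endocarp)
  lf <- if (mode == "fast") {
    pl <- ps$leaf
    info <- list(length = pl$petiole_length_mm,
                 thickness_upper = pl$petiole_width_mm,
                 thickness_lower = pl$petiole_width_mm)
    leaf_features(contour_from_params(pl, n_points), info)
  } else {
    leaf_features_from_silhouette(generate_leaf(ps$leaf, mm_per_px), n_points)
  }
  list(fruit = fruit_features(fr$A, fr$B),
       leaf = lf,
       endocarp = endocarp_features(en$A, en$B, extended = extended_endocarp))
}

#' Built-in cultivar specification sets
#'
#' Named presets with known structure:
#' \describe{
#'   \item{separable3}{three cultivars with widely separated means and small
#'     within-cultivar variation; trivially separable.}
#'   \item{overlap14}{fourteen cultivars named after a classic Greek/Spanish
#'     nursery panel, with realistic overlap: graded sizes, elongated
#'     (Koroneiki-like) to spherical fruit shapes, nipples and mucros present
#'     in some cultivars only, one wide-leaved cultivar (Kalamon).}
#'   \item{kalamon_leaf}{three cultivars identical in fruit and endocarp
#'     means; only "Kalamon" differs, and only in its leaf.}
#'   \item{complementary}{three cultivars with organ-complementary signal:
#'     fruit separates \{c1, c2\} from \{c3\}, endocarp separates \{c1\} from
#'     \{c2\}, leaves are uninformative.}
#' }
#'
#' @param name preset name.
#' @return list of [cultivar_spec()]s.
#' @export
preset_cohorts <- function(name = c("separable3", "overlap14", "kalamon_leaf",
                                    "complementary")) {
  name <- match.arg(name)
  fruitp <- function(h, w, ...) shape_params("fruit", h, w, ...)
  leafp <- function(h, w, pl, pw, ...)
    shape_params("leaf", h, w, petiole_length_mm = pl, petiole_width_mm = pw, ...)
  endop <- function(h, w, ...) shape_params("endocarp", h, w, ...)
  switch(name,
    separable3 = list(
      cultivar_spec("elongata",
        fruit = fruitp(28, 13, taper = 0.1, apex_sharpness = 1.2, noise_amp = 0.01),
        leaf = leafp(62, 10, 9, 1.1, noise_amp = 0.01),
        endocarp = endop(17, 7, taper = 0.1, mucro_amplitude = 0.06, noise_amp = 0.01),
        rel_sd = 0.03, year_effect = 1.03),
      cultivar_spec("sphaerica",
        fruit = fruitp(16, 15.5, noise_amp = 0.01),
        leaf = leafp(44, 17, 6, 1.5, noise_amp = 0.01),
        endocarp = endop(11, 9, noise_amp = 0.01),
        rel_sd = 0.03, year_effect = 1.03),
      cultivar_spec("papillata",
        fruit = fruitp(22, 16, nipple_amplitude = 0.08, noise_amp = 0.01),
        leaf = leafp(53, 13, 13, 0.9, noise_amp = 0.01),
        endocarp = endop(14, 8, taper = 0.05, noise_amp = 0.01),
        rel_sd = 0.03, year_effect = 1.03),
      NULL)[1:3],
    overlap14 = overlap14_specs(),
    kalamon_leaf = {
      fr <- fruitp(21, 15, taper = 0.08, noise_amp = 0.01)
      en <- endop(13, 8, taper = 0.06, noise_amp = 0.01)
      list(
        cultivar_spec("Kalamon", fruit = fr,
          leaf = leafp(72, 22, 10, 1.6, noise_amp = 0.01), endocarp = en),
        cultivar_spec("angustifolia", fruit = fr,
          leaf = leafp(50, 10, 10, 1.0, noise_amp = 0.01), endocarp = en),
        cultivar_spec("intermedia", fruit = fr,
          leaf = leafp(55, 13, 10, 1.2, noise_amp = 0.01), endocarp = en))
    },
    complementary = {
      lf <- leafp(52, 12, 9, 1.1, noise_amp = 0.01)
      fr_small <- fruitp(19, 14, noise_amp = 0.01)
      fr_big <- fruitp(27, 18, noise_amp = 0.01)
      en_round <- endop(12, 9, noise_amp = 0.01)
      en_long <- endop(17, 7, taper = 0.1, noise_amp = 0.01)
      list(
        cultivar_spec("c1", fruit = fr_small, leaf = lf, endocarp = en_round),
        cultivar_spec("c2", fruit = fr_small, leaf = lf, endocarp = en_long),
        cultivar_spec("c3", fruit = fr_big, leaf = lf, endocarp = en_round))
    })
}

# Fourteen cultivars with graded, overlapping trait structure. Sizes, shape
# indices, taper, apex sharpness, nipple/mucro presence and leaf geometry vary
# on coarse grids so neighbouring cultivars overlap at rel_sd = 0.10.
overlap14_specs <- function() {
  names14 <- c("Arbequina", "Arbosana", "Asprolia", "Kalamon", "Karidolia",
               "Koroneiki", "Kothreiki", "Koutsourelia", "Mastoidis",
               "Mavrolia", "Megaron", "Ntopia", "Thiaki", "Tragolia")
  specs <- vector("list", 14L)
  for (i in seq_len(14L)) {
    fh <- 16 + 0.8 * (i - 1)                      # graded fruit size, mm
    ratio <- 1.15 + 0.07 * ((i * 5) %% 7)         # elongation 1.15 .. 1.57
    nip <- if (i %% 3 == 0) 0.05 else 0           # nipple in a third
    mucro <- if (i %% 4 == 1) 0.05 else 0         # mucro in a quarter
    taper <- 0.04 * ((i * 3) %% 4)                # 0 .. 0.12
    sharp <- 1 + 0.15 * (i %% 3)                  # 1 .. 1.3
    # leaves overlap heavily across the panel (only Kalamon stands out)
    lw <- if (names14[i] == "Kalamon") 21 else 11 + 0.25 * ((i * 2) %% 5)
    lh <- if (names14[i] == "Kalamon") 70 else 48 + 0.8 * ((i * 3) %% 6)
    specs[[i]] <- cultivar_spec(
      names14[i],
      fruit = shape_params("fruit", fh, fh / ratio, taper = taper,
                           apex_sharpness = sharp, nipple_amplitude = nip,
                           noise_amp = 0.012),
      leaf = shape_params("leaf", lh, lw,
                          petiole_length_mm = 8 + 0.3 * (i %% 4),
                          petiole_width_mm = 1 + 0.03 * (i %% 3),
                          noise_amp = 0.012),
      endocarp = shape_params("endocarp", fh * 0.62, fh * 0.62 / (ratio * 1.1),
                              taper = taper * 0.8, mucro_amplitude = mucro,
                              noise_amp = 0.012),
      rel_sd = 0.10, year_effect = 1 + 0.03 * ((i %% 5) - 2))
  }
  specs
}
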