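# Organ-specific shape descriptor catalogs: 24 fruit, 16 leaf, 22 endocarp
# (+3 optional cross-position extras), and labeled feature tables.
#
# The catalogs include every descriptor named in the source methodology (shape
# index, circularity, fitted-ellipse axes, apex curvature, nipple index and
# size, petiole thickness, vertical/transversal symmetry, transversal-diameter
# position, minimum distance to the contour, base length, apex-curve area) and
# fill the declared counts with standard morphometric descriptors (perimeter,
# convexity, ellipse major axis); the latter are reconstructed, not copied
# from any published formula sheet.

NIPPLE_DEVIATION_FLOOR <- 0.02   # outward deviation threshold, fraction of height
MUCRO_AREA_FRAC <- 0.01          # apex-curve area fraction of area flagging a mucro

fruit_descriptors_per_position <- c(
  "area", "perimeter", "height", "width", "shape_index", "circularity",
  "ellipse_a", "ellipse_b", "apex_pointedness", "nipple_index", "nipple_size",
  "trans_asymmetry")

leaf_descriptors <- c(
  "area", "perimeter", "length", "width", "shape_index", "circularity",
  "ellipse_a", "ellipse_b", "apex_pointedness", "base_pointedness",
  "vertical_symmetry", "trans_asymmetry", "convexity",
  "petiole_length", "petiole_thickness_upper", "petiole_thickness_lower")

endocarp_descriptors_per_position <- c(
  "area", "perimeter", "height", "width", "shape_index", "circularity",
  "ellipse_b", "apex_curve_area", "base_length", "width_position",
  "min_dist_width_chord")

endocarp_extended_extras <- c("mucro_index", "mean_circularity", "width_ratio_AB")

#' Canonical descriptor names for an organ
#'
#' @param organ `"fruit"`, `"leaf"` or `"endocarp"`.
#' @param extended add the 3 cross-position endocarp extras (25 instead of 22).
#' @return character vector of descriptor names in canonical order.
#' @export
feature_names <- function(organ, extended = FALSE) {
  switch(organ,
    fruit = c(paste0("A_", fruit_descriptors_per_position),
              paste0("B_", fruit_descriptors_per_position)),
    leaf = leaf_descriptors,
    endocarp = {
      nm <- c(paste0("A_", endocarp_descriptors_per_position),
              paste0("B_", endocarp_descriptors_per_position))
      if (extended) c(nm, endocarp_extended_extras) else nm
    },
    stop("unknown organ ", organ))
}

# Shared per-contour measurements.
contour_metrics <- function(c, window = DEFAULT_CURV_WINDOW) {
  area <- polygon_area(c)
  per <- polygon_perimeter(c)
  cal <- caliper_dimensions(c)
  fit <- fit_ellipse(c)
  curv <- curvature_profile(c, window)
  lm <- locate_landmarks(c)
  sym <- symmetry_measures(c, cal)
  # baseline ellipse for apex-deviation descriptors: robust trimmed refit so
  # an apex bump cannot distort its own baseline
  fit_base <- fit_ellipse_trimmed(c$points)
  list(area = area, perimeter = per, cal = cal, fit = fit,
       fit_base = fit_base, curv = curv,
       landmarks = lm, sym = sym,
       circularity = 4 * pi * area / per^2,
       shape_index = cal$height / cal$width)
}

# Ellipse fit robust to a localized outward protrusion: fit all points, then
# refit excluding points whose outward radial residual is extreme (> k robust
# sds, at most 15% of the contour). Two passes are enough in practice.
fit_ellipse_trimmed <- function(p, k = 2.5, iters = 2L) {
  fit <- fit_ellipse(p)
  for (i in seq_len(iters)) {
    q <- cbind(p[, 1] - fit$center[1], p[, 2] - fit$center[2])
    dev <- sqrt(rowSums(q^2)) - ellipse_radius_at(fit, atan2(q[, 2], q[, 1]))
    s <- stats::mad(dev)
    if (s < 1e-12) return(fit)
    bad <- which(dev > k * s)
    if (length(bad) == 0L) return(fit)
    cap <- floor(0.15 * nrow(p))
    if (length(bad) > cap) bad <- order(dev, decreasing = TRUE)[seq_len(cap)]
    fit <- fit_ellipse(p[-bad, , drop = FALSE])
  }
  fit
}

# Radial deviation of contour points from the fitted ellipse, and the polar
# increments needed for area-between-curves integrals.
ellipse_deviation <- function(c, fit, idx) {
  q <- cbind(c$points[idx, 1] - fit$center[1], c$points[idx, 2] - fit$center[2])
  r <- sqrt(rowSums(q^2))
  th <- atan2(q[, 2], q[, 1])
  r_ell <- ellipse_radius_at(fit, th)
  dth <- abs(atan2(sin(diff(th)), cos(diff(th))))
  dth <- c(dth[1], (dth[-length(dth)] + dth[-1]) / 2, dth[length(dth)])[seq_along(th)]
  list(dev = r - r_ell, r = r, r_ell = r_ell, dth = dth)
}

#' Detect a fruit nipple at the contour apex
#'
#' Within the apex landmark window the fitted-ellipse arc serves as baseline.
#' A nipple is present iff the maximum outward deviation exceeds 2% of the
#' height and the deviation region contains a local curvature maximum at least
#' twice the window median. Its size is the area between contour and arc over
#' the deviation region.
#'
#' @param c a normalized fruit `olive_contour`.
#' @param metrics optional precomputed [contour_metrics] (internal reuse).
#' @return list with `index` (0/1) and `size` (mm^2).
#' @export
detect_nipple <- function(c, metrics = NULL) {
  m <- metrics %||% contour_metrics(c)
  W <- m$landmarks$apex_window
  ed <- ellipse_deviation(c, m$fit_base, W)
  imax <- which.max(ed$dev)
  if (ed$dev[imax] <= NIPPLE_DEVIATION_FLOOR * m$cal$height)
    return(list(index = 0, size = 0))
  inreg <- ed$dev > 0.1 * ed$dev[imax]
  # contiguous run around the maximum deviation
  lo <- imax; while (lo > 1L && inreg[lo - 1L]) lo <- lo - 1L
  hi <- imax; while (hi < length(W) && inreg[hi + 1L]) hi <- hi + 1L
  reg <- lo:hi
  # a nipple is a localized teat: a deviation region filling most of the apex
  # window is a pointed apex, not a nipple
  if (length(reg) > 0.8 * length(W))
    return(list(index = 0, size = 0))
  # spike check on a lightly smoothed curvature: the descriptor window (15)
  # flattens a narrow teat, a 7-point window keeps it localized
  kap <- closed_curvature(c$points, window = 7L)[W]
  if (max(kap[reg]) < 2 * stats::median(kap))
    return(list(index = 0, size = 0))
  size <- sum((ed$r[reg]^2 - ed$r_ell[reg]^2) * ed$dth[reg]) / 2
  list(index = 1, size = max(size, 0))
}

#' Fruit descriptor vector (24 values) from the two viewing positions
#'
#' Twelve descriptors per position: area, perimeter, height, maximum
#' transversal diameter, shape index, circularity, fitted-ellipse semi-axes,
#' apex pointedness (mean apex curvature x height, unitless), nipple index and
#' size, and transversal asymmetry.
#'
#' @param contour_A,contour_B normalized contours of positions A and B of the
#'   same fruit.
#' @return named numeric vector of length 24 with attribute `organ = "fruit"`.
#' @export
fruit_features <- function(contour_A, contour_B) {
  one <- function(c) {
    m <- contour_metrics(c)
    nip <- detect_nipple(c, m)
    c(area = m$area, perimeter = m$perimeter, height = m$cal$height,
      width = m$cal$width, shape_index = m$shape_index,
      circularity = m$circularity, ellipse_a = m$fit$a, ellipse_b = m$fit$b,
      apex_pointedness = mean(m$curv$kappa[m$landmarks$apex_window]) * m$cal$height,
      nipple_index = nip$index, nipple_size = nip$size,
      trans_asymmetry = m$sym$transversal_asymmetry)
  }
  v <- c(one(contour_A), one(contour_B))
  names(v) <- feature_names("fruit")
  structure(v, organ = "fruit")
}

#' Split a leaf silhouette into blade and petiole
#'
#' The petiole is the maximal run of the width profile below 20% of the
#' maximum width, adjacent to one end of the principal axis and longer than 5%
#' of the total length. Thicknesses are mean widths over the petiole quarter
#' adjoining the blade (upper) and the distal quarter (lower).
#'
#' @param s a leaf [silhouette()].
#' @return list with `blade` (silhouette), `petiole` (silhouette or `NULL`)
#'   and `info` (length and thicknesses in mm, plus the attachment point in
#'   the mm frame used by [contour_from_silhouette()]).
#' @export
split_petiole <- function(s) {
  stopifnot(inherits(s, "olive_silhouette"))
  mask <- s$mask
  idx <- which(mask)
  nr <- nrow(mask)
  xy <- cbind(x = ((idx - 1L) %/% nr) + 1L, y = nr + 1L - (((idx - 1L) %% nr) + 1L))
  ev <- eigen(stats::cov(xy), symmetric = TRUE)
  u <- ev$vectors[, 1]
  t_ <- drop(xy %*% u)
  bin <- floor(t_ - min(t_)) + 1L
  nb <- max(bin)
  wcount <- tabulate(bin, nb)
  wsm <- as.numeric(stats::filter(wcount, rep(1 / 3, 3), sides = 2))
  wsm[is.na(wsm)] <- wcount[is.na(wsm)]
  thr <- 0.2 * max(wsm)
  below <- wsm < thr
  run_from <- function(start, dir) {
    i <- start; n <- 0L
    while (i >= 1L && i <= nb && below[i]) { n <- n + 1L; i <- i + dir }
    n
  }
  n_lo <- run_from(1L, 1L); n_hi <- run_from(nb, -1L)
  no_pet <- list(blade = s, petiole = NULL,
                 info = list(length = 0, thickness_upper = 0,
                             thickness_lower = 0, base_point = NULL))
  best <- max(n_lo, n_hi)
  if (best <= 0.05 * nb) return(no_pet)
  pet_bins <- if (n_lo >= n_hi) seq_len(n_lo) else (nb - n_hi + 1L):nb
  pet_sel <- bin %in% pet_bins
  if (sum(!pet_sel) < 100L) return(no_pet)
  pet_idx <- idx[pet_sel]
  blade_mask <- mask; blade_mask[pet_idx] <- FALSE
  pet_mask <- mask & !blade_mask
  # quarter adjoining the blade = upper; distal quarter = lower
  k <- length(pet_bins); q <- max(1L, floor(k / 4))
  ordered <- if (n_lo >= n_hi) rev(pet_bins) else pet_bins  # blade side first
  upper <- mean(wcount[ordered[seq_len(q)]])
  lower <- mean(wcount[ordered[(k - q + 1L):k]])
  info <- list(length = k * s$mm_per_px,
               thickness_upper = upper * s$mm_per_px,
               thickness_lower = lower * s$mm_per_px,
               base_point = colMeans(xy[pet_sel, , drop = FALSE]) * s$mm_per_px)
  blade <- silhouette(blade_mask, s$mm_per_px, organ = "leaf",
                      sample_id = s$sample_id, cultivar = s$cultivar,
                      year = s$year, validate = FALSE)
  pet <- silhouette(pet_mask, s$mm_per_px, organ = "leaf",
                    sample_id = s$sample_id, cultivar = s$cultivar,
                    year = s$year, validate = FALSE)
  list(blade = blade, petiole = pet, info = info)
}

#' Leaf descriptor vector (16 values)
#'
#' Blade area, perimeter, length, maximum transverse diameter, shape index,
#' circularity (roundness), fitted-ellipse semi-axes, apex and base
#' pointedness (mean landmark-window curvature x length), vertical symmetry,
#' transversal asymmetry, convexity (area / convex-hull area) and the three
#' petiole descriptors. Petiole descriptors are 0 when no petiole is present.
#'
#' @param blade a normalized blade `olive_contour`.
#' @param petiole_info list with `length`, `thickness_upper`,
#'   `thickness_lower` in mm (from [split_petiole()]), or `NULL`.
#' @return named numeric vector of length 16 with attribute `organ = "leaf"`.
#' @export
leaf_features <- function(blade, petiole_info = NULL) {
  m <- contour_metrics(blade)
  hull <- grDevices::chull(blade$points)
  hull_area <- abs(shoelace(blade$points[hull, , drop = FALSE]))
  pi_ <- petiole_info %||% list(length = 0, thickness_upper = 0, thickness_lower = 0)
  v <- c(area = m$area, perimeter = m$perimeter, length = m$cal$height,
         width = m$cal$width, shape_index = m$shape_index,
         circularity = m$circularity, ellipse_a = m$fit$a, ellipse_b = m$fit$b,
         apex_pointedness = mean(m$curv$kappa[m$landmarks$apex_window]) * m$cal$height,
         base_pointedness = mean(m$curv$kappa[m$landmarks$base_window]) * m$cal$height,
         vertical_symmetry = m$sym$vertical_symmetry,
         trans_asymmetry = m$sym$transversal_asymmetry,
         convexity = m$area / hull_area,
         petiole_length = pi_$length,
         petiole_thickness_upper = pi_$thickness_upper,
         petiole_thickness_lower = pi_$thickness_lower)
  names(v) <- feature_names("leaf")
  structure(v, organ = "leaf")
}

#' Leaf descriptor vector straight from a silhouette
#'
#' Convenience wrapper: [split_petiole()], then blade contour with the petiole
#' attachment as base hint, then [leaf_features()].
#'
#' @param s a leaf [silhouette()].
#' @param n_points contour resolution.
#' @export
leaf_features_from_silhouette <- function(s, n_points = DEFAULT_N_POINTS) {
  sp <- split_petiole(s)
  blade <- contour_from_silhouette(sp$blade, n_points = n_points,
                                   base_point = sp$info$base_point)
  leaf_features(blade, sp$info)
}

#' Endocarp descriptor vector (22 or 25 values)
#'
#' Eleven descriptors per position: area, perimeter, height, maximum
#' transversal diameter, shape index, circularity, fitted-ellipse semi-minor
#' axis, apex-curve area (area between contour and ellipse arc over the apex
#' window; the mucro signal), base length (chord of the low-curvature base
#' region), position of the transversal diameter and the minimum distance
#' from the maximum-width chord midpoint to the contour. With
#' `extended = TRUE` three cross-position extras are added: mucro index, mean
#' circularity of A and B, and the A/B width ratio.
#'
#' @param contour_A,contour_B normalized contours of positions A and B.
#' @param extended add the 3 extras (25 values).
#' @return named numeric vector with attribute `organ = "endocarp"`.
#' @export
endocarp_features <- function(contour_A, contour_B, extended = FALSE) {
  one <- function(c) {
    m <- contour_metrics(c)
    W <- m$landmarks$apex_window
    ed <- ellipse_deviation(c, m$fit_base, W)
    apex_curve_area <- sum(abs(ed$r^2 - ed$r_ell^2) * ed$dth) / 2
    # flat base region: |curvature| below half the contour median
    kap <- abs(m$curv$kappa)
    Wb <- m$landmarks$base_window
    flat <- kap[Wb] < 0.5 * stats::median(kap)
    bi <- which(Wb == m$landmarks$base_index)
    base_length <- 0
    if (length(bi) == 1L && flat[bi]) {
      lo <- bi; while (lo > 1L && flat[lo - 1L]) lo <- lo - 1L
      hi <- bi; while (hi < length(Wb) && flat[hi + 1L]) hi <- hi + 1L
      base_length <- sqrt(sum((c$points[Wb[hi], ] - c$points[Wb[lo], ])^2))
    }
    # midpoint of the widest chord to nearest contour point
    h_star <- min(c$points[, 2]) + m$sym$vertical_symmetry * m$cal$height
    y1 <- c$points[, 2]; y2 <- c(y1[-1], y1[1])
    x1 <- c$points[, 1]; x2 <- c(x1[-1], x1[1])
    sel <- (y1 <= h_star & y2 > h_star) | (y2 <= h_star & y1 > h_star)
    mid <- if (any(sel)) {
      xc <- x1[sel] + (h_star - y1[sel]) / (y2[sel] - y1[sel]) * (x2[sel] - x1[sel])
      c(mean(range(xc)), h_star)
    } else c(0, h_star)
    min_dist <- sqrt(min((c$points[, 1] - mid[1])^2 + (c$points[, 2] - mid[2])^2))
    c(area = m$area, perimeter = m$perimeter, height = m$cal$height,
      width = m$cal$width, shape_index = m$shape_index,
      circularity = m$circularity, ellipse_b = m$fit$b,
      apex_curve_area = apex_curve_area, base_length = base_length,
      width_position = m$sym$vertical_symmetry, min_dist_width_chord = min_dist)
  }
  a <- one(contour_A); b <- one(contour_B)
  v <- c(a, b)
  names(v) <- feature_names("endocarp")
  if (extended) {
    extras <- c(
      mucro_index = as.numeric(a[["apex_curve_area"]] > MUCRO_AREA_FRAC * a[["area"]] ||
                               b[["apex_curve_area"]] > MUCRO_AREA_FRAC * b[["area"]]),
      mean_circularity = mean(c(a[["circularity"]], b[["circularity"]])),
      width_ratio_AB = a[["width"]] / b[["width"]])
    v <- c(v, extras)
    names(v) <- feature_names("endocarp", extended = TRUE)
  }
  structure(v, organ = "endocarp")
}

#' Assemble a labeled feature table
#'
#' @param rows list of entries, each a list with `sample_id`, `cultivar`,
#'   `year` and `features` (a named vector from one of the `*_features()`
#'   functions). Entries whose feature vector is an error condition are
#'   skipped with a message, never imputed.
#' @param organ organ tag of the table (must match the rows).
#' @return a `data.frame` of class `olive_features` with metadata columns
#'   `sample_id`, `cultivar`, `year`, `organ` followed by the descriptors,
#'   ordered by (cultivar, sample_id).
#' @export
build_feature_table <- function(rows, organ) {
  keep <- vapply(rows, function(r) !inherits(r$features, "try-error") &&
                   all(is.finite(r$features)), logical(1))
  if (any(!keep)) message(sum(!keep), " sample(s) failed feature extraction; skipped")
  rows <- rows[keep]
  if (length(rows) == 0L) stop("no usable samples")
  ids <- vapply(rows, function(r) as.character(r$sample_id), character(1))
  if (anyDuplicated(ids)) stop("duplicate sample_id: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  fmat <- do.call(rbind, lapply(rows, `[[`, "features"))
  stopifnot(all(vapply(rows, function(r) attr(r$features, "organ"), character(1)) == organ))
  df <- data.frame(
    sample_id = ids,
    cultivar = vapply(rows, function(r) as.character(r$cultivar), character(1)),
    year = vapply(rows, function(r) as.integer(r$year), integer(1)),
    organ = organ, fmat, stringsAsFactors = FALSE, check.names = FALSE)
  df <- df[order(df$cultivar, df$sample_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("olive_features", "data.frame"),
            feature_names = colnames(fmat), organ = organ)
}

feature_matrix <- function(tab) {
  as.matrix(tab[, attr(tab, "feature_names"), drop = FALSE])
}

#' Write / read a feature table as CSV
#'
#' UTF-8, header row, '.' decimal separator; metadata columns first.
#'
#' @param tab an `olive_features` table.
#' @param path CSV path.
#' @export
write_feature_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param organ organ tag; inferred from the `organ` column when omitted.
#' @export
read_feature_table <- function(path, organ = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  organ <- organ %||% df$organ[1]
  meta <- c("sample_id", "cultivar", "year", "organ")
  structure(df, class = c("olive_features", "data.frame"),
            feature_names = setdiff(colnames(df), meta), organ = organ)
}
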