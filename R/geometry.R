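# Contour extraction, normalization and the primitive geometric measurements
# every shape descriptor is built from.
#
# A contour is an ordered, closed (closure implicit), counter-clockwise polygon
# in millimetres, orientation-normalized: centroid at the origin, first
# principal axis vertical, apex end up.

DEFAULT_N_POINTS <- 512L
DEFAULT_CURV_WINDOW <- 15L
LANDMARK_FRAC <- 0.10      # landmark window: +/- 10% of perimeter
MIRROR_RES_MM <- 0.05      # rasterization step for mirror-overlap asymmetry

new_contour <- function(points, mm_per_px) {
  y <- points[, 2]
  structure(list(points = points, n_points = nrow(points),
                 apex_index = which.max(y), base_index = which.min(y),
                 mm_per_px = mm_per_px),
            class = "olive_contour")
}

#' @export
print.olive_contour <- function(x, ...) {
  cat(sprintf("<olive_contour> %d points, area %.3f mm^2, height %.3f mm\n",
              x$n_points, polygon_area(x), diff(range(x$points[, 2]))))
  invisible(x)
}

# --- closed-polygon primitives on raw point matrices -------------------------

shoelace <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

poly_centroid <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

resample_closed <- function(p, n) {
  seg <- sqrt(rowSums((rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE]) - p)^2))
  keep <- c(TRUE, seg[-length(seg)] > 1e-12)  # drop duplicated vertices
  p <- p[keep, , drop = FALSE]
  seg <- sqrt(rowSums((rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE]) - p)^2))
  s <- c(0, cumsum(seg))
  per <- s[length(s)]
  t_out <- per * (seq_len(n) - 1) / n
  i <- findInterval(t_out, s, rightmost.closed = TRUE)
  i[i > nrow(p)] <- nrow(p)
  frac <- (t_out - s[i]) / pmax(seg[i], 1e-300)
  nxt <- ifelse(i == nrow(p), 1L, i + 1L)
  cbind(p[i, 1] + frac * (p[nxt, 1] - p[i, 1]),
        p[i, 2] + frac * (p[nxt, 2] - p[i, 2]))
}

rotate_pts <- function(p, theta) {
  ct <- cos(theta); st <- sin(theta)
  cbind(ct * p[, 1] - st * p[, 2], st * p[, 1] + ct * p[, 2])
}

# Signed curvature of a closed, equally-spaced polygon via Savitzky-Golay
# derivative filters applied on a circular padding. Positive on convex arcs of
# a counter-clockwise contour.
closed_curvature <- function(p, window = DEFAULT_CURV_WINDOW) {
  n <- nrow(p)
  if (window %% 2 != 1 || window < 5) stop("window must be an odd integer >= 5")
  if (window >= n / 2) stop("smoothing window must be < n_points / 2")
  per <- polygon_perimeter_pts(p)
  ds <- per / n
  h <- (window - 1L) %/% 2L
  pad <- function(v) c(v[(n - h + 1L):n], v, v[1L:h])
  F1 <- signal::sgolay(p = 3, n = window, m = 1, ts = ds)
  F2 <- signal::sgolay(p = 3, n = window, m = 2, ts = ds)
  mid <- h + 1L
  d <- function(v, Fm) {
    vp <- pad(v)
    as.numeric(stats::filter(vp, rev(Fm[mid, ]), sides = 2))[(h + 1L):(h + n)]
  }
  xp <- d(p[, 1], F1); yp <- d(p[, 2], F1)
  xpp <- d(p[, 1], F2); ypp <- d(p[, 2], F2)
  (xp * ypp - yp * xpp) / pmax((xp^2 + yp^2)^1.5, 1e-300)
}

polygon_perimeter_pts <- function(p) {
  sum(sqrt(rowSums((rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE]) - p)^2)))
}

# Circular Gaussian smoothing along arc length (sigma in the units of p).
# Suppresses rasterization staircase without measurably biasing area for
# features larger than a few sigma.
smooth_closed <- function(p, sigma) {
  n <- nrow(p)
  ds <- polygon_perimeter_pts(p) / n
  hw <- max(1L, ceiling(3 * sigma / ds))
  if (2L * hw + 1L >= n) return(p)
  w <- exp(-0.5 * ((-hw:hw) * ds / sigma)^2)
  w <- w / sum(w)
  sm <- function(v) {
    vp <- c(v[(n - hw + 1L):n], v, v[1L:hw])
    stats::filter(vp, w, sides = 2)[(hw + 1L):(hw + n)]
  }
  cbind(as.numeric(sm(p[, 1])), as.numeric(sm(p[, 2])))
}

win_indices <- function(center, n, frac = LANDMARK_FRAC) {
  k <- max(1L, round(frac * n))
  ((center - 1L + seq(-k, k)) %% n) + 1L
}

# --- normalization -----------------------------------------------------------

# Normalize a raw closed boundary: resample to n equal-arc points, centroid at
# origin, principal axis vertical, CCW, apex up. `base_point` (same input
# frame) wins the up/down disambiguation when supplied (leaves: petiole
# attachment is the base); otherwise the end with the larger mean |curvature|
# over its landmark window is the apex.
normalize_contour <- function(p, mm_per_px, n_points = DEFAULT_N_POINTS,
                              base_point = NULL) {
  if (n_points < 64) stop("n_points must be >= 64")
  p <- resample_closed(p, n_points)
  ctr <- poly_centroid(p)
  p <- cbind(p[, 1] - ctr[1], p[, 2] - ctr[2])
  if (!is.null(base_point)) base_point <- base_point - ctr
  ev <- eigen(stats::cov(p), symmetric = TRUE)
  v1 <- ev$vectors[, 1]
  theta <- pi / 2 - atan2(v1[2], v1[1])
  p <- rotate_pts(p, theta)
  if (!is.null(base_point)) base_point <- drop(rotate_pts(rbind(base_point), theta))
  if (shoelace(p) < 0) {
    p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
  }
  p <- resample_closed(p, n_points)
  flip <- if (!is.null(base_point)) {
    base_point[2] > 0
  } else {
    # the sharper end is the apex; the window *maximum* is used because a
    # nipple's flat flanks can drag the window mean below the plain end's
    kap <- abs(closed_curvature(p))
    top <- max(kap[win_indices(which.max(p[, 2]), n_points)])
    bot <- max(kap[win_indices(which.min(p[, 2]), n_points)])
    bot > top
  }
  if (flip) p <- rotate_pts(p, pi)
  ctr <- poly_centroid(p)
  p <- cbind(p[, 1] - ctr[1], p[, 2] - ctr[2])
  new_contour(p, mm_per_px)
}

#' Extract an orientation-normalized contour from a silhouette
#'
#' Traces the sub-pixel 0.5-level boundary of the mask, resamples it to
#' `n_points` at equal arc length, converts to millimetres and normalizes the
#' pose (centroid at origin, principal axis vertical, counter-clockwise, apex
#' up).
#'
#' @param s an [silhouette()].
#' @param n_points number of boundary points (>= 64, default 512).
#' @param base_point optional (x, y) in the silhouette's mm frame (y up) that
#'   must end up on the base (bottom) side, e.g. the petiole attachment.
#' @return an object of class `olive_contour`.
#' @export
contour_from_silhouette <- function(s, n_points = DEFAULT_N_POINTS,
                                    base_point = NULL) {
  stopifnot(inherits(s, "olive_silhouette"))
  m <- s$mask
  if (sum(m) < 100L) stop("degenerate mask: area < 100 px")
  z <- t(m * 1.0)[, rev(seq_len(nrow(m))), drop = FALSE]  # x = col, y up
  cl <- grDevices::contourLines(x = seq_len(ncol(m)), y = seq_len(nrow(m)),
                                z = z, levels = 0.5)
  if (length(cl) == 0L) stop("no boundary found")
  areas <- vapply(cl, function(cc) abs(shoelace(cbind(cc$x, cc$y))), numeric(1))
  cc <- cl[[which.max(areas)]]
  p <- cbind(cc$x, cc$y)
  if (sqrt(sum((p[1, ] - p[nrow(p), ])^2)) < 1e-9) p <- p[-nrow(p), , drop = FALSE]
  p <- resample_closed(p, max(2L * n_points, 1024L))
  p <- smooth_closed(p, sigma = 1.0)    # 1 px: kills the raster staircase
  p <- p * s$mm_per_px
  normalize_contour(p, s$mm_per_px, n_points, base_point = base_point)
}

#' Build a contour directly from boundary points
#'
#' Used by the synthetic generator's fast path and for importing externally
#' traced boundaries; applies the same resampling and pose normalization as
#' [contour_from_silhouette()].
#'
#' @param points two-column matrix of (x, y) boundary points (closed implied).
#' @param mm_per_px nominal scale recorded on the contour.
#' @inheritParams contour_from_silhouette
#' @export
contour_from_points <- function(points, mm_per_px = 1,
                                n_points = DEFAULT_N_POINTS, base_point = NULL) {
  normalize_contour(as.matrix(points), mm_per_px, n_points, base_point)
}

# --- measurements ------------------------------------------------------------

#' Polygon area of a contour (mm^2)
#' @param c an `olive_contour`.
#' @export
polygon_area <- function(c) abs(shoelace(c$points))

#' Polygon perimeter of a contour (mm)
#' @param c an `olive_contour`.
#' @export
polygon_perimeter <- function(c) polygon_perimeter_pts(c$points)

#' Height, maximum width and the width profile of a normalized contour
#'
#' Height is the y-extent; width the maximum horizontal chord; the width
#' profile gives the chord length as a function of normalized height h in
#' \[0, 1\] measured from the base.
#'
#' @param c an `olive_contour`.
#' @param n_levels number of horizontal levels used to sample the profile.
#' @return list with `height`, `width`, `width_profile` (a function of h),
#'   `width_position` (normalized height of the widest chord) and the sampled
#'   `profile` data frame.
#' @export
caliper_dimensions <- function(c, n_levels = 256L) {
  p <- c$points
  y <- p[, 2]
  ymin <- min(y); ymax <- max(y)
  height <- ymax - ymin
  hs <- seq(ymin + 1e-9 * height, ymax - 1e-9 * height, length.out = n_levels)
  chord <- chord_lengths(p, hs)
  h01 <- (hs - ymin) / height
  wp <- stats::approxfun(h01, chord, yleft = 0, yright = 0)
  imax <- which.max(chord)
  list(height = height, width = max(chord), width_profile = wp,
       width_position = h01[imax],
       profile = data.frame(h = h01, chord = chord))
}

#' Direct least-squares ellipse fit
#'
#' Fits a conic constrained to be an ellipse (Fitzgibbon's direct method in the
#' numerically stable Halir–Flusser formulation) and converts it to geometric
#' parameters. The residual is the root-mean-square radial distance from the
#' points to the ellipse.
#'
#' @param c an `olive_contour` (or a two-column point matrix).
#' @return list of class `olive_ellipse`: `center`, `a` (semi-major), `b`
#'   (semi-minor), `angle` (radians, major axis from +x), `rms_residual`.
#' @export
fit_ellipse <- function(c) {
  p <- if (inherits(c, "olive_contour")) c$points else as.matrix(c)
  mx <- mean(p[, 1]); my <- mean(p[, 2])
  x <- p[, 1] - mx; y <- p[, 2] - my
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e) stop("degenerate ellipse fit"))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0L) stop("degenerate ellipse fit: no elliptical solution")
  a1 <- V[, ok[1]]
  coef <- c(a1, drop(Tm %*% a1))      # A B C D E F at centered coords
  A <- coef[1]; B <- coef[2]; C <- coef[3]; D <- coef[4]; E <- coef[5]; Fc <- coef[6]
  den <- B^2 - 4 * A * C
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 + Fc * B^2 - B * D * E - 4 * A * C * Fc)
  s <- sqrt((A - C)^2 + B^2)
  ax1 <- -sqrt(num * (A + C + s)) / den
  ax2 <- -sqrt(num * (A + C - s)) / den
  a <- max(ax1, ax2); b <- min(ax1, ax2)
  angle <- if (abs(B) < 1e-12 && A <= C) 0
           else if (abs(B) < 1e-12) pi / 2
           else atan2(C - A - s, B)
  if (ax2 > ax1) angle <- angle + pi / 2
  angle <- atan2(sin(angle), cos(angle))
  center <- c(cx + mx, cy + my)
  # radial residual in the ellipse frame
  q <- rotate_pts(cbind(p[, 1] - center[1], p[, 2] - center[2]), -angle)
  th <- atan2(q[, 2], q[, 1])
  r_ell <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  rms <- sqrt(mean((sqrt(rowSums(q^2)) - r_ell)^2))
  structure(list(center = center, a = a, b = b, angle = angle,
                 rms_residual = rms), class = "olive_ellipse")
}

# Radius of a fitted ellipse along the ray at contour angle theta (contour
# frame, measured from the ellipse center).
ellipse_radius_at <- function(fit, theta) {
  phi <- theta - fit$angle
  fit$a * fit$b / sqrt((fit$b * cos(phi))^2 + (fit$a * sin(phi))^2)
}

#' Signed curvature profile of a contour
#'
#' Curvature from Savitzky-Golay-smoothed first and second arc-length
#' derivatives; convex regions of the counter-clockwise contour are positive.
#'
#' @param c an `olive_contour`.
#' @param window odd smoothing window (points), default 15; must be < n/2.
#' @return object of class `olive_curvature` with per-point `kappa` (1/mm) and
#'   `smoothing_window`.
#' @export
curvature_profile <- function(c, window = DEFAULT_CURV_WINDOW) {
  kap <- closed_curvature(c$points, window)
  structure(list(kappa = kap, smoothing_window = as.integer(window)),
            class = "olive_curvature")
}

#' Apex and base landmarks of a normalized contour
#'
#' The apex is the boundary point of maximal y, the base that of minimal y;
#' each carries a window of points within +/- 10% of the perimeter.
#'
#' @param c an `olive_contour`.
#' @return list with `apex_index`, `base_index`, `apex_window`, `base_window`.
#' @export
locate_landmarks <- function(c) {
  y <- c$points[, 2]
  ai <- which.max(y); bi <- which.min(y)
  list(apex_index = ai, base_index = bi,
       apex_window = win_indices(ai, c$n_points),
       base_window = win_indices(bi, c$n_points))
}

#' Mirror asymmetry and width-position symmetry of a contour
#'
#' `transversal_asymmetry` is 1 minus the fractional overlap of the shape with
#' its mirror image about the vertical axis (computed on a 0.05 mm/px
#' rasterization); `vertical_symmetry` is the normalized height (from the
#' base) at which the width profile peaks.
#'
#' @param c an `olive_contour`.
#' @return list with `transversal_asymmetry` and `vertical_symmetry`, both in
#'   \[0, 1\].
#' @param cal optional precomputed [caliper_dimensions()] result.
#' @export
symmetry_measures <- function(c, cal = NULL) {
  cal <- cal %||% caliper_dimensions(c)
  p <- c$points
  res <- MIRROR_RES_MM
  nx <- ceiling((max(abs(p[, 1])) + 2 * res) / res)
  xs <- (seq(-nx, nx - 1) + 0.5) * res
  ys <- seq(min(p[, 2]) - 2 * res, max(p[, 2]) + 2 * res, by = res)
  mask <- rasterize_polygon(p, xs, ys)
  mirrored <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
  area <- sum(mask)
  ta <- if (area == 0) 0 else 1 - sum(mask & mirrored) / area
  list(transversal_asymmetry = ta, vertical_symmetry = cal$width_position)
}

# All (scanline, edge) crossings of a closed polygon: returns row index into
# `hs` and crossing abscissa, fully vectorized.
edge_crossings <- function(p, hs) {
  x1 <- p[, 1]; y1 <- p[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  lo <- pmin(y1, y2); hi <- pmax(y1, y2)
  i1 <- findInterval(lo, hs) + 1L          # first level strictly above lo
  i2 <- findInterval(hi - 1e-300, hs)      # last level below hi
  n_per <- pmax(i2 - i1 + 1L, 0L)
  keep <- n_per > 0L
  if (!any(keep)) return(list(row = integer(0), x = numeric(0)))
  e <- rep.int(which(keep), n_per[keep])
  row <- sequence(n_per[keep]) + rep.int(i1[keep] - 1L, n_per[keep])
  h <- hs[row]
  xc <- x1[e] + (h - y1[e]) / (y2[e] - y1[e]) * (x2[e] - x1[e])
  list(row = row, x = xc)
}

# Maximum horizontal chord (max - min crossing) at each level in hs.
chord_lengths <- function(p, hs) {
  cr <- edge_crossings(p, hs)
  chord <- numeric(length(hs))
  if (length(cr$row)) {
    mx <- tapply(cr$x, cr$row, max)
    mn <- tapply(cr$x, cr$row, min)
    idx <- as.integer(names(mx))
    chord[idx] <- mx - mn
  }
  chord
}

# Scanline rasterization of a closed polygon onto pixel centers (xs, ys).
# Returns a logical matrix indexed [y, x]: a center is inside iff an odd
# number of crossings lie to its left.
rasterize_polygon <- function(p, xs, ys) {
  cr <- edge_crossings(p, ys)
  ny <- length(ys); nx <- length(xs)
  toggle <- matrix(0L, ny, nx)
  if (length(cr$row)) {
    col <- findInterval(cr$x, xs) + 1L   # first center right of the crossing
    ok <- col <= nx
    li <- cr$row[ok] + (col[ok] - 1L) * ny
    toggle[] <- tabulate(li, ny * nx)
  }
  parity <- t(apply(toggle, 1, cumsum)) %% 2L
  parity == 1L
}

#' Export a contour as CSV
#'
#' One row per boundary point (`x_mm`, `y_mm`); sample metadata may be passed
#' and is stored in comment-prefixed header lines.
#'
#' @param c an `olive_contour`.
#' @param path output path.
#' @param meta optional named list echoed as `# key: value` header lines.
#' @export
write_contour_csv <- function(c, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  utils::write.csv(data.frame(x_mm = c$points[, 1], y_mm = c$points[, 2]),
                   con, row.names = FALSE)
  invisible(path)
}
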