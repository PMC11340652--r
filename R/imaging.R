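# Silhouette container, segmentation and mask I/O.
#
# Pixel-space convention: masks are logical matrices with row 1 at the top of
# the image, x increasing with column index and y increasing downward. The
# geometry module converts to y-up millimetre coordinates.

#' Construct a calibrated organ silhouette
#'
#' A silhouette is a binary foreground mask plus the physical scale and organ
#' metadata. Validation enforces a single 4-connected foreground component of
#' at least 100 pixels that touches no image border.
#'
#' @param mask logical matrix, `TRUE` = organ foreground.
#' @param mm_per_px millimetres per pixel (> 0).
#' @param organ one of `"fruit"`, `"leaf"`, `"endocarp"`.
#' @param position viewing position, `"A"`, `"B"` or `"none"`.
#' @param sample_id sample identifier.
#' @param cultivar cultivar label or `NA` if unknown.
#' @param year sampling year or `NA` if unknown.
#' @param validate check the silhouette invariants (default `TRUE`).
#' @return an object of class `olive_silhouette`.
#' @export
silhouette <- function(mask, mm_per_px, organ = c("fruit", "leaf", "endocarp"),
                       position = c("none", "A", "B"), sample_id = "s1",
                       cultivar = NA_character_, year = NA_integer_,
                       validate = TRUE) {
  organ <- match.arg(organ)
  position <- match.arg(position)
  if (is.numeric(mask)) mask <- mask > 0.5
  stopifnot(is.logical(mask), is.matrix(mask))
  stopifnot_scalar_pos(mm_per_px, "mm_per_px")
  s <- structure(
    list(mask = mask, mm_per_px = mm_per_px, organ = organ,
         position = position, sample_id = as.character(sample_id),
         cultivar = as.character(cultivar),
         year = if (is.na(year)) NA_integer_ else as.integer(year)),
    class = "olive_silhouette")
  if (validate) validate_silhouette(s)
  s
}

#' @export
print.olive_silhouette <- function(x, ...) {
  cat(sprintf("<olive_silhouette> %s (%s) %dx%d px, %d fg px, %.4g mm/px, sample %s\n",
              x$organ, x$position, nrow(x$mask), ncol(x$mask),
              sum(x$mask), x$mm_per_px, x$sample_id))
  invisible(x)
}

validate_silhouette <- function(s) {
  m <- s$mask
  if (sum(m) < 100L) stop("silhouette has fewer than 100 foreground pixels")
  if (any(m[1, ]) || any(m[nrow(m), ]) || any(m[, 1]) || any(m[, ncol(m)]))
    stop("foreground touches the image border")
  lab <- label_components(m)
  if (max(lab) != 1L) stop("foreground is not a single 4-connected component (",
                           max(lab), " found)")
  invisible(s)
}

# 4-connected labeling of TRUE pixels. Returns an integer matrix, 0 =
# background, components numbered by decreasing size.
label_components <- function(mask) {
  idx <- which(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx) == 0L) return(lab)
  id <- integer(length(mask)); id[idx] <- seq_along(idx)
  nr <- nrow(mask)
  r <- ((idx - 1L) %% nr) + 1L
  down <- idx[r < nr]
  down <- down[mask[down + 1L]]
  right <- idx[idx + nr <= length(mask)]
  right <- right[mask[right + nr]]
  edges <- rbind(cbind(id[down], id[down + 1L]),
                 cbind(id[right], id[right + nr]))
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  sizes <- tabulate(comp)
  rank <- integer(length(sizes))
  rank[order(sizes, decreasing = TRUE)] <- seq_along(sizes)
  lab[idx] <- rank[comp]
  lab
}

# Fill holes: background 4-connected components not touching the border become
# foreground.
fill_holes <- function(mask) {
  bg <- !mask
  lab <- label_components(bg)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0L]
  mask | (lab > 0L & !(lab %in% border))
}

#' Millimetres per pixel from scan resolution
#'
#' @param dpi dots per inch (> 0).
#' @return mm per pixel, `25.4 / dpi`.
#' @examples scale_from_dpi(600)
#' @export
scale_from_dpi <- function(dpi) {
  stopifnot_scalar_pos(dpi, "dpi")
  25.4 / dpi
}

#' Segment a single-organ image into a silhouette
#'
#' Separates one dominant object from a uniform background: global Otsu
#' threshold, automatic polarity choice (the object must not touch three or
#' more borders), hole filling, removal of spurious components smaller than 1%
#' of the largest, and retention of the largest 4-connected component.
#'
#' @param image a numeric matrix of intensities in \[0, 1\], a 3-d array
#'   (RGB), or a path to a PNG/JPEG file.
#' @param mm_per_px physical scale; give either this or `dpi`.
#' @param dpi scan resolution, used as `25.4 / dpi` when `mm_per_px` is missing.
#' @param organ,position,sample_id,cultivar,year silhouette metadata.
#' @return an [silhouette()] object.
#' @export
segment_image <- function(image, mm_per_px = NULL, dpi = NULL,
                          organ = "fruit", position = "none",
                          sample_id = "s1", cultivar = NA, year = NA) {
  if (is.character(image)) {
    img <- EBImage::readImage(image)
    dat <- EBImage::imageData(img)
    image <- if (length(dim(dat)) == 3L) aperm(dat, c(2, 1, 3)) else t(dat)
  }
  if (length(dim(image)) == 3L) {
    image <- 0.2126 * image[, , 1] + 0.7152 * image[, , 2] + 0.0722 * image[, , 3]
  }
  stopifnot(is.matrix(image), nrow(image) >= 16, ncol(image) >= 16,
            all(is.finite(image)))
  if (is.null(mm_per_px)) {
    if (is.null(dpi)) stop("supply mm_per_px or dpi")
    mm_per_px <- scale_from_dpi(dpi)
  }
  rng <- range(image)
  if (diff(rng) < 1e-12) stop("no foreground found: image is uniform")
  img01 <- (image - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(t(img01)))

  candidate <- function(fg) {
    fg <- fill_holes(fg)
    lab <- label_components(fg)
    if (max(lab) == 0L) return(NULL)
    sizes <- tabulate(lab[lab > 0L])
    main <- lab == 1L
    borders <- sum(any(main[1, ]), any(main[nrow(main), ]),
                   any(main[, 1]), any(main[, ncol(main)]))
    list(mask = fg, lab = lab, sizes = sizes, borders = borders,
         frac = mean(fg))
  }
  dark <- candidate(img01 < thr)   # dark object on light background
  light <- candidate(img01 >= thr)
  cands <- Filter(function(cc) !is.null(cc) && cc$borders < 3, list(dark, light))
  if (length(cands) == 0L) stop("no foreground found: both polarities touch >= 3 borders")
  cand <- cands[[which.min(vapply(cands, `[[`, numeric(1), "frac"))]]

  sizes <- cand$sizes
  if (max(sizes) < 100L) stop("no foreground found: largest component < 100 px")
  if (length(sizes) > 1L && sort(sizes, decreasing = TRUE)[2] > 0.25 * max(sizes))
    warning("multiple objects detected: second-largest component > 25% of largest")
  keep <- cand$lab == 1L
  # spurious specks < 1% of the largest are dropped with it; only the largest
  # component is returned.
  silhouette(keep, mm_per_px = mm_per_px, organ = organ, position = position,
             sample_id = sample_id, cultivar = cultivar, year = year)
}

#' Write a silhouette as a binary PNG plus JSON sidecar
#'
#' The mask is stored as an 8-bit grayscale PNG with values {0, 255}; the
#' metadata (sample id, cultivar, year, organ, position, mm per pixel) goes to
#' a `.json` sidecar next to it.
#'
#' @param s an [silhouette()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(s, path) {
  stopifnot(inherits(s, "olive_silhouette"))
  png::writePNG(s$mask * 1.0, path)
  meta <- list(sample_id = s$sample_id, cultivar = s$cultivar, year = s$year,
               organ = s$organ, position = s$position, mm_per_px = s$mm_per_px)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read a binary PNG mask (and its JSON sidecar) as a silhouette
#'
#' @param path PNG path written by [write_mask()] or any strictly binary
#'   single-channel PNG.
#' @param mm_per_px fallback scale when no sidecar is present.
#' @return an [silhouette()].
#' @export
read_mask <- function(path, mm_per_px = NULL) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  if (!all(px %in% c(0, 1)))
    stop("mask PNG is not binary: values other than {0, 255} present")
  side <- sidecar_path(path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  } else {
    warning("missing sidecar ", side, ": cultivar/year unknown")
    meta <- list()
  }
  silhouette(px > 0.5,
             mm_per_px = meta$mm_per_px %||% mm_per_px %||%
               stop("no mm_per_px in sidecar and none supplied"),
             organ = meta$organ %||% "fruit",
             position = meta$position %||% "none",
             sample_id = meta$sample_id %||% tools::file_path_sans_ext(basename(path)),
             cultivar = if (is.null(meta$cultivar) || is.na(meta$cultivar)) NA else meta$cultivar,
             year = if (is.null(meta$year) || is.na(meta$year)) NA else meta$year)
}
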