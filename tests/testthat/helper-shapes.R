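# Shared fixtures, all generated in code.

# pixel-grid disc mask of radius r_px centered in a padded image
disc_mask <- function(r_px, pad = 40L) {
  n <- 2L * r_px + 2L * pad
  xx <- outer(rep(1, n), seq_len(n))
  yy <- t(xx)
  (xx - n / 2)^2 + (yy - n / 2)^2 <= r_px^2
}

square_mask <- function(side_px, pad = 40L) {
  n <- side_px + 2L * pad
  m <- matrix(FALSE, n, n)
  m[(pad + 1L):(pad + side_px), (pad + 1L):(pad + side_px)] <- TRUE
  m
}

ellipse_points <- function(a, b, n = 256L, angle = 0, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  p <- cbind(a * cos(th), b * sin(th))
  if (angle != 0) p <- cbind(cos(angle) * p[, 1] - sin(angle) * p[, 2],
                             sin(angle) * p[, 1] + cos(angle) * p[, 2])
  sweep(p, 2, center, "+")
}

# Ramanujan's approximation to an ellipse perimeter
ellipse_perimeter_ramanujan <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# Gaussian-blob feature tables for classifier tests (no geometry involved):
# k cultivars, mean separation `sep` (in within-sd units) on every feature.
blob_table <- function(organ, k = 2L, n_per_class = 20L, n_feat = 6L,
                       sep = 10, seed = 0L, year = 1L) {
  set.seed(seed)
  rows <- list()
  feats <- paste0("d", seq_len(n_feat))
  for (ci in seq_len(k)) {
    X <- matrix(rnorm(n_per_class * n_feat, mean = ci * sep), n_per_class)
    for (i in seq_len(n_per_class)) {
      v <- setNames(X[i, ], feats)
      attr(v, "organ") <- organ
      rows[[length(rows) + 1L]] <- list(
        sample_id = sprintf("c%d_%03d", ci, i),
        cultivar = paste0("cv", ci), year = year, features = v)
    }
  }
  build_feature_table(rows, organ)
}

# memoised cohorts so expensive generation happens once per test run
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(preset, n_per_organ, years = c(1L, 2L), seed = 0L, ...) {
  key <- paste(preset, n_per_organ, paste(years, collapse = ""), seed, sep = "_")
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- generate_cohort(preset_cohorts(preset),
                                            n_per_organ = n_per_organ,
                                            years = years, seed = seed, ...)
  .cohort_cache[[key]]
}
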