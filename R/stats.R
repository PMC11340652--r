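# Exploratory analyses over feature tables: PCA, coefficient-of-variation
# stability across years, Ward clustering of cultivar mean phenotypes, and
# violin-plot summaries.

#' Principal component analysis of a feature table
#'
#' Features are z-standardized first (the descriptor catalog mixes mm, mm^2
#' and unitless quantities, so raw-covariance PCA would be dominated by the
#' largest units); constant features are dropped with a warning.
#'
#' @param table an `olive_features` table (or any data frame with descriptor
#'   columns and `cultivar`/`year` metadata).
#' @param n_components number of components to keep (default all).
#' @return object of class `olive_pca`: `scores` (data frame with cultivar
#'   and year), `loadings` (features x components, unit-norm columns),
#'   `explained_variance_ratio`.
#' @export
olive_pca <- function(table, n_components = NULL) {
  X <- feature_matrix(table)
  if (nrow(X) < 3) stop("need >= 3 instances")
  sds <- apply(X, 2, stats::sd)
  if (any(sds < 1e-12)) {
    warning("dropping constant feature(s): ",
            paste(colnames(X)[sds < 1e-12], collapse = ", "))
    X <- X[, sds >= 1e-12, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  k <- min(n_components %||% ncol(pc$x), ncol(pc$x))
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- data.frame(cultivar = table$cultivar, year = table$year,
                       pc$x[, seq_len(k), drop = FALSE])
  structure(list(scores = scores,
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 explained_variance_ratio = evr[seq_len(k)],
                 center = pc$center, scale = pc$scale),
            class = "olive_pca")
}

#' @export
print.olive_pca <- function(x, ...) {
  cat("<olive_pca>", nrow(x$loadings), "features,",
      length(x$explained_variance_ratio), "components\n")
  cat("explained variance ratio:",
      paste(sprintf("%.3f", utils::head(x$explained_variance_ratio, 5)),
            collapse = " "), "\n")
  invisible(x)
}

#' Coefficient of variation per cultivar, year and feature
#'
#' CV = sample standard deviation / |mean|, a unit-free stability measure;
#' groups with fewer than 3 rows or |mean| below 1e-12 give `NA`. Also
#' returns a per-feature stability summary (mean CV across cultivars and
#' years).
#'
#' @param table an `olive_features` table with a populated `year` column.
#' @return list of class `olive_cv`: `cv` (long data frame: cultivar, year,
#'   feature, cv, n) and `stability` (feature, mean_cv, most stable first).
#' @export
cv_by_year <- function(table) {
  feats <- attr(table, "feature_names")
  out <- list()
  small <- FALSE
  for (cv_ in unique(table$cultivar)) for (yr in unique(table$year)) {
    rows <- table$cultivar == cv_ & table$year == yr
    if (!any(rows)) next
    n <- sum(rows)
    for (ft in feats) {
      x <- table[rows, ft]
      mu <- mean(x)
      val <- if (n < 3) { small <- TRUE; NA_real_ }
             else if (abs(mu) < 1e-12) NA_real_
             else stats::sd(x) / abs(mu)
      out[[length(out) + 1L]] <- data.frame(cultivar = cv_, year = yr,
                                            feature = ft, cv = val, n = n)
    }
  }
  if (small) warning("groups with fewer than 3 rows give NA coefficients")
  long <- do.call(rbind, out)
  stab <- aggregate(cv ~ feature, long, mean, na.rm = TRUE, na.action = NULL)
  names(stab)[2] <- "mean_cv"
  stab <- stab[order(stab$mean_cv), , drop = FALSE]
  rownames(stab) <- NULL
  structure(list(cv = long, stability = stab), class = "olive_cv")
}

#' @export
print.olive_cv <- function(x, ...) {
  rng <- range(x$cv$cv, na.rm = TRUE)
  cat(sprintf("<olive_cv> %d (cultivar, year, feature) groups; CV range %.3g - %.3g\n",
              nrow(x$cv), rng[1], rng[2]))
  cat("most stable features:\n")
  print(utils::head(x$stability, 5), digits = 3)
  invisible(x)
}

#' Ward dendrogram of cultivar mean phenotypes
#'
#' Builds one mean vector per cultivar over the concatenated z-standardized
#' descriptors of all three organs, clusters them with Ward linkage on
#' Euclidean distances, and exports the tree in Newick format.
#'
#' @param fruit,leaf,endocarp `olive_features` tables; cultivars missing from
#'   any table are excluded with a warning.
#' @return object of class `olive_dendrogram`: `hclust`, `phylo` (ape),
#'   `newick` (character), `cultivars`.
#' @export
cultivar_dendrogram <- function(fruit, leaf, endocarp) {
  tables <- list(fruit = fruit, leaf = leaf, endocarp = endocarp)
  cvs <- Reduce(intersect, lapply(tables, function(t) unique(t$cultivar)))
  all_cvs <- unique(unlist(lapply(tables, function(t) unique(t$cultivar))))
  if (length(setdiff(all_cvs, cvs)))
    warning("cultivars missing an organ excluded: ",
            paste(setdiff(all_cvs, cvs), collapse = ", "))
  if (length(cvs) < 3) stop("need >= 3 cultivars present in all organ tables")
  blocks <- lapply(names(tables), function(org) {
    tab <- tables[[org]]
    X <- feature_matrix(tab)
    sds <- apply(X, 2, stats::sd); sds[sds < 1e-12] <- 1
    Z <- sweep(sweep(X, 2, colMeans(X)), 2, sds, "/")
    M <- do.call(rbind, lapply(cvs, function(cv_)
      colMeans(Z[tab$cultivar == cv_, , drop = FALSE])))
    colnames(M) <- paste(org, colnames(X), sep = ".")
    M
  })
  M <- do.call(cbind, blocks)
  rownames(M) <- cvs
  hc <- stats::hclust(stats::dist(M), method = "ward.D2")
  phy <- ape::as.phylo(hc)
  structure(list(hclust = hc, phylo = phy,
                 newick = ape::write.tree(phy), cultivars = cvs),
            class = "olive_dendrogram")
}

#' @export
print.olive_dendrogram <- function(x, ...) {
  cat("<olive_dendrogram>", length(x$cultivars), "cultivars, Ward/Euclidean\n")
  cat(substr(x$newick, 1, 70), "...\n")
  invisible(x)
}

#' Violin-plot summary of one feature
#'
#' Gaussian kernel density (Silverman's bandwidth) on a 128-point grid with
#' outliers beyond 1.5 x IQR removed before density estimation, plus median
#' and quartiles, per group (cultivar, optionally split by year). Groups with
#' fewer than 5 points report quartiles only.
#'
#' @param table an `olive_features` table.
#' @param feature descriptor name.
#' @param by_year split each cultivar by year (the two sides of a split
#'   violin).
#' @return list of class `olive_violin`: `density` (long data frame: group,
#'   cultivar, year, x, density) and `summary` (group, n, median, q1, q3,
#'   n_outliers).
#' @export
violin_summary <- function(table, feature, by_year = TRUE) {
  if (!feature %in% attr(table, "feature_names"))
    stop("unknown feature ", feature)
  groups <- if (by_year) split(seq_len(nrow(table)),
                               list(table$cultivar, table$year), drop = TRUE)
            else split(seq_len(nrow(table)), table$cultivar)
  dens <- list(); summ <- list()
  for (g in names(groups)) {
    x <- table[groups[[g]], feature]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    keep <- x >= q[1] - 1.5 * iqr & x <= q[3] + 1.5 * iqr
    summ[[g]] <- data.frame(group = g, n = length(x), median = q[2],
                            q1 = q[1], q3 = q[3], n_outliers = sum(!keep))
    if (length(x) >= 5 && stats::sd(x[keep]) > 1e-12) {
      d <- stats::density(x[keep], bw = "nrd0", n = 128)
      cv_yr <- strsplit(g, ".", fixed = TRUE)[[1]]
      dens[[g]] <- data.frame(group = g, cultivar = cv_yr[1],
                              year = if (by_year) cv_yr[2] else NA,
                              x = d$x, density = d$y)
    }
  }
  structure(list(density = if (length(dens)) do.call(rbind, c(dens, list(make.row.names = FALSE))) else NULL,
                 summary = do.call(rbind, c(summ, list(make.row.names = FALSE))),
                 feature = feature),
            class = "olive_violin")
}

#' @export
print.olive_violin <- function(x, ...) {
  cat("<olive_violin>", x$feature, "-", nrow(x$summary), "groups\n")
  print(utils::head(x$summary, 5), digits = 3)
  invisible(x)
}
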