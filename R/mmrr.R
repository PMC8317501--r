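# Isolation by distance vs isolation by environment: great-circle
# geographic distances, environment PC1 distances, Bray-Curtis community
# dissimilarity, and multiple matrix regression with randomization (MMRR),
# with significance from joint row/column permutation of the response.

EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance matrix between sites (haversine)
#'
#' @param geo Tibble with columns site, lat, lon (decimal degrees).
#' @return Symmetric matrix of distances in kilometres.
#' @examples
#' great_circle_km(tibble::tibble(site = c("a", "b"),
#'                                lat = c(0, 0), lon = c(0, 90)))
#' @export
great_circle_km <- function(geo) {
  if (!all(c("site", "lat", "lon") %in% names(geo))) {
    abort("`geo` needs columns site, lat, lon")
  }
  if (anyDuplicated(geo$site)) abort("duplicate site ids")
  if (any(abs(geo$lat) > 90) || any(abs(geo$lon) > 180)) {
    abort("coordinates out of range")
  }
  lat <- geo$lat * pi / 180
  lon <- geo$lon * pi / 180
  n <- nrow(geo)
  d <- matrix(0, n, n, dimnames = list(geo$site, geo$site))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      h <- sin((lat[j] - lat[i]) / 2)^2 +
        cos(lat[i]) * cos(lat[j]) * sin((lon[j] - lon[i]) / 2)^2
      d[i, j] <- d[j, i] <- 2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(h)))
    }
  }
  d
}

#' Row-wise Hellinger transformation
#'
#' Each entry becomes the square root of its share of the row total, so
#' transformed rows have unit sum of squares.
#'
#' @param m Non-negative numeric matrix with no all-zero row.
#' @return Matrix of the same shape.
#' @export
hellinger_rows <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) abort("entries must be non-negative")
  rs <- rowSums(m)
  if (any(rs == 0)) abort("all-zero row: Hellinger transform undefined")
  sqrt(sweep(m, 1L, rs, "/"))
}

#' Environmental distance from the first principal component
#'
#' Column-standardizes the site-by-variable table, runs a PCA, and returns
#' pairwise absolute differences of PC1 scores (Euclidean distance in one
#' dimension). Constant variables are dropped with a warning. The matrix
#' carries the PC1 variance explained as attribute
#' `"variance_explained"`.
#'
#' @param env Tibble: first column site ids, remaining columns numeric
#'   environmental variables.
#' @return Distance matrix with attributes `variance_explained` and
#'   `scores`.
#' @export
env_pc1_distance <- function(env) {
  sites <- as.character(env[[1L]])
  x <- as.matrix(env[, -1L, drop = FALSE])
  if (nrow(x) < 2L) abort("need at least two sites")
  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) {
    warn(paste0("constant variable(s) dropped: ",
                paste(colnames(x)[sds == 0], collapse = ", ")))
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (ncol(x) == 0L) abort("no variable with nonzero variance")
  z <- scale(x)
  p <- prcomp(z, center = FALSE, scale. = FALSE)
  scores <- p$x[, 1L]
  ve <- p$sdev[1L]^2 / sum(p$sdev^2)
  d <- abs(outer(scores, scores, "-"))
  dimnames(d) <- list(sites, sites)
  attr(d, "variance_explained") <- ve
  attr(d, "scores") <- setNames(scores, sites)
  d
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{BC(x, y) = \sum |x - y| / \sum (x + y)} over sample rows, via
#' [vegan::vegdist()].
#'
#' @param comm Community matrix (samples x oligotypes) or tibble with a
#'   leading sample-id column.
#' @return Symmetric dissimilarity matrix in `[0, 1]`.
#' @export
bray_curtis <- function(comm) {
  m <- validate_community(comm)
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' Expand a site-level distance matrix to sample pairs
#'
#' Entry (i, j) of the result is the site distance between the sites of
#' samples i and j; within-site pairs are 0 (the site diagonal).
#'
#' @param site_dist Site-level distance matrix with site dimnames.
#' @param sample_sites Named character vector: sample id -> site id.
#' @return Sample-level matrix.
#' @export
expand_site_matrix <- function(site_dist, sample_sites) {
  miss <- setdiff(unique(sample_sites), rownames(site_dist))
  if (length(miss)) {
    abort(paste0("sites missing from the matrix: ",
                 paste(miss, collapse = ", ")))
  }
  idx <- match(sample_sites, rownames(site_dist))
  out <- site_dist[idx, idx]
  dimnames(out) <- list(names(sample_sites), names(sample_sites))
  out
}

unfold_lower <- function(m) m[lower.tri(m)]

#' Multiple matrix regression with randomization (MMRR)
#'
#' Vectorizes the lower triangles of the response and predictor distance
#' matrices, fits ordinary least squares with intercept, and assesses
#' significance by jointly permuting rows and columns of the response and
#' refitting: per-coefficient \eqn{p = \Pr(|t_{null}| \ge |t_{obs}|)} and
#' model-level \eqn{p = \Pr(F_{null} \ge F_{obs})}, both with the add-one
#' estimator. Predictors are used on their supplied scale.
#'
#' @param Y Response distance matrix.
#' @param X Named list of predictor distance matrices (same dimension and
#'   sample order as `Y`).
#' @param perms Number of permutations (default 9999, giving p-values at
#'   1/10000 resolution).
#' @param seed Optional seed.
#' @return An `mmrr_fit` with [tidy()] (per-predictor coefficient, t
#'   statistic, permutation p) and [glance()] (R-squared, F, permutation
#'   p) methods.
#' @export
mmrr <- function(Y, X, perms = 9999L, seed = NULL) {
  Y <- as.matrix(Y)
  if (!is.list(X)) X <- list(X)
  if (is.null(names(X)) || any(names(X) == "")) {
    names(X) <- paste0("X", seq_along(X))
  }
  n <- nrow(Y)
  for (x in X) {
    if (!all(dim(x) == c(n, n))) abort("matrix dimensions differ")
  }
  if (perms < 1L) abort("perms must be >= 1")
  xv <- vapply(X, unfold_lower, numeric(n * (n - 1) / 2))
  # collinearity guard, naming the offending pair
  if (ncol(xv) > 1L) {
    cc <- cor(xv)
    bad <- which(abs(cc) > 1 - 1e-10 & upper.tri(cc), arr.ind = TRUE)
    if (nrow(bad)) {
      abort(paste0("collinear predictors: ",
                   colnames(cc)[bad[1L, 1L]], " and ",
                   colnames(cc)[bad[1L, 2L]]))
    }
  }
  design <- cbind(`(Intercept)` = 1, xv)
  xtx <- crossprod(design)
  if (qr(xtx)$rank < ncol(design)) abort("singular design matrix")
  xtx_inv <- solve(xtx)
  fit_stats <- function(y) {
    beta <- drop(xtx_inv %*% crossprod(design, y))
    res <- y - drop(design %*% beta)
    df_res <- length(y) - ncol(design)
    sigma2 <- sum(res^2) / df_res
    se <- sqrt(diag(xtx_inv) * sigma2)
    tstat <- beta / se
    ssr <- sum((drop(design %*% beta) - mean(y))^2)
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst > 0) 1 - sum(res^2) / sst else NA_real_
    f <- (ssr / (ncol(design) - 1)) / sigma2
    list(beta = beta, t = tstat, r2 = r2, f = f)
  }
  yv <- unfold_lower(Y)
  obs <- fit_stats(yv)
  with_seed(seed, {
    t_hits <- numeric(ncol(design))
    f_hits <- 0
    for (r in seq_len(perms)) {
      p <- sample.int(n)
      yp <- unfold_lower(Y[p, p])
      nul <- fit_stats(yp)
      t_hits <- t_hits + (abs(nul$t) >= abs(obs$t) - 1e-12)
      f_hits <- f_hits + (nul$f >= obs$f - 1e-12)
    }
    coef_tbl <- tibble(
      term = colnames(design),
      estimate = as.numeric(obs$beta),
      t_statistic = as.numeric(obs$t),
      p_value = (t_hits + 1) / (perms + 1)
    )
    structure(
      list(coefficients = coef_tbl,
           r_squared = obs$r2,
           f_statistic = obs$f,
           f_p_value = (f_hits + 1) / (perms + 1),
           n = n, n_perm = as.integer(perms)),
      class = "mmrr_fit")
  })
}

#' @export
print.mmrr_fit <- function(x, ...) {
  cat("<mmrr_fit> n =", x$n, " R2 =", format(x$r_squared, digits = 4),
      " F =", format(x$f_statistic, digits = 4),
      " (p =", format(x$f_p_value, digits = 4), ")\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.mmrr_fit <- function(x, ...) x$coefficients

#' @export
glance.mmrr_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, statistic = x$f_statistic,
         p.value = x$f_p_value, n = x$n, n_perm = x$n_perm)
}
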