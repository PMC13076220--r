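# Core niche geometry: centroids, covariance ellipses, SEA/SEAc,
# isotope standard deviations, and centroid-distance dissimilarity.

.as_points <- function(points) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2)
    stop("points must have two columns (d13C, d15N)", call. = FALSE)
  if (!is.numeric(pts) || any(!is.finite(pts)))
    stop("all points must be finite numeric", call. = FALSE)
  pts
}

#' Bivariate centroid and sample covariance of an isotope point cloud
#'
#' @param points A two-column matrix or data frame of (d13C, d15N) values in
#'   per mil; at least two rows.
#' @return A list with `centroid` (length-2 mean vector), `cov` (2x2 sample
#'   covariance, n-1 denominator) and `n`.
#' @export
#' @examples
#' fit_centroid_covariance(cbind(c(0, 2, 0, 2), c(0, 0, 2, 2)))
fit_centroid_covariance <- function(points) {
  pts <- .as_points(points)
  if (nrow(pts) < 2)
    stop("at least 2 points are needed to fit a covariance", call. = FALSE)
  S <- cov(pts)
  S <- (S + t(S)) / 2  # enforce exact symmetry against rounding
  list(centroid = colMeans(pts), cov = unname(S), n = nrow(pts))
}

.check_covariance <- function(sigma, tol = 1e-10) {
  if (!is.matrix(sigma) || any(dim(sigma) != 2) || !is.numeric(sigma))
    stop("covariance must be a numeric 2x2 matrix", call. = FALSE)
  if (any(!is.finite(sigma)))
    stop("covariance entries must be finite", call. = FALSE)
  scale <- max(abs(sigma), 1)
  if (abs(sigma[1, 2] - sigma[2, 1]) > tol * scale)
    stop("covariance must be symmetric", call. = FALSE)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * scale)
    stop("covariance must be positive semi-definite", call. = FALSE)
  invisible(sigma)
}

#' Standard ellipse area (SEA) of a bivariate covariance
#'
#' The standard ellipse is the 1-standard-deviation ellipse of a bivariate
#' point cloud: its semi-axes are the square roots of the covariance
#' eigenvalues, so its area is \eqn{\pi\sqrt{\det\Sigma}} (per mil squared).
#' For a bivariate normal it contains a fraction \eqn{1 - e^{-1/2} \approx
#' 0.39} of the distribution. Rank-deficient covariances (collinear data)
#' give area 0.
#'
#' @param sigma Symmetric positive semi-definite 2x2 covariance matrix.
#' @return Area in per mil squared.
#' @export
#' @examples
#' standard_ellipse_area(diag(2))        # pi
#' standard_ellipse_area(diag(c(4, 1)))  # 2 pi
standard_ellipse_area <- function(sigma) {
  .check_covariance(sigma)
  d <- sigma[1, 1] * sigma[2, 2] - sigma[1, 2] * sigma[2, 1]
  pi * sqrt(max(d, 0))
}

#' Small-sample corrected standard ellipse area (SEAc)
#'
#' SEA systematically underestimates niche area at small n; the corrected
#' area SEAc = SEA (n - 1) / (n - 2) removes most of that bias and is the
#' niche-breadth statistic used throughout this package. Undefined for
#' n <= 2 (an error, never a silent fallback to SEA).
#'
#' @param sea Standard ellipse area, per mil squared.
#' @param n Sample size, at least 3.
#' @return Corrected area, per mil squared; always >= `sea`.
#' @export
#' @examples
#' seac(3, 5)  # 4
seac <- function(sea, n) {
  if (any(!is.finite(sea)) || any(sea < 0))
    stop("sea must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(n)) || any(n != round(n)) || any(n <= 2))
    stop("the SEAc correction requires an integer sample size n >= 3",
         call. = FALSE)
  sea * (n - 1) / (n - 2)
}

#' Fit the full standard ellipse for one group of points
#'
#' Convenience wrapper combining [fit_centroid_covariance()],
#' [standard_ellipse_area()] and [seac()].
#'
#' @inheritParams fit_centroid_covariance
#' @return A list of class `ellipse_fit`: `centroid`, `cov`, `n`, `sea`,
#'   `seac` (`seac` is `NA` when n < 3).
#' @export
fit_ellipse <- function(points) {
  fit <- fit_centroid_covariance(points)
  fit$sea <- standard_ellipse_area(fit$cov)
  fit$seac <- if (fit$n >= 3) seac(fit$sea, fit$n) else NA_real_
  class(fit) <- "ellipse_fit"
  fit
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("<ellipse_fit> n = %d, centroid = (%.3f, %.3f)\n",
              x$n, x$centroid[1], x$centroid[2]))
  cat(sprintf("  SEA = %.4f, SEAc = %.4f (per mil squared)\n", x$sea, x$seac))
  invisible(x)
}

#' Coordinate-wise isotope standard deviations
#'
#' Sample standard deviations (n-1 denominator) of d13C and d15N within a
#' group; indicators of variation in basal resource use and in trophic
#' position, respectively.
#'
#' @inheritParams fit_centroid_covariance
#' @return Named numeric vector `c(sd13C, sd15N)` in per mil.
#' @export
isotope_sds <- function(points) {
  pts <- .as_points(points)
  if (nrow(pts) < 2)
    stop("at least 2 points are needed for a standard deviation",
         call. = FALSE)
  c(sd13C = sd(pts[, 1]), sd15N = sd(pts[, 2]))
}

#' Filter grouped records by minimum sample size
#'
#' Ellipses are only computed for groups with at least `threshold` samples
#' per site, limiting small-sample bias. The threshold must be at least 3
#' (below that SEAc is undefined); the default is 5.
#'
#' @param records A record tibble (e.g. from [read_records()]).
#' @param group_cols Character vector of columns defining a group
#'   (e.g. `c("site_id", "functional_group")`).
#' @param threshold Minimum samples per group; >= 3.
#' @return A list with `retained` (records of qualifying groups) and
#'   `excluded` (one row per dropped group with its `n`).
#' @export
min_sample_filter <- function(records,
                              group_cols = c("site_id", "functional_group"),
                              threshold = 5) {
  if (!is.numeric(threshold) || threshold < 3)
    stop("threshold must be >= 3 (SEAc is undefined below 3 samples)",
         call. = FALSE)
  stopifnot(all(group_cols %in% names(records)))
  counts <- dplyr::count(records, dplyr::across(dplyr::all_of(group_cols)),
                         name = "n")
  ok <- counts[counts$n >= threshold, group_cols, drop = FALSE]
  list(retained = dplyr::semi_join(records, ok, by = group_cols),
       excluded = counts[counts$n < threshold, , drop = FALSE])
}

#' Trophic dissimilarity: mean pairwise centroid distance
#'
#' The niche-partitioning indicator: the arithmetic mean of Euclidean
#' distances between taxon centroids in the d13C-d15N plane, over all
#' unordered pairs, in raw per mil units. With fewer than two centroids the
#' statistic is undefined and `NA` is returned (never 0).
#'
#' @param centroids Two-column matrix of taxon centroids (d13C, d15N).
#' @return Mean pairwise distance in per mil, or `NA_real_`.
#' @export
#' @examples
#' trophic_dissimilarity(rbind(c(0, 0), c(3, 4)))  # 5
trophic_dissimilarity <- function(centroids) {
  pts <- .as_points(centroids)
  if (nrow(pts) < 2) return(NA_real_)
  mean(dist(pts))
}
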