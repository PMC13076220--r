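# Permutation Moran's I on site-level residuals with k-nearest-neighbour
# weights from great-circle distances.

.knn_weights <- function(lon, lat, k) {
  n <- length(lon)
  D <- geosphere::distm(cbind(lon, lat))  # great-circle metres
  nb <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    ord <- order(D[i, ], seq_len(n))  # distance, then index for ties
    nb[i, ] <- setdiff(ord, i)[seq_len(k)]
  }
  W <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                            j = as.vector(t(nb)),
                            x = 1 / k, dims = c(n, n))
  W
}

#' Moran's I with k-nearest-neighbour weights and a permutation test
#'
#' Computes Moran's I for site-level values (typically model residuals)
#' using row-standardized k-nearest-neighbour spatial weights built from
#' great-circle distances between site coordinates:
#' \eqn{I = \frac{n}{\sum_{ij} w_{ij}} \frac{\sum_{ij} w_{ij} z_i z_j}
#' {\sum_i z_i^2}} with \eqn{z_i} the centred values. Significance is
#' assessed by a two-sided permutation test: values are randomly permuted
#' across sites `nperm` times and the p-value is the fraction of permuted
#' \eqn{|I - E[I]|} at least as large as observed, with
#' \eqn{E[I] = -1/(n-1)}.
#'
#' @param values Numeric vector of site-level values; must not be constant.
#' @param lon,lat Site coordinates in decimal degrees.
#' @param k Number of nearest neighbours (default 5).
#' @param nperm Number of permutations (default 999).
#' @param seed Integer seed for the permutation draw (required, for
#'   reproducibility).
#' @return A list of class `moran_test`: `I`, `expected` (-1/(n-1)),
#'   `p_value`, `k`, `nperm`, `n`.
#' @export
#' @examples
#' set.seed(7)
#' moran_i(rnorm(30), runif(30, -10, 10), runif(30, 40, 55), seed = 1)
moran_i <- function(values, lon, lat, k = 5, nperm = 999, seed) {
  if (missing(seed)) stop("a permutation seed is required", call. = FALSE)
  n <- length(values)
  stopifnot(length(lon) == n, length(lat) == n)
  if (any(!is.finite(values)) || any(!is.finite(lon)) || any(!is.finite(lat)))
    stop("values and coordinates must be finite", call. = FALSE)
  if (anyDuplicated(cbind(lon, lat)))
    stop("site coordinates must be distinct", call. = FALSE)
  if (n < k + 2)
    stop("need at least k + 2 sites", call. = FALSE)
  if (sd(values) == 0)
    stop("Moran's I is undefined for constant values", call. = FALSE)

  W <- .knn_weights(lon, lat, k)
  z <- values - mean(values)
  denom <- sum(z^2)
  s0 <- sum(W)  # equals n for row-standardized weights
  I_obs <- (n / s0) * sum(z * as.vector(W %*% z)) / denom

  set.seed(seed)
  Z <- vapply(seq_len(nperm), function(b) z[sample.int(n)], numeric(n))
  I_perm <- (n / s0) * colSums(Z * as.matrix(W %*% Z)) / denom
  e_i <- -1 / (n - 1)
  p <- (1 + sum(abs(I_perm - e_i) >= abs(I_obs - e_i))) / (nperm + 1)

  structure(list(I = I_obs, expected = e_i, p_value = p, k = k,
                 nperm = nperm, n = n), class = "moran_test")
}

#' @export
print.moran_test <- function(x, ...) {
  cat(sprintf(
    "Moran's I = %.4f (expected %.4f), k = %d, n = %d\npermutation p = %.4f (%d permutations)\n",
    x$I, x$expected, x$k, x$n, x$p_value, x$nperm))
  invisible(x)
}
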