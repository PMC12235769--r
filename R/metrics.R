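#' Mean squared error
#'
#' @param y,yhat numeric vectors of equal length (at least 1).
#' @return mean of squared residuals.
#' @export
mse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (!length(y)) stop("empty input")
  mean((y - yhat)^2)
}

#' Pearson correlation between observations and predictions
#'
#' Standard product-moment correlation. A constant input leaves the
#' correlation undefined; it is reported as `NA` (missing), never as 0.
#'
#' @param y,yhat numeric vectors of equal length (at least 2).
#' @return correlation in `[-1, 1]`, or `NA` if either input is constant.
#' @export
pearson_r <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (length(y) < 2L) stop("need at least two observations")
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0) return(NA_real_)
  stats::cor(y, yhat)
}

#' Distance correlation
#'
#' Sample distance correlation (the classical biased estimator): pairwise
#' Euclidean distance matrices of the two samples are double-centered, the
#' distance covariance is the mean of their elementwise product, and dCor
#' is the distance covariance normalized by the square root of the product
#' of the two distance variances. dCor lies in `[0, 1]`, is zero for the
#' population version exactly under independence, and detects non-linear as
#' well as linear dependence, which makes it a useful complement to
#' Pearson's r for genomic prediction. It is invariant to translation,
#' orthogonal transformation and non-zero rescaling of either argument.
#'
#' Arguments may be vectors or matrices (rows = observations); the
#' definition is dimension-agnostic. If either sample has zero distance
#' variance (a constant sample), dCor is 0 by convention.
#'
#' @param x,y numeric vectors or matrices with the same number of
#'   observations (at least 2).
#' @return scalar in `[0, 1]`.
#' @examples
#' set.seed(1)
#' u <- rnorm(100)
#' dcor(u, u^2)        # strong non-linear dependence
#' pearson_r(u, u^2)   # near zero
#' @export
dcor <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  if (nrow(y) != n) stop("x and y must have the same number of observations")
  if (n < 2L) stop("need at least two observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs contain non-finite values")
  A <- dcenter(as.matrix(stats::dist(x)))
  B <- dcenter(as.matrix(stats::dist(y)))
  dcov2 <- mean(A * B)
  dvarx <- mean(A * A)
  dvary <- mean(B * B)
  if (dvarx <= 0 || dvary <= 0) return(0)
  v <- dcov2 / sqrt(dvarx * dvary)
  sqrt(max(v, 0))
}

# double-center a distance matrix: d_ij - rowmean_i - colmean_j + grandmean
dcenter <- function(d) {
  rm_ <- rowMeans(d)
  gm <- mean(d)
  d - outer(rm_, rep(1, ncol(d))) - outer(rep(1, nrow(d)), colMeans(d)) + gm
}

# per-trait metric row used by cross-validation
metric_row <- function(y, yhat) {
  c(mse = mse(y, yhat),
    pearson_r = pearson_r(y, yhat),
    dcor = dcor(y, yhat))
}
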