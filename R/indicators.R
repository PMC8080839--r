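#' Lag-1 autocorrelation
#'
#' `sum((x_t - m)(x_{t+1} - m)) / sum((x_t - m)^2)` with the global mean `m`.
#'
#' @param x Numeric vector, length >= 3, non-constant.
#' @return Value in `[-1, 1]`.
#' @examples
#' lag1_autocorrelation(c(1, -1, 1, -1))  # -0.75
#' @export
lag1_autocorrelation <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3) stop_parameter("need at least 3 observations")
  xc <- x - mean(x)
  den <- sum(xc^2)
  if (den == 0)
    stop_degenerate("lag-1 autocorrelation is undefined for a constant series")
  sum(xc[-n] * xc[-1]) / den
}

#' Sample covariance matrix of a time-series matrix
#'
#' Column means removed, divisor `T - 1`.
#'
#' @param X An [mvts()] or numeric matrix.
#' @export
covariance_matrix <- function(X) {
  X <- ts_values(X)
  if (nrow(X) < 2) stop_parameter("need at least 2 rows")
  stats::cov(X)
}

ts_values <- function(X) {
  if (inherits(X, "mvts")) X$values else as.matrix(X)
}

#' Whitening (standardize-decorrelate-standardize) transform
#'
#' Returns `Y = (X - mean) %*% W` with `cov(Y)` equal to the identity, using
#' the eigendecomposition of the sample covariance
#' (`W = V diag(1/sqrt(d)) `). If the covariance is rank deficient the data
#' are reduced to the non-degenerate subspace with a warning.
#'
#' @param X An [mvts()] or numeric matrix.
#' @param tol Relative eigenvalue tolerance declaring a null direction.
#' @return List with `Y` (whitened matrix) and `transform` (`N x k` matrix W).
#' @export
whiten <- function(X, tol = 1e-10) {
  X <- ts_values(X)
  C <- stats::cov(X)
  e <- eigen(C, symmetric = TRUE)
  keep <- e$values > tol * max(e$values, 0)
  if (!any(keep))
    stop_degenerate("covariance is zero; cannot whiten")
  if (!all(keep)) {
    null_dirs <- paste(which(!keep), collapse = ", ")
    warning("rank-deficient covariance; dropping null direction(s) ",
            null_dirs)
  }
  W <- e$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e$values[keep]), sum(keep))
  Y <- sweep(X, 2, colMeans(X)) %*% W
  list(Y = Y, transform = W)
}

#' Min/max autocorrelation factor (MAF) decomposition
#'
#' Whitens the data, then eigendecomposes the covariance of the first
#' difference of the whitened series. Small eigenvalues correspond to slow
#' (high-autocorrelation) directions: for a stationary series the difference
#' variance of a unit-variance projection is `2 * (1 - lag-1 AC)`. The first
#' MAF (first column of `weights`, mapped back to the original variable
#' space and scaled to unit norm) is the most autocorrelated linear
#' combination. Identical, up to numerical error, to the generalized
#' eigenproblem `cov(diff(X)) v = lambda cov(X) v`.
#'
#' @param X An [mvts()] or numeric matrix with at least 3 rows.
#' @return List of class `maf_decomposition` with `eigenvalues` (ascending)
#'   and `weights` (columns = MAF directions in original variable space,
#'   first = slowest, unit norm).
#' @export
maf_decomposition <- function(X) {
  X <- ts_values(X)
  if (nrow(X) < 3) stop_parameter("need at least 3 rows")
  w <- whiten(X)
  D <- diff(w$Y)
  e <- eigen(stats::cov(D), symmetric = TRUE)
  ord <- order(e$values)   # ascending: slowest direction first
  vals <- pmax(e$values[ord], 0)
  dirs <- w$transform %*% e$vectors[, ord, drop = FALSE]
  dirs <- sweep(dirs, 2, sqrt(colSums(dirs^2)), "/")
  structure(list(eigenvalues = vals, weights = dirs),
            class = "maf_decomposition")
}

# canonical indicator catalogue ----------------------------------------------

.indicator_orientation <- c(
  degenerate_fingerprinting = "increases_toward_transition",
  maf_autocorrelation       = "increases_toward_transition",
  maf_eigenvalue            = "decreases_toward_transition",
  mutual_information        = "increases_toward_transition",
  avg_autocorrelation       = "increases_toward_transition",
  node_max_autocorrelation  = "increases_toward_transition",
  maf_variance              = "increases_toward_transition",
  node_max_variance         = "increases_toward_transition",
  avg_variance              = "increases_toward_transition",
  pca_variance              = "increases_toward_transition",
  max_covariance            = "increases_toward_transition",
  explained_variance        = "increases_toward_transition",
  avg_cross_correlation     = "increases_toward_transition"
)

.multivariate_only <- c("degenerate_fingerprinting", "maf_autocorrelation",
                        "maf_eigenvalue", "maf_variance", "pca_variance",
                        "explained_variance", "avg_cross_correlation")

#' Names of the thirteen canonical indicators
#' @return Character vector.
#' @export
indicator_names <- function() names(.indicator_orientation)

#' Kraskov-Stoegbauer-Grassberger k-nearest-neighbour mutual information
#'
#' Estimator variant 1 under the max-norm: `psi(k) + psi(T) -
#' mean(psi(n_x + 1) + psi(n_y + 1))`, with marginal neighbour counts strictly
#' inside the k-th joint neighbour distance and no bias correction. A
#' deterministic jitter of amplitude `1e-10 * sd` (fixed sub-seed) breaks
#' exact ties; constant columns trigger a degeneracy warning.
#'
#' @param X,Y Numeric matrices with paired rows.
#' @param k Number of neighbours (default 3).
#' @param base Logarithm base of the result (default 2, i.e. bits).
#' @return Mutual information estimate.
#' @export
ksg_mutual_information <- function(X, Y, k = 3L, base = 2) {
  X <- as.matrix(ts_values(X))
  Y <- as.matrix(ts_values(Y))
  n <- nrow(X)
  if (nrow(Y) != n) stop_dimension("X and Y must have paired rows")
  if (n <= k + 1) stop_parameter("too few samples for k = ", k)
  sx <- apply(X, 2, stats::sd)
  sy <- apply(Y, 2, stats::sd)
  if (any(sx == 0) || any(sy == 0))
    warning("constant column(s) in mutual-information input; ",
            "tie-breaking jitter dominates these columns")
  jit <- function(M, s) {
    amp <- ifelse(s > 0, s, 1) * 1e-10
    M + matrix(stats::rnorm(length(M)), nrow(M)) %*% diag(amp, ncol(M))
  }
  with_private_seed(20260101L, {
    X <- jit(X, sx)
    Y <- jit(Y, sy)
  })
  ksg_mi_cpp(X, Y, as.integer(k)) / log(base)
}

#' Compute one multivariate resilience indicator
#'
#' The catalogue follows the standard multivariate early-warning battery:
#' \describe{
#'   \item{degenerate_fingerprinting}{lag-1 AC of the projection on the first
#'     principal component of the covariance PCA.}
#'   \item{maf_autocorrelation}{lag-1 AC of the projection on the first MAF.}
#'   \item{maf_eigenvalue}{smallest MAF eigenvalue (decreases toward the
#'     transition).}
#'   \item{mutual_information}{KSG mutual information between the series and
#'     its lag-1 shifted copy (bits, k = 3).}
#'   \item{avg_autocorrelation / node_max_autocorrelation}{mean / max of the
#'     per-variable lag-1 AC.}
#'   \item{maf_variance}{variance of the de-meaned data projected on the
#'     (unit-norm) first MAF direction.}
#'   \item{avg_variance / node_max_variance}{mean / max per-variable variance.}
#'   \item{pca_variance}{variance of the first-PC projection (= largest
#'     covariance eigenvalue).}
#'   \item{max_covariance}{maximum entry of the covariance matrix (diagonal
#'     included).}
#'   \item{explained_variance}{largest covariance eigenvalue over the trace.}
#'   \item{avg_cross_correlation}{mean absolute Pearson correlation over
#'     unordered variable pairs (lag 0).}
#' }
#' Constant columns contribute an autocorrelation of 0 inside the aggregate
#' indicators, with a warning.
#'
#' @param name One of [indicator_names()].
#' @param X An [mvts()] or numeric matrix.
#' @param k Neighbour count for the mutual-information indicator.
#' @return List of class `indicator_value`: `name`, `value`, `orientation`,
#'   `details`.
#' @export
compute_indicator <- function(name, X, k = 3L) {
  if (!name %in% indicator_names())
    stop_catalogue("unknown indicator '", name, "'; valid names: ",
                   paste(indicator_names(), collapse = ", "))
  V <- ts_values(X)
  N <- ncol(V)
  if (N < 2 && name %in% .multivariate_only)
    stop_parameter("indicator '", name, "' needs at least 2 variables")

  details <- NULL
  value <- switch(
    name,
    degenerate_fingerprinting = {
      e <- eigen(stats::cov(V), symmetric = TRUE)
      v1 <- e$vectors[, 1]
      details <- list(direction = v1)
      lag1_ac_safe(sweep(V, 2, colMeans(V)) %*% v1)
    },
    maf_autocorrelation = {
      m <- maf_decomposition(V)
      details <- list(direction = m$weights[, 1])
      lag1_ac_safe(sweep(V, 2, colMeans(V)) %*% m$weights[, 1])
    },
    maf_eigenvalue = {
      m <- maf_decomposition(V)
      details <- list(direction = m$weights[, 1])
      m$eigenvalues[1]
    },
    mutual_information = {
      T_ <- nrow(V)
      ksg_mutual_information(V[-T_, , drop = FALSE], V[-1, , drop = FALSE],
                             k = k)
    },
    avg_autocorrelation = mean(apply(V, 2, lag1_ac_safe)),
    node_max_autocorrelation = max(apply(V, 2, lag1_ac_safe)),
    maf_variance = {
      m <- maf_decomposition(V)
      details <- list(direction = m$weights[, 1], projection = "raw de-meaned")
      stats::var(as.vector(sweep(V, 2, colMeans(V)) %*% m$weights[, 1]))
    },
    node_max_variance = max(apply(V, 2, stats::var)),
    avg_variance = mean(apply(V, 2, stats::var)),
    pca_variance = {
      e <- eigen(stats::cov(V), symmetric = TRUE)
      details <- list(direction = e$vectors[, 1])
      e$values[1]
    },
    max_covariance = max(stats::cov(V)),
    explained_variance = {
      ev <- eigen(stats::cov(V), symmetric = TRUE, only.values = TRUE)$values
      if (sum(ev) <= 0) stop_degenerate("zero total variance")
      max(ev) / sum(ev)
    },
    avg_cross_correlation = {
      R <- suppressWarnings(stats::cor(V))
      mean(abs(R[upper.tri(R)]), na.rm = TRUE)
    }
  )
  if (!is.finite(value))
    stop_degenerate("indicator '", name, "' is not finite on this input")
  structure(list(name = name, value = as.numeric(value),
                 orientation = unname(.indicator_orientation[name]),
                 details = details),
            class = "indicator_value")
}

lag1_ac_safe <- function(x) {
  tryCatch(lag1_autocorrelation(x),
           ewsbench_degenerate_error = function(e) {
             warning("constant series inside an aggregate indicator; ",
                     "autocorrelation taken as 0")
             0
           })
}

#' @export
print.indicator_value <- function(x, ...) {
  cat(sprintf("%s = %.6g (%s)\n", x$name, x$value, x$orientation))
  invisible(x)
}

#' Compute a battery of indicators on one series
#'
#' @param X An [mvts()] or numeric matrix (or a path to a delimited file
#'   readable by [read_mvts()]).
#' @param indicators Character vector of indicator names (default: all 13).
#' @param k Neighbour count for the mutual-information indicator.
#' @return Long-format data frame with columns `indicator`, `value`,
#'   `orientation`.
#' @export
compute_indicators <- function(X, indicators = indicator_names(), k = 3L) {
  if (is.character(X) && length(X) == 1) X <- read_mvts(X)
  rows <- lapply(indicators, function(nm) {
    iv <- compute_indicator(nm, X, k = k)
    data.frame(indicator = nm, value = iv$value,
               orientation = iv$orientation, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
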