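#' Energy score of an ensemble forecast
#'
#' `ES = (1/M) sum_m ||x_m - y|| - (1/(2 M^2)) sum_m sum_m' ||x_m - x_m'||`
#' (Euclidean norms). A proper multivariate score: 0 iff every member
#' equals the observation; sensitive to calibration of the joint forecast.
#'
#' @param ensemble matrix of M ensemble members x n series.
#' @param y observed n-vector.
#' @export
energy_score <- function(ensemble, y) {
  ensemble <- as.matrix(ensemble)
  M <- nrow(ensemble)
  if (M < 2) stop("need at least 2 ensemble members")
  if (ncol(ensemble) != length(y)) stop("ensemble/observation dimension mismatch")
  d1 <- mean(sqrt(rowSums((ensemble - matrix(y, M, length(y), byrow = TRUE))^2)))
  G <- tcrossprod(ensemble)
  sq <- diag(G)
  D2 <- outer(sq, sq, "+") - 2 * G
  d2 <- mean(sqrt(pmax(D2, 0)))
  d1 - 0.5 * d2
}

#' Variogram score of an ensemble forecast
#'
#' `VS = sum_{i<j} w_ij (|y_i - y_j|^p - (1/M) sum_m |x_mi - x_mj|^p)^2`.
#' Sensitive to misrepresented between-series dependence; requires at least
#' two series.
#'
#' @param ensemble matrix of M ensemble members x n series.
#' @param y observed n-vector.
#' @param p variogram exponent (default 0.5).
#' @param w optional n x n matrix of pair weights (default all 1).
#' @export
variogram_score <- function(ensemble, y, p = 0.5, w = NULL) {
  ensemble <- as.matrix(ensemble)
  n <- length(y)
  if (n < 2) stop("variogram score undefined for a single series")
  if (nrow(ensemble) < 2) stop("need at least 2 ensemble members")
  if (ncol(ensemble) != n) stop("ensemble/observation dimension mismatch")
  if (is.null(w)) w <- matrix(1, n, n)
  s <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n) {
      vy <- abs(y[i] - y[j])^p
      vx <- mean(abs(ensemble[, i] - ensemble[, j])^p)
      s <- s + w[i, j] * (vy - vx)^2
    }
  s
}

#' Evenly weighted combination of energy and variogram scores
#'
#' @inheritParams variogram_score
#' @export
combined_score <- function(ensemble, y, p = 0.5, w = NULL) {
  0.5 * (energy_score(ensemble, y) + variogram_score(ensemble, y, p = p, w = w))
}
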