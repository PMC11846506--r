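#' Stationarity-enforcing reparameterization of a VAR(1) coefficient matrix
#'
#' Maps an unconstrained real matrix to a VAR(1) coefficient matrix with
#' spectral radius strictly below one (the order-1 case of the
#' partial-autocorrelation construction). The raw matrix R is squashed to a
#' partial-autocorrelation matrix `P = (I + R R')^{-1/2} R` whose singular
#' values all lie below one; A is then recovered so that the implied process
#' with innovation covariance `Sigma` is stationary, and the stationary
#' covariance Gamma comes out of the same construction. In one dimension the
#' map reduces to `a = r / sqrt(1 + r^2)`.
#'
#' @param raw_A unconstrained square matrix (or scalar).
#' @param Sigma positive-definite innovation covariance.
#' @return list with `A` (stationary coefficient matrix), `P` (partial
#'   autocorrelations) and `Gamma` (stationary covariance).
#' @export
map_to_stationary <- function(raw_A, Sigma) {
  raw_A <- as.matrix(raw_A)
  Sigma <- as.matrix(Sigma)
  stopifnot(nrow(raw_A) == ncol(raw_A), all(dim(Sigma) == dim(raw_A)))
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("Sigma must be positive definite")
  cpp_map_to_stationary(raw_A, Sigma)
}

#' Assemble a process covariance from standard deviations and a correlation
#'
#' @param sigma vector of positive process standard deviations.
#' @param C correlation matrix (symmetric, unit diagonal, positive definite).
#' @return `Sigma = diag(sigma) C diag(sigma)`.
#' @export
make_covariance <- function(sigma, C) {
  C <- as.matrix(C)
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  if (max(abs(diag(C) - 1)) > 1e-10) stop("C must have unit diagonal")
  if (max(abs(C - t(C))) > 1e-10) stop("C must be symmetric")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("C must be positive definite")
  diag(sigma, length(sigma)) %*% C %*% diag(sigma, length(sigma))
}

#' Stationary covariance of a VAR(1) process
#'
#' Solves the discrete Lyapunov equation `Gamma = A Gamma A' + Sigma`.
#'
#' @param A stationary coefficient matrix (spectral radius < 1).
#' @param Sigma innovation covariance.
#' @export
stationary_covariance <- function(A, Sigma) {
  A <- as.matrix(A); Sigma <- as.matrix(Sigma)
  if (spectral_radius(A) >= 1) stop("A is not stationary")
  cpp_lyapunov(A, Sigma)
}

#' @rdname stationary_covariance
#' @export
spectral_radius <- function(A) {
  max(Mod(eigen(as.matrix(A), only.values = TRUE)$values))
}

#' Simulate latent VAR(1) states around a deterministic predictor
#'
#' `z_1 ~ N(0, Gamma)` (stationary start) unless `init` is supplied;
#' `z_t = A z_{t-1} + e_t` with `e_t ~ N(0, Sigma)`; `X = mu + z`.
#'
#' @param A,Sigma VAR coefficient matrix and innovation covariance.
#' @param mu n x T predictor matrix.
#' @param init optional initial state vector `z_1`.
#' @param burn_in extra initial steps simulated and discarded.
#' @return list with `X` (n x T) and the latent deviations `z`.
#' @export
simulate_states <- function(A, Sigma, mu, init = NULL, burn_in = 0) {
  A <- as.matrix(A); Sigma <- as.matrix(Sigma)
  if (spectral_radius(A) >= 1) stop("A is not stationary")
  n <- nrow(mu); T <- ncol(mu)
  Ls <- chol_psd(Sigma)
  if (is.null(init)) {
    Gamma <- stationary_covariance(A, Sigma)
    z <- as.vector(chol_psd(Gamma) %*% rnorm(n))
  } else z <- init
  for (b in seq_len(burn_in)) z <- as.vector(A %*% z + Ls %*% rnorm(n))
  Z <- matrix(0, n, T)
  Z[, 1] <- z
  for (t in seq_len(T - 1))
    Z[, t + 1] <- as.vector(A %*% Z[, t] + Ls %*% rnorm(n))
  list(X = mu + Z, z = Z)
}

# lower-triangular factor tolerating a numerically semidefinite input
chol_psd <- function(S) {
  S <- as.matrix(S)
  if (max(abs(S)) == 0) return(S * 0)
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(S))
}

#' Draw a random correlation matrix from the LKJ distribution
#'
#' Onion-style construction through canonical partial correlations; used by
#' the synthetic-data generator.
#'
#' @param n dimension.
#' @param eta LKJ shape (eta = 1 uniform; larger concentrates near identity).
#' @export
rlkj <- function(n, eta = 2) {
  if (n == 1) return(matrix(1, 1, 1))
  P <- matrix(0, n, n)
  for (k in seq_len(n - 1))
    for (i in (k + 1):n) {
      a <- eta + (n - 1 - k) / 2
      P[k, i] <- 2 * rbeta(1, a, a) - 1
    }
  C <- diag(n)
  for (k in seq_len(n - 1))
    for (i in (k + 1):n) {
      p <- P[k, i]
      if (k > 1) for (l in (k - 1):1)
        p <- p * sqrt((1 - P[l, i]^2) * (1 - P[l, k]^2)) + P[l, i] * P[l, k]
      C[k, i] <- C[i, k] <- p
    }
  C
}
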