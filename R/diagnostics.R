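#' Rank-normalized split-Rhat
#'
#' Chains are split in half, pooled draws are replaced by the inverse-normal
#' transform of their fractional ranks, and the classic between/within
#' variance ratio is computed on the transformed draws. Values near 1
#' indicate the chains agree; > 1.05 is commonly treated as a convergence
#' failure. Constant draws return NaN with a warning.
#'
#' @param x matrix of draws (iterations x chains) or a vector from a single
#'   chain split in two.
#' @export
rank_normalized_rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 chains")
  if (nrow(x) < 4) stop("need at least 4 draws per chain")
  half <- floor(nrow(x) / 2)
  sp <- cbind(x[seq_len(half), , drop = FALSE],
              x[(nrow(x) - half + 1):nrow(x), , drop = FALSE])
  if (diff(range(sp)) == 0) {
    warning("constant draws: Rhat undefined")
    return(NaN)
  }
  zr <- matrix(qnorm((rank(sp) - 3 / 8) / (length(sp) + 1 / 4)),
               nrow(sp), ncol(sp))
  m <- ncol(zr); nn <- nrow(zr)
  means <- colMeans(zr)
  B <- nn * var(means)
  W <- mean(apply(zr, 2, var))
  if (W == 0) {
    warning("zero within-chain variance: Rhat undefined")
    return(NaN)
  }
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Bulk effective sample size of rank-normalized draws
#'
#' Multi-chain ESS via Geyer's initial monotone positive sequence on the
#' chain-averaged autocorrelations of the rank-normalized draws.
#'
#' @param x matrix of draws (iterations x chains).
#' @export
ess_bulk <- function(x) {
  x <- as.matrix(x)
  nn <- nrow(x); m <- ncol(x)
  if (diff(range(x)) == 0) return(NaN)
  z <- matrix(qnorm((rank(x) - 3 / 8) / (length(x) + 1 / 4)), nn, m)
  acov <- sapply(seq_len(m), function(j) {
    a <- acf(z[, j], lag.max = nn - 1, plot = FALSE, type = "covariance")$acf[, 1, 1]
    a
  })
  mean_var <- mean(acov[1, ]) * nn / (nn - 1)
  W <- mean(apply(z, 2, var))
  B <- if (m > 1) nn * var(colMeans(z)) else 0
  var_plus <- mean_var * (nn - 1) / nn + B / nn
  rho <- 1 - (W - rowMeans(acov)) / var_plus   # rho[1] is lag 0
  # Geyer initial positive monotone sequence on paired sums
  total <- 0
  prev_pair <- Inf
  k <- 1
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (pair <= 0) break
    pair <- min(pair, prev_pair)
    prev_pair <- pair
    total <- total + pair
    k <- k + 2
  }
  tau <- max(-1 + 2 * total, 1e-8)
  ess <- m * nn / tau
  min(ess, m * nn * log10(m * nn))
}

#' Convergence diagnostics for the reported parameters of a fit
#'
#' @param fit a `gamvar_fit`.
#' @param thin keep every `thin`-th draw.
#' @param draws optional pre-computed [extract_draws()] result, to avoid
#'   re-unpacking a large fit.
#' @return data frame with one row per reported scalar parameter: Rhat
#'   (rank-normalized split) and bulk ESS, plus divergence counts as an
#'   attribute.
#' @export
fit_diagnostics <- function(fit, thin = 1, draws = NULL) {
  ex <- if (is.null(draws)) extract_draws(fit, thin = thin) else draws
  rep <- ex$reported
  chain <- attr(rep, "chain_id")
  per_chain <- split(seq_len(nrow(rep)), chain)
  out <- data.frame(parameter = colnames(rep),
                    rhat = NA_real_, ess_bulk = NA_real_)
  for (j in seq_len(ncol(rep))) {
    m <- sapply(per_chain, function(idx) rep[idx, j])
    out$rhat[j] <- suppressWarnings(rank_normalized_rhat(m))
    out$ess_bulk[j] <- ess_bulk(m)
  }
  attr(out, "divergences") <- sum(fit$divergences)
  out
}

#' Randomized quantile residuals for observed counts
#'
#' For each posterior draw and observed cell, draws
#' `u ~ Uniform(F(y - 1; lambda), F(y; lambda))` with F the Poisson CDF at
#' that draw's rate and returns `qnorm(u)`. Under a correctly specified
#' model the residuals are standard normal white noise.
#'
#' @param fit a `gamvar_fit`.
#' @param thin keep every `thin`-th draw.
#' @param seed seed for the uniform randomization.
#' @return matrix draws x observations of residuals, `obs_index` attribute
#'   as in [log_lik_matrix()].
#' @export
randomized_quantile_residuals <- function(fit, thin = 1, seed = 1) {
  set.seed(seed)
  model <- fit$model
  O <- model$cpp_data$O == 1
  Y <- model$cpp_data$Y
  obs <- which(O, arr.ind = TRUE)
  keep <- seq(1, fit$sampling, by = thin)
  S <- length(keep) * fit$chains
  res <- matrix(NA_real_, S, nrow(obs))
  rows <- seq_len(model$T_train)
  y <- Y[obs]
  s <- 1
  for (ch in seq_len(fit$chains)) {
    for (it in keep) {
      nat <- unpack_draw(model, fit$draws[it, ch, ])
      lam <- exp((compute_mu(model, nat, rows) + nat$z)[obs])
      lo <- ppois(y - 1, lam)      # = 0 when y = 0
      hi <- ppois(y, lam)
      u <- runif(length(y), lo, hi)
      u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
      res[s, ] <- qnorm(u)
      s <- s + 1
    }
  }
  attr(res, "obs_index") <- obs
  res
}
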