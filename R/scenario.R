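#' Posterior-predictive forecast over a future horizon
#'
#' For each posterior draw, latent deviations are propagated forward from
#' the last training state with that draw's A and Sigma, the GAM mean is
#' evaluated from the (observed, hindcast-mode) future covariates, and
#' Poisson counts are emitted. Forecast variance stays bounded with horizon
#' because every stored A draw is stationary.
#'
#' @param fit a `gamvar_fit`.
#' @param horizon number of forecast steps (months).
#' @param thin keep every `thin`-th posterior draw.
#' @param seed seed for the forecast noise.
#' @return a `forecast_ensemble`: list with `counts` (draws x horizon x
#'   species), `latent` (X draws), `mu` draws and the forecast timepoints.
#' @export
forecast <- function(fit, horizon = 12, thin = 1, seed = 1) {
  model <- fit$model
  rows <- model$T_train + seq_len(horizon)
  if (max(rows) > model$T_full)
    stop(sprintf("future covariates cover only %d timepoints beyond training, need %d",
                 model$T_full - model$T_train, horizon))
  set.seed(seed)
  n <- model$n
  keep <- seq(1, fit$sampling, by = thin)
  S <- length(keep) * fit$chains
  counts <- array(NA_real_, c(S, horizon, n))
  latent <- array(NA_real_, c(S, horizon, n))
  mu_arr <- array(NA_real_, c(S, horizon, n))
  s <- 1
  for (ch in seq_len(fit$chains)) {
    for (it in keep) {
      nat <- unpack_draw(model, fit$draws[it, ch, ])
      mu_f <- compute_mu(model, nat, rows)
      Ls <- chol_psd(nat$Sigma)
      z <- nat$z[, model$T_train]
      for (h in seq_len(horizon)) {
        z <- as.vector(nat$A %*% z + Ls %*% rnorm(n))
        x <- mu_f[, h] + z
        latent[s, h, ] <- x
        mu_arr[s, h, ] <- mu_f[, h]
        counts[s, h, ] <- rpois(n, exp(pmin(x, 20)))
      }
      s <- s + 1
    }
  }
  structure(list(counts = counts, latent = latent, mu = mu_arr,
                 timepoints = rows, species = model$data$species),
            class = "forecast_ensemble")
}

#' Generalized impulse-response functions for community dynamics
#'
#' Simulates an impulse of `extra_captures` additional captures for one
#' species and tracks the expected change in the log-mean of every species
#' over the following months. Per posterior draw the impulse is mapped to
#' the latent scale through the log-ratio at that draw's baseline expected
#' captures (the exponentiated posterior median of mu over the training
#' window); contemporaneous spillover uses the covariance-conditioned
#' (generalized) convention `delta = Sigma[, i] * delta_i / Sigma[i, i]`,
#' and propagation is by powers of that draw's A matrix.
#'
#' @param fit a `gamvar_fit`.
#' @param species label of the perturbed species.
#' @param extra_captures impulse size in captures (default 3).
#' @param horizon months of propagation (default 6).
#' @param thin keep every `thin`-th posterior draw.
#' @return an `impulse_response`: array draws x (horizon + 1) x species of
#'   log-mean differences (horizon 0 is the contemporaneous response).
#' @export
impulse_response <- function(fit, species, extra_captures = 3, horizon = 6,
                             thin = 1) {
  model <- fit$model
  i <- match(species, model$data$species)
  if (is.na(i)) stop("unknown species '", species, "'")
  n <- model$n
  keep <- seq(1, fit$sampling, by = thin)
  S <- length(keep) * fit$chains
  resp <- array(0, c(S, horizon + 1, n),
                dimnames = list(NULL, NULL, model$data$species))
  rows <- seq_len(model$T_train)
  s <- 1
  for (ch in seq_len(fit$chains)) {
    for (it in keep) {
      nat <- unpack_draw(model, fit$draws[it, ch, ])
      if (extra_captures != 0) {
        mu <- compute_mu(model, nat, rows)
        lam_base <- exp(apply(mu, 1, median))
        delta_i <- log(lam_base[i] + extra_captures) - log(lam_base[i])
        delta <- nat$Sigma[, i] * delta_i / nat$Sigma[i, i]
        resp[s, 1, ] <- delta
        for (h in seq_len(horizon)) {
          delta <- as.vector(nat$A %*% delta)
          resp[s, h + 1, ] <- delta
        }
      }
      s <- s + 1
    }
  }
  structure(list(response = resp, species = species,
                 extra_captures = extra_captures, horizon = horizon),
            class = "impulse_response")
}

#' Posterior contrast of expected captures between two NDVI states
#'
#' Per draw and species, the change in expected captures
#' `Delta = exp(mu_ref + slope (high - low)) - exp(mu_ref)` when the
#' z-scored NDVI moving average moves from `low` to `high`, holding every
#' other covariate at its training mean and the dynamic deviation at zero
#' (the reference state sits at the low NDVI value).
#'
#' @param fit a `gamvar_fit` of a variant with an NDVI term.
#' @param low,high z-scored NDVI values contrasted (defaults -0.50, 0.50).
#' @param thin keep every `thin`-th posterior draw.
#' @return a `covariate_contrast`: draws matrix (draws x species) plus the
#'   per-species proportions of probability mass at or below zero vs above.
#' @export
covariate_contrast <- function(fit, low = -0.50, high = 0.50, thin = 1) {
  model <- fit$model
  if (!model$cfg$has_ndvi)
    stop("variant '", model$variant, "' has no NDVI term")
  n <- model$n
  keep <- seq(1, fit$sampling, by = thin)
  S <- length(keep) * fit$chains
  delta <- matrix(NA_real_, S, n, dimnames = list(NULL, model$data$species))
  tr <- seq_len(model$T_train)
  bg_mean <- if (!is.null(model$Bg_full))
    colMeans(model$Bg_full[tr, , drop = FALSE]) else NULL
  bd_mean <- if (!is.null(model$Bd_full))
    colMeans(model$Bd_full[tr, , drop = FALSE]) else NULL
  s <- 1
  for (ch in seq_len(fit$chains)) {
    for (it in keep) {
      nat <- unpack_draw(model, fit$draws[it, ch, ])
      mu_ref <- nat$alpha
      if (!is.null(nat$beta_global))
        mu_ref <- mu_ref + as.numeric(bg_mean %*% nat$beta_global)
      if (!is.null(nat$beta_dev))
        for (d in seq_along(model$dev_idx))
          mu_ref[model$dev_idx[d]] <- mu_ref[model$dev_idx[d]] +
            as.numeric(bd_mean %*% nat$beta_dev[, d])
      delta[s, ] <- exp(mu_ref + nat$slope * (high - low)) - exp(mu_ref)
      s <- s + 1
    }
  }
  prop_le0 <- colMeans(delta <= 0)
  structure(list(draws = delta, prop_le0 = prop_le0, prop_gt0 = 1 - prop_le0,
                 low = low, high = high),
            class = "covariate_contrast")
}

#' Conditional distributed-lag temperature functions
#'
#' Reconstructs the seasonal effect implied by the distributed-lag smooth
#' for each calendar month of a supplied year of temperatures (wrapping
#' across the year boundary): the summed tensor-basis effect at lags 0..L
#' evaluated with posterior coefficient draws. Species inside the deviation
#' subset use global + deviation coefficients; others use the global
#' function alone. Curves are scaled to unit variance for shape comparison.
#'
#' @param fit a `gamvar_fit` of a variant with the distributed-lag term.
#' @param temperature_year 12 monthly minimum temperatures (deg C, raw
#'   scale; standardized internally with the training moments).
#' @param n_functions number of simulated functions (default 1000),
#'   sampled from the posterior draws with replacement.
#' @param seed sampling seed.
#' @return array n_functions x 12 x species of scaled effect curves.
#' @export
conditional_lag_function <- function(fit, temperature_year,
                                     n_functions = 1000, seed = 1) {
  model <- fit$model
  if (is.null(model$tensor))
    stop("variant '", model$variant, "' has no distributed-lag term")
  stopifnot(length(temperature_year) == 12)
  set.seed(seed)
  mo <- attr(model$covars, "mintemp_moments")
  tz <- (temperature_year - mo["mean"]) / mo["sd"]
  max_lag <- 6
  # design row for each calendar month: sum over lags of tensor basis
  rows_un <- matrix(0, 12, ncol(model$tensor$X))
  for (m in 1:12) {
    lags <- 0:max_lag
    temps <- tz[((m - 1 - lags) %% 12) + 1]
    rows_un[m, ] <- colSums(eval_tensor(model$tensor, lags, temps))
  }
  Z <- model$constraint$Z
  Xm <- rows_un %*% Z
  ex <- extract_draws(fit)
  S <- nrow(ex$reported)
  pick <- sample.int(S, n_functions, replace = TRUE)
  n <- model$n
  out <- array(NA_real_, c(n_functions, 12, n),
               dimnames = list(NULL, month.abb, model$data$species))
  zero_var <- FALSE
  for (f in seq_len(n_functions)) {
    d <- pick[f]
    g <- if (!is.null(ex$beta_global)) as.vector(Xm %*% ex$beta_global[d, ]) else rep(0, 12)
    for (i in seq_len(n)) {
      cur <- g
      di <- match(model$data$species[i], model$dev_labels)
      if (!is.na(di) && !is.null(ex$beta_dev))
        cur <- cur + as.vector(Xm %*% ex$beta_dev[d, , di])
      s <- sd(cur)
      if (s > 0) cur <- cur / s else zero_var <- TRUE
      out[f, , i] <- cur
    }
  }
  if (zero_var)
    warning("zero-variance curve(s): scaling skipped for those draws")
  out
}
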