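#' Simulation configuration for synthetic community data
#'
#' Defaults emulate the structure of a long-running desert rodent monitoring
#' series: nine species, about 319 monthly timepoints, roughly 5% of
#' trapping sessions missing, a seasonal minimum-temperature cycle and a
#' slowly varying NDVI series with a 12-month lead-in before the counts.
#'
#' @param n_species number of species.
#' @param n_months recorded monthly timepoints (>= 24 so the 12-month moving
#'   average and 6-month lags are computable).
#' @param missing_rate proportion of whole sessions masked as missing.
#' @param seed integer seed; all simulation draws are reproducible from it.
#' @param burn_in latent-state months discarded before recording.
#' @param temp_mean,temp_amp,temp_noise monthly minimum temperature:
#'   annual-sinusoid mean level (deg C), amplitude and Gaussian noise sd.
#' @param ndvi_base,ndvi_amp,ndvi_rw_sd,ndvi_noise NDVI: base level, seasonal
#'   amplitude, random-walk innovation sd of the slow trend, and noise sd.
#' @param lead_in covariate months generated before the count window.
#' @export
sim_config <- function(n_species = 9, n_months = 319, missing_rate = 0.05,
                       seed = 1, burn_in = 24,
                       temp_mean = 5, temp_amp = 8, temp_noise = 1.5,
                       ndvi_base = 0.25, ndvi_amp = 0.08, ndvi_rw_sd = 0.01,
                       ndvi_noise = 0.02, lead_in = 12) {
  if (n_months < 24) stop("n_months must be at least 24 (12-month moving average and 6-month lags)")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate monthly covariate series
#'
#' Minimum temperature is an annual sinusoid (period 12) plus Gaussian
#' noise; NDVI is an annual sinusoid plus a slow random-walk trend and
#' noise, clipped to a plausible positive range. The table includes
#' `lead_in` months before the count window (time_index <= 0), mirroring
#' covariate collection starting one year before the counts.
#'
#' @param config a [sim_config()].
#' @return data frame with `time_index` (1..n_months for the count window,
#'   non-positive for lead-in), `date`, `mintemp`, `ndvi`.
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  M <- config$lead_in + config$n_months
  m <- seq_len(M)
  mintemp <- config$temp_mean +
    config$temp_amp * sin(2 * pi * (m - config$lead_in) / 12) +
    rnorm(M, 0, config$temp_noise)
  trend <- cumsum(rnorm(M, 0, config$ndvi_rw_sd))
  ndvi <- config$ndvi_base + config$ndvi_amp * sin(2 * pi * (m - config$lead_in) / 12 + pi / 3) +
    trend + rnorm(M, 0, config$ndvi_noise)
  ndvi <- pmin(pmax(ndvi, 0.02), 0.9)
  start <- as.Date("1996-12-01")   # first count month
  first <- seq(start, by = "-1 month", length.out = config$lead_in + 1)
  data.frame(
    time_index = m - config$lead_in,
    date = seq(first[config$lead_in + 1], by = "month", length.out = M),
    mintemp = mintemp, ndvi = ndvi
  )
}

#' Default "true" parameter set for the generative GAM-VAR model
#'
#' Draws a parameter set satisfying every invariant of the model: a positive
#' NDVI community response with species scatter, a smooth global
#' distributed-lag surface, cross-species lagged dependence with
#' off-diagonal raw entries bounded by 0.3 projected through the
#' stationarity map, positive process standard deviations, and an LKJ
#' process-error correlation matrix.
#'
#' @param n_species number of species.
#' @param seed integer seed.
#' @param k_coef number of (constrained, null-penalized) distributed-lag
#'   coefficients to draw for the global surface.
#' @export
default_true_params <- function(n_species = 9, seed = 1, k_coef = 11) {
  stopifnot(n_species >= 1)
  set.seed(seed)
  intercepts <- rnorm(n_species, log(3), 0.4)
  ndvi_slopes <- rnorm(n_species, 0.3, 0.15)
  lag_surface_coefs <- rnorm(k_coef, 0, 0.4)
  sigma <- runif(n_species, 0.3, 0.5)
  C <- rlkj(n_species, eta = 2)
  raw <- matrix(runif(n_species^2, -0.3, 0.3), n_species, n_species)
  diag(raw) <- rnorm(n_species, 0.6, 0.15)
  if (n_species > 1 && all(raw[row(raw) != col(raw)] == 0))
    raw[1, 2] <- 0.2
  Sigma <- make_covariance(sigma, C)
  mp <- map_to_stationary(raw, Sigma)
  structure(list(species_intercepts = intercepts, ndvi_slopes = ndvi_slopes,
                 lag_surface_coefs = lag_surface_coefs, A = mp$A,
                 sigma = sigma, C = C, Sigma = Sigma, raw_A = raw),
            class = "true_params")
}

#' Check the invariants of a true parameter set
#'
#' @param params a `true_params` object.
#' @return TRUE invisibly, or an error describing the violated invariant.
#' @export
check_true_params <- function(params) {
  if (spectral_radius(params$A) >= 1) stop("A is not stationary")
  if (any(params$sigma <= 0)) stop("sigma must be positive")
  C <- params$C
  if (max(abs(diag(C) - 1)) > 1e-8 || max(abs(C - t(C))) > 1e-8)
    stop("C must be a correlation matrix")
  if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("C must be positive definite")
  invisible(TRUE)
}

#' Simulate a community count series from the generative model
#'
#' Builds the GAM mean from the supplied parameters and covariates
#' (hierarchical NDVI slopes on the z-scored 12-month moving average and a
#' global distributed-lag smooth of z-scored minimum temperature), adds
#' latent VAR(1) deviations started from the stationary distribution, and
#' draws Poisson counts. Whole timepoints are then masked as missing at
#' `missing_rate` (a skipped trapping session is community-wide).
#'
#' @param params a `true_params` (see [default_true_params()]).
#' @param covars covariate table from [simulate_covariates()].
#' @param config the [sim_config()] used.
#' @return list with the `community_ts` (`data`), the latent states and the
#'   design objects used (for oracle checks).
#' @export
simulate_community <- function(params, covars, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- length(params$species_intercepts)
  T <- config$n_months
  if (sum(covars$time_index <= 0) < config$lead_in)
    stop("covariate table lacks the required lead-in window")
  if (sum(covars$time_index >= 1) < T)
    stop("covariate window shorter than the count window")
  if (spectral_radius(params$A) >= 1) stop("A is not stationary")
  set.seed(config$seed + 1L)

  pc <- prepare_covariates(covars, lead_in = config$lead_in)
  count_rows <- which(pc$time_index >= 1)[seq_len(T)]
  v <- pc$ndvi_ma12[count_rows]

  # distributed-lag design on z-scored minimum temperature
  ld <- build_lag_design(pc$mintemp_z, max_lag = 6,
                         start = count_rows[1])
  ld$value_matrix <- ld$value_matrix[seq_len(T), , drop = FALSE]
  ld$lag_matrix <- ld$lag_matrix[seq_len(T), , drop = FALSE]
  b_lag <- cubic_basis(as.vector(ld$lag_matrix), k = 4)
  b_temp <- thin_plate_basis(as.vector(ld$value_matrix), k = 3)
  tens <- tensor_product(b_lag, b_temp)
  dl <- add_nullspace_penalty(absorb_constraint(distributed_lag_design(tens, ld)))
  k_avail <- ncol(dl$X)
  beta_g <- params$lag_surface_coefs
  if (length(beta_g) < k_avail) beta_g <- c(beta_g, rep(0, k_avail - length(beta_g)))
  beta_g <- beta_g[seq_len(k_avail)]
  fg <- as.vector(dl$X %*% beta_g)

  mu <- matrix(params$species_intercepts, n, T) +
    params$ndvi_slopes %*% t(v) +
    matrix(fg, n, T, byrow = TRUE)

  st <- simulate_states(params$A, params$Sigma, mu, burn_in = config$burn_in)
  counts <- matrix(rpois(n * T, exp(pmin(st$X, 20))), n, T)
  mask <- matrix(TRUE, n, T)
  miss <- runif(T) < config$missing_rate
  mask[, miss] <- FALSE
  counts[!mask] <- NA_integer_
  start_date <- pc$date[count_rows[1]]
  data <- community_ts(counts, mask,
                       species = paste0("sp", seq_len(n)),
                       start_date = as.Date(start_date))
  list(data = data, states = st, mu = mu, design = dl, covars = pc,
       ndvi = v, lag_design = ld)
}
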