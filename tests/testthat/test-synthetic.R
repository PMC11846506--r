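test_that("covariate simulation: noiseless sinusoid, determinism, seasonality", {
  cfg <- sim_config(n_months = 36, seed = 2, temp_mean = 0, temp_amp = 1,
                    temp_noise = 0)
  cv <- simulate_covariates(cfg)
  m <- cv$time_index
  expect_equal(cv$mintemp, sin(2 * pi * m / 12), tolerance = 1e-12)

  cfg1 <- sim_config(seed = 1, n_months = 48)
  expect_identical(simulate_covariates(cfg1), simulate_covariates(cfg1))

  cfg7 <- sim_config(n_months = 120, seed = 7)
  cv7 <- simulate_covariates(cfg7)
  a <- acf(cv7$mintemp, lag.max = 12, plot = FALSE)$acf[13]
  expect_gt(a, 0.5)
  expect_error(sim_config(n_months = 20), "24")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  # NDVI stays in a plausible positive range
  expect_true(all(cv7$ndvi > 0 & cv7$ndvi < 1))
  expect_gte(sum(cv7$time_index <= 0), 12)   # one year of covariate lead-in
})

test_that("default parameter sets satisfy every invariant across seeds", {
  p1 <- default_true_params(1, seed = 4)
  expect_equal(dim(p1$A), c(1, 1))
  expect_lt(abs(p1$A[1, 1]), 1)
  expect_equal(p1$C, matrix(1, 1, 1))

  for (seed in 1:100) {
    p <- default_true_params(4, seed = seed)
    expect_silent(check_true_params(p))
  }
  # multispecies structure exists
  p <- default_true_params(5, seed = 9)
  offdiag <- p$A[row(p$A) != col(p$A)]
  expect_gt(max(abs(offdiag)), 0)
})

test_that("community simulation hits the Poisson limit when dynamics are off", {
  n_m <- 2400
  cfg <- sim_config(n_species = 2, n_months = n_m, missing_rate = 0, seed = 31)
  cv <- simulate_covariates(cfg)
  p <- default_true_params(2, seed = 31)
  p$A[] <- 0
  p$ndvi_slopes[] <- 0
  p$lag_surface_coefs[] <- 0
  p$species_intercepts[] <- log(5)
  p$sigma[] <- 1e-8
  p$C <- diag(2)
  p$Sigma <- make_covariance(p$sigma, p$C)
  sim <- simulate_community(p, cv, cfg)
  means <- rowMeans(sim$data$counts)
  expect_equal(unname(means), c(5, 5), tolerance = 0.15)
  # index of dispersion ~ 1 in the Poisson limit
  disp <- apply(sim$data$counts, 1, var) / means
  expect_true(all(abs(disp - 1) < 0.15))
  expect_true(all(sim$data$mask))   # missing_rate = 0 masks nothing
})

test_that("whole-timepoint missingness lands near the requested rate", {
  cfg <- sim_config(n_species = 3, n_months = 1000, missing_rate = 0.05,
                    seed = 13)
  cv <- simulate_covariates(cfg)
  sim <- simulate_community(default_true_params(3, seed = 13), cv, cfg)
  frac <- mean(!sim$data$mask[1, ])
  expect_gte(frac, 0.03); expect_lte(frac, 0.07)
  # sessions are masked community-wide
  expect_true(all(apply(sim$data$mask, 2, function(col) all(col) || !any(col))))
})

test_that("latent lag-1 autocovariance matches A Gamma on a long simulation", {
  cfg <- sim_config(n_species = 3, n_months = 20000, missing_rate = 0, seed = 17)
  p <- default_true_params(3, seed = 17)
  mu <- matrix(0, 3, cfg$n_months)
  set.seed(99)
  st <- simulate_states(p$A, p$Sigma, mu)
  G <- stationary_covariance(p$A, p$Sigma)
  z <- st$z
  T <- ncol(z)
  lag1 <- z[, 2:T] %*% t(z[, 1:(T - 1)]) / (T - 1)
  expect_lt(max(abs(lag1 - p$A %*% G)) / max(abs(G)), 0.1)
})

test_that("seeded community simulation is bit-reproducible", {
  cfg <- sim_config(n_species = 3, n_months = 60, seed = 23)
  cv <- simulate_covariates(cfg)
  p <- default_true_params(3, seed = 23)
  s1 <- simulate_community(p, cv, cfg)
  s2 <- simulate_community(p, cv, cfg)
  expect_identical(s1$data$counts, s2$data$counts)
  expect_identical(s1$data$mask, s2$data$mask)
})
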