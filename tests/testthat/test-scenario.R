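test_that("forecast: intercept-only noiseless model predicts exp(intercept)", {
  fx <- small_sim(n_species = 2, n_months = 60, seed = 25, missing_rate = 0)
  m <- build_model(fx$data, fx$covars, variant = "AR", train_end = 48)
  theta <- pack_theta(m, alpha = c(log(5), log(2)), raw_a = c(0, 0),
                      lsig = c(-13, -13))
  ft <- manual_fit(m, theta, n_draws = 200, chains = 2)
  fc <- forecast(ft, horizon = 12, seed = 3)
  expect_equal(dim(fc$counts), c(400, 12, 2))
  expect_equal(mean(fc$counts[, , 1]), 5, tolerance = 4 * sqrt(5 / 4800))
  expect_equal(mean(fc$counts[, , 2]), 2, tolerance = 4 * sqrt(2 / 4800))
  expect_error(forecast(ft, horizon = 20), "future covariates")
})

test_that("forecast variance stays bounded at long horizons (stationary draws)", {
  cf <- cached_fit()
  ex <- extract_draws(cf$fit)
  for (s in seq(1, nrow(ex$sigma), by = 40)) {
    A <- ex$A[s, , ]; S <- ex$sigma[s, ] * t(ex$sigma[s, ] * ex$C[s, , ])
    G <- stationary_covariance(A, S)
    V <- matrix(0, nrow(A), nrow(A))
    for (h in 1:12) V <- A %*% V %*% t(A) + S
    expect_true(all(diag(V) <= 1.2 * diag(G) + 1e-10))
  }
})

test_that("impulse responses match the A-power closed form with noise off", {
  fx <- small_sim(n_species = 2, n_months = 50, seed = 26, missing_rate = 0)
  m <- build_model(fx$data, fx$covars, variant = "AR")
  a <- 0.5
  theta <- pack_theta(m, alpha = c(log(2), log(2)),
                      raw_a = rep(a / sqrt(1 - a^2), 2), lsig = c(0, 0))
  ft <- manual_fit(m, theta)
  ir <- impulse_response(ft, "sp1", extra_captures = 3, horizon = 6)
  delta1 <- log(2 + 3) - log(2)
  for (h in 0:6) {
    expect_equal(unname(ir$response[1, h + 1, 1]), 0.5^h * delta1, tolerance = 1e-10)
    expect_equal(unname(ir$response[1, h + 1, 2]), 0, tolerance = 1e-12)  # no spillover
  }
  # zero impulse: identically zero response
  ir0 <- impulse_response(ft, "sp1", extra_captures = 0)
  expect_true(all(ir0$response == 0))
  expect_error(impulse_response(ft, "nope"), "unknown species")
})

test_that("contemporaneous spillover follows the generalized-impulse convention", {
  fx <- small_sim(n_species = 2, n_months = 50, seed = 27, missing_rate = 0)
  m <- build_model(fx$data, fx$covars, variant = "GAM-VAR")
  theta <- pack_theta(m, alpha = c(log(2), log(2)), raw_a = rep(0, 4),
                      lsig = c(log(1), log(2)), u = atanh(0.6))
  ft <- manual_fit(m, theta)
  ir <- impulse_response(ft, "sp1", extra_captures = 3, horizon = 3)
  delta1 <- log(5) - log(2)
  expect_equal(unname(ir$response[1, 1, 2]), 0.6 * delta1 * 2 / 1, tolerance = 1e-8)
  expect_equal(unname(ir$response[1, 2, 2]), 0, tolerance = 1e-12)  # decays with A = 0
})

test_that("NDVI contrast: closed form, sign proportions, variant guard", {
  fx <- small_sim(n_species = 2, n_months = 50, seed = 28, missing_rate = 0)
  m <- build_model(fx$data, fx$covars, variant = "GAM-VAR")
  theta0 <- pack_theta(m, alpha = c(0, 0), slope = c(0.4, 0))
  ft <- manual_fit(m, theta0, n_draws = 5)
  ct <- covariate_contrast(ft, low = -0.5, high = 0.5)
  expect_equal(unname(ct$draws[1, 1]), exp(0.4) - 1, tolerance = 1e-8)
  expect_equal(unname(ct$draws[1, 2]), 0, tolerance = 1e-12)
  expect_equal(unname(ct$prop_le0 + ct$prop_gt0), c(1, 1))
  expect_equal(unname(ct$prop_gt0[1]), 1)

  # slope draws N(0.4, 0.1): essentially all mass above zero;
  # slope draws N(0, 1): about half
  set.seed(2)
  nd <- 400
  draws <- array(rep(theta0, each = nd), c(nd, 1, length(theta0)))
  b <- gamvar:::layout_blocks(m)
  draws[, 1, b$slope[3]] <- rnorm(nd, 0.4, 0.1)   # eta_1 with muN=0, sigN=1
  draws[, 1, b$slope[4]] <- rnorm(nd, 0, 1)
  ft2 <- manual_fit(m, theta0, n_draws = nd, chains = 1)
  ft2$draws <- draws
  ct2 <- covariate_contrast(ft2)
  expect_gt(unname(ct2$prop_gt0[1]), 0.98)
  expect_lt(abs(ct2$prop_gt0[2] - 0.5), 0.1)

  m_ar <- build_model(fx$data, fx$covars, variant = "AR")
  ft_ar <- manual_fit(m_ar, pack_theta(m_ar, alpha = c(0, 0)))
  expect_error(covariate_contrast(ft_ar), "no NDVI term")
})

test_that("conditional lag functions: counts, pooling, zero-coefficient edge", {
  fx <- small_sim(n_species = 3, n_months = 60, seed = 29, missing_rate = 0)
  m <- build_model(fx$data, fx$covars, variant = "GAM-VAR",
                   species_subset = fx$data$species[1:2])
  b <- gamvar:::layout_blocks(m)
  temps <- 5 + 8 * sin(2 * pi * (1:12) / 12)

  # all coefficients zero: flat curves, scaling skipped with a warning
  ft0 <- manual_fit(m, pack_theta(m, alpha = rep(0, 3)), n_draws = 5)
  expect_warning(c0 <- conditional_lag_function(ft0, temps, n_functions = 20),
                 "zero-variance")
  expect_true(all(c0 == 0))

  # nonzero global, zero deviations: every species shows the global curve
  set.seed(4)
  thg <- pack_theta(m, alpha = rep(0, 3),
                    beta_global = rnorm(length(b$bg), 0, 0.5))
  ftg <- manual_fit(m, thg, n_draws = 5)
  cg <- conditional_lag_function(ftg, temps, n_functions = 50)
  expect_equal(dim(cg), c(50, 12, 3))
  expect_equal(cg[1, , 3], cg[1, , 1], tolerance = 1e-10)  # outside subset
  expect_equal(cg[1, , 2], cg[1, , 1], tolerance = 1e-10)  # zero deviation
  expect_equal(sd(cg[1, , 1]), 1, tolerance = 1e-8)        # unit variance

  # a nonzero deviation separates the subset species from the global curve
  thd <- thg
  thd[b$bd[seq_len(b$kd)]] <- rnorm(b$kd, 0, 0.5)
  ftd <- manual_fit(m, thd, n_draws = 5)
  cd <- conditional_lag_function(ftd, temps, n_functions = 10)
  expect_gt(max(abs(cd[1, , 1] - cd[1, , 3])), 1e-4)
  expect_equal(dim(conditional_lag_function(ftg, temps, n_functions = 1000))[1],
               1000)
})
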