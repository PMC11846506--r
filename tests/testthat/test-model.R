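test_that("observation term is the Poisson log-pmf and masking zeroes it", {
  fx <- small_sim(n_species = 2, n_months = 40, seed = 19, missing_rate = 0)
  m <- build_model(fx$data, fx$covars, variant = "AR")
  # craft a draw: intercepts such that X = log 2 everywhere, z = 0
  theta <- pack_theta(m, alpha = rep(log(2), 2), lsig = log(1e-6))
  lp <- log_posterior(m, theta, want_grad = FALSE)
  y <- m$cpp_data$Y
  expected <- sum(dpois(y, 2, log = TRUE))
  expect_equal(lp$parts[["obs"]], expected, tolerance = 1e-10)
  # the single-cell check: y = 3, X = log 2 -> 3 log 2 - 2 - log 6
  expect_equal(dpois(3, 2, log = TRUE), 3 * log(2) - 2 - log(6))

  # masking a whole timepoint removes its observation contribution
  cts <- fx$data$counts; msk <- fx$data$mask
  msk[, 5] <- FALSE; cts[, 5] <- NA
  d2 <- community_ts(cts, msk, fx$data$species, start_date = fx$data$dates[1])
  m2 <- build_model(d2, fx$covars, variant = "AR")
  lp2 <- log_posterior(m2, theta, want_grad = FALSE)
  expect_equal(lp2$parts[["obs"]],
               expected - sum(dpois(y[, 5], 2, log = TRUE)),
               tolerance = 1e-10)
  # but gradient still flows to the masked latent states through dynamics
  set.seed(1)
  theta_z <- pack_theta(m2, alpha = rep(log(2), 2), lsig = c(0, 0),
                        z = rnorm(2 * m2$T_train, 0, 0.3))
  g <- log_posterior(m2, theta_z, want_grad = TRUE)$grad
  b <- gamvar:::layout_blocks(m2)
  zidx <- matrix(g[b$z], 2, m2$T_train)
  expect_true(any(zidx[, 5] != 0))
})

test_that("variant structure: AR has no GAM blocks, unknown variant errors", {
  fx <- small_sim(n_species = 3, n_months = 40, seed = 20)
  m <- build_model(fx$data, fx$covars, variant = "AR")
  b <- gamvar:::layout_blocks(m)
  expect_length(b$slope, 0)
  expect_length(b$bg, 0)
  expect_length(b$bd, 0)
  expect_equal(m$layout$n_araw, 3)      # diagonal dynamics only
  expect_equal(m$layout$n_u, 0)         # C = I
  expect_error(build_model(fx$data, fx$covars, variant = "VARMA"), "unknown")

  mnp <- build_model(fx$data, fx$covars, variant = "GAM-AR-no-pooling")
  bnp <- gamvar:::layout_blocks(mnp)
  expect_length(bnp$slope, 3)           # independent slopes, no hyperpriors
  expect_length(bnp$bg, 0)              # no shared smooth
  expect_equal(bnp$ndev, 3)             # every species gets its own smooth
})

test_that("GAM-VAR and GAM-AR densities agree when the extra structure is switched off", {
  fx <- small_sim(n_species = 3, n_months = 50, seed = 21)
  mv <- build_model(fx$data, fx$covars, variant = "GAM-VAR",
                    species_subset = fx$data$species[1:2])
  ma <- build_model(fx$data, fx$covars, variant = "GAM-AR",
                    species_subset = fx$data$species[1:2])
  set.seed(3)
  n <- 3; Tt <- mv$T_train
  alpha <- rnorm(n); slope <- rnorm(n, 0, 0.2); lsig <- rnorm(n, -1, 0.1)
  raw_d <- rnorm(n, 0.4, 0.2)
  z <- rnorm(n * Tt, 0, 0.3)
  bg <- rnorm(length(gamvar:::layout_blocks(mv)$bg), 0, 0.2)
  bd <- rnorm(length(gamvar:::layout_blocks(mv)$bd), 0, 0.1)
  rawA <- matrix(0, n, n); diag(rawA) <- raw_d
  thv <- pack_theta(mv, alpha = alpha, slope = slope, beta_global = bg,
                    beta_dev = bd, raw_a = as.vector(rawA), lsig = lsig,
                    u = 0, z = z)
  tha <- pack_theta(ma, alpha = alpha, slope = slope, beta_global = bg,
                    beta_dev = bd, raw_a = raw_d, lsig = lsig, z = z)
  pv <- log_posterior(mv, thv, want_grad = FALSE)$parts
  pa <- log_posterior(ma, tha, want_grad = FALSE)$parts
  # data-dependent components coincide; only the extra priors differ
  expect_equal(pv[["obs"]], pa[["obs"]], tolerance = 1e-9)
  expect_equal(pv[["dyn"]], pa[["dyn"]], tolerance = 1e-9)
})

test_that("joint density is finite at prior-centre values for all variants", {
  fx <- small_sim(n_species = 3, n_months = 40, seed = 22)
  for (vr in c("GAM-VAR", "GAM-AR", "GAM-AR-no-pooling", "AR")) {
    m <- build_model(fx$data, fx$covars, variant = vr)
    th <- init_theta(m)
    expect_true(is.finite(log_posterior(m, th, want_grad = FALSE)$lp))
  }
})

test_that("analytic gradients match numerical differentiation", {
  fx <- small_sim(n_species = 3, n_months = 40, seed = 23)
  for (vr in c("GAM-VAR", "GAM-AR-no-pooling")) {
    m <- build_model(fx$data, fx$covars, variant = vr)
    set.seed(31)
    th <- init_theta(m) + rnorm(m$layout$dim, 0, 0.05)
    g <- log_posterior(m, th)$grad
    b <- gamvar:::layout_blocks(m)
    idx <- unique(c(b$alpha[1], head(b$slope, 2), head(b$bg, 2), head(b$bd, 2),
                    head(b$lam, 2), b$araw[seq_len(min(5, length(b$araw)))],
                    b$lsig, head(b$u, 3), b$z[c(1, 2, 50)]))
    eps <- 1e-5
    for (j in idx) {
      tp <- th; tp[j] <- tp[j] + eps
      tm <- th; tm[j] <- tm[j] - eps
      num <- (log_posterior(m, tp, FALSE)$lp - log_posterior(m, tm, FALSE)$lp) / (2 * eps)
      expect_lt(abs(num - g[j]) / max(1, abs(num)), 1e-6)
    }
  }
})
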