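# Shared small fixtures, generated in code. Fits are cached per test run so
# several test files can reuse the same posterior without refitting.

small_sim <- function(n_species = 3, n_months = 100, seed = 7,
                      missing_rate = 0.05) {
  sc <- sim_config(n_species = n_species, n_months = n_months,
                   missing_rate = missing_rate, seed = seed)
  covars <- simulate_covariates(sc)
  params <- default_true_params(n_species, seed = seed)
  sim <- simulate_community(params, covars, sc)
  list(config = sc, covars = covars, params = params, sim = sim,
       data = sim$data)
}

.fixture_env <- new.env(parent = emptyenv())

cached_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    fx <- small_sim(n_species = 3, n_months = 100, seed = 7)
    model <- build_model(fx$data, fx$covars, variant = "GAM-VAR",
                         species_subset = fx$data$species[1:2])
    .fixture_env$fx <- fx
    .fixture_env$fit <- fit_model(model, chains = 2, warmup = 300,
                                  sampling = 300, seed = 42)
  }
  list(fit = .fixture_env$fit, fx = .fixture_env$fx)
}

# pack an unconstrained parameter vector from chosen natural values; used to
# build posterior objects with exactly known parameters for closed-form tests.
# beta_global / beta_dev are given on the natural (coefficient) scale and
# converted to the sampler's non-centered scale eta = S(lambda)^{1/2} beta.
pack_theta <- function(model, alpha = NULL, slope = NULL, beta_global = NULL,
                       beta_dev = NULL, loglam = 0, raw_a = 0, lsig = 0,
                       u = 0, z = 0) {
  b <- gamvar:::layout_blocks(model)
  theta <- numeric(model$layout$dim)
  if (!is.null(alpha)) theta[b$alpha] <- alpha
  if (!is.null(slope) && length(b$slope)) {
    if (model$cfg$pooled) {
      # mu_N = 0, sigma_N = 1, eta = slope (so slope_i comes out exactly)
      theta[b$slope] <- c(0, 0, slope)
    } else theta[b$slope] <- slope
  }
  if (length(b$lam)) theta[b$lam] <- loglam
  lam_all <- exp(rep_len(loglam, max(length(b$lam), 1)))
  eta_from_beta <- function(beta, Slist, lam) {
    Sl <- Reduce(`+`, Map(`*`, as.list(lam), Slist))
    as.vector(chol(Sl) %*% beta)   # eta = L' beta with S = L L'
  }
  lam_pos <- 0
  if (length(b$bg)) {
    if (!is.null(beta_global)) theta[b$bg] <- beta_global   # centered block
    lam_pos <- lam_pos + length(model$cpp_data$Sg)
  }
  if (length(b$bd) && !is.null(beta_dev)) {
    bd <- matrix(beta_dev, b$kd, b$ndev)
    J <- length(model$cpp_data$Sd)
    for (d in seq_len(b$ndev)) {
      idx <- b$bd[(d - 1) * b$kd + seq_len(b$kd)]
      if (model$cfg$has_global) {     # deviations are non-centered
        theta[idx] <- eta_from_beta(bd[, d], model$cpp_data$Sd,
                                    lam_all[lam_pos + seq_len(J)])
      } else theta[idx] <- bd[, d]
      lam_pos <- lam_pos + J
    }
  }
  theta[b$araw] <- raw_a
  theta[b$lsig] <- lsig
  if (length(b$u)) theta[b$u] <- u
  theta[b$z] <- z
  theta
}

# wrap fixed parameter draws as a minimal gamvar_fit (every draw identical)
manual_fit <- function(model, theta, n_draws = 8, chains = 2) {
  draws <- array(rep(theta, each = n_draws * chains),
                 c(n_draws, chains, length(theta)))
  structure(list(model = model, draws = draws,
                 lp = matrix(0, n_draws, chains),
                 divergences = integer(chains), stepsize = numeric(chains),
                 accept = numeric(chains), depth_hits = integer(chains),
                 chains = chains, warmup = 0, sampling = n_draws, seed = 1),
            class = "gamvar_fit")
}
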