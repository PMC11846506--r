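#' Assemble a joint model for one of the four benchmark variants
#'
#' Builds the design matrices, penalty structure, prior settings and data
#' blocks for the Poisson state-space model. The four variants form a
#' nested ladder: `GAM-VAR` (hierarchical GAM mean + full VAR(1) dynamics
#' with correlated process errors), `GAM-AR` (same mean, diagonal dynamics,
#' independent process errors), `GAM-AR-no-pooling` (independent species
#' slopes and independent full-rank distributed-lag smooths, diagonal
#' dynamics) and `AR` (species intercepts only, diagonal dynamics).
#'
#' Knots, standardization moments and identifiability constraints all come
#' from the training window only; design rows are built for every available
#' timepoint so held-out periods can be forecast.
#'
#' @param data a `community_ts`.
#' @param covars raw covariate table (with 12 months of lead-in), as from
#'   [simulate_covariates()].
#' @param variant one of "GAM-VAR", "GAM-AR", "GAM-AR-no-pooling", "AR".
#' @param species_subset labels of species receiving deviation smooths
#'   (default: the four most frequently captured).
#' @param train_end last timepoint used for fitting (default: all).
#' @param k_lag,k_temp,max_lag basis dimensions and maximum lag.
#' @param priors named list overriding prior constants (see Details).
#' @details Default priors: species intercepts N(0, 2^2); hierarchical NDVI
#'   slope mean N(0,1) and sd Exponential(2) (non-centered); independent
#'   slopes N(0,1) in the no-pooling variant; smoothing parameters
#'   Gamma(2, 0.1); unconstrained VAR entries N(0, 0.5^2); process sds
#'   Exponential(1); process correlation LKJ(2).
#' @return a `gamvar_model` object.
#' @export
build_model <- function(data, covars, variant = "GAM-VAR",
                        species_subset = NULL, train_end = NULL,
                        k_lag = 4, k_temp = 3, max_lag = 6,
                        priors = list()) {
  variants <- c("GAM-VAR", "GAM-AR", "GAM-AR-no-pooling", "AR")
  if (!variant %in% variants)
    stop("unknown variant '", variant, "'; must be one of ",
         paste(variants, collapse = ", "))
  stopifnot(inherits(data, "community_ts"))
  n <- nrow(data$counts); T_full <- ncol(data$counts)
  if (is.null(train_end)) train_end <- T_full
  stopifnot(train_end >= 24, train_end <= T_full)

  cfg <- switch(variant,
    "GAM-VAR" = list(has_ndvi = TRUE, pooled = TRUE, has_global = TRUE,
                     use_dev = "subset", full_A = TRUE, full_C = TRUE),
    "GAM-AR" = list(has_ndvi = TRUE, pooled = TRUE, has_global = TRUE,
                    use_dev = "subset", full_A = FALSE, full_C = FALSE),
    "GAM-AR-no-pooling" = list(has_ndvi = TRUE, pooled = FALSE,
                               has_global = FALSE, use_dev = "all",
                               full_A = FALSE, full_C = FALSE),
    "AR" = list(has_ndvi = FALSE, pooled = FALSE, has_global = FALSE,
                use_dev = "none", full_A = FALSE, full_C = FALSE))

  pr <- modifyList(list(alpha_sd = 2, slope_sd = 1, muN_sd = 1, sigN_rate = 2,
                        sigma_rate = 1, lkj_eta = 2, rawA_sd = 0.5,
                        lam_shape = 2, lam_rate = 0.1), priors)

  # covariate preparation: lead-in + standardization on the training window
  lead_rows <- sum(covars$time_index <= 0)
  if (lead_rows < 12) stop("covariate table needs 12 months of lead-in")
  pc <- prepare_covariates(covars, lead_in = lead_rows, train_end = train_end)
  count_rows <- which(pc$time_index >= 1)
  if (length(count_rows) < T_full)
    stop("covariate window shorter than the count window")
  count_rows <- count_rows[seq_len(T_full)]
  v_full <- pc$ndvi_ma12[count_rows]
  train_idx <- seq_len(train_end)

  smooth_set <- NULL; Bg_full <- NULL; Sg <- list()
  Bd_full <- NULL; Sd <- list(); dev_labels <- character(0)
  if (cfg$has_global || cfg$use_dev != "none") {
    ld <- build_lag_design(pc$mintemp_z, max_lag = max_lag,
                           start = count_rows[1])
    ld$value_matrix <- ld$value_matrix[seq_len(T_full), , drop = FALSE]
    ld$lag_matrix <- ld$lag_matrix[seq_len(T_full), , drop = FALSE]
    # knots from the training window only
    tr_rows <- as.vector(outer(train_idx, (seq_len(max_lag + 1) - 1) * T_full, "+"))
    b_lag <- cubic_basis(as.vector(ld$lag_matrix)[tr_rows], k = k_lag)
    b_temp <- thin_plate_basis(as.vector(ld$value_matrix)[tr_rows], k = k_temp)
    tens <- tensor_product(b_lag, b_temp)
    dl <- distributed_lag_design(tens, ld)
    dl_c <- add_nullspace_penalty(absorb_constraint(dl, rows = train_idx))
    if (cfg$use_dev == "all") dev_labels <- data$species
    else if (cfg$use_dev == "subset") {
      if (is.null(species_subset)) {
        tot <- rowSums(data$counts[, train_idx, drop = FALSE] *
                         data$mask[, train_idx, drop = FALSE], na.rm = TRUE)
        species_subset <- data$species[order(-tot)][seq_len(min(4, n))]
      }
      dev_labels <- species_subset
    }
    if (cfg$has_global) {
      smooth_set <- make_hierarchical(dl,
                                      if (length(dev_labels)) dev_labels else data$species[1],
                                      data$species, rows = train_idx)
      Bg_full <- smooth_set$global$X
      Sg <- smooth_set$global$penalties
      if (length(dev_labels)) { Bd_full <- Bg_full; Sd <- Sg }
    } else if (length(dev_labels)) {
      Bd_full <- dl_c$X
      Sd <- dl_c$penalties
    }
  }
  dev_idx <- match(dev_labels, data$species) - 1L   # 0-based for C++

  Ytr <- data$counts[, train_idx, drop = FALSE]
  Ytr[is.na(Ytr)] <- 0
  cpp_data <- list(
    Y = unname(Ytr) * 1.0,
    O = unname(data$mask[, train_idx, drop = FALSE]) * 1.0,
    v = v_full[train_idx],
    Bg = if (!is.null(Bg_full)) Bg_full[train_idx, , drop = FALSE] else NULL,
    Sg = Sg,
    Bd = if (!is.null(Bd_full)) Bd_full[train_idx, , drop = FALSE] else NULL,
    Sd = Sd,
    dev = as.integer(dev_idx),
    has_ndvi = cfg$has_ndvi, pooled = cfg$pooled,
    has_global = cfg$has_global,
    full_A = cfg$full_A, full_C = cfg$full_C,
    priors = pr)
  layout <- cpp_param_layout(cpp_data)

  structure(list(
    variant = variant, data = data, cpp_data = cpp_data, layout = layout,
    n = n, T_train = train_end, T_full = T_full,
    v_full = v_full, Bg_full = Bg_full, Bd_full = Bd_full,
    dev_labels = dev_labels, dev_idx = dev_idx + 1L,
    smooth_set = smooth_set, covars = pc, count_rows = count_rows,
    priors = pr, cfg = cfg,
    tensor = if (exists("tens", inherits = FALSE)) tens else NULL,
    constraint = if (exists("dl_c", inherits = FALSE)) dl_c$constraint else NULL,
    nullspace_pen = if (exists("dl_c", inherits = FALSE)) dl_c$penalties else NULL
  ), class = "gamvar_model")
}

#' @export
print.gamvar_model <- function(x, ...) {
  cat(sprintf("<gamvar_model> variant %s: %d species x %d training months (%d total), %d parameters\n",
              x$variant, x$n, x$T_train, x$T_full, x$layout$dim))
  invisible(x)
}

#' Joint log-posterior density and gradient
#'
#' Evaluates the unnormalized joint log-posterior (on the unconstrained
#' parameterization, change-of-variable Jacobians included) and its
#' gradient. Masked observations contribute nothing to the observation term
#' but their latent states remain defined through the dynamics.
#'
#' @param model a `gamvar_model`.
#' @param theta unconstrained parameter vector of length `model$layout$dim`.
#' @param want_grad compute the gradient.
#' @return list with `lp`, `grad` and a named `parts` breakdown
#'   (observation, dynamics, priors).
#' @export
log_posterior <- function(model, theta, want_grad = TRUE) {
  cpp_logpost(theta, model$cpp_data, want_grad)
}

# block index helpers (layout offsets are 0-based from C++)
.block <- function(model, name, len) {
  off <- model$layout[[name]]
  if (len == 0) integer(0) else (off + 1):(off + len)
}

layout_blocks <- function(model) {
  l <- model$layout; n <- model$n
  kg <- if (!is.null(model$cpp_data$Bg)) ncol(model$cpp_data$Bg) else 0
  kd <- if (!is.null(model$cpp_data$Bd)) ncol(model$cpp_data$Bd) else 0
  ndev <- length(model$cpp_data$dev)
  slope_len <- if (model$cfg$has_ndvi) { if (model$cfg$pooled) 2 + n else n } else 0
  list(alpha = .block(model, "alpha", n),
       slope = .block(model, "slope", slope_len),
       bg = .block(model, "bg", kg),
       bd = .block(model, "bd", kd * ndev),
       lam = .block(model, "lam", l$n_lam),
       araw = .block(model, "araw", l$n_araw),
       lsig = .block(model, "lsig", n),
       u = .block(model, "u", l$n_u),
       z = .block(model, "z", n * model$T_train),
       kg = kg, kd = kd, ndev = ndev)
}

#' Initial parameter values for one chain
#'
#' Intercepts start at the log observed species means; everything else gets
#' small jitter. Latent states start near zero.
#'
#' @param model a `gamvar_model`.
#' @param jitter jitter scale.
#' @export
init_theta <- function(model, jitter = 0.1) {
  b <- layout_blocks(model)
  theta <- rnorm(model$layout$dim, 0, jitter * 0.2)
  Y <- model$cpp_data$Y; O <- model$cpp_data$O
  my <- rowSums(Y * O) / pmax(rowSums(O), 1)
  theta[b$alpha] <- log(my + 0.5) + rnorm(model$n, 0, jitter)
  if (length(b$lam)) theta[b$lam] <- log(10) + rnorm(length(b$lam), 0, jitter)
  theta[b$lsig] <- log(0.3) + rnorm(model$n, 0, jitter)
  if (model$cfg$pooled && length(b$slope))
    theta[b$slope[2]] <- log(0.3) + rnorm(1, 0, jitter)
  theta
}

# natural parameters from one unconstrained draw; with_z = FALSE skips the
# latent-state reconstruction (the expensive part) for summaries that only
# need structural parameters
unpack_draw <- function(model, theta, with_z = TRUE) {
  b <- layout_blocks(model)
  n <- model$n
  out <- list(alpha = theta[b$alpha])
  if (model$cfg$has_ndvi) {
    if (model$cfg$pooled) {
      muN <- theta[b$slope[1]]; sigN <- exp(theta[b$slope[2]])
      eta <- theta[b$slope[-(1:2)]]
      out$mu_ndvi <- muN; out$sigma_ndvi <- sigN
      out$slope <- muN + sigN * eta
    } else out$slope <- theta[b$slope]
  }
  if (length(b$lam)) out$lambda <- exp(theta[b$lam])
  # deviation blocks are non-centered (beta = L^{-T} eta with S(lambda) =
  # L L') when a global smooth is present; the global (and no-pooling)
  # blocks are centered
  lam_pos <- 0
  beta_from_eta <- function(eta_b, Slist) {
    J <- length(Slist)
    lam <- out$lambda[lam_pos + seq_len(J)]
    lam_pos <<- lam_pos + J
    Sl <- Reduce(`+`, Map(`*`, as.list(lam), Slist))
    backsolve(chol(Sl), eta_b)
  }
  if (b$kg > 0) {
    out$beta_global <- theta[b$bg]
    lam_pos <- lam_pos + length(model$cpp_data$Sg)
  }
  if (b$ndev > 0) {
    coef_d <- matrix(theta[b$bd], b$kd, b$ndev)
    out$beta_dev <- matrix(NA_real_, b$kd, b$ndev,
                           dimnames = list(NULL, model$dev_labels))
    for (d in seq_len(b$ndev)) {
      if (model$cfg$has_global) {
        out$beta_dev[, d] <- beta_from_eta(coef_d[, d], model$cpp_data$Sd)
      } else {
        out$beta_dev[, d] <- coef_d[, d]
        lam_pos <- lam_pos + length(model$cpp_data$Sd)
      }
    }
  }
  sigma <- exp(theta[b$lsig])
  out$sigma <- sigma
  if (model$cfg$full_C) {
    L <- chol_from_partials(n, theta[b$u])
    out$C <- L %*% t(L)
  } else out$C <- diag(n)
  Sigma <- diag(sigma, n) %*% out$C %*% diag(sigma, n)
  out$Sigma <- Sigma
  R <- matrix(0, n, n)
  if (model$cfg$full_A) R[] <- theta[b$araw] else diag(R) <- theta[b$araw]
  out$raw_A <- R
  mp <- cpp_map_to_stationary(R, Sigma)
  out$A <- mp$A; out$Gamma <- mp$Gamma
  if (with_z) {
    # latent states from their non-centered innovations:
    # z_1 = Gamma^{1/2} eps_1, z_t = A z_{t-1} + Sigma^{1/2} eps_t
    eps <- matrix(theta[b$z], n, model$T_train)
    G <- sqrtm_sym(mp$Gamma)
    Ss <- sqrtm_sym(Sigma)
    z <- matrix(0, n, model$T_train)
    z[, 1] <- G %*% eps[, 1]
    for (t in seq_len(model$T_train - 1))
      z[, t + 1] <- out$A %*% z[, t] + Ss %*% eps[, t + 1]
    out$eps <- eps
    out$z <- z
  }
  out
}

# unique symmetric positive-semidefinite matrix square root
sqrtm_sym <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

chol_from_partials <- function(n, u) {
  L <- diag(n)
  if (n < 2) return(L)
  pos <- 1
  for (i in 2:n) {
    s <- 1
    for (j in 1:(i - 1)) {
      r <- tanh(u[pos]); pos <- pos + 1
      L[i, j] <- r * s
      s <- s * sqrt(1 - r^2)
    }
    L[i, i] <- s
  }
  L
}

# GAM mean for given timepoint rows from one natural-parameter draw
compute_mu <- function(model, nat, rows) {
  n <- model$n
  mu <- matrix(nat$alpha, n, length(rows))
  if (model$cfg$has_ndvi)
    mu <- mu + nat$slope %*% t(model$v_full[rows])
  if (!is.null(nat$beta_global))
    mu <- mu + matrix(model$Bg_full[rows, , drop = FALSE] %*% nat$beta_global,
                      n, length(rows), byrow = TRUE)
  if (!is.null(nat$beta_dev)) {
    fd <- model$Bd_full[rows, , drop = FALSE] %*% nat$beta_dev
    for (d in seq_along(model$dev_idx))
      mu[model$dev_idx[d], ] <- mu[model$dev_idx[d], ] + fd[, d]
  }
  mu
}
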