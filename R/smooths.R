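#' Penalized spline bases and hierarchical distributed-lag smooths
#'
#' The distributed-lag effect of minimum temperature is a bivariate smooth
#' f(lag, temp), built as a tensor product of a cubic regression spline
#' margin in lag (k = 4) and a low-rank thin-plate margin in temperature
#' (k = 3), summed over lags 0..L for each timepoint. A shared community
#' smooth is paired with per-species deviation smooths whose penalties are
#' full rank, so deviations shrink to zero unless the data support them.
#'
#' @name smooths
NULL

new_penalized_design <- function(X, penalties, nullspace_dim, smooth = NULL,
                                 constraint = NULL) {
  structure(list(X = X, penalties = penalties, nullspace_dim = nullspace_dim,
                 smooth = smooth, constraint = constraint),
            class = "penalized_design")
}

#' Cubic regression spline basis
#'
#' @param x covariate values (at least `k` distinct).
#' @param k number of basis functions (default 4).
#' @return a `penalized_design` with one second-derivative penalty;
#'   the penalty null space (constant + linear) has dimension 2.
#' @export
cubic_basis <- function(x, k = 4) {
  stopifnot(k >= 3)
  if (length(unique(x)) < k) stop("need at least k distinct covariate values")
  sm <- mgcv::smoothCon(mgcv::s(xv, bs = "cr", k = k),
                        data = data.frame(xv = x), absorb.cons = FALSE)[[1]]
  new_penalized_design(sm$X, sm$S, nullspace_dim = sm$null.space.dim,
                       smooth = sm)
}

#' Low-rank thin-plate regression spline basis
#'
#' Eigen-truncated thin-plate basis with the order-2 wiggliness penalty;
#' constants (and linear functions before any constraint) are unpenalized.
#'
#' @param x covariate values (at least `k` distinct).
#' @param k number of basis functions (default 3).
#' @export
thin_plate_basis <- function(x, k = 3) {
  stopifnot(k >= 3)
  if (length(unique(x)) < k) stop("need at least k distinct covariate values")
  sm <- mgcv::smoothCon(mgcv::s(xv, bs = "tp", k = k),
                        data = data.frame(xv = x), absorb.cons = FALSE)[[1]]
  new_penalized_design(sm$X, sm$S, nullspace_dim = sm$null.space.dim,
                       smooth = sm)
}

row_tensor <- function(A, B) {
  # row-wise Kronecker: out[i, ] = A[i, ] %x% B[i, ]
  kA <- ncol(A); kB <- ncol(B)
  out <- matrix(0, nrow(A), kA * kB)
  for (a in seq_len(kA))
    out[, (a - 1) * kB + seq_len(kB)] <- A[, a] * B
  out
}

#' Tensor-product smooth of two marginal bases
#'
#' Columns follow the convention `column = (a - 1) * k2 + b` for marginal
#' basis functions a (first margin) and b (second margin). Each margin
#' contributes one penalty, Kronecker-expanded against the other margin's
#' identity, so the tensor smooth carries exactly two penalties.
#'
#' @param b1,b2 `penalized_design` marginals built on matched rows.
#' @return a `penalized_design` that also stores the marginal smooths so it
#'   can be evaluated at new (margin1, margin2) pairs.
#' @export
tensor_product <- function(b1, b2) {
  if (nrow(b1$X) != nrow(b2$X)) stop("marginal bases built on mismatched rows")
  k1 <- ncol(b1$X); k2 <- ncol(b2$X)
  X <- row_tensor(b1$X, b2$X)
  penalties <- list(b1$penalties[[1]] %x% diag(k2),
                    diag(k1) %x% b2$penalties[[1]])
  pd <- new_penalized_design(X, penalties,
                             nullspace_dim = b1$nullspace_dim * b2$nullspace_dim)
  pd$marginals <- list(b1$smooth, b2$smooth)
  class(pd) <- c("tensor_design", class(pd))
  pd
}

eval_marginal <- function(sm, x) {
  mgcv::PredictMat(sm, data.frame(xv = x))
}

#' Evaluate a tensor smooth basis at arbitrary coordinate pairs
#'
#' @param tensor a `tensor_design`.
#' @param x1,x2 coordinate vectors (same length) for the two margins.
#' @return matrix with one row per coordinate pair.
#' @export
eval_tensor <- function(tensor, x1, x2) {
  row_tensor(eval_marginal(tensor$marginals[[1]], x1),
             eval_marginal(tensor$marginals[[2]], x2))
}

#' Distributed-lag summation design
#'
#' For timepoint t the design row is the sum over lags l = 0..L of the
#' tensor basis evaluated at (lag = l, temp = value_matrix[t, l + 1]).
#' Summation is linear, so the penalties are inherited unchanged from the
#' tensor smooth.
#'
#' @param tensor a `tensor_design` with lag as its first margin.
#' @param lag_design output of [build_lag_design()].
#' @export
distributed_lag_design <- function(tensor, lag_design) {
  V <- lag_design$value_matrix
  Lm <- lag_design$lag_matrix
  if (!identical(dim(V), dim(Lm))) stop("misaligned lag design matrices")
  k <- ncol(tensor$X)
  X <- matrix(0, nrow(V), k)
  for (l in seq_len(ncol(V)))
    X <- X + row_tensor(eval_marginal(tensor$marginals[[1]], Lm[, l]),
                        eval_marginal(tensor$marginals[[2]], V[, l]))
  pd <- new_penalized_design(X, tensor$penalties, tensor$nullspace_dim)
  pd$tensor <- tensor
  class(pd) <- c("lag_design_matrix", class(pd))
  pd
}

#' Absorb a sum-to-zero constraint into a penalized design
#'
#' Reparameterizes so that fitted effects are orthogonal to the intercept
#' over the supplied rows: columns are projected onto the null space of the
#' column-sum constraint, dropping one coefficient.
#'
#' @param pd a `penalized_design`.
#' @param rows rows over which the constraint is applied (default all).
#' @export
absorb_constraint <- function(pd, rows = seq_len(nrow(pd$X))) {
  cs <- colSums(pd$X[rows, , drop = FALSE])
  qrC <- qr(matrix(cs, ncol = 1))
  Z <- qr.Q(qrC, complete = TRUE)[, -1, drop = FALSE]
  out <- pd
  out$X <- pd$X %*% Z
  out$penalties <- lapply(pd$penalties, function(S) t(Z) %*% S %*% Z)
  out$constraint <- list(type = "sumzero", Z = Z)
  out$nullspace_dim <- max(pd$nullspace_dim - 1, 0)
  out
}

#' Add a null-space penalty so the total penalty is full rank
#'
#' The null space of the summed penalties is found by eigendecomposition and
#' penalized with its own smoothing parameter (an `N N'` projection penalty),
#' making the implied Gaussian prior on the coefficients proper.
#'
#' @param pd a `penalized_design`.
#' @param tol relative eigenvalue tolerance for the null space.
#' @export
add_nullspace_penalty <- function(pd, tol = 1e-8) {
  S <- Reduce(`+`, pd$penalties)
  e <- eigen(S, symmetric = TRUE)
  null_idx <- which(e$values < tol * max(e$values, 1))
  if (length(null_idx) == 0) return(pd)
  N <- e$vectors[, null_idx, drop = FALSE]
  pd$penalties <- c(pd$penalties, list(N %*% t(N)))
  pd$nullspace_dim <- 0
  pd
}

#' Hierarchical global + species-deviation smooth set
#'
#' The global smooth (applied to every species) is centered with a
#' sum-to-zero constraint and given a null-space penalty so its prior is
#' proper. Each species in `species_subset` receives a deviation smooth on
#' the same constrained basis with its own smoothing parameters and a fully
#' penalized null space; the species effect is the sum of the two.
#'
#' @param global an (unconstrained) `penalized_design` for the shared smooth.
#' @param species_subset labels of species that get deviation smooths.
#' @param species all modelled species labels.
#' @param rows rows (timepoints) over which the centering constraint is
#'   taken; defaults to all rows of the design.
#' @export
make_hierarchical <- function(global, species_subset, species,
                              rows = seq_len(nrow(global$X))) {
  if (length(species_subset) == 0) stop("species subset must be nonempty")
  if (!all(species_subset %in% species))
    stop("unknown species label(s): ",
         paste(setdiff(species_subset, species), collapse = ", "))
  g <- add_nullspace_penalty(absorb_constraint(global, rows = rows))
  dev_template <- g   # same basis, own smoothing parameters per species
  deviations <- setNames(rep(list(dev_template), length(species_subset)),
                         species_subset)
  structure(list(global = g, deviations = deviations,
                 species_subset = species_subset),
            class = "hierarchical_smooth_set")
}
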