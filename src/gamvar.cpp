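// Core numerical machinery: stationarity-enforcing VAR reparameterization,
// joint log-posterior (Poisson observations, GAM mean, VAR(1) latent states)
// with hand-derived reverse-mode gradients, and a No-U-Turn sampler with
// dual-averaging step-size and diagonal mass-matrix adaptation.
//
// Conventions: all matrices are species x species (n small, <= ~10);
// latent states z are stored as an n x T matrix, packed column-major
// (time-major) into the parameter vector.

#include <RcppArmadillo.h>
#include <functional>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// ---------------------------------------------------------------------------
// symmetric matrix square root and its reverse-mode adjoint
// ---------------------------------------------------------------------------

struct SqrtmCache {
  mat U;     // eigenvectors of the input
  vec s;     // sqrt of eigenvalues
  mat X;     // the square root itself
};

static SqrtmCache sqrtm_sym(const mat& S) {
  SqrtmCache c;
  vec eval;
  if (!eig_sym(eval, c.U, symmatu(S)))
    Rcpp::stop("eigendecomposition failed in symmetric square root");
  if (eval.min() <= 0)
    Rcpp::stop("matrix not positive definite in symmetric square root");
  c.s = sqrt(eval);
  c.X = c.U * diagmat(c.s) * c.U.t();
  return c;
}

// adjoint: given Xbar (adjoint of X = sqrtm(S)), return Sbar.
// Solves the Sylvester system X Sbar + Sbar X = sym(Xbar) in the eigenbasis.
static mat sqrtm_adj(const SqrtmCache& c, const mat& Xbar) {
  mat B = c.U.t() * (0.5 * (Xbar + Xbar.t())) * c.U;
  const uword n = B.n_rows;
  for (uword i = 0; i < n; ++i)
    for (uword j = 0; j < n; ++j)
      B(i, j) /= (c.s(i) + c.s(j));
  return c.U * B * c.U.t();
}

// reverse-mode through a lower Cholesky factorization S = L L':
// given Lbar, returns Sbar (to be symmetrized by the caller)
static mat chol_rev(const mat& L, const mat& Lbar) {
  mat P = trimatl(L.t() * Lbar);
  P.diag() *= 0.5;
  mat Li = inv(trimatl(L));
  return Li.t() * P * Li;
}

// ---------------------------------------------------------------------------
// stationarity map: unconstrained raw matrix R + innovation covariance Sigma
//   P = (I + R R')^{-1/2} R           (all singular values of P < 1)
//   G = Gamma^{1/2} solves G (I - P P') G = Sigma
//   A = G P G^{-1}                     (similar to P => spectral radius < 1)
// Gamma = G G is the stationary covariance of z_t = A z_{t-1} + e_t.
// ---------------------------------------------------------------------------

struct MapCache {
  mat R, Sigma;
  SqrtmCache Ms;          // sqrtm(I + R R')
  mat Msi, P, Q;
  SqrtmCache Qs;          // sqrtm(I - P P')
  mat Qsi, Tm;
  SqrtmCache Ts;          // sqrtm(Qs Sigma Qs)
  mat G, Gi, A, Gamma;
};

static MapCache map_forward(const mat& R, const mat& Sigma) {
  MapCache m;
  const uword n = R.n_rows;
  m.R = R; m.Sigma = Sigma;
  mat I = eye(n, n);
  m.Ms  = sqrtm_sym(I + R * R.t());
  m.Msi = inv_sympd(symmatu(m.Ms.X));
  m.P   = m.Msi * R;
  m.Q   = I - m.P * m.P.t();
  m.Qs  = sqrtm_sym(m.Q);
  m.Qsi = inv_sympd(symmatu(m.Qs.X));
  m.Tm  = m.Qs.X * Sigma * m.Qs.X;
  m.Ts  = sqrtm_sym(m.Tm);
  m.G   = m.Qsi * m.Ts.X * m.Qsi;
  m.Gi  = inv_sympd(symmatu(m.G));
  m.A   = m.G * m.P * m.Gi;
  m.Gamma = m.G * m.G;
  return m;
}

// reverse pass: given adjoints of A, Gamma, G (= Gamma^{1/2}) and a partial
// adjoint of Sigma, accumulate adjoints of R and Sigma.
static void map_backward(const MapCache& m, const mat& Abar_in,
                         const mat& Gammabar_in, const mat& Gbar_in,
                         mat& Rbar, mat& Sigmabar) {
  mat Gbar = Gbar_in;
  mat Pbar(size(m.P), fill::zeros);
  mat Gibar(size(m.G), fill::zeros);

  // A = (G P) Gi
  Gbar  += Abar_in * m.Gi.t() * m.P.t();
  Pbar  += m.G.t() * Abar_in * m.Gi.t();
  Gibar += (m.G * m.P).t() * Abar_in;
  // Gi = inv(G)
  Gbar  += -m.Gi.t() * Gibar * m.Gi.t();
  // Gamma = G G
  Gbar  += Gammabar_in * m.G.t() + m.G.t() * Gammabar_in;

  // G = Qsi Ts Qsi
  mat Qsibar(size(m.G), fill::zeros);
  Qsibar += Gbar * (m.Ts.X * m.Qsi).t();
  Qsibar += (m.Qsi * m.Ts.X).t() * Gbar;
  mat Tsbar = m.Qsi.t() * Gbar * m.Qsi.t();
  // Ts = sqrtm(Tm)
  mat Tmbar = sqrtm_adj(m.Ts, Tsbar);
  // Tm = Qs Sigma Qs
  mat Qsbar(size(m.G), fill::zeros);
  Qsbar += Tmbar * (m.Sigma * m.Qs.X).t();
  Qsbar += (m.Qs.X * m.Sigma).t() * Tmbar;
  Sigmabar += m.Qs.X.t() * Tmbar * m.Qs.X.t();
  // Qsi = inv(Qs)
  Qsbar += -m.Qsi.t() * Qsibar * m.Qsi.t();
  // Qs = sqrtm(Q)
  mat Qbar = sqrtm_adj(m.Qs, Qsbar);
  // Q = I - P P'
  Pbar += -(Qbar + Qbar.t()) * m.P;
  // P = Msi R
  Rbar += m.Msi.t() * Pbar;
  mat Msibar = Pbar * m.R.t();
  // Msi = inv(Ms)
  mat Msbar = -m.Msi.t() * Msibar * m.Msi.t();
  // Ms = sqrtm(I + R R')
  mat Mbar = sqrtm_adj(m.Ms, Msbar);
  Rbar += (Mbar + Mbar.t()) * m.R;
}

// [[Rcpp::export]]
Rcpp::List cpp_map_to_stationary(const arma::mat& R, const arma::mat& Sigma) {
  MapCache m = map_forward(R, Sigma);
  return Rcpp::List::create(Rcpp::Named("P") = m.P,
                            Rcpp::Named("A") = m.A,
                            Rcpp::Named("Gamma") = m.Gamma);
}

// ---------------------------------------------------------------------------
// model data and parameter layout
// ---------------------------------------------------------------------------

struct ModelData {
  mat Y, O, lgY;            // n x T counts, observation indicator, lgamma(Y+1)
  vec v;                    // NDVI moving-average covariate (length T)
  mat Bg;                   // T x kg global distributed-lag design
  std::vector<mat> Sg;      // global penalties (kg x kg)
  mat Bd;                   // T x kd deviation design (shared basis)
  std::vector<mat> Sd;      // deviation penalties
  uvec dev;                 // 0-based species indices with deviation smooths
  bool full_A, full_C, has_ndvi, pooled, has_global;
  // prior constants
  double alpha_sd, slope_sd, muN_sd, sigN_rate, sigma_rate, lkj_eta,
         rawA_sd, lam_shape, lam_rate;
  // derived sizes
  uword n, T, kg, kd, ndev, n_lam, n_araw, n_u, dim;
  // block offsets (0-based)
  uword o_alpha, o_slope, o_bg, o_bd, o_lam, o_araw, o_lsig, o_u, o_z;

  void finalize() {
    n = Y.n_rows; T = Y.n_cols;
    kg = has_global ? Bg.n_cols : 0;
    ndev = dev.n_elem;
    kd = ndev > 0 ? Bd.n_cols : 0;
    n_lam = (has_global ? Sg.size() : 0) + ndev * Sd.size();
    n_araw = full_A ? n * n : n;
    n_u = full_C ? n * (n - 1) / 2 : 0;
    // the dynamics block (raw A, log sigma, correlation partials) leads the
    // layout so the sampler can give it a dense mass-matrix block; its
    // entries are the most strongly correlated a posteriori
    uword off = 0;
    o_araw = off; off += n_araw;
    o_lsig = off; off += n;
    o_u = off; off += n_u;
    o_alpha = off; off += n;
    o_slope = off;
    if (has_ndvi) off += pooled ? (2 + n) : n;
    o_bg = off; off += kg;
    o_bd = off; off += kd * ndev;
    o_lam = off; off += n_lam;
    o_z = off; off += n * T;
    dim = off;
  }
};

static std::vector<mat> as_matlist(const Rcpp::List& l) {
  std::vector<mat> out;
  for (int i = 0; i < l.size(); ++i)
    out.push_back(Rcpp::as<mat>(l[i]));
  return out;
}

static ModelData parse_data(const Rcpp::List& d) {
  ModelData md;
  md.Y = Rcpp::as<mat>(d["Y"]);
  md.O = Rcpp::as<mat>(d["O"]);
  md.lgY = md.Y;
  md.lgY.transform([](double y) { return std::lgamma(y + 1.0); });
  md.has_ndvi   = Rcpp::as<bool>(d["has_ndvi"]);
  md.pooled     = Rcpp::as<bool>(d["pooled"]);
  md.has_global = Rcpp::as<bool>(d["has_global"]);
  md.full_A     = Rcpp::as<bool>(d["full_A"]);
  md.full_C     = Rcpp::as<bool>(d["full_C"]);
  if (md.has_ndvi) md.v = Rcpp::as<vec>(d["v"]); else md.v = zeros(md.Y.n_cols);
  if (md.has_global) {
    md.Bg = Rcpp::as<mat>(d["Bg"]);
    md.Sg = as_matlist(d["Sg"]);
  }
  md.dev = Rcpp::as<uvec>(d["dev"]);
  if (md.dev.n_elem > 0) {
    md.Bd = Rcpp::as<mat>(d["Bd"]);
    md.Sd = as_matlist(d["Sd"]);
  }
  Rcpp::List pr = d["priors"];
  md.alpha_sd   = Rcpp::as<double>(pr["alpha_sd"]);
  md.slope_sd   = Rcpp::as<double>(pr["slope_sd"]);
  md.muN_sd     = Rcpp::as<double>(pr["muN_sd"]);
  md.sigN_rate  = Rcpp::as<double>(pr["sigN_rate"]);
  md.sigma_rate = Rcpp::as<double>(pr["sigma_rate"]);
  md.lkj_eta    = Rcpp::as<double>(pr["lkj_eta"]);
  md.rawA_sd    = Rcpp::as<double>(pr["rawA_sd"]);
  md.lam_shape  = Rcpp::as<double>(pr["lam_shape"]);
  md.lam_rate   = Rcpp::as<double>(pr["lam_rate"]);
  md.finalize();
  return md;
}

// [[Rcpp::export]]
Rcpp::List cpp_param_layout(const Rcpp::List& data) {
  ModelData md = parse_data(data);
  return Rcpp::List::create(
    Rcpp::Named("dim") = (int)md.dim,
    Rcpp::Named("alpha") = (int)md.o_alpha, Rcpp::Named("slope") = (int)md.o_slope,
    Rcpp::Named("bg") = (int)md.o_bg, Rcpp::Named("bd") = (int)md.o_bd,
    Rcpp::Named("lam") = (int)md.o_lam, Rcpp::Named("araw") = (int)md.o_araw,
    Rcpp::Named("lsig") = (int)md.o_lsig, Rcpp::Named("u") = (int)md.o_u,
    Rcpp::Named("z") = (int)md.o_z,
    Rcpp::Named("n_lam") = (int)md.n_lam, Rcpp::Named("n_araw") = (int)md.n_araw,
    Rcpp::Named("n_u") = (int)md.n_u);
}

// ---------------------------------------------------------------------------
// joint log-posterior with gradient
// ---------------------------------------------------------------------------

// Cholesky factor of the process-error correlation matrix from unconstrained
// partials (row-wise tanh parameterization); accumulates the LKJ(eta) prior
// and both change-of-variable Jacobians into lp.  Also supports the reverse
// pass given Lbar.
static mat build_L(const ModelData& md, const vec& u, double& lp,
                   std::vector<vec>& s_store, mat& rmat) {
  const uword n = md.n;
  mat L = eye(n, n);
  rmat = zeros(n, n);
  s_store.assign(n, vec());
  uword pos = 0;
  for (uword i = 1; i < n; ++i) {
    vec sarr(i);
    double s = 1.0;
    for (uword j = 0; j < i; ++j) {
      double r = std::tanh(u(pos++));
      rmat(i, j) = r;
      L(i, j) = r * s;
      // Jacobian of tanh and of r -> L (triangular, diag entries s_{j-1})
      lp += std::log1p(-r * r);
      if (j >= 1) lp += std::log(sarr(j - 1));
      s *= std::sqrt(1.0 - r * r);
      sarr(j) = s;
    }
    L(i, i) = s;
    s_store[i] = sarr;
    // LKJ(eta) density on the Cholesky factor
    lp += (md.n - (i + 1) + 2.0 * md.lkj_eta - 2.0) * std::log(s);
  }
  return L;
}

static void build_L_backward(const ModelData& md, const mat& Lbar,
                             const std::vector<vec>& s_store, const mat& rmat,
                             vec& ubar) {
  const uword n = md.n;
  uword pos = 0;
  std::vector<uword> row_start(n, 0);
  for (uword i = 1; i < n; ++i) { row_start[i] = pos; pos += i; }
  for (uword i = 1; i < n; ++i) {
    const vec& sarr = s_store[i];
    vec sbar(i, fill::zeros);
    double coef = md.n - (i + 1) + 2.0 * md.lkj_eta - 2.0;
    sbar(i - 1) += Lbar(i, i) + coef / sarr(i - 1);
    // forward pass added Jacobian terms log(sarr(j-1)) for j = 1..i-1
    for (uword j = 1; j < i; ++j) sbar(j - 1) += 1.0 / sarr(j - 1);
    for (uword jj = i; jj-- > 0; ) {
      double r = rmat(i, jj);
      double c = std::sqrt(1.0 - r * r);
      double s_before = (jj > 0) ? sarr(jj - 1) : 1.0;
      double rbar = 0.0;
      // s_j = s_{j-1} * c
      if (jj > 0) sbar(jj - 1) += sbar(jj) * c;
      double cbar = sbar(jj) * s_before;
      rbar += cbar * (-r / c);
      // L(i,j) = r * s_{j-1}
      rbar += Lbar(i, jj) * s_before;
      if (jj > 0) sbar(jj - 1) += Lbar(i, jj) * r;
      // tanh Jacobian term d/dr log(1 - r^2)
      rbar += -2.0 * r / (1.0 - r * r);
      ubar(row_start[i] + jj) += rbar * (1.0 - r * r);
    }
  }
}

// full joint log-posterior; fills grad if want_grad; parts gets named pieces
static double logpost(const ModelData& md, const vec& theta, vec& grad,
                      bool want_grad, vec& parts) {
  const uword n = md.n, T = md.T;
  double lp = 0.0;
  double lp_obs = 0.0, lp_dyn = 0.0;
  grad.zeros(md.dim);
  parts.zeros(3);

  // --- unpack ---------------------------------------------------------------
  vec alpha = theta.subvec(md.o_alpha, md.o_alpha + n - 1);
  vec slope(n, fill::zeros), eta;
  double muN = 0, lsigN = 0, sigN = 1;
  if (md.has_ndvi) {
    if (md.pooled) {
      muN = theta(md.o_slope); lsigN = theta(md.o_slope + 1);
      sigN = std::exp(lsigN);
      eta = theta.subvec(md.o_slope + 2, md.o_slope + 1 + n);
      slope = muN + sigN * eta;
    } else {
      slope = theta.subvec(md.o_slope, md.o_slope + n - 1);
    }
  }
  vec bg;
  if (md.has_global) bg = theta.subvec(md.o_bg, md.o_bg + md.kg - 1);
  mat bd;
  if (md.ndev > 0)
    bd = reshape(theta.subvec(md.o_bd, md.o_bd + md.kd * md.ndev - 1),
                 md.kd, md.ndev);
  vec loglam = md.n_lam > 0 ?
    vec(theta.subvec(md.o_lam, md.o_lam + md.n_lam - 1)) : vec();
  vec araw = theta.subvec(md.o_araw, md.o_araw + md.n_araw - 1);
  vec lsig = theta.subvec(md.o_lsig, md.o_lsig + n - 1);
  vec sigma = exp(lsig);
  vec u = md.n_u > 0 ? vec(theta.subvec(md.o_u, md.o_u + md.n_u - 1)) : vec();
  // latent states are parameterized non-centrally through their innovations:
  // z_1 = Gamma^{1/2} eps_1, z_t = A z_{t-1} + Sigma^{1/2} eps_t
  mat eps = reshape(theta.subvec(md.o_z, md.o_z + n * T - 1), n, T);

  // --- simple priors --------------------------------------------------------
  lp += -0.5 * dot(alpha, alpha) / (md.alpha_sd * md.alpha_sd);
  if (want_grad)
    grad.subvec(md.o_alpha, md.o_alpha + n - 1) -=
      alpha / (md.alpha_sd * md.alpha_sd);
  if (md.has_ndvi) {
    if (md.pooled) {
      lp += -0.5 * muN * muN / (md.muN_sd * md.muN_sd);
      lp += -md.sigN_rate * sigN + lsigN;       // Exponential prior + Jacobian
      lp += -0.5 * dot(eta, eta);
      if (want_grad) {
        grad(md.o_slope) -= muN / (md.muN_sd * md.muN_sd);
        grad(md.o_slope + 1) += -md.sigN_rate * sigN + 1.0;
        grad.subvec(md.o_slope + 2, md.o_slope + 1 + n) -= eta;
      }
    } else {
      lp += -0.5 * dot(slope, slope) / (md.slope_sd * md.slope_sd);
      if (want_grad)
        grad.subvec(md.o_slope, md.o_slope + n - 1) -=
          slope / (md.slope_sd * md.slope_sd);
    }
  }
  lp += -0.5 * dot(araw, araw) / (md.rawA_sd * md.rawA_sd);
  if (want_grad)
    grad.subvec(md.o_araw, md.o_araw + md.n_araw - 1) -=
      araw / (md.rawA_sd * md.rawA_sd);
  lp += accu(-md.sigma_rate * sigma + lsig);    // Exponential prior + Jacobian
  if (want_grad)
    grad.subvec(md.o_lsig, md.o_lsig + n - 1) += -md.sigma_rate * sigma + 1.0;

  // --- smoothing priors: beta ~ N(0, S(lam)^{-1}) ---------------------------
  // Data-informed blocks (the global smooth; the independent per-species
  // smooths of the no-pooling variant) keep the centered parameterization.
  // Weakly-informed deviation blocks are non-centered,
  // beta = S(lam)^{-1/2} eta with eta ~ N(0, I), which removes their
  // lambda-beta funnel. One block for the global smooth, one per species.
  const bool dev_noncentered = md.has_global;
  uword lam_pos = 0;
  std::vector<mat> blk_L;            // lower Cholesky of S(lam)
  std::vector<mat> blk_Sl;           // penalty sums (centered blocks)
  std::vector<uword> blk_lampos;
  auto smooth_block = [&](const vec& coef, const std::vector<mat>& Slist,
                          bool centered) {
    uword J = Slist.size();
    uword k = coef.n_elem;
    mat Sl(k, k, fill::zeros);
    for (uword j = 0; j < J; ++j)
      Sl += std::exp(loglam(lam_pos + j)) * Slist[j];
    mat Lc;
    if (!chol(Lc, symmatu(Sl), "lower")) Rcpp::stop("penalty sum not PD");
    vec beta;
    if (centered) {
      beta = coef;
      double ld = 2.0 * accu(log(Lc.diag()));
      lp += 0.5 * ld - 0.5 * dot(beta, Sl * beta);
      if (want_grad) {
        mat Li = inv(trimatl(Lc));
        mat Sinv = Li.t() * Li;
        for (uword j = 0; j < J; ++j) {
          double lam = std::exp(loglam(lam_pos + j));
          grad(md.o_lam + lam_pos + j) +=
            0.5 * lam * accu(Sinv % Slist[j])
            - 0.5 * lam * dot(beta, Slist[j] * beta);
        }
      }
    } else {
      // Cholesky-factor non-centering: beta = L^{-T} eta, eta ~ N(0, I)
      // implies beta ~ N(0, S(lam)^{-1}) with its normalizing constant
      beta = solve(trimatu(Lc.t()), coef);
      lp += -0.5 * dot(coef, coef);
    }
    for (uword j = 0; j < J; ++j) {
      double lam = std::exp(loglam(lam_pos + j));
      // Gamma(shape, rate) prior on lam + log Jacobian of exp
      lp += md.lam_shape * loglam(lam_pos + j) - md.lam_rate * lam;
      if (want_grad)
        grad(md.o_lam + lam_pos + j) += md.lam_shape - md.lam_rate * lam;
    }
    blk_L.push_back(Lc); blk_Sl.push_back(Sl);
    blk_lampos.push_back(lam_pos);
    lam_pos += J;
    return beta;
  };
  vec bg_eta = bg;
  if (md.has_global) bg = smooth_block(bg, md.Sg, true);
  mat bd_eta = bd;
  for (uword d = 0; d < md.ndev; ++d)
    bd.col(d) = smooth_block(bd_eta.col(d), md.Sd, !dev_noncentered);

  // reverse pass for one smooth block given the adjoint of beta
  auto smooth_block_backward = [&](uword blk, const vec& coef,
                                   const std::vector<mat>& Slist,
                                   const vec& betabar, uword coef_off,
                                   bool centered) {
    if (centered) {
      grad.subvec(coef_off, coef_off + coef.n_elem - 1) +=
        betabar - blk_Sl[blk] * coef;
      return;
    }
    const mat& Lc = blk_L[blk];
    // beta = L^{-T} eta
    grad.subvec(coef_off, coef_off + coef.n_elem - 1) +=
      solve(trimatl(Lc), betabar) - coef;
    // W = L^{-T}: Wbar = betabar eta', Lbar = -L^{-T} Wbar' L^{-T} (lower part)
    vec Wb_l = solve(trimatu(Lc.t()), betabar);
    vec Wb_r = solve(trimatu(Lc.t()), coef);   // = beta
    mat Lbar = -(Wb_r * Wb_l.t());              // = -(L^-T Wbar^T L^-T)^T? see below
    // derivation: Lbar = -L^{-T} Wbar^T L^{-T} with Wbar = betabar eta^T,
    // so Lbar = -(L^{-T} eta)(L^{-1} betabar)^T ... compute directly:
    Lbar = -Wb_r * (solve(trimatl(Lc), betabar)).t();
    Lbar = trimatl(Lbar);
    mat Slbar = chol_rev(Lc, Lbar);
    Slbar = 0.5 * (Slbar + Slbar.t());
    for (uword j = 0; j < Slist.size(); ++j) {
      double lam = std::exp(loglam(blk_lampos[blk] + j));
      grad(md.o_lam + blk_lampos[blk] + j) += lam * accu(Slbar % Slist[j]);
    }
  };

  // --- GAM mean -------------------------------------------------------------
  mat mu(n, T, fill::zeros);
  mu.each_col() = alpha;
  if (md.has_ndvi) mu += slope * md.v.t();
  vec fg;
  if (md.has_global) {
    fg = md.Bg * bg;
    mu.each_row() += fg.t();
  }
  mat fd;
  if (md.ndev > 0) {
    fd = md.Bd * bd;                       // T x ndev
    for (uword d = 0; d < md.ndev; ++d)
      mu.row(md.dev(d)) += fd.col(d).t();
  }

  // --- dynamics: correlation, stationarity map, state reconstruction ------
  mat R(n, n, fill::zeros);
  if (md.full_A) R = reshape(araw, n, n); else R.diag() = araw;
  std::vector<vec> s_store;
  mat rmat, L;
  if (md.full_C) {
    L = build_L(md, u, lp, s_store, rmat);
  } else {
    L = eye(n, n);
  }
  mat C = L * L.t();
  mat D = diagmat(sigma);
  mat Sigma = D * C * D;
  MapCache mc = map_forward(R, Sigma);
  SqrtmCache Ssc = sqrtm_sym(symmatu(Sigma));   // Sigma^{1/2}

  // non-centered states: z_1 = Gamma^{1/2} eps_1, z_t = A z_{t-1} + S^{1/2} eps_t
  mat z(n, T);
  mat Se = Ssc.X * eps;                 // one BLAS call for all innovations
  z.col(0) = mc.G * eps.col(0);
  {
    const double* Ap = mc.A.memptr();
    const double* Sp = Se.memptr();
    double* zp = z.memptr();
    for (uword t = 1; t < T; ++t) {
      const double* zprev = zp + (t - 1) * n;
      double* zcur = zp + t * n;
      const double* scur = Sp + t * n;
      for (uword i = 0; i < n; ++i) {
        double acc = scur[i];
        for (uword j = 0; j < n; ++j) acc += Ap[i + j * n] * zprev[j];
        zcur[i] = acc;
      }
    }
  }
  lp_dyn = -0.5 * accu(eps % eps);
  lp += lp_dyn;

  // --- observation layer ----------------------------------------------------
  mat x = mu + z;
  mat ex = exp(x);
  lp_obs = accu(md.O % (md.Y % x - ex - md.lgY));
  lp += lp_obs;

  if (want_grad) {
    mat xbar = md.O % (md.Y - ex);

    // GAM mean blocks via xbar
    vec rowsum = sum(xbar, 1);
    grad.subvec(md.o_alpha, md.o_alpha + n - 1) += rowsum;
    if (md.has_ndvi) {
      vec sl_bar = xbar * md.v;
      if (md.pooled) {
        grad(md.o_slope) += accu(sl_bar);
        grad(md.o_slope + 1) += sigN * dot(sl_bar, eta);
        grad.subvec(md.o_slope + 2, md.o_slope + 1 + n) += sigN * sl_bar;
      } else {
        grad.subvec(md.o_slope, md.o_slope + n - 1) += sl_bar;
      }
    }
    uword blk = 0;
    if (md.has_global) {
      vec colsum = sum(xbar, 0).t();
      vec bgbar = md.Bg.t() * colsum;
      smooth_block_backward(blk++, bg_eta, md.Sg, bgbar, md.o_bg, true);
    }
    for (uword d = 0; d < md.ndev; ++d) {
      vec bdbar = md.Bd.t() * xbar.row(md.dev(d)).t();
      smooth_block_backward(blk++, bd_eta.col(d), md.Sd, bdbar,
                            md.o_bd + d * md.kd, !dev_noncentered);
    }

    // backward scan through the state recursion:
    // s_t = dlp/dz_t (total) = xbar_t + A' s_{t+1}
    mat sadj(n, T);
    sadj.col(T - 1) = xbar.col(T - 1);
    {
      const double* Ap = mc.A.memptr();
      const double* xp = xbar.memptr();
      double* sp = sadj.memptr();
      for (uword t = T - 1; t-- > 0; ) {
        const double* snext = sp + (t + 1) * n;
        const double* xcur = xp + t * n;
        double* scur = sp + t * n;
        for (uword i = 0; i < n; ++i) {
          double acc = xcur[i];
          for (uword j = 0; j < n; ++j) acc += Ap[j + i * n] * snext[j];
          scur[i] = acc;
        }
      }
    }

    // all time-summed adjoints as single matrix products
    mat epsbar = Ssc.X.t() * sadj;
    epsbar.col(0) = mc.G.t() * sadj.col(0);
    mat Abar = sadj.cols(1, T - 1) * z.cols(0, T - 2).t();
    mat Ssbar = sadj.cols(1, T - 1) * eps.cols(1, T - 1).t();
    mat Gbar_extra = sadj.col(0) * eps.col(0).t();
    epsbar -= eps;   // standard-normal innovation prior
    grad.subvec(md.o_z, md.o_z + n * T - 1) += vectorise(epsbar);

    // dynamics adjoints back to raw parameters
    mat Sigmabar = sqrtm_adj(Ssc, Ssbar);
    mat Gammabar(n, n, fill::zeros);
    mat Rbar(n, n, fill::zeros);
    map_backward(mc, Abar, Gammabar, Gbar_extra, Rbar, Sigmabar);
    if (md.full_A)
      grad.subvec(md.o_araw, md.o_araw + n * n - 1) += vectorise(Rbar);
    else
      grad.subvec(md.o_araw, md.o_araw + n - 1) += Rbar.diag();

    // Sigma = D (L L') D
    mat Sb = 0.5 * (Sigmabar + Sigmabar.t());
    mat Cbar = D * Sb * D;
    for (uword i = 0; i < n; ++i) {
      double sb = 2.0 * dot(Sb.row(i).t() % (C.row(i).t()), sigma);
      grad(md.o_lsig + i) += sb * sigma(i);               // chain log sigma
    }
    if (md.full_C) {
      mat Lbar = (Cbar + Cbar.t()) * L;
      vec ubar(md.n_u, fill::zeros);
      build_L_backward(md, Lbar, s_store, rmat, ubar);
      grad.subvec(md.o_u, md.o_u + md.n_u - 1) += ubar;
    }
  }

  parts(0) = lp_obs; parts(1) = lp_dyn; parts(2) = lp - lp_obs - lp_dyn;
  return lp;
}

// [[Rcpp::export]]
Rcpp::List cpp_logpost(const arma::vec& theta, const Rcpp::List& data,
                       bool want_grad = true) {
  ModelData md = parse_data(data);
  if (theta.n_elem != md.dim) Rcpp::stop("theta has wrong length");
  vec grad, parts;
  double lp = logpost(md, theta, grad, want_grad, parts);
  return Rcpp::List::create(
    Rcpp::Named("lp") = lp, Rcpp::Named("grad") = grad,
    Rcpp::Named("parts") = Rcpp::NumericVector::create(
      Rcpp::Named("obs") = parts(0), Rcpp::Named("dyn") = parts(1),
      Rcpp::Named("prior") = parts(2)));
}

// ---------------------------------------------------------------------------
// No-U-Turn sampler (slice variant) with dual-averaging step size and
// diagonal mass-matrix adaptation over an expanding warmup window schedule
// ---------------------------------------------------------------------------

typedef std::function<double(const vec&, vec&)> LogPostFn;

struct NutsState {
  vec theta, r, grad;
  double logp;
};

struct NutsControl {
  int max_treedepth = 10;
  double delta = 0.8;
  double deltamax = 1000.0;
};

class Nuts {
public:
  // dense_dim: leading parameter block that gets a dense mass matrix
  // (structural parameters); the remaining dimensions (latent-state
  // innovations) keep a diagonal metric.
  Nuts(LogPostFn f, uword dim, const NutsControl& ctrl, uword dense_dim = 0)
    : f_(f), dim_(dim), ctrl_(ctrl), minv_(dim, fill::ones),
      p_dense_(std::min(dense_dim, dim)) {}

  double eval(const vec& th, vec& gr) {
    double lp = f_(th, gr);
    if (!std::isfinite(lp)) { lp = -datum::inf; gr.zeros(); }
    return lp;
  }

  // velocity M^{-1} r under the (block dense + diagonal) metric
  vec vel(const vec& r) {
    vec v = minv_ % r;
    if (dense_ready_)
      v.head(p_dense_) = Sd_ * r.head(p_dense_);
    return v;
  }

  void leapfrog(vec& th, vec& r, vec& gr, double& lp, double eps) {
    r += 0.5 * eps * gr;
    th += eps * vel(r);
    lp = eval(th, gr);
    r += 0.5 * eps * gr;
  }

  double joint(double lp, const vec& r) {
    return lp - 0.5 * dot(vel(r), r);
  }

  vec draw_momentum() {
    vec r(dim_);
    for (uword i = 0; i < dim_; ++i) r(i) = norm_rand() / std::sqrt(minv_(i));
    if (dense_ready_) {
      vec xi(p_dense_);
      for (uword i = 0; i < p_dense_; ++i) xi(i) = norm_rand();
      r.head(p_dense_) = Lmom_ * xi;
    }
    return r;
  }

  // recursive tree building (Hoffman & Gelman, Alg. 6)
  struct Tree {
    vec thm, rm, gm, thp, rp, gp, thprime, gprime;
    double lpm, lpp, lpprime;
    double nprime, alpha, nalpha;
    bool sprime;
  };

  Tree build_tree(const vec& th, const vec& r, const vec& g, double lp,
                  double logu, int dir, int depth, double eps, double joint0) {
    Tree t;
    if (depth == 0) {
      vec th1 = th, r1 = r, g1 = g; double lp1 = lp;
      leapfrog(th1, r1, g1, lp1, dir * eps);
      double j1 = joint(lp1, r1);
      t.thm = th1; t.rm = r1; t.gm = g1; t.lpm = lp1;
      t.thprime = std::move(th1); t.gprime = std::move(g1); t.lpprime = lp1;
      t.thp = t.thm; t.rp = std::move(r1); t.gp = t.gm; t.lpp = lp1;
      t.nprime = (logu <= j1) ? 1.0 : 0.0;
      t.sprime = (logu < ctrl_.deltamax + j1);
      if (!t.sprime) ++n_divergent_;
      double a = j1 - joint0;
      t.alpha = std::min(1.0, std::exp(a));
      if (!std::isfinite(t.alpha)) t.alpha = 0.0;
      t.nalpha = 1.0;
      return t;
    }
    Tree t1 = build_tree(th, r, g, lp, logu, dir, depth - 1, eps, joint0);
    if (!t1.sprime) return t1;
    Tree t2;
    if (dir == -1) {
      t2 = build_tree(t1.thm, t1.rm, t1.gm, t1.lpm, logu, dir, depth - 1,
                      eps, joint0);
      t1.thm = std::move(t2.thm); t1.rm = std::move(t2.rm);
      t1.gm = std::move(t2.gm); t1.lpm = t2.lpm;
    } else {
      t2 = build_tree(t1.thp, t1.rp, t1.gp, t1.lpp, logu, dir, depth - 1,
                      eps, joint0);
      t1.thp = std::move(t2.thp); t1.rp = std::move(t2.rp);
      t1.gp = std::move(t2.gp); t1.lpp = t2.lpp;
    }
    double ntot = t1.nprime + t2.nprime;
    if (ntot > 0 && unif_rand() < t2.nprime / ntot) {
      t1.thprime = std::move(t2.thprime); t1.gprime = std::move(t2.gprime);
      t1.lpprime = t2.lpprime;
    }
    t1.alpha += t2.alpha; t1.nalpha += t2.nalpha;
    vec dth = t1.thp - t1.thm;
    bool noturn = (dot(dth, vel(t1.rm)) >= 0) &&
                  (dot(dth, vel(t1.rp)) >= 0);
    t1.sprime = t2.sprime && noturn;
    t1.nprime = ntot;
    return t1;
  }

  double find_initial_eps(const vec& th0) {
    vec g0(dim_);
    double lp0 = eval(th0, g0);
    double eps = 1.0;
    vec r0 = draw_momentum();
    double j0 = joint(lp0, r0);
    vec th = th0, r = r0, g = g0; double lp = lp0;
    leapfrog(th, r, g, lp, eps);
    double j1 = joint(lp, r);
    double a = (std::isfinite(j1) ? j1 : -datum::inf) - j0;
    int dir = (a > std::log(0.5)) ? 1 : -1;
    for (int it = 0; it < 50; ++it) {
      th = th0; r = r0; g = g0; lp = lp0;
      leapfrog(th, r, g, lp, eps);
      j1 = joint(lp, r);
      a = (std::isfinite(j1) ? j1 : -datum::inf) - j0;
      if (dir == 1 && !(a > std::log(0.5))) break;
      if (dir == -1 && !(a < std::log(0.5))) break;
      eps *= (dir == 1) ? 2.0 : 0.5;
      if (eps < 1e-10 || eps > 1e7) break;
    }
    return eps;
  }

  Rcpp::List run(const vec& theta0, int warmup, int iter) {
    vec theta = theta0, grad(dim_);
    double lp = eval(theta, grad);
    if (!std::isfinite(lp)) Rcpp::stop("initial point has non-finite density");

    double eps = find_initial_eps(theta);
    double mu = std::log(10.0 * eps), logeps = std::log(eps), logepsbar = 0.0;
    double Hbar = 0.0;
    const double da_gamma = 0.05, t0 = 10.0, kappa = 0.75;
    int da_m = 0;

    // mass-adaptation window schedule
    int init_buf = std::min(75, (int)std::floor(0.15 * warmup));
    int term_buf = std::min(50, (int)std::floor(0.10 * warmup));
    int wstart = init_buf, wsize = 25;
    std::vector<int> window_ends;
    if (warmup - init_buf - term_buf > 20) {
      int pos = wstart;
      int size = wsize;
      while (pos + size < warmup - term_buf) {
        if (pos + 3 * size >= warmup - term_buf) size = warmup - term_buf - pos;
        window_ends.push_back(pos + size);
        pos += size;
        size *= 2;
      }
      if (window_ends.empty() || window_ends.back() != warmup - term_buf)
        window_ends.push_back(warmup - term_buf);
    }
    size_t wi = 0;
    running_stat_vec<vec> acc;
    running_stat_vec<rowvec> acc_dense(true);   // with covariance

    mat draws(iter, dim_);
    vec lps(iter), accept(iter);
    ivec depths(iter);
    n_divergent_ = 0;
    int div_sampling = 0;

    for (int m = 0; m < warmup + iter; ++m) {
      if (m == warmup) n_divergent_ = 0;   // report post-warmup divergences
      vec r0 = draw_momentum();
      double joint0 = joint(lp, r0);
      double logu = joint0 - exp_rand();
      Tree t;
      t.thm = theta; t.rm = r0; t.gm = grad; t.lpm = lp;
      t.thp = theta; t.rp = r0; t.gp = grad; t.lpp = lp;
      t.thprime = theta; t.gprime = grad; t.lpprime = lp;
      t.nprime = 1.0; t.sprime = true; t.alpha = 0; t.nalpha = 0;
      double ntot = 1.0;
      int depth = 0;
      double cur_eps = (m < warmup) ? std::exp(logeps) : std::exp(logepsbar);
      while (t.sprime && depth < ctrl_.max_treedepth) {
        int dir = (unif_rand() < 0.5) ? -1 : 1;
        Tree t2;
        if (dir == -1) {
          t2 = build_tree(t.thm, t.rm, t.gm, t.lpm, logu, dir, depth,
                          cur_eps, joint0);
          t.thm = std::move(t2.thm); t.rm = std::move(t2.rm);
          t.gm = std::move(t2.gm); t.lpm = t2.lpm;
        } else {
          t2 = build_tree(t.thp, t.rp, t.gp, t.lpp, logu, dir, depth,
                          cur_eps, joint0);
          t.thp = std::move(t2.thp); t.rp = std::move(t2.rp);
          t.gp = std::move(t2.gp); t.lpp = t2.lpp;
        }
        if (t2.sprime && unif_rand() < std::min(1.0, t2.nprime / ntot)) {
          t.thprime = std::move(t2.thprime); t.gprime = std::move(t2.gprime);
          t.lpprime = t2.lpprime;
        }
        ntot += t2.nprime;
        t.alpha = t2.alpha; t.nalpha = t2.nalpha;
        vec dth = t.thp - t.thm;
        bool noturn = (dot(dth, vel(t.rm)) >= 0) &&
                      (dot(dth, vel(t.rp)) >= 0);
        t.sprime = t2.sprime && noturn;
        ++depth;
      }
      theta = t.thprime; grad = t.gprime; lp = t.lpprime;
      double astat = (t.nalpha > 0) ? t.alpha / t.nalpha : 0.0;

      if (m < warmup) {
        ++da_m;
        Hbar = (1.0 - 1.0 / (da_m + t0)) * Hbar +
               (ctrl_.delta - astat) / (da_m + t0);
        logeps = mu - std::sqrt((double)da_m) / da_gamma * Hbar;
        double pw = std::pow((double)da_m, -kappa);
        logepsbar = pw * logeps + (1.0 - pw) * logepsbar;
        // mass-matrix windows
        if (m >= init_buf && wi < window_ends.size()) {
          acc(theta);
          if (p_dense_ > 0) acc_dense(theta.head(p_dense_).t());
          if (m + 1 == window_ends[wi]) {
            double cnt = acc.count();
            if (cnt >= 10) {
              vec vv = acc.var();
              minv_ = (cnt / (cnt + 5.0)) * vv +
                      (5.0 / (cnt + 5.0)) * 1e-3 * vec(dim_, fill::ones);
              minv_.clamp(1e-10, 1e10);
              // dense block: installed once, at the last window, from the
              // covariance accumulated over all post-init-buffer warmup
              // draws, shrunk toward the diagonal so the estimate stays
              // well conditioned
              double dcnt = acc_dense.count();
              if (p_dense_ > 0 && wi + 1 == window_ends.size() &&
                  dcnt >= 2.0 * p_dense_) {
                double cnt2 = dcnt;
                mat cv = symmatu(acc_dense.cov());
                double w = cnt2 / (cnt2 + (double)p_dense_);
                mat Sd = w * cv +
                         (1.0 - w) * diagmat(vv.head(p_dense_)) +
                         1e-8 * eye(p_dense_, p_dense_);
                mat Lc;
                bool ok = chol(Lc, symmatu(Sd), "lower");
                if (!ok) {
                  Sd += 1e-5 * diagmat(vv.head(p_dense_)) +
                        1e-8 * eye(p_dense_, p_dense_);
                  ok = chol(Lc, symmatu(Sd), "lower");
                }
                if (ok) {
                  Sd_ = Sd;
                  Lmom_ = inv(trimatl(Lc)).t();
                  dense_ready_ = true;
                }
              }
            }
            acc.reset();
            // restart step-size adaptation around the current value
            eps = std::exp(logeps);
            mu = std::log(10.0 * eps);
            Hbar = 0.0; da_m = 0; logepsbar = std::log(eps);
            ++wi;
          }
        }
      } else {
        draws.row(m - warmup) = theta.t();
        lps(m - warmup) = lp;
        accept(m - warmup) = astat;
        depths(m - warmup) = depth;
      }
      if ((m & 0x3f) == 0) Rcpp::checkUserInterrupt();
    }
    div_sampling = n_divergent_;
    return Rcpp::List::create(
      Rcpp::Named("draws") = draws, Rcpp::Named("lp") = lps,
      Rcpp::Named("accept") = accept, Rcpp::Named("treedepth") = depths,
      Rcpp::Named("divergences") = div_sampling,
      Rcpp::Named("stepsize") = std::exp(logepsbar),
      Rcpp::Named("inv_mass") = minv_);
  }

private:
  LogPostFn f_;
  uword dim_;
  NutsControl ctrl_;
  vec minv_;
  uword p_dense_ = 0;
  mat Sd_, Lmom_;
  bool dense_ready_ = false;
  int n_divergent_ = 0;
};

// [[Rcpp::export]]
Rcpp::List cpp_nuts(const Rcpp::List& data, const arma::vec& theta0,
                    int warmup, int iter, int max_treedepth = 10,
                    double delta = 0.8, bool dense_mass = true) {
  Rcpp::RNGScope scope;
  ModelData md = parse_data(data);
  if (theta0.n_elem != md.dim) Rcpp::stop("theta0 has wrong length");
  NutsControl ctrl;
  ctrl.max_treedepth = max_treedepth;
  ctrl.delta = delta;
  LogPostFn f = [&md](const vec& th, vec& gr) -> double {
    vec parts;
    double lp;
    try {
      lp = logpost(md, th, gr, true, parts);
    } catch (...) {
      gr.zeros(md.dim);
      return -datum::inf;
    }
    return lp;
  };
  uword dyn_block = md.n_araw + md.n + md.n_u;   // raw A, log sigma, u
  Nuts sampler(f, md.dim, ctrl, dense_mass ? dyn_block : 0);
  return sampler.run(theta0, warmup, iter);
}

// conjugate Poisson-Gamma toy model on theta = log(rate); used to validate
// the sampler against the closed-form Gamma(a + sum y, b + n) posterior
// [[Rcpp::export]]
Rcpp::List cpp_nuts_poisson_gamma(const arma::vec& y, double a, double b,
                                  int warmup, int iter) {
  Rcpp::RNGScope scope;
  double sy = accu(y);
  double nn = (double)y.n_elem;
  LogPostFn f = [&](const vec& th, vec& gr) -> double {
    double lam = std::exp(th(0));
    gr.set_size(1);
    gr(0) = (a + sy) - (b + nn) * lam;
    return (a + sy) * th(0) - (b + nn) * lam;
  };
  NutsControl ctrl;
  Nuts sampler(f, 1, ctrl);
  return sampler.run(vec(1, fill::zeros), warmup, iter);
}

// batch spectral radii of mapped matrices: each row of Rflat is one
// vectorized n x n unconstrained matrix
// [[Rcpp::export]]
arma::vec cpp_map_spectral_radii(const arma::mat& Rflat, const arma::mat& Sigma) {
  uword n = Sigma.n_rows;
  vec out(Rflat.n_rows);
  for (uword i = 0; i < Rflat.n_rows; ++i) {
    mat R = reshape(Rflat.row(i).t(), n, n);
    MapCache m = map_forward(R, Sigma);
    cx_vec ev = eig_gen(m.A);
    out(i) = abs(ev).max();
  }
  return out;
}

// discrete Lyapunov solve: Gamma = A Gamma A' + Sigma, via Kronecker system
// [[Rcpp::export]]
arma::mat cpp_lyapunov(const arma::mat& A, const arma::mat& Sigma) {
  uword n = A.n_rows;
  mat K = eye(n * n, n * n) - kron(A, A);
  vec g = solve(K, vectorise(Sigma));
  mat Gamma = reshape(g, n, n);
  return 0.5 * (Gamma + Gamma.t());
}
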