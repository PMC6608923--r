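#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOG2PI = std::log(2.0 * M_PI);

// Shared filter recursion. Rows of y may contain NaN: those entries are
// treated as missing and the measurement update uses only the finite ones
// (a fully-missing row propagates the prediction untouched).
// Joseph-form covariance update + symmetrization each step; innovation
// system solved through the Cholesky factor, never an explicit inverse.
static double filter_core(const mat& y, const mat& F, const mat& G,
                          const mat& W, const mat& V,
                          const vec& m0, const mat& C0,
                          bool store,
                          mat& a_out, cube& R_out, mat& m_out, cube& C_out) {
  const uword T = y.n_rows, p = G.n_rows;
  vec m = m0;
  mat Cf = C0;
  double ll = 0.0;
  if (store) {
    a_out.set_size(p, T); R_out.set_size(p, p, T);
    m_out.set_size(p, T); C_out.set_size(p, p, T);
  }
  const mat Ip = eye(p, p);
  for (uword t = 0; t < T; ++t) {
    vec a = G * m;
    mat Rp = G * Cf * G.t() + W;
    Rp = 0.5 * (Rp + Rp.t());

    vec yt = y.row(t).t();
    uvec obs = find_finite(yt);
    vec mnew;
    mat Cnew;
    if (obs.n_elem == 0) {
      mnew = a;
      Cnew = Rp;
    } else {
      mat Fo = F.rows(obs);
      mat Vo = V.submat(obs, obs);
      vec yo = yt.elem(obs);
      mat Q = Fo * Rp * Fo.t() + Vo;
      Q = 0.5 * (Q + Q.t());
      mat L;
      if (!chol(L, Q, "lower"))
        Rcpp::stop("innovation covariance not positive definite at time %d",
                   (int)(t + 1));
      vec v = yo - Fo * a;
      vec z = solve(trimatl(L), v);
      ll += -0.5 * obs.n_elem * LOG2PI - accu(log(L.diag())) - 0.5 * dot(z, z);
      // K = Rp Fo' Q^{-1}, via two triangular solves
      mat FoRp = Fo * Rp;                          // k x p
      mat K = solve(trimatu(L.t()), solve(trimatl(L), FoRp)).t();  // p x k
      mnew = a + K * v;
      mat ImKF = Ip - K * Fo;
      Cnew = ImKF * Rp * ImKF.t() + K * Vo * K.t();
      Cnew = 0.5 * (Cnew + Cnew.t());
    }
    if (store) {
      a_out.col(t) = a; R_out.slice(t) = Rp;
      m_out.col(t) = mnew; C_out.slice(t) = Cnew;
    }
    m = mnew;
    Cf = Cnew;
  }
  return ll;
}

// [[Rcpp::export]]
double kf_loglik_cpp(const arma::mat& y, const arma::mat& F, const arma::mat& G,
                     const arma::mat& W, const arma::mat& V,
                     const arma::vec& m0, const arma::mat& C0) {
  mat a, m; cube R, C;
  return filter_core(y, F, G, W, V, m0, C0, false, a, R, m, C);
}

// [[Rcpp::export]]
Rcpp::List kf_filter_cpp(const arma::mat& y, const arma::mat& F,
                         const arma::mat& G, const arma::mat& W,
                         const arma::mat& V, const arma::vec& m0,
                         const arma::mat& C0) {
  mat a, m; cube R, C;
  double ll = filter_core(y, F, G, W, V, m0, C0, true, a, R, m, C);
  return Rcpp::List::create(
    Rcpp::Named("loglik") = ll,
    Rcpp::Named("pred_mean") = a, Rcpp::Named("pred_cov") = R,
    Rcpp::Named("filt_mean") = m, Rcpp::Named("filt_cov") = C);
}

static mat sympd_solve(const mat& A, const mat& B) {
  mat X;
  if (!solve(X, A, B, solve_opts::likely_sympd))
    Rcpp::stop("singular one-step prediction covariance in backward recursion");
  return X;
}

// Fixed-interval (RTS) smoother over stored filter output; returns moments
// for t = 0..T with row/slice 0 holding the initial-state posterior.
// [[Rcpp::export]]
Rcpp::List rts_smooth_cpp(const arma::mat& a, const arma::cube& R,
                          const arma::mat& m, const arma::cube& C,
                          const arma::mat& G, const arma::vec& m0,
                          const arma::mat& C0) {
  const uword T = a.n_cols, p = G.n_rows;
  mat s(p, T + 1);
  cube S(p, p, T + 1);
  s.col(T) = m.col(T - 1);
  S.slice(T) = C.slice(T - 1);
  for (uword t = T - 1; t-- > 0; ) {
    // smooth theta_{t+1} (1-based) using filtered moments at t+1 and
    // prediction at t+2; loop variable t runs T-2 .. 0
    mat J = sympd_solve(R.slice(t + 1), G * C.slice(t)).t();  // C_t G' R_{t+1}^{-1}
    s.col(t + 1) = m.col(t) + J * (s.col(t + 2) - a.col(t + 1));
    mat Sm = C.slice(t) + J * (S.slice(t + 2) - R.slice(t + 1)) * J.t();
    S.slice(t + 1) = 0.5 * (Sm + Sm.t());
  }
  mat J0 = sympd_solve(R.slice(0), G * C0).t();
  s.col(0) = m0 + J0 * (s.col(1) - a.col(0));
  mat S0 = C0 + J0 * (S.slice(1) - R.slice(0)) * J0.t();
  S.slice(0) = 0.5 * (S0 + S0.t());
  return Rcpp::List::create(Rcpp::Named("mean") = s, Rcpp::Named("cov") = S);
}

// Square root of a symmetric PSD matrix by eigendecomposition with
// negative eigenvalues clipped to zero (exact for degenerate covariances).
static mat psd_sqrt(const mat& A) {
  vec ev; mat V;
  eig_sym(ev, V, 0.5 * (A + A.t()));
  ev.transform([](double x) { return x > 0.0 ? std::sqrt(x) : 0.0; });
  return V * diagmat(ev);
}

static vec rnorm_vec(uword n) {
  vec z(n);
  for (uword i = 0; i < n; ++i) z(i) = R::norm_rand();
  return z;
}

// Forward-filtering backward-sampling. The evolution covariance
// R_sel Sd R_sel' is rank-deficient (noise enters only the slope
// coordinates), so the backward pass samples the C-dimensional slope
// disturbance delta_t | theta_t, Y_{1:t-1} and reconstructs
// theta_{t-1} = G^{-1} (theta_t - R_sel delta_t) exactly.
// Returns a cube p x (T+1) x ndraws; column 0 is theta_0.
// [[Rcpp::export]]
arma::cube ffbs_cpp(const arma::mat& a, const arma::cube& R,
                    const arma::mat& m, const arma::cube& C,
                    const arma::mat& G, const arma::mat& Ginv,
                    const arma::mat& Rsel, const arma::mat& Sd,
                    const arma::vec& m0, const arma::mat& C0,
                    int ndraws) {
  const uword T = a.n_cols, p = G.n_rows, Cdim = Sd.n_rows;
  // precompute gain and conditional covariance factor for each backward step
  std::vector<mat> M(T), Lc(T);
  mat SdR = Sd * Rsel.t();  // C x p
  for (uword t = 0; t < T; ++t) {
    M[t] = sympd_solve(R.slice(t), SdR.t()).t();        // Sd R' Rp_t^{-1}
    mat Cc = Sd - M[t] * Rsel * Sd;
    Lc[t] = psd_sqrt(Cc);
  }
  mat LT = psd_sqrt(C.slice(T - 1));
  cube out(p, T + 1, ndraws);
  for (int d = 0; d < ndraws; ++d) {
    vec th = m.col(T - 1) + LT * rnorm_vec(p);
    out.slice(d).col(T) = th;
    for (uword t = T; t-- > 0; ) {
      vec delta = M[t] * (th - a.col(t)) + Lc[t] * rnorm_vec(Cdim);
      th = Ginv * (th - Rsel * delta);
      out.slice(d).col(t) = th;
    }
  }
  return out;
}
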