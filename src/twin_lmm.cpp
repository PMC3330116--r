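// Variance-components engine for twin cohorts.
//
// The marginal covariance of a family block is
//   cov(co-twins) = s2f + s2z * 1[MZ],   var = s2f + s2z * 1[MZ] + s2e,
// i.e. a family random intercept plus an extra MZ-pair intercept. An
// orthogonal within-pair rotation ((y1+y2)/sqrt2, (y1-y2)/sqrt2) diagonalizes
// every 2x2 block, so after rotation each row has variance s2e * u with u
// depending only on its class:
//   class 0: lone non-MZ individual        u = 1 + lf
//   class 1: lone individual from MZ pair  u = 1 + lf + lz
//   class 2: within-pair difference        u = 1
//   class 3: DZ pair sum                   u = 1 + 2 lf
//   class 4: MZ pair sum                   u = 1 + 2 lf + 2 lz
// with lf = s2f/s2e, lz = s2z/s2e. GLS then reduces to weighted least squares
// with at most five distinct weights, and the profile log-likelihood needs
// only per-class crossproducts, making each fit O(p^3) after an O(n p)
// setup. That is what lets permutation FDR re-run whole scans.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static const int NCLASS = 5;

static inline void class_u(double lf, double lz, double* u) {
  u[0] = 1.0 + lf;
  u[1] = 1.0 + lf + lz;
  u[2] = 1.0;
  u[3] = 1.0 + 2.0 * lf;
  u[4] = 1.0 + 2.0 * lf + 2.0 * lz;
}

// Profiled (over beta and s2e) -2 log likelihood from per-class crossproducts.
struct BlockLik {
  std::vector<mat> A;   // per class: X_c' X_c  (p x p)
  std::vector<vec> b;   // per class: X_c' y_c
  vec yy;               // per class: y_c' y_c
  ivec nc;              // per class row counts
  int n = 0, p = 0;
  bool reml = false;

  // refreshed by eval()
  vec beta;
  mat Aw;
  double s2e = NA_REAL;

  double eval(double lf, double lz) {
    double u[NCLASS];
    class_u(lf, lz, u);
    Aw.zeros(p, p);
    vec bw(p, fill::zeros);
    double yyw = 0.0, sumlog = 0.0;
    for (int c = 0; c < NCLASS; ++c) {
      if (nc[c] == 0) continue;
      double w = 1.0 / u[c];
      Aw += w * A[c];
      bw += w * b[c];
      yyw += w * yy[c];
      sumlog += nc[c] * std::log(u[c]);
    }
    bool ok = solve(beta, Aw, bw, solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok) beta = pinv(Aw) * bw;
    double rss = yyw - dot(bw, beta);
    if (!(rss > 0.0)) rss = 1e-300;          // perfect fit: clamp, p underflows
    double val;
    if (!reml) {
      s2e = rss / n;
      val = n * (std::log(2.0 * M_PI) + 1.0 + std::log(s2e)) + sumlog;
    } else {
      int nr = n - p;
      s2e = rss / nr;
      double ldet, sign;
      log_det(ldet, sign, Aw);
      val = nr * (std::log(2.0 * M_PI) + 1.0 + std::log(s2e)) + sumlog + ldet;
    }
    return val;
  }
};

// lambda = exp(t) with t clamped; boundary (lambda -> 0) reachable to 1e-8.
static inline double t2l(double t) {
  if (t < -18.0) t = -18.0;
  if (t > 12.0) t = 12.0;
  return std::exp(t);
}

struct OptOut {
  double lf = 0.0, lz = 0.0, obj = NA_REAL;
  bool conv = true;
  int iters = 0;
};

// Nelder-Mead on log-variance-ratio scale, dimension 1 or 2.
static OptOut nm_optimize(BlockLik& lik, bool freef, bool freez,
                          double tf0, double tz0, int maxit, double tol) {
  OptOut out;
  int d = (freef ? 1 : 0) + (freez ? 1 : 0);
  auto fobj = [&](const double* t) {
    double lf = 0.0, lz = 0.0;
    int k = 0;
    if (freef) lf = t2l(t[k++]);
    if (freez) lz = t2l(t[k++]);
    return lik.eval(lf, lz);
  };
  if (d == 0) {
    out.obj = lik.eval(0.0, 0.0);
    return out;
  }
  const int np = d + 1;
  std::vector<std::array<double, 2>> pts(np);
  std::vector<double> fv(np);
  double start[2];
  int k = 0;
  if (freef) start[k++] = tf0;
  if (freez) start[k++] = tz0;
  for (int i = 0; i < np; ++i) {
    pts[i] = {start[0], d > 1 ? start[1] : 0.0};
    if (i > 0) pts[i][i - 1] += 1.0;
    fv[i] = fobj(pts[i].data());
  }
  int it = 0;
  bool conv = false;
  for (; it < maxit; ++it) {
    // order
    for (int i = 0; i < np; ++i)
      for (int j = i + 1; j < np; ++j)
        if (fv[j] < fv[i]) { std::swap(fv[i], fv[j]); std::swap(pts[i], pts[j]); }
    if (std::fabs(fv[np - 1] - fv[0]) < tol * (1.0 + std::fabs(fv[0]))) { conv = true; break; }
    std::array<double, 2> cen = {0.0, 0.0};
    for (int i = 0; i < np - 1; ++i)
      for (int j = 0; j < d; ++j) cen[j] += pts[i][j] / (np - 1);
    std::array<double, 2> xr, xe, xc;
    for (int j = 0; j < d; ++j) xr[j] = cen[j] + (cen[j] - pts[np - 1][j]);
    double fr = fobj(xr.data());
    if (fr < fv[0]) {
      for (int j = 0; j < d; ++j) xe[j] = cen[j] + 2.0 * (cen[j] - pts[np - 1][j]);
      double fe = fobj(xe.data());
      if (fe < fr) { pts[np - 1] = xe; fv[np - 1] = fe; }
      else { pts[np - 1] = xr; fv[np - 1] = fr; }
    } else if (fr < fv[np - 2]) {
      pts[np - 1] = xr; fv[np - 1] = fr;
    } else {
      for (int j = 0; j < d; ++j) xc[j] = cen[j] + 0.5 * (pts[np - 1][j] - cen[j]);
      double fc = fobj(xc.data());
      if (fc < fv[np - 1]) { pts[np - 1] = xc; fv[np - 1] = fc; }
      else {
        for (int i = 1; i < np; ++i) {
          for (int j = 0; j < d; ++j) pts[i][j] = pts[0][j] + 0.5 * (pts[i][j] - pts[0][j]);
          fv[i] = fobj(pts[i].data());
        }
      }
    }
  }
  // best point
  int ibest = 0;
  for (int i = 1; i < np; ++i) if (fv[i] < fv[ibest]) ibest = i;
  k = 0;
  if (freef) out.lf = t2l(pts[ibest][k++]);
  if (freez) out.lz = t2l(pts[ibest][k++]);
  out.obj = lik.eval(out.lf, out.lz);   // refresh beta/s2e/Aw at optimum
  out.conv = conv;
  out.iters = it;
  return out;
}

// Method-of-moments start values on the log-ratio scale.
static void mom_start(const BlockLik& lik, double& tf0, double& tz0) {
  // OLS (u = 1) residual second moments per class
  BlockLik tmp = lik;
  tmp.reml = false;
  tmp.eval(0.0, 0.0);
  vec beta = tmp.beta;
  double vc[NCLASS];
  for (int c = 0; c < NCLASS; ++c) {
    if (lik.nc[c] == 0) { vc[c] = NA_REAL; continue; }
    double rss = lik.yy[c] - 2.0 * dot(lik.b[c], beta) +
                 as_scalar(beta.t() * lik.A[c] * beta);
    vc[c] = rss / lik.nc[c];
  }
  double se = (lik.nc[2] > 0 && vc[2] > 0) ? vc[2] : 1.0;
  double lf = 0.1, lz = 0.1;
  if (lik.nc[3] > 0) lf = std::max((vc[3] / se - 1.0) / 2.0, 1e-3);
  else if (lik.nc[0] > 0) lf = std::max(vc[0] / se - 1.0, 1e-3);
  if (lik.nc[4] > 0) lz = std::max((vc[4] / se - 1.0) / 2.0 - lf, 1e-3);
  tf0 = std::log(std::max(lf, 1e-3));
  tz0 = std::log(std::max(lz, 1e-3));
}

static void fill_classes(BlockLik& lik, const mat& X, const vec& y, const ivec& type) {
  int n = X.n_rows, p = X.n_cols;
  lik.n = n; lik.p = p;
  lik.A.assign(NCLASS, mat(p, p, fill::zeros));
  lik.b.assign(NCLASS, vec(p, fill::zeros));
  lik.yy.zeros(NCLASS);
  lik.nc.zeros(NCLASS);
  for (int i = 0; i < n; ++i) {
    int c = type[i];
    rowvec xi = X.row(i);
    lik.A[c] += xi.t() * xi;
    lik.b[c] += xi.t() * y[i];
    lik.yy[c] += y[i] * y[i];
    lik.nc[c] += 1;
  }
}

// Single model fit on pre-rotated data.
// [[Rcpp::export]]
List cpp_twin_fit(const arma::mat& X, const arma::vec& y, const arma::ivec& type,
                  bool reml, bool est_fam, bool est_mz,
                  int maxit = 200, double tol = 1e-8) {
  BlockLik lik;
  fill_classes(lik, X, y, type);
  lik.reml = reml;
  double tf0, tz0;
  mom_start(lik, tf0, tz0);
  OptOut o = nm_optimize(lik, est_fam, est_mz, tf0, tz0, maxit, tol);
  mat cov;
  bool ok = inv_sympd(cov, lik.Aw);
  if (!ok) cov = pinv(lik.Aw);
  cov *= lik.s2e;
  vec se = sqrt(cov.diag());
  return List::create(
      _["beta"] = lik.beta, _["se"] = se, _["vcov"] = cov,
      _["s2e"] = lik.s2e, _["s2f"] = o.lf * lik.s2e, _["s2z"] = o.lz * lik.s2e,
      _["loglik"] = -0.5 * o.obj, _["converged"] = o.conv, _["iters"] = o.iters,
      _["n"] = lik.n, _["p"] = lik.p);
}

// Association scan: for each test (iy, ig) fit y ~ X0 + g by ML (full) and
// y ~ X0 (null). Tests must be grouped by iy so the null fit is reused.
// [[Rcpp::export]]
List cpp_twin_assoc(const arma::mat& Y, const arma::mat& X0, const arma::mat& G,
                    const arma::ivec& iy, const arma::ivec& ig, const arma::ivec& type,
                    bool est_fam, bool est_mz, int maxit = 200, double tol = 1e-8) {
  const int n = X0.n_rows, p0 = X0.n_cols, K = G.n_cols, M = iy.n_elem;
  // per-class row indices
  std::vector<uvec> idx(NCLASS);
  {
    std::vector<std::vector<uword>> tmp(NCLASS);
    for (int i = 0; i < n; ++i) tmp[type[i]].push_back(i);
    for (int c = 0; c < NCLASS; ++c) idx[c] = uvec(tmp[c]);
  }
  // base crossproducts per class
  std::vector<mat> A0(NCLASS), Xc(NCLASS), Gc(NCLASS);
  std::vector<mat> Vc(NCLASS);  // p0 x K
  std::vector<rowvec> Sc(NCLASS);
  ivec ncount(NCLASS, fill::zeros);
  for (int c = 0; c < NCLASS; ++c) {
    ncount[c] = idx[c].n_elem;
    if (ncount[c] == 0) {
      A0[c].zeros(p0, p0); Vc[c].zeros(p0, K); Sc[c].zeros(K);
      continue;
    }
    Xc[c] = X0.rows(idx[c]);
    Gc[c] = G.rows(idx[c]);
    A0[c] = Xc[c].t() * Xc[c];
    Vc[c] = Xc[c].t() * Gc[c];
    Sc[c] = sum(square(Gc[c]), 0);
  }

  BlockLik full, nul;
  full.n = n; full.p = p0 + 1; full.reml = false;
  nul.n = n; nul.p = p0; nul.reml = false;
  full.A.assign(NCLASS, mat(p0 + 1, p0 + 1, fill::zeros));
  full.b.assign(NCLASS, vec(p0 + 1, fill::zeros));
  full.yy.zeros(NCLASS); full.nc = ncount;
  nul.A = A0;
  nul.b.assign(NCLASS, vec(p0, fill::zeros));
  nul.yy.zeros(NCLASS); nul.nc = ncount;

  vec beta_g(M), se_g(M), ll_f(M), ll_n(M), s2e_v(M), s2f_v(M), s2z_v(M);
  ivec conv(M);
  std::vector<vec> b0(NCLASS, vec(p0));
  vec yyc(NCLASS);
  std::vector<vec> yc(NCLASS);

  int last_iy = -1;
  double ll_null_cached = NA_REAL;
  bool conv_null = true;
  double tf0 = std::log(0.1), tz0 = std::log(0.1);

  for (int m = 0; m < M; ++m) {
    int yi = iy[m], gi = ig[m];
    if (yi != last_iy) {
      vec y = Y.col(yi);
      for (int c = 0; c < NCLASS; ++c) {
        if (ncount[c] == 0) continue;
        yc[c] = y(idx[c]);
        b0[c] = Xc[c].t() * yc[c];
        yyc[c] = dot(yc[c], yc[c]);
        nul.b[c] = b0[c];
        nul.yy[c] = yyc[c];
      }
      mom_start(nul, tf0, tz0);
      OptOut on = nm_optimize(nul, est_fam, est_mz, tf0, tz0, maxit, tol);
      ll_null_cached = -0.5 * on.obj;
      conv_null = on.conv;
      last_iy = yi;
    }
    for (int c = 0; c < NCLASS; ++c) {
      if (ncount[c] == 0) continue;
      full.A[c].submat(0, 0, p0 - 1, p0 - 1) = A0[c];
      full.A[c].submat(0, p0, p0 - 1, p0) = Vc[c].col(gi);
      full.A[c].submat(p0, 0, p0, p0 - 1) = Vc[c].col(gi).t();
      full.A[c](p0, p0) = Sc[c](gi);
      full.b[c].subvec(0, p0 - 1) = b0[c];
      full.b[c](p0) = dot(Gc[c].col(gi), yc[c]);
      full.yy[c] = yyc[c];
    }
    OptOut of = nm_optimize(full, est_fam, est_mz, tf0, tz0, maxit, tol);
    mat cov;
    bool ok = inv_sympd(cov, full.Aw);
    if (!ok) cov = pinv(full.Aw);
    beta_g[m] = full.beta(p0);
    se_g[m] = std::sqrt(std::max(cov(p0, p0) * full.s2e, 0.0));
    ll_f[m] = -0.5 * of.obj;
    ll_n[m] = ll_null_cached;
    s2e_v[m] = full.s2e;
    s2f_v[m] = of.lf * full.s2e;
    s2z_v[m] = of.lz * full.s2e;
    conv[m] = (of.conv && conv_null) ? 1 : 0;
    if (m % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
      _["beta"] = beta_g, _["se"] = se_g, _["ll_full"] = ll_f, _["ll_null"] = ll_n,
      _["s2e"] = s2e_v, _["s2f"] = s2f_v, _["s2z"] = s2z_v, _["converged"] = conv);
}
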