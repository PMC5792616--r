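// Binomial (Bernoulli) GLMM with a single random intercept:
//   y_i ~ Bern(plogis(beta0 [+ beta1 * x_i] + u_g)),  u_g ~ N(0, sigma_u^2).
// Estimation follows the Laplace scheme used by mixed-model software for
// GLMMs: at fixed sigma the fixed effects and the group modes are obtained
// jointly by a penalized Newton solve (Schur complement over the diagonal
// random-effect block), giving the profiled Laplace log-likelihood; the
// variance parameter is then optimized in one dimension (golden section on
// log sigma). The sigma -> 0 limit is handled explicitly: a plain logistic
// Newton fit is always computed and reported whenever it matches or beats
// the random-intercept optimum, making the reduction to fixed-effects
// logistic regression exact. An adaptive Gauss-Hermite evaluator is
// exposed as an independent cross-check.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Prob {
  std::vector<double> y, x;   // compacted (no NA); x empty when no covariate
  std::vector<int> gs;        // group sizes, groups contiguous
  std::vector<double> ucache; // warm-start modes for nll_laplace
  long evals = 0;
  bool has_x() const { return !x.empty(); }
  int n() const { return (int) y.size(); }
  int G() const { return (int) gs.size(); }
};

struct State {
  double b0 = 0.0, b1 = 0.0;
  std::vector<double> u;
  bool newton_ok = false;
};

static inline double log1pexp_(double eta) {
  if (eta > 30.0) return eta;
  if (eta < -30.0) return std::exp(eta);
  return std::log1p(std::exp(eta));
}

// Profiled Laplace negative log-likelihood at fixed log-sigma: joint
// penalized Newton over (beta, u) with a Schur-complement solve, then the
// Laplace correction.
static double profile_nll(Prob& P, double ls, State& st) {
  const bool hx = P.has_x();
  const int G = P.G();
  const double sig2 = std::exp(2.0 * ls), s2inv = 1.0 / sig2;
  if ((int) st.u.size() != G) st.u.assign(G, 0.0);
  double b0 = st.b0, b1 = hx ? st.b1 : 0.0;
  st.newton_ok = false;
  std::vector<double> s2g(G), gu(G), B0(G), B1(G);
  for (int iter = 0; iter < 80; ++iter) {
    P.evals++;
    double g0 = 0, g1 = 0, a00 = 0, a01 = 0, a11 = 0;
    double s00 = 0, s01 = 0, s11 = 0, r0 = 0, r1 = 0;
    int pos = 0;
    for (int g = 0; g < G; ++g) {
      const int m = P.gs[g];
      const double u = st.u[g];
      double sg = 0, b0g = 0, b1g = 0, s2 = 0;
      for (int j = pos; j < pos + m; ++j) {
        double xi = hx ? P.x[j] : 0.0;
        double eta = b0 + b1 * xi + u;
        double p = 1.0 / (1.0 + std::exp(-eta));
        double w = p * (1.0 - p);
        double r = P.y[j] - p;
        sg += r;
        s2 += w;
        b0g += w; b1g += w * xi;
        g0 += r; g1 += r * xi;
        a00 += w; a01 += w * xi; a11 += w * xi * xi;
      }
      double D = s2 + s2inv;
      double gug = sg - u * s2inv;
      s2g[g] = s2; gu[g] = gug; B0[g] = b0g; B1[g] = b1g;
      s00 += b0g * b0g / D; s01 += b0g * b1g / D; s11 += b1g * b1g / D;
      r0 += b0g * gug / D; r1 += b1g * gug / D;
      pos += m;
    }
    // Schur system for the fixed effects
    double S00 = a00 - s00, S01 = a01 - s01, S11 = a11 - s11;
    double rhs0 = g0 - r0, rhs1 = g1 - r1;
    double d0, d1 = 0.0;
    if (hx) {
      double det = S00 * S11 - S01 * S01;
      if (!(det > 1e-12)) break;
      d0 = (S11 * rhs0 - S01 * rhs1) / det;
      d1 = (S00 * rhs1 - S01 * rhs0) / det;
    } else {
      if (!(S00 > 1e-12)) break;
      d0 = rhs0 / S00;
    }
    double mx = std::max(std::fabs(d0), std::fabs(d1));
    double damp = mx > 4.0 ? 4.0 / mx : 1.0;
    d0 *= damp; d1 *= damp;
    b0 += d0; b1 += d1;
    double mxu = 0.0;
    for (int g = 0; g < G; ++g) {
      double du = (gu[g] - B0[g] * d0 - B1[g] * d1) / (s2g[g] + s2inv);
      if (du > 4.0) du = 4.0;
      if (du < -4.0) du = -4.0;
      st.u[g] += du;
      double a = std::fabs(du);
      if (a > mxu) mxu = a;
    }
    if (std::fabs(b0) > 30.0) b0 = b0 > 0 ? 30.0 : -30.0;
    if (std::fabs(b1) > 30.0) b1 = b1 > 0 ? 30.0 : -30.0;
    if (std::max(mx, mxu) < 1e-10) { st.newton_ok = true; break; }
  }
  st.b0 = b0;
  if (hx) st.b1 = b1;
  // Laplace log-likelihood at the joint mode
  double ll = 0.0;
  int pos = 0;
  for (int g = 0; g < G; ++g) {
    const int m = P.gs[g];
    const double u = st.u[g];
    double s2 = 0.0, lg = 0.0;
    for (int j = pos; j < pos + m; ++j) {
      double xi = hx ? P.x[j] : 0.0;
      double eta = b0 + b1 * xi + u;
      double p = 1.0 / (1.0 + std::exp(-eta));
      s2 += p * (1.0 - p);
      lg += P.y[j] * eta - log1pexp_(eta);
    }
    ll += lg - 0.5 * u * u * s2inv - 0.5 * std::log1p(sig2 * s2);
    pos += m;
  }
  return -ll;
}

// Laplace negative log-likelihood at arbitrary (beta, log sigma): inner
// Newton on the modes only. Exposed for testing the likelihood surface.
static double nll_laplace(Prob& P, const double* par) {
  P.evals++;
  const bool hx = P.has_x();
  double b0 = par[0];
  double b1 = hx ? par[1] : 0.0;
  double ls = hx ? par[2] : par[1];
  const double sig2 = std::exp(2.0 * ls), s2inv = 1.0 / sig2;
  const int G = P.G();
  if ((int) P.ucache.size() != G) P.ucache.assign(G, 0.0);
  double ll = 0.0;
  int pos = 0;
  for (int g = 0; g < G; ++g) {
    const int m = P.gs[g];
    double u = P.ucache[g], s2 = 0.0;
    for (int iter = 0; iter < 80; ++iter) {
      double s1 = 0.0;
      s2 = 0.0;
      for (int j = pos; j < pos + m; ++j) {
        double eta = b0 + (hx ? b1 * P.x[j] : 0.0) + u;
        double p = 1.0 / (1.0 + std::exp(-eta));
        s1 += P.y[j] - p;
        s2 += p * (1.0 - p);
      }
      double du = (s1 - u * s2inv) / (s2 + s2inv);
      if (du > 5.0) du = 5.0;
      if (du < -5.0) du = -5.0;
      u += du;
      if (std::fabs(du) < 1e-11 * (1.0 + std::fabs(u))) break;
    }
    P.ucache[g] = u;
    double lg = 0.0;
    for (int j = pos; j < pos + m; ++j) {
      double eta = b0 + (hx ? b1 * P.x[j] : 0.0) + u;
      lg += P.y[j] * eta - log1pexp_(eta);
    }
    ll += lg - 0.5 * u * u * s2inv - 0.5 * std::log1p(sig2 * s2);
    pos += m;
  }
  return -ll;
}

// Finite-difference Newton polish of the profile solution on the exact
// Laplace objective (the profiled Newton ignores the log-determinant's
// dependence on beta, which biases beta slightly toward zero). Also yields
// standard errors from the observed information.
static void fd_grad_hess(Prob& P, double* par, int d, double* g, double* H) {
  const double h = 5e-4;
  double fp[3], fm[3], f0 = nll_laplace(P, par);
  for (int j = 0; j < d; ++j) {
    double save = par[j];
    par[j] = save + h; fp[j] = nll_laplace(P, par);
    par[j] = save - h; fm[j] = nll_laplace(P, par);
    par[j] = save;
    g[j] = (fp[j] - fm[j]) / (2.0 * h);
    H[j * d + j] = (fp[j] - 2.0 * f0 + fm[j]) / (h * h);
  }
  for (int i = 0; i < d; ++i)
    for (int j = i + 1; j < d; ++j) {
      double si = par[i], sj = par[j];
      par[i] = si + h; par[j] = sj + h; double fpp = nll_laplace(P, par);
      par[j] = sj - h; double fpm = nll_laplace(P, par);
      par[i] = si - h; double fmm = nll_laplace(P, par);
      par[j] = sj + h; double fmp = nll_laplace(P, par);
      par[i] = si; par[j] = sj;
      H[i * d + j] = H[j * d + i] = (fpp - fpm - fmp + fmm) / (4.0 * h * h);
    }
}

// solve H x = b for d in {2,3}; returns false when H is not usable
static bool solve_sym(const double* H, const double* b, int d, double* x) {
  if (d == 2) {
    double det = H[0] * H[3] - H[1] * H[2];
    if (!(det > 1e-12)) return false;
    x[0] = (H[3] * b[0] - H[1] * b[1]) / det;
    x[1] = (H[0] * b[1] - H[2] * b[0]) / det;
    return true;
  }
  double a[9];
  for (int i = 0; i < 9; ++i) a[i] = H[i];
  double c00 = a[4] * a[8] - a[5] * a[7];
  double c01 = a[5] * a[6] - a[3] * a[8];
  double c02 = a[3] * a[7] - a[4] * a[6];
  double det = a[0] * c00 + a[1] * c01 + a[2] * c02;
  if (!(std::fabs(det) > 1e-12)) return false;
  double inv[9];
  inv[0] = c00; inv[3] = c01; inv[6] = c02;
  inv[1] = a[2] * a[7] - a[1] * a[8];
  inv[4] = a[0] * a[8] - a[2] * a[6];
  inv[7] = a[1] * a[6] - a[0] * a[7];
  inv[2] = a[1] * a[5] - a[2] * a[4];
  inv[5] = a[2] * a[3] - a[0] * a[5];
  inv[8] = a[0] * a[4] - a[1] * a[3];
  for (int i = 0; i < 3; ++i) {
    x[i] = 0.0;
    for (int j = 0; j < 3; ++j) x[i] += inv[i * 3 + j] / det * b[j];
  }
  return true;
}

// returns the polished nll; fills se[0..1] (NA when not available)
static double polish_newton(Prob& P, double* par, int d, double* se) {
  double g[3], H[9], stp[3];
  double f0 = nll_laplace(P, par);
  se[0] = NA_REAL; se[1] = NA_REAL;
  for (int round = 0; round < 2; ++round) {
    fd_grad_hess(P, par, d, g, H);
    double nb[3] = {-g[0], -g[1], -g[2]};
    if (!solve_sym(H, nb, d, stp)) break;
    double mx = 0.0;
    for (int j = 0; j < d; ++j)
      if (std::fabs(stp[j]) > mx) mx = std::fabs(stp[j]);
    if (mx > 1.0)
      for (int j = 0; j < d; ++j) stp[j] *= 1.0 / mx;
    double trial[3] = {par[0], par[1], par[2]};
    for (int j = 0; j < d; ++j) trial[j] += stp[j];
    double ft = nll_laplace(P, trial);
    if (ft < f0) {
      for (int j = 0; j < d; ++j) par[j] = trial[j];
      double gain = f0 - ft;
      f0 = ft;
      if (gain < 1e-9) break;
    } else break;
  }
  // standard errors of the fixed effects from the observed information
  double cov[3];
  double e0[3] = {1, 0, 0}, e1[3] = {0, 1, 0};
  if (solve_sym(H, e0, d, cov) && cov[0] > 0) se[0] = std::sqrt(cov[0]);
  if (d >= 3 && solve_sym(H, e1, d, cov) && cov[1] > 0) se[1] = std::sqrt(cov[1]);
  return f0;
}

// plain logistic Newton fit (the sigma_u = 0 limit)
static double glm_newton(Prob& P, double* beta, bool& conv, double* se) {
  const int n = P.n();
  const bool hx = P.has_x();
  double b0 = 0.0, b1 = 0.0;
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += P.y[i];
  ybar /= n;
  if (ybar < 0.02) ybar = 0.02;
  if (ybar > 0.98) ybar = 0.98;
  b0 = std::log(ybar / (1.0 - ybar));
  conv = false;
  for (int iter = 0; iter < 80; ++iter) {
    double g0 = 0, g1 = 0, h00 = 0, h01 = 0, h11 = 0;
    for (int i = 0; i < n; ++i) {
      double xi = hx ? P.x[i] : 0.0;
      double eta = b0 + b1 * xi;
      double p = 1.0 / (1.0 + std::exp(-eta));
      double w = p * (1.0 - p);
      double r = P.y[i] - p;
      g0 += r; g1 += r * xi;
      h00 += w; h01 += w * xi; h11 += w * xi * xi;
    }
    double d0, d1 = 0.0;
    if (hx) {
      double det = h00 * h11 - h01 * h01;
      if (det < 1e-12) break;
      d0 = (h11 * g0 - h01 * g1) / det;
      d1 = (h00 * g1 - h01 * g0) / det;
    } else {
      if (h00 < 1e-12) break;
      d0 = g0 / h00;
    }
    double step = std::max(std::fabs(d0), std::fabs(d1));
    if (step > 5.0) { d0 *= 5.0 / step; d1 *= 5.0 / step; }
    b0 += d0; b1 += d1;
    if (std::fabs(b0) > 30.0 || std::fabs(b1) > 30.0) break;  // separation
    if (step < 1e-11) { conv = true; break; }
  }
  double ll = 0.0, h00 = 0, h01 = 0, h11 = 0;
  for (int i = 0; i < n; ++i) {
    double xi = hx ? P.x[i] : 0.0;
    double eta = b0 + b1 * xi;
    ll += P.y[i] * eta - log1pexp_(eta);
    double p = 1.0 / (1.0 + std::exp(-eta));
    double w = p * (1.0 - p);
    h00 += w; h01 += w * xi; h11 += w * xi * xi;
  }
  se[0] = NA_REAL; se[1] = NA_REAL;
  if (hx) {
    double det = h00 * h11 - h01 * h01;
    if (det > 1e-12) { se[0] = std::sqrt(h11 / det); se[1] = std::sqrt(h00 / det); }
  } else if (h00 > 1e-12) se[0] = std::sqrt(1.0 / h00);
  beta[0] = b0;
  beta[1] = b1;
  return ll;
}

// core fit; out = (b0, b1, sigma, loglik, conv, neval, nobs, se0, se1)
static void fit_one(Prob& P, double* out) {
  const bool hx = P.has_x();
  double ysum = 0.0;
  for (double v : P.y) ysum += v;
  if (ysum == 0.0 || ysum == (double) P.y.size()) {
    out[0] = NA_REAL; out[1] = NA_REAL; out[2] = NA_REAL; out[3] = NA_REAL;
    out[4] = 0; out[5] = 0; out[6] = P.n(); out[7] = NA_REAL; out[8] = NA_REAL;
    return;
  }
  P.evals = 0;
  double bg[2], seg[2];
  bool gconv = false;
  double ll_glm = glm_newton(P, bg, gconv, seg);
  // golden section on log sigma
  State st;
  st.b0 = bg[0];
  st.b1 = hx ? bg[1] : 0.0;
  const double gr = 0.61803398874989485;
  double a = -7.0, b = 2.5;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = profile_nll(P, x1, st), f2 = profile_nll(P, x2, st);
  while (b - a > 8e-3) {
    if (f1 <= f2) {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - gr * (b - a);
      f1 = profile_nll(P, x1, st);
    } else {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (b - a);
      f2 = profile_nll(P, x2, st);
    }
  }
  double ls = (f1 <= f2) ? x1 : x2;
  double fbest = profile_nll(P, ls, st);
  // polish (beta, log sigma) on the exact Laplace objective
  const int d = hx ? 3 : 2;
  double par[3] = {0, 0, 0}, se[2];
  par[0] = st.b0;
  if (hx) { par[1] = st.b1; par[2] = ls; }
  else par[1] = ls;
  P.ucache.assign(P.G(), 0.0);
  double fpol = polish_newton(P, par, d, se);
  bool polished = fpol < fbest;
  double ll_lap = -(polished ? fpol : fbest);
  double ls_out = polished ? (hx ? par[2] : par[1]) : ls;
  bool use_glm = (ll_glm >= ll_lap - 1e-8) || ls_out < -5.5;
  if (use_glm) {
    out[0] = bg[0];
    out[1] = hx ? bg[1] : NA_REAL;
    out[2] = 0.0;
    out[3] = ll_glm;
    out[4] = (gconv && std::fabs(bg[0]) < 25.0 && std::fabs(bg[1]) < 25.0) ? 1 : 0;
    out[7] = seg[0];
    out[8] = hx ? seg[1] : NA_REAL;
  } else {
    double b0o = polished ? par[0] : st.b0;
    double b1o = polished ? par[1] : st.b1;
    out[0] = b0o;
    out[1] = hx ? b1o : NA_REAL;
    out[2] = std::exp(ls_out);
    out[3] = ll_lap;
    out[4] = ((st.newton_ok || polished) && std::fabs(b0o) < 25.0 &&
              (!hx || std::fabs(b1o) < 25.0)) ? 1 : 0;
    out[7] = se[0];
    out[8] = hx ? se[1] : NA_REAL;
  }
  out[5] = (double) P.evals;
  out[6] = (double) P.n();
}

// build compacted problem for one response vector
static bool build_prob(Prob& P, const double* y, const double* x, bool hx,
                       const int* gsize, int G, int n) {
  P.y.clear(); P.x.clear(); P.gs.clear();
  P.y.reserve(n);
  if (hx) P.x.reserve(n);
  int pos = 0;
  for (int g = 0; g < G; ++g) {
    int m = 0;
    for (int j = pos; j < pos + gsize[g]; ++j) {
      if (ISNAN(y[j]) || (hx && ISNAN(x[j]))) continue;
      P.y.push_back(y[j]);
      if (hx) P.x.push_back(x[j]);
      ++m;
    }
    if (m > 0) P.gs.push_back(m);
    pos += gsize[g];
  }
  return !P.y.empty();
}

// [[Rcpp::export]]
NumericMatrix glmm_scan_cpp(NumericMatrix Y, Nullable<NumericVector> x_,
                            IntegerVector gsize) {
  const int n = Y.nrow(), L = Y.ncol(), G = gsize.size();
  int tot = 0;
  for (int g = 0; g < G; ++g) tot += gsize[g];
  if (tot != n) stop("group sizes do not sum to the number of rows");
  const bool hx = x_.isNotNull();
  NumericVector x;
  if (hx) {
    x = x_.get();
    if (x.size() != n) stop("covariate length mismatch");
  }
  NumericMatrix out(L, 10);
  colnames(out) = CharacterVector::create("beta0", "beta1", "sigma_u",
                                          "loglik", "converged", "neval",
                                          "n_obs", "n_groups", "se_beta0",
                                          "se_beta1");
  Prob P;
  double res[9];
  for (int l = 0; l < L; ++l) {
    if (!build_prob(P, &Y(0, l), hx ? &x[0] : nullptr, hx, &gsize[0], G, n)) {
      for (int j = 0; j < 10; ++j) out(l, j) = NA_REAL;
      out(l, 4) = 0;
      continue;
    }
    fit_one(P, res);
    for (int j = 0; j < 7; ++j) out(l, j) = res[j];
    out(l, 7) = (double) P.G();
    out(l, 8) = res[7];
    out(l, 9) = res[8];
  }
  return out;
}

// [[Rcpp::export]]
double glmm_nll_cpp(NumericVector par, NumericVector y,
                    Nullable<NumericVector> x_, IntegerVector gsize) {
  Prob P;
  const bool hx = x_.isNotNull();
  NumericVector x;
  if (hx) x = x_.get();
  if (!build_prob(P, &y[0], hx ? &x[0] : nullptr, hx, &gsize[0],
                  gsize.size(), y.size()))
    stop("no usable observations");
  std::vector<double> p(par.begin(), par.end());
  return nll_laplace(P, p.data());
}

// adaptive Gauss-Hermite marginal log-likelihood at fixed parameters
// (nodes/weights for int exp(-z^2) f(z) dz)
// [[Rcpp::export]]
double glmm_loglik_agq_cpp(NumericVector par, NumericVector y,
                           Nullable<NumericVector> x_, IntegerVector gsize,
                           NumericVector nodes, NumericVector weights) {
  Prob P;
  const bool hx = x_.isNotNull();
  NumericVector x;
  if (hx) x = x_.get();
  if (!build_prob(P, &y[0], hx ? &x[0] : nullptr, hx, &gsize[0],
                  gsize.size(), y.size()))
    stop("no usable observations");
  double b0 = par[0];
  double b1 = hx ? par[1] : 0.0;
  double ls = hx ? par[2] : par[1];
  const double sig2 = std::exp(2.0 * ls), s2inv = 1.0 / sig2;
  const int K = nodes.size();
  double ll = 0.0;
  int pos = 0;
  for (int g = 0; g < P.G(); ++g) {
    const int m = P.gs[g];
    double u = 0.0, s2 = 0.0;
    for (int iter = 0; iter < 100; ++iter) {
      double s1 = 0.0;
      s2 = 0.0;
      for (int j = pos; j < pos + m; ++j) {
        double eta = b0 + (hx ? b1 * P.x[j] : 0.0) + u;
        double p = 1.0 / (1.0 + std::exp(-eta));
        s1 += P.y[j] - p;
        s2 += p * (1.0 - p);
      }
      double du = (s1 - u * s2inv) / (s2 + s2inv);
      u += du;
      if (std::fabs(du) < 1e-12 * (1.0 + std::fabs(u))) break;
    }
    double H = s2 + s2inv;
    double s = 1.0 / std::sqrt(H);
    double mx = -INFINITY;
    std::vector<double> ex(K);
    for (int k = 0; k < K; ++k) {
      double uk = u + std::sqrt(2.0) * s * nodes[k];
      double F = -0.5 * uk * uk * s2inv - 0.5 * std::log(2.0 * M_PI * sig2);
      for (int j = pos; j < pos + m; ++j) {
        double eta = b0 + (hx ? b1 * P.x[j] : 0.0) + uk;
        F += P.y[j] * eta - log1pexp_(eta);
      }
      ex[k] = nodes[k] * nodes[k] + F + std::log(weights[k]);
      if (ex[k] > mx) mx = ex[k];
    }
    double sum = 0.0;
    for (int k = 0; k < K; ++k) sum += std::exp(ex[k] - mx);
    ll += mx + std::log(sum) + std::log(std::sqrt(2.0) * s);
    pos += m;
  }
  return ll;
}
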