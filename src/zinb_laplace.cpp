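// Compiled inner loop of the Laplace-marginal likelihood for the
// zero-inflated NB2 model with per-centre latent AR(1) series.
//
// The joint Hessian in the latent vector is tridiagonal (AR(1) precision
// plus a diagonal likelihood contribution), so the Newton step and the
// log-determinant use an LDL^T factorisation in O(T) per centre.

#include <Rcpp.h>
#include <cmath>
#include <map>
#include <limits>
using namespace Rcpp;

static double nb2_logpmf1(double y, double mu, double theta) {
  return R::lgammafn(y + theta) - R::lgammafn(theta) - R::lgammafn(y + 1.0) +
         theta * (std::log(theta) - std::log(mu + theta)) +
         y * (std::log(mu) - std::log(mu + theta));
}

// log-likelihood of one observation and derivatives w.r.t. the linear
// predictor eta (mu = exp(eta)); p is the structural-zero probability
static void obs_derivs(double y, double eta, double theta, double p,
                       double *ll, double *d1, double *d2) {
  double mu = std::exp(std::min(eta, 30.0));
  double mt = mu + theta;
  if (y > 0.0 || p <= 0.0) {
    double base = nb2_logpmf1(y, mu, theta);
    *ll = (p > 0.0 ? std::log1p(-p) : 0.0) + base;
    *d1 = y - (y + theta) * mu / mt;
    *d2 = -(y + theta) * theta * mu / (mt * mt);
  } else {
    double lq = theta * (std::log(theta) - std::log(mt));
    double q = std::exp(lq);
    double s = theta * mu / mt;
    double f = p + (1.0 - p) * q;
    double dq = -q * s;
    double g1 = (1.0 - p) * dq / f;
    double d2q = q * s * s - q * theta * theta * mu / (mt * mt);
    *ll = std::log(f);
    *d1 = g1;
    *d2 = (1.0 - p) * d2q / f - g1 * g1;
  }
}

struct CentreData {
  const double *y, *eta0, *theta, *p;
  const int *times;
  int T;
  double sigma, phi;
  std::vector<double> qd, qe; // tridiagonal precision
  double ldQ;

  void build_precision() {
    qd.assign(T, 0.0);
    qe.assign(T > 1 ? T - 1 : 0, 0.0);
    double s2 = sigma * sigma;
    ldQ = -2.0 * T * std::log(sigma);
    if (T == 1) { qd[0] = 1.0 / s2; return; }
    std::vector<double> a(T - 1);
    for (int k = 0; k < T - 1; k++) {
      double rho = std::pow(phi, (double)(times[k + 1] - times[k]));
      a[k] = 1.0 - rho * rho;
      qe[k] = -rho / a[k] / s2;
      ldQ -= std::log(a[k]);
    }
    qd[0] = 1.0;
    for (int k = 1; k < T; k++) qd[k] = 1.0 / a[k - 1];
    for (int k = 0; k < T - 1; k++) {
      double rho = std::pow(phi, (double)(times[k + 1] - times[k]));
      qd[k] += rho * rho / a[k];
    }
    for (int k = 0; k < T; k++) qd[k] /= s2;
  }

  double quad(const std::vector<double> &u) const { // u' Q u
    double s = 0.0;
    for (int i = 0; i < T; i++) s += qd[i] * u[i] * u[i];
    for (int i = 0; i < T - 1; i++) s += 2.0 * qe[i] * u[i] * u[i + 1];
    return s;
  }

  double fval(const std::vector<double> &u) const {
    double s = 0.5 * quad(u);
    for (int i = 0; i < T; i++) {
      double ll, d1, d2;
      obs_derivs(y[i], eta0[i] + u[i], theta[i], p[i], &ll, &d1, &d2);
      s -= ll;
    }
    return s;
  }
};

// LDL^T of the tridiagonal (hd, he); returns false if not positive
// definite. On success d holds the pivots and l the multipliers.
static bool ldl_tridiag(const std::vector<double> &hd,
                        const std::vector<double> &he,
                        std::vector<double> &d, std::vector<double> &l) {
  int T = hd.size();
  d.assign(T, 0.0);
  l.assign(T > 1 ? T - 1 : 0, 0.0);
  d[0] = hd[0];
  if (d[0] <= 1e-12) return false;
  for (int i = 1; i < T; i++) {
    l[i - 1] = he[i - 1] / d[i - 1];
    d[i] = hd[i] - l[i - 1] * he[i - 1];
    if (d[i] <= 1e-12) return false;
  }
  return true;
}

static void ldl_solve(const std::vector<double> &d,
                      const std::vector<double> &l,
                      std::vector<double> &x) {
  int T = d.size();
  for (int i = 1; i < T; i++) x[i] -= l[i - 1] * x[i - 1];
  for (int i = 0; i < T; i++) x[i] /= d[i];
  for (int i = T - 2; i >= 0; i--) x[i] -= l[i] * x[i + 1];
}

// Laplace (or, for T = 1, adaptive Gauss-Hermite) marginal log-likelihood
// of one centre; u is updated in place (warm start across calls).
static double centre_loglik(CentreData &c, double *u_io, bool *ok,
                            const double *ghx, const double *ghw, int ngh) {
  int T = c.T;
  c.build_precision();
  std::vector<double> u(u_io, u_io + T);
  std::vector<double> g(T), hd(T), he(c.qe), d, l, step;
  double f_cur = c.fval(u);
  if (!std::isfinite(f_cur)) { std::fill(u.begin(), u.end(), 0.0); f_cur = c.fval(u); }
  *ok = false;
  std::vector<double> d1(T), d2(T);
  for (int it = 0; it < 80; it++) {
    double gmax = 0.0;
    for (int i = 0; i < T; i++) {
      double ll;
      obs_derivs(c.y[i], c.eta0[i] + u[i], c.theta[i], c.p[i], &ll, &d1[i],
                 &d2[i]);
      g[i] = c.qd[i] * u[i] - d1[i];
    }
    for (int i = 0; i < T - 1; i++) {
      g[i] += c.qe[i] * u[i + 1];
      g[i + 1] += c.qe[i] * u[i];
    }
    for (int i = 0; i < T; i++) gmax = std::max(gmax, std::fabs(g[i]));
    if (gmax < 1e-8) { *ok = true; break; }
    for (int i = 0; i < T; i++) hd[i] = c.qd[i] - d2[i];
    double ridge = 0.0;
    while (!ldl_tridiag(hd, he, d, l)) {
      ridge = (ridge == 0.0) ? 1e-4 : ridge * 10.0;
      for (int i = 0; i < T; i++) hd[i] = c.qd[i] - d2[i] + ridge;
      if (ridge > 1e6) return -std::numeric_limits<double>::infinity();
    }
    step = g;
    ldl_solve(d, l, step);
    double lam = 1.0;
    std::vector<double> u_new(T);
    double f_new;
    for (;;) {
      for (int i = 0; i < T; i++) u_new[i] = u[i] - lam * step[i];
      f_new = c.fval(u_new);
      if (std::isfinite(f_new) && f_new <= f_cur + 1e-12) break;
      lam *= 0.5;
      if (lam < 1e-8) { u_new = u; f_new = f_cur; break; }
    }
    bool small = std::fabs(f_new - f_cur) < 1e-12;
    u = u_new;
    f_cur = f_new;
    if (small && gmax < 1e-5) { *ok = true; break; }
  }
  // final Hessian and log-determinant
  for (int i = 0; i < T; i++) {
    double ll;
    obs_derivs(c.y[i], c.eta0[i] + u[i], c.theta[i], c.p[i], &ll, &d1[i],
               &d2[i]);
    hd[i] = c.qd[i] - d2[i];
  }
  if (!ldl_tridiag(hd, he, d, l))
    return -std::numeric_limits<double>::infinity();
  for (int i = 0; i < T; i++) u_io[i] = u[i];
  if (T == 1) {
    double s = std::sqrt(1.0 / hd[0]);
    double m = -std::numeric_limits<double>::infinity();
    std::vector<double> gk(ngh);
    for (int k = 0; k < ngh; k++) {
      double uk = u[0] + std::sqrt(2.0) * s * ghx[k];
      double ll, a1, a2;
      obs_derivs(c.y[0], c.eta0[0] + uk, c.theta[0], c.p[0], &ll, &a1, &a2);
      gk[k] = 0.5 * c.ldQ - 0.5 * std::log(2.0 * M_PI) -
              0.5 * c.qd[0] * uk * uk + ll + ghx[k] * ghx[k] +
              std::log(ghw[k]);
      m = std::max(m, gk[k]);
    }
    double sum = 0.0;
    for (int k = 0; k < ngh; k++) sum += std::exp(gk[k] - m);
    return std::log(std::sqrt(2.0) * s) + m + std::log(sum);
  }
  double ldH = 0.0;
  for (int i = 0; i < T; i++) ldH += std::log(d[i]);
  return 0.5 * c.ldQ - f_cur - 0.5 * ldH;
}

// Exact marginal log-likelihood of one centre by a sequential grid
// filter: the latent AR(1) is Markov, so the T-dimensional integral
// factorises into T one-dimensional integrals propagated along the chain.
// The grid is in standardised units x = u / sigma with trapezoid weights;
// the transition kernel for a gap of dt months is
// N(x_t ; rho^dt x_{t-1}, 1 - rho^(2dt)).
static double centre_loglik_filter(const CentreData &c,
                                   const std::vector<double> &xg,
                                   const std::vector<double> &wg,
                                   std::map<int, std::vector<double> > &kern) {
  int G = xg.size(), T = c.T;
  std::vector<double> alpha(G), pred(G), lf(G);
  double ll_total = 0.0;
  for (int t = 0; t < T; t++) {
    // observation log-likelihood on the grid; the lgamma terms do not
    // depend on the latent value, so they are hoisted out of the loop
    double y = c.y[t], th = c.theta[t], pz = c.p[t];
    double c0 = R::lgammafn(y + th) - R::lgammafn(th) -
                R::lgammafn(y + 1.0) + th * std::log(th);
    double mx = -std::numeric_limits<double>::infinity();
    for (int j = 0; j < G; j++) {
      double eta = std::min(c.eta0[t] + c.sigma * xg[j], 30.0);
      double mu = std::exp(eta);
      double lnb = c0 - (y + th) * std::log(mu + th) + y * eta;
      double ll;
      if (y > 0.0 || pz <= 0.0)
        ll = (pz > 0.0 ? std::log1p(-pz) : 0.0) + lnb;
      else
        ll = std::log(pz + (1.0 - pz) * std::exp(lnb));
      lf[j] = ll;
      mx = std::max(mx, ll);
    }
    if (t == 0) {
      for (int j = 0; j < G; j++)
        pred[j] = std::exp(-0.5 * xg[j] * xg[j]) / std::sqrt(2.0 * M_PI);
    } else {
      int dt = c.times[t] - c.times[t - 1];
      std::vector<double> &K = kern[dt];
      if (K.empty()) {
        // rows j: density of x_t = xg[j] given x_{t-1} = xg[i], times w_i
        K.resize((size_t)G * G);
        double rho = std::pow(c.phi, (double)dt);
        double v = 1.0 - rho * rho;
        double nc = 1.0 / std::sqrt(2.0 * M_PI * v);
        for (int j = 0; j < G; j++)
          for (int i = 0; i < G; i++) {
            double z = xg[j] - rho * xg[i];
            K[(size_t)j * G + i] = nc * std::exp(-0.5 * z * z / v) * wg[i];
          }
      }
      for (int j = 0; j < G; j++) {
        double s = 0.0;
        const double *row = &K[(size_t)j * G];
        for (int i = 0; i < G; i++) s += row[i] * alpha[i];
        pred[j] = s;
      }
    }
    double ct = 0.0;
    for (int j = 0; j < G; j++) {
      alpha[j] = pred[j] * std::exp(lf[j] - mx);
      ct += wg[j] * alpha[j];
    }
    if (!(ct > 0.0) || !std::isfinite(ct))
      return -std::numeric_limits<double>::infinity();
    ll_total += std::log(ct) + mx;
    for (int j = 0; j < G; j++) alpha[j] /= ct;
  }
  return ll_total;
}

// [[Rcpp::export(name = ".zinb_ar1_filter_cpp")]]
double zinb_ar1_filter_cpp(NumericVector y, NumericVector eta0,
                           NumericVector theta, NumericVector p,
                           IntegerVector times, IntegerVector offsets,
                           double sigma, double phi, NumericVector grid_x,
                           NumericVector grid_w) {
  int nc = offsets.size() - 1;
  std::vector<double> xg(grid_x.begin(), grid_x.end());
  std::vector<double> wg(grid_w.begin(), grid_w.end());
  std::map<int, std::vector<double> > kern; // shared across centres
  double tot = 0.0;
  for (int c = 0; c < nc; c++) {
    int s = offsets[c], e = offsets[c + 1];
    CentreData cd;
    cd.y = &y[s]; cd.eta0 = &eta0[s]; cd.theta = &theta[s]; cd.p = &p[s];
    cd.times = &times[s]; cd.T = e - s; cd.sigma = sigma; cd.phi = phi;
    tot += centre_loglik_filter(cd, xg, wg, kern);
  }
  return tot;
}

// [[Rcpp::export(name = ".zinb_ar1_loglik_cpp")]]
double zinb_ar1_loglik_cpp(NumericVector y, NumericVector eta0,
                           NumericVector theta, NumericVector p,
                           IntegerVector times, IntegerVector offsets,
                           double sigma, double phi, NumericVector u,
                           NumericVector gh_x, NumericVector gh_w,
                           LogicalVector converged) {
  int nc = offsets.size() - 1;
  double tot = 0.0;
  bool all_ok = true;
  for (int c = 0; c < nc; c++) {
    int s = offsets[c], e = offsets[c + 1];
    CentreData cd;
    cd.y = &y[s]; cd.eta0 = &eta0[s]; cd.theta = &theta[s]; cd.p = &p[s];
    cd.times = &times[s]; cd.T = e - s; cd.sigma = sigma; cd.phi = phi;
    bool ok = false;
    tot += centre_loglik(cd, &u[s], &ok, &gh_x[0], &gh_w[0], gh_x.size());
    all_ok = all_ok && ok;
  }
  converged[0] = all_ok;
  return tot;
}
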