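#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Laplace-approximate likelihood of a cumulative logit model with a single
// random patient intercept:
//   logit P(Y_it <= k | b_i) = theta_k - eta_it - b_i,   b_i ~ N(0, sigma^2)
// Raw parameter vector: theta_1, log(theta_2-theta_1), ...,
// log(theta_{m-1}-theta_{m-2}), beta (p entries), log(sigma).
//
// The gradient is analytic: the envelope term in b vanishes at the
// conditional mode, and the log-determinant correction is differentiated
// through the mode by the implicit function theorem, which requires third
// derivatives of the joint log-density in b.

static inline double logistic_cdf(double x) {
  if (x >= 0.0) {
    return 1.0 / (1.0 + std::exp(-x));
  }
  double e = std::exp(x);
  return e / (1.0 + e);
}

struct ObsDerivs {
  // derivatives of one observation's log-probability with respect to the
  // upper/lower threshold arguments a_hi, a_lo and the intercept b
  double ll;            // log p
  double l_hi, l_lo;    // d ll / d a
  double l1, l2, l3;    // d^k ll / d b^k
  double M_hi, M_lo;    // d2 ll / (da db)
  double L2_hi, L2_lo;  // d (d2 ll/db2) / da
};

static inline void obs_derivs(int k, int m, const double *theta, double shift,
                              ObsDerivs &o) {
  double F_hi = 1.0, f_hi = 0.0, fp_hi = 0.0, fpp_hi = 0.0;
  double F_lo = 0.0, f_lo = 0.0, fp_lo = 0.0, fpp_lo = 0.0;
  if (k < m - 1) {
    double a = theta[k] - shift;
    F_hi = logistic_cdf(a);
    f_hi = F_hi * (1.0 - F_hi);
    double u = 1.0 - 2.0 * F_hi;
    fp_hi = f_hi * u;
    fpp_hi = f_hi * u * u - 2.0 * f_hi * f_hi;
  }
  if (k > 0) {
    double a = theta[k - 1] - shift;
    F_lo = logistic_cdf(a);
    f_lo = F_lo * (1.0 - F_lo);
    double u = 1.0 - 2.0 * F_lo;
    fp_lo = f_lo * u;
    fpp_lo = f_lo * u * u - 2.0 * f_lo * f_lo;
  }
  double p = F_hi - F_lo;
  if (p < 1e-300) p = 1e-300;
  double ip = 1.0 / p;
  double q1 = f_lo - f_hi;        // dp/db
  double q2 = fp_hi - fp_lo;      // d2p/db2
  double q3 = fpp_lo - fpp_hi;    // d3p/db3
  o.ll = std::log(p);
  o.l_hi = f_hi * ip;
  o.l_lo = -f_lo * ip;
  o.l1 = q1 * ip;
  o.l2 = q2 * ip - o.l1 * o.l1;
  o.l3 = q3 * ip - 3.0 * q2 * q1 * ip * ip + 2.0 * o.l1 * o.l1 * o.l1;
  o.M_hi = -fp_hi * ip - o.l_hi * o.l1;
  o.M_lo = fp_lo * ip - o.l_lo * o.l1;
  o.L2_hi = fpp_hi * ip - q2 * f_hi * ip * ip +
            2.0 * o.l1 * (fp_hi * ip + o.l1 * f_hi * ip);
  o.L2_lo = -fpp_lo * ip + q2 * f_lo * ip * ip -
            2.0 * o.l1 * (fp_lo * ip + o.l1 * f_lo * ip);
}

// joint log-density and first two b-derivatives for a patient block
static void joint_ll(const int *y, const double *eta, int lo, int hi,
                     const double *theta, int m, double b, double inv_var,
                     double log_sigma, double &ll, double &g, double &h) {
  ll = 0.0;
  g = 0.0;
  h = 0.0;
  ObsDerivs o;
  for (int t = lo; t < hi; ++t) {
    obs_derivs(y[t], m, theta, eta[t] + b, o);
    ll += o.ll;
    g += o.l1;
    h += o.l2;
  }
  ll += -0.5 * b * b * inv_var - log_sigma - 0.5 * std::log(2.0 * M_PI);
  g += -b * inv_var;
  h += -inv_var;
}

static double solve_mode(const int *y, const double *eta, int lo, int hi,
                         const double *theta, int m, double inv_var,
                         double log_sigma, double b0) {
  double b = b0, ll, g, h;
  joint_ll(y, eta, lo, hi, theta, m, b, inv_var, log_sigma, ll, g, h);
  for (int it = 0; it < 80; ++it) {
    if (std::fabs(g) < 1e-10 * (1.0 + std::fabs(h))) break;
    double step = -g / h;
    if (step > 5.0) step = 5.0;
    if (step < -5.0) step = -5.0;
    double lam = 1.0, b_new = b, ll_new = ll, g_new = g, h_new = h;
    for (int half = 0; half < 30; ++half) {
      b_new = b + lam * step;
      joint_ll(y, eta, lo, hi, theta, m, b_new, inv_var, log_sigma,
               ll_new, g_new, h_new);
      if (ll_new >= ll - 1e-12) break;
      lam *= 0.5;
    }
    double moved = std::fabs(b_new - b);
    b = b_new; ll = ll_new; g = g_new; h = h_new;
    if (moved < 1e-13) break;
  }
  return b;
}

// value and analytic gradient of the Laplace NLL; bhat is an in/out cache
// of conditional modes used to warm-start the inner Newton solves
// [[Rcpp::export]]
List clmm_obj_grad_cpp(NumericVector par, IntegerVector y, NumericMatrix X,
                       IntegerVector pat_start, int m, NumericVector bhat,
                       NumericVector w, bool want_grad) {
  const int p = X.ncol();
  const int nobs = X.nrow();
  const int npat = pat_start.size() - 1;
  const int ntheta = m - 1;
  const int np = ntheta + p + 1;

  std::vector<double> theta(ntheta);
  theta[0] = par[0];
  for (int k = 1; k < ntheta; ++k) theta[k] = theta[k - 1] + std::exp(par[k]);
  const double log_sigma = par[np - 1];
  const double sigma = std::exp(log_sigma);
  const double inv_var = 1.0 / (sigma * sigma);

  std::vector<double> eta(nobs, 0.0);
  for (int j = 0; j < p; ++j) {
    double bj = par[ntheta + j];
    if (bj != 0.0) {
      const double *xc = &X(0, j);
      for (int i = 0; i < nobs; ++i) eta[i] += bj * xc[i];
    }
  }

  const int *yp = &y[0];
  double total = 0.0;
  // gradient in theta-space (theta_1..theta_{m-1}, beta, log_sigma)
  std::vector<double> grad(np, 0.0);
  std::vector<double> g_phi(np), g_bphi(np), g_bbphi(np);
  ObsDerivs o;

  for (int i = 0; i < npat; ++i) {
    const int lo = pat_start[i], hi = pat_start[i + 1];
    double b = solve_mode(yp, eta.data(), lo, hi, theta.data(), m, inv_var,
                          log_sigma, bhat[i]);
    bhat[i] = b;

    double ll = 0.0, lbb = 0.0, lbbb = 0.0;
    if (want_grad) {
      std::fill(g_phi.begin(), g_phi.end(), 0.0);
      std::fill(g_bphi.begin(), g_bphi.end(), 0.0);
      std::fill(g_bbphi.begin(), g_bbphi.end(), 0.0);
    }
    for (int t = lo; t < hi; ++t) {
      int k = yp[t];
      obs_derivs(k, m, theta.data(), eta[t] + b, o);
      ll += o.ll;
      lbb += o.l2;
      lbbb += o.l3;
      if (!want_grad) continue;
      if (k < m - 1) {
        g_phi[k] += o.l_hi;
        g_bphi[k] += o.M_hi;
        g_bbphi[k] += o.L2_hi;
      }
      if (k > 0) {
        g_phi[k - 1] += o.l_lo;
        g_bphi[k - 1] += o.M_lo;
        g_bbphi[k - 1] += o.L2_lo;
      }
      double s_phi = o.l_hi + o.l_lo;
      double s_bphi = o.M_hi + o.M_lo;
      double s_bbphi = o.L2_hi + o.L2_lo;
      for (int j = 0; j < p; ++j) {
        double xx = -X(t, j);
        if (xx != 0.0) {
          g_phi[ntheta + j] += s_phi * xx;
          g_bphi[ntheta + j] += s_bphi * xx;
          g_bbphi[ntheta + j] += s_bbphi * xx;
        }
      }
    }
    // normal prior on b
    ll += -0.5 * b * b * inv_var - log_sigma - 0.5 * std::log(2.0 * M_PI);
    lbb += -inv_var;
    double H = -lbb;
    double wi = w[i];
    total += wi * (ll + 0.5 * std::log(2.0 * M_PI) - 0.5 * std::log(H));
    if (!want_grad) continue;
    g_phi[np - 1] += b * b * inv_var - 1.0;
    g_bphi[np - 1] += 2.0 * b * inv_var;
    g_bbphi[np - 1] += 2.0 * inv_var;
    double iH = 1.0 / H;
    for (int j = 0; j < np; ++j) {
      grad[j] += wi * (g_phi[j] + 0.5 * iH * (g_bbphi[j] + lbbb * g_bphi[j] * iH));
    }
  }

  NumericVector gout(np);
  if (want_grad) {
    // chain from theta-space to raw cutpoint parameters
    double acc = 0.0;
    for (int k = ntheta - 1; k >= 1; --k) {
      acc += grad[k];
      gout[k] = -std::exp(par[k]) * acc;
    }
    acc += grad[0];
    gout[0] = -acc;
    for (int j = ntheta; j < np; ++j) gout[j] = -grad[j];
  }
  double value = std::isfinite(total) ? -total : 1e10;
  return List::create(_["value"] = value, _["gradient"] = gout);
}


// Evaluate NLL and gradient into caller-provided storage; shared by the
// exported objective and the built-in BFGS driver.
static double eval_nll_grad(const std::vector<double> &par, const int *yp,
                            const NumericMatrix &X, const int *ps, int npat,
                            int m, const double *w, double *bhat,
                            std::vector<double> &gout) {
  const int p = X.ncol();
  const int nobs = X.nrow();
  const int ntheta = m - 1;
  const int np = ntheta + p + 1;

  std::vector<double> theta(ntheta);
  theta[0] = par[0];
  for (int k = 1; k < ntheta; ++k) theta[k] = theta[k - 1] + std::exp(par[k]);
  double log_sigma = par[np - 1];
  if (log_sigma < -20.0) log_sigma = -20.0;
  const double sigma = std::exp(log_sigma);
  const double inv_var = 1.0 / (sigma * sigma);

  std::vector<double> eta(nobs, 0.0);
  for (int j = 0; j < p; ++j) {
    double bj = par[ntheta + j];
    if (bj != 0.0) {
      const double *xc = &X(0, j);
      for (int i = 0; i < nobs; ++i) eta[i] += bj * xc[i];
    }
  }

  double total = 0.0;
  std::vector<double> grad(np, 0.0), g_phi(np), g_bphi(np), g_bbphi(np);
  ObsDerivs o;

  for (int i = 0; i < npat; ++i) {
    const int lo = ps[i], hi = ps[i + 1];
    double b = solve_mode(yp, eta.data(), lo, hi, theta.data(), m, inv_var,
                          log_sigma, bhat[i]);
    bhat[i] = b;
    double ll = 0.0, lbb = 0.0, lbbb = 0.0;
    std::fill(g_phi.begin(), g_phi.end(), 0.0);
    std::fill(g_bphi.begin(), g_bphi.end(), 0.0);
    std::fill(g_bbphi.begin(), g_bbphi.end(), 0.0);
    for (int t = lo; t < hi; ++t) {
      int k = yp[t];
      obs_derivs(k, m, theta.data(), eta[t] + b, o);
      ll += o.ll;
      lbb += o.l2;
      lbbb += o.l3;
      if (k < m - 1) {
        g_phi[k] += o.l_hi;
        g_bphi[k] += o.M_hi;
        g_bbphi[k] += o.L2_hi;
      }
      if (k > 0) {
        g_phi[k - 1] += o.l_lo;
        g_bphi[k - 1] += o.M_lo;
        g_bbphi[k - 1] += o.L2_lo;
      }
      double s_phi = o.l_hi + o.l_lo;
      double s_bphi = o.M_hi + o.M_lo;
      double s_bbphi = o.L2_hi + o.L2_lo;
      for (int j = 0; j < p; ++j) {
        double xx = -X(t, j);
        if (xx != 0.0) {
          g_phi[ntheta + j] += s_phi * xx;
          g_bphi[ntheta + j] += s_bphi * xx;
          g_bbphi[ntheta + j] += s_bbphi * xx;
        }
      }
    }
    ll += -0.5 * b * b * inv_var - log_sigma - 0.5 * std::log(2.0 * M_PI);
    lbb += -inv_var;
    double H = -lbb;
    double wi = w[i];
    total += wi * (ll + 0.5 * std::log(2.0 * M_PI) - 0.5 * std::log(H));
    g_phi[np - 1] += b * b * inv_var - 1.0;
    g_bphi[np - 1] += 2.0 * b * inv_var;
    g_bbphi[np - 1] += 2.0 * inv_var;
    double iH = 1.0 / H;
    for (int j = 0; j < np; ++j) {
      grad[j] += wi * (g_phi[j] + 0.5 * iH * (g_bbphi[j] + lbbb * g_bphi[j] * iH));
    }
  }

  // chain to raw cutpoint parameters; negate for NLL
  double acc = 0.0;
  for (int k = ntheta - 1; k >= 1; --k) {
    acc += grad[k];
    gout[k] = -std::exp(par[k]) * acc;
  }
  acc += grad[0];
  gout[0] = -acc;
  for (int j = ntheta; j < np; ++j) gout[j] = -grad[j];
  if (!std::isfinite(total)) return 1e10;
  return -total;
}

// Quasi-Newton (BFGS, inverse-Hessian form) minimisation of the Laplace NLL
// with Armijo backtracking; no R callbacks, so simulation loops pay only for
// arithmetic. Returns par, value, gradient, convergence flag.
// [[Rcpp::export]]
List clmm_bfgs_cpp(NumericVector start, IntegerVector y, NumericMatrix X,
                   IntegerVector pat_start, int m, NumericVector w,
                   int max_iter, double gtol) {
  const int np = start.size();
  const int npat = pat_start.size() - 1;
  std::vector<double> bhat(npat, 0.0);
  std::vector<double> par(start.begin(), start.end());
  std::vector<double> g(np), g_new(np), d(np), par_new(np), s(np), yv(np);
  std::vector<double> Hmat(np * np, 0.0);
  for (int i = 0; i < np; ++i) Hmat[i * np + i] = 1.0;

  double f = eval_nll_grad(par, &y[0], X, &pat_start[0], npat, m, &w[0],
                           bhat.data(), g);
  bool converged = false;
  int it = 0;
  for (; it < max_iter; ++it) {
    double gmax = 0.0;
    for (int i = 0; i < np; ++i) gmax = std::max(gmax, std::fabs(g[i]));
    if (gmax < gtol * (1.0 + std::fabs(f))) { converged = true; break; }
    // d = -H g
    for (int i = 0; i < np; ++i) {
      double acc = 0.0;
      for (int j = 0; j < np; ++j) acc += Hmat[i * np + j] * g[j];
      d[i] = -acc;
    }
    double dg = 0.0;
    for (int i = 0; i < np; ++i) dg += d[i] * g[i];
    if (dg >= 0.0) {  // not a descent direction: reset to steepest descent
      for (int i = 0; i < np; ++i) {
        for (int j = 0; j < np; ++j) Hmat[i * np + j] = (i == j) ? 1.0 : 0.0;
        d[i] = -g[i];
      }
      dg = 0.0;
      for (int i = 0; i < np; ++i) dg -= g[i] * g[i];
    }
    // cap the step so a wild direction cannot overflow the model
    double dmax = 0.0;
    for (int i = 0; i < np; ++i) dmax = std::max(dmax, std::fabs(d[i]));
    double alpha = (dmax > 10.0) ? 10.0 / dmax : 1.0;
    double f_new = f;
    bool ok = false;
    for (int ls = 0; ls < 40; ++ls) {
      for (int i = 0; i < np; ++i) par_new[i] = par[i] + alpha * d[i];
      f_new = eval_nll_grad(par_new, &y[0], X, &pat_start[0], npat, m, &w[0],
                            bhat.data(), g_new);
      if (f_new <= f + 1e-4 * alpha * dg) { ok = true; break; }
      alpha *= 0.5;
    }
    if (!ok) break;
    double sy = 0.0, yy = 0.0;
    for (int i = 0; i < np; ++i) {
      s[i] = par_new[i] - par[i];
      yv[i] = g_new[i] - g[i];
      sy += s[i] * yv[i];
      yy += yv[i] * yv[i];
    }
    if (it == 0 && sy > 0.0 && yy > 0.0) {
      double scale = sy / yy;
      for (int i = 0; i < np; ++i) Hmat[i * np + i] = scale;
    }
    if (sy > 1e-12) {
      // H <- (I - s y'/sy) H (I - y s'/sy) + s s'/sy
      std::vector<double> Hy(np, 0.0);
      for (int i = 0; i < np; ++i) {
        double acc = 0.0;
        for (int j = 0; j < np; ++j) acc += Hmat[i * np + j] * yv[j];
        Hy[i] = acc;
      }
      double yHy = 0.0;
      for (int i = 0; i < np; ++i) yHy += yv[i] * Hy[i];
      double c1 = (sy + yHy) / (sy * sy);
      for (int i = 0; i < np; ++i) {
        for (int j = 0; j < np; ++j) {
          Hmat[i * np + j] += c1 * s[i] * s[j] -
            (Hy[i] * s[j] + s[i] * Hy[j]) / sy;
        }
      }
    }
    par.swap(par_new);
    g.swap(g_new);
    if (std::fabs(f - f_new) < 1e-10 * (1.0 + std::fabs(f))) {
      f = f_new;
      double gm2 = 0.0;
      for (int i = 0; i < np; ++i) gm2 = std::max(gm2, std::fabs(g[i]));
      converged = gm2 < 1e3 * gtol * (1.0 + std::fabs(f));
      break;
    }
    f = f_new;
  }
  return List::create(_["par"] = NumericVector(par.begin(), par.end()),
                      _["value"] = f,
                      _["gradient"] = NumericVector(g.begin(), g.end()),
                      _["converged"] = converged,
                      _["iterations"] = it);
}

// plain objective (used by tests and oracles)
// [[Rcpp::export]]
double clmm_nll_cpp(NumericVector par, IntegerVector y, NumericMatrix X,
                    IntegerVector pat_start, int m) {
  NumericVector bh(pat_start.size() - 1);
  NumericVector w(pat_start.size() - 1, 1.0);
  List r = clmm_obj_grad_cpp(par, y, X, pat_start, m, bh, w, false);
  return as<double>(r["value"]);
}

// central finite-difference gradient (kept as an independent check of the
// analytic gradient)
// [[Rcpp::export]]
NumericVector clmm_nll_grad_fd_cpp(NumericVector par, IntegerVector y,
                                   NumericMatrix X, IntegerVector pat_start,
                                   int m) {
  int np = par.size();
  NumericVector g(np);
  NumericVector pp = clone(par);
  for (int k = 0; k < np; ++k) {
    double h = 1e-6 * (1.0 + std::fabs(par[k]));
    pp[k] = par[k] + h;
    double fu = clmm_nll_cpp(pp, y, X, pat_start, m);
    pp[k] = par[k] - h;
    double fl = clmm_nll_cpp(pp, y, X, pat_start, m);
    pp[k] = par[k];
    g[k] = (fu - fl) / (2.0 * h);
  }
  return g;
}

// conditional modes of the random intercepts at given parameters
// [[Rcpp::export]]
NumericVector clmm_ranef_cpp(NumericVector par, IntegerVector y,
                             NumericMatrix X, IntegerVector pat_start, int m) {
  int p = X.ncol();
  int nobs = X.nrow();
  int npat = pat_start.size() - 1;
  int ntheta = m - 1;
  std::vector<double> theta(ntheta);
  theta[0] = par[0];
  for (int k = 1; k < ntheta; ++k) theta[k] = theta[k - 1] + std::exp(par[k]);
  double log_sigma = par[ntheta + p];
  double sigma = std::exp(log_sigma);
  double inv_var = 1.0 / (sigma * sigma);
  std::vector<double> eta(nobs, 0.0);
  for (int j = 0; j < p; ++j) {
    double bj = par[ntheta + j];
    for (int i = 0; i < nobs; ++i) eta[i] += bj * X(i, j);
  }
  NumericVector out(npat);
  for (int i = 0; i < npat; ++i) {
    out[i] = solve_mode(&y[0], eta.data(), pat_start[i], pat_start[i + 1],
                        theta.data(), m, inv_var, log_sigma, 0.0);
  }
  return out;
}
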