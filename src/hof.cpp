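// Huisman-Olff-Fresco response models I-VII on a [0,1]-scaled gradient,
// Bernoulli negative log-likelihood, and bounded multi-start Nelder-Mead
// fitting.  Kept in C++ because the resampling scheme refits the whole
// seven-model family hundreds of times per species.

#include <Rcpp.h>
#include <R_ext/Applic.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double P_EPS = 1e-9;

// numerically stable 1 / (1 + exp(t))
static inline double inv1pexp(double t) {
  if (t > 0.0) {
    double e = std::exp(-t);
    return e / (1.0 + e);
  }
  return 1.0 / (1.0 + std::exp(t));
}

// single skewed hump shared by models IV (d = b), V, VI, VII
static inline double hump(double u, double a, double b, double c, double d) {
  return inv1pexp(a + b * u) * inv1pexp(c - d * u);
}

// Response y(u) for model `type` (1..7) with parameter vector:
//   I:   a
//   II:  a, b
//   III: a, b, c
//   IV:  a, b, c            (second slope tied to b)
//   V:   a, b, c, d
//   VI:  a, b, c, f         (two IV-shaped humps, second shifted by f)
//   VII: a, b, c, f, r      (second hump height scaled by r)
static double hof_y(int type, const double* p, double u) {
  double y = 0.0;
  switch (type) {
  case 1: y = inv1pexp(p[0]); break;
  case 2: y = inv1pexp(p[0] + p[1] * u); break;
  case 3: y = inv1pexp(p[0] + p[1] * u) * inv1pexp(p[2]); break;
  case 4: y = hump(u, p[0], p[1], p[2], p[1]); break;
  case 5: y = hump(u, p[0], p[1], p[2], p[3]); break;
  case 6: y = hump(u, p[0], p[1], p[2], p[1]) +
              hump(u - p[3], p[0], p[1], p[2], p[1]); break;
  case 7: y = hump(u, p[0], p[1], p[2], p[1]) +
              p[4] * hump(u - p[3], p[0], p[1], p[2], p[1]); break;
  default: Rcpp::stop("unknown HOF model type");
  }
  if (y < 0.0) y = 0.0;
  if (y > 1.0) y = 1.0;
  return y;
}

// [[Rcpp::export(name = ".hof_response_cpp")]]
NumericVector hof_response_cpp(int type, NumericVector params, NumericVector u) {
  int n = u.size();
  NumericVector out(n);
  std::vector<double> p(params.begin(), params.end());
  for (int i = 0; i < n; ++i) out[i] = hof_y(type, p.data(), u[i]);
  return out;
}

static double nll_core(int type, const double* p, const double* u,
                       const double* y, int n) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    double pr = hof_y(type, p, u[i]);
    if (pr < P_EPS) pr = P_EPS;
    if (pr > 1.0 - P_EPS) pr = 1.0 - P_EPS;
    s -= y[i] * std::log(pr) + (1.0 - y[i]) * std::log(1.0 - pr);
  }
  return s;
}

// [[Rcpp::export(name = ".hof_nll_cpp")]]
double hof_nll_cpp(int type, NumericVector params, NumericVector u,
                   NumericVector y) {
  std::vector<double> p(params.begin(), params.end());
  return nll_core(type, p.data(), u.begin(), y.begin(), u.size());
}

// ---- bounded optimisation via sigmoid reparameterisation --------------
// free theta in R^k maps to par = lo + (hi - lo) * plogis(theta), so any
// Nelder-Mead iterate respects the box.

struct HofData {
  int type, k, n;
  const double* u;
  const double* y;
  const double* lo;
  const double* hi;
};

static inline double theta_to_par(double th, double lo, double hi) {
  return lo + (hi - lo) * inv1pexp(-th);
}

static double obj_fn(int k, double* theta, void* ex) {
  HofData* d = static_cast<HofData*>(ex);
  double par[5];
  for (int j = 0; j < k; ++j) par[j] = theta_to_par(theta[j], d->lo[j], d->hi[j]);
  return nll_core(d->type, par, d->u, d->y, d->n);
}

// Multi-start Nelder-Mead fit of one model type.  `starts` is an S x k
// matrix of starting values in *parameter* space (inside the box).
// Returns best parameters, NLL and convergence flag.
// [[Rcpp::export(name = ".hof_fit_cpp")]]
List hof_fit_cpp(int type, NumericVector u, NumericVector y,
                 NumericMatrix starts, NumericVector lower,
                 NumericVector upper, int maxit) {
  int k = starts.ncol(), S = starts.nrow(), n = u.size();
  if (k != lower.size() || k != upper.size())
    Rcpp::stop("bounds length must match parameter count");

  HofData d;
  d.type = type; d.k = k; d.n = n;
  d.u = u.begin(); d.y = y.begin();
  d.lo = lower.begin(); d.hi = upper.begin();

  std::vector<double> theta(k), out(k);
  int any_ok = 0;

  // screen every start with a short Nelder-Mead run ...
  int maxit_screen = maxit < 50 ? maxit : 50;
  std::vector<std::vector<double> > screened(S, std::vector<double>(k));
  std::vector<double> screened_f(S);
  for (int s = 0; s < S; ++s) {
    for (int j = 0; j < k; ++j) {
      // invert the sigmoid map; clamp away from the box edges
      double w = (starts(s, j) - lower[j]) / (upper[j] - lower[j]);
      if (w < 0.02) w = 0.02;
      if (w > 0.98) w = 0.98;
      theta[j] = std::log(w / (1.0 - w));
    }
    double fmin = 0.0;
    int fail = 0, fncount = 0;
    nmmin(k, theta.data(), out.data(), &fmin, obj_fn, &fail, -R_PosInf,
          1e-8, &d, 1.0, 0.5, 2.0, 0, &fncount, maxit_screen);
    screened[s] = out;
    screened_f[s] = fmin;
  }
  // ... then polish the most promising to convergence
  std::vector<double> best_theta = screened[0];
  double best_f = R_PosInf;
  for (int round = 0; round < 1; ++round) {
    int s_best = 0;
    for (int s = 1; s < S; ++s)
      if (screened_f[s] < screened_f[s_best]) s_best = s;
    theta = screened[s_best];
    screened_f[s_best] = R_PosInf;
    double fmin = 0.0;
    int fail = 0, fncount = 0;
    nmmin(k, theta.data(), out.data(), &fmin, obj_fn, &fail, -R_PosInf,
          1e-8, &d, 1.0, 0.5, 2.0, 0, &fncount, maxit);
    if (fmin < best_f) {
      best_f = fmin;
      best_theta = out;
      any_ok = (fail == 0) ? 1 : 0;
    }
  }

  NumericVector par(k);
  for (int j = 0; j < k; ++j)
    par[j] = theta_to_par(best_theta[j], lower[j], upper[j]);
  return List::create(_["par"] = par, _["nll"] = best_f,
                      _["converged"] = any_ok == 1);
}
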