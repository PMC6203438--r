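#include <Rcpp.h>
using namespace Rcpp;

// First-passage-time machinery for the Wiener diffusion with unit variance,
// absorbing bounds at 0 and a, start a*z, drift v. Times are decision times
// (non-decision latencies are added/subtracted by the callers in R).

// log density of absorption at the LOWER bound at decision time t.
// Series in normalised time u = t/a^2; small-time and large-time expansions
// with the usual term-count switching rule at truncation tolerance `tol`.
static double wfpt_log_lower(double t, double v, double a, double w,
                             double tol) {
  if (t <= 0.0 || !R_finite(t)) return R_NegInf;
  double u = t / (a * a);

  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * u) * tol < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * u * std::log(2.0 * tol *
                                             std::sqrt(2.0 * M_PI * u)));
    ks = std::max(ks, std::sqrt(u) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * u * tol < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * u * tol) / (M_PI * M_PI * u));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(u)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(u));
  }

  double p;
  if (ks < kl) {  // small-time expansion
    int K = (int)std::ceil(ks);
    int lo = -(int)std::floor((K - 1) / 2.0);
    int hi = (int)std::ceil((K - 1) / 2.0);
    p = 0.0;
    for (int k = lo; k <= hi; ++k) {
      double q = w + 2.0 * k;
      p += q * std::exp(-q * q / (2.0 * u));
    }
    p /= std::sqrt(2.0 * M_PI * u * u * u);
  } else {        // large-time expansion
    int K = (int)std::ceil(kl);
    p = 0.0;
    for (int k = 1; k <= K; ++k) {
      p += k * std::exp(-k * k * M_PI * M_PI * u / 2.0) *
           std::sin(k * M_PI * w);
    }
    p *= M_PI;
  }
  if (!(p > 0.0)) return R_NegInf;
  return std::log(p) - v * a * w - v * v * t / 2.0 - 2.0 * std::log(a);
}

// [[Rcpp::export]]
NumericVector wfpt_log_density_cpp(NumericVector t, IntegerVector upper,
                                   NumericVector v, double a, double z,
                                   double tol) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (upper[i] == 1)
      out[i] = wfpt_log_lower(t[i], -v[i], a, 1.0 - z, tol);
    else
      out[i] = wfpt_log_lower(t[i], v[i], a, z, tol);
  }
  return out;
}

// Summed negative log-likelihood for one reward context.
// rt are full response times; the choice-specific non-decision time is
// subtracted here so that impossible observations (rt <= t_nd) yield +Inf.
// [[Rcpp::export]]
double ddm_negloglik_cpp(NumericVector rt, IntegerVector right,
                         NumericVector coh, double a, double k,
                         double t0, double t1, double z, double me,
                         double tol) {
  int n = rt.size();
  double nll = 0.0;
  for (int i = 0; i < n; ++i) {
    double v = k * (coh[i] + me);
    double td, ld;
    if (right[i] == 1) {
      td = rt[i] - t1;
      ld = wfpt_log_lower(td, -v, a, 1.0 - z, tol);
    } else {
      td = rt[i] - t0;
      ld = wfpt_log_lower(td, v, a, z, tol);
    }
    if (ld == R_NegInf) return R_PosInf;
    nll -= ld;
  }
  return nll;
}

// Euler-Maruyama walk between fixed bounds 0 and a, start a*z, step
// drift*dt + sqrt(dt)*N(0,1). With bridge=true a Brownian-bridge crossing
// test is applied within each step, removing the O(sqrt(dt)) first-passage
// bias of the plain scheme.
// [[Rcpp::export]]
List ddm_simulate_cpp(int n, double v, double a, double z, double dt,
                      double max_t, bool bridge) {
  IntegerVector choice(n);   // 1 = upper/right, 0 = lower/left
  NumericVector tdec(n);
  LogicalVector censored(n);
  double sdt = std::sqrt(dt);
  double mu = v * dt;
  int max_steps = (int)std::ceil(max_t / dt);
  double cut = 20.0 * dt;  // bridge-crossing prob below exp(-40): skip

  for (int i = 0; i < n; ++i) {
    double x = a * z;
    double t = 0.0;
    int ch = -1;
    for (int s = 0; s < max_steps; ++s) {
      double y = x + mu + sdt * R::norm_rand();
      t += dt;
      if (y >= a) { ch = 1; break; }
      if (y <= 0.0) { ch = 0; break; }
      if (bridge) {
        double qu = (a - x) * (a - y);
        if (qu < cut && R::unif_rand() < std::exp(-2.0 * qu / dt)) {
          ch = 1; break;
        }
        double ql = x * y;
        if (ql < cut && R::unif_rand() < std::exp(-2.0 * ql / dt)) {
          ch = 0; break;
        }
      }
      x = y;
    }
    if (ch < 0) {        // censored at the horizon; report nearer bound
      censored[i] = true;
      ch = (x > a / 2.0) ? 1 : 0;
      t = max_t;
    }
    choice[i] = ch;
    tdec[i] = t;
  }
  return List::create(_["choice"] = choice, _["tdec"] = tdec,
                      _["censored"] = censored);
}

// Collapsing-bound variant: bound distance a/(1+exp(beta*t-d)), both bounds
// collapsing symmetrically toward a/2; start a*z held fixed.
// [[Rcpp::export]]
List ddm_simulate_collapse_cpp(int n, double v, double a, double z,
                               double beta, double d, double dt,
                               double max_t) {
  IntegerVector choice(n);
  NumericVector tdec(n);
  LogicalVector censored(n);
  double sdt = std::sqrt(dt);
  double mu = v * dt;
  int max_steps = (int)std::ceil(max_t / dt);
  double cut = 20.0 * dt;

  for (int i = 0; i < n; ++i) {
    double x = a * z;
    double t = 0.0;
    int ch = -1;
    // immediate decision if the start lies outside the initial bounds
    {
      double h0 = a / (2.0 * (1.0 + std::exp(-d)));
      if (x >= a / 2.0 + h0) ch = 1;
      else if (x <= a / 2.0 - h0) ch = 0;
    }
    if (ch < 0) {
      double hu_prev = a / 2.0 + a / (2.0 * (1.0 + std::exp(-d)));
      double hl_prev = a - hu_prev;
      for (int s = 0; s < max_steps; ++s) {
        double y = x + mu + sdt * R::norm_rand();
        t += dt;
        double half = a / (2.0 * (1.0 + std::exp(beta * t - d)));
        double ub = a / 2.0 + half, lb = a / 2.0 - half;
        if (y >= ub) { ch = 1; break; }
        if (y <= lb) { ch = 0; break; }
        // bridge test against the (slowly moving) bounds
        double qu = (hu_prev - x) * (ub - y);
        if (qu > 0 && qu < cut && R::unif_rand() < std::exp(-2.0 * qu / dt)) {
          ch = 1; break;
        }
        double ql = (x - hl_prev) * (y - lb);
        if (ql > 0 && ql < cut && R::unif_rand() < std::exp(-2.0 * ql / dt)) {
          ch = 0; break;
        }
        x = y; hu_prev = ub; hl_prev = lb;
      }
    }
    if (ch < 0) {
      censored[i] = true;
      ch = (x > a / 2.0) ? 1 : 0;
      t = max_t;
    }
    choice[i] = ch;
    tdec[i] = t;
  }
  return List::create(_["choice"] = choice, _["tdec"] = tdec,
                      _["censored"] = censored);
}
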