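#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Feedback evaluation for the analytic variants; code: 0 constant, 1 linear,
// 2 Michaelis-Menten, 3 Hill. par = (b, v, K, h). K is in molecules^h for the
// Hill variant, matching the n^h/(n^h + K) parameterization.
static inline double feval(int code, const double *par, double n) {
  switch (code) {
  case 0: return par[0];
  case 1: return par[0] + par[1] * n;
  case 2: return par[0] + par[1] * n / (n + par[2]);
  default: {
    double nh = std::pow(n, par[3]);
    return par[0] + par[1] * nh / (nh + par[2]);
  }
  }
}

// Geometric burst size with mean mu (support 1, 2, ...); inverse-CDF sampler.
// mu == 1 degenerates to a point mass at 1.
static inline int rgeom_burst(double mu) {
  if (mu <= 1.0) return 1;
  double u;
  do { u = unif_rand(); } while (u <= 0.0 || u >= 1.0);
  double m = 1.0 + std::floor(std::log(u) / std::log(1.0 - 1.0 / mu));
  if (m < 1.0) m = 1.0;
  if (m > 2147483000.0) m = 2147483000.0;
  return (int)m;
}

// Endpoint ensemble: state at t_end for each replicate (the state before the
// first event whose waiting time crosses the horizon).
// [[Rcpp::export]]
IntegerVector ssa_burst_ends_cpp(int code, NumericVector par, double mu,
                                 double delta, IntegerVector n0, double t_end) {
  int nruns = n0.size();
  IntegerVector out(nruns);
  const double *p = REAL(par);
  for (int r = 0; r < nruns; ++r) {
    int n = n0[r];
    double t = 0.0;
    for (;;) {
      double wb = feval(code, p, (double)n) / mu;
      double wd = delta * (double)n;
      double wt = wb + wd;
      if (wt <= 0.0) break;
      double tau = exp_rand() / wt;
      if (t + tau > t_end) break;
      t += tau;
      if (unif_rand() * wt < wb) n += rgeom_burst(mu);
      else n -= 1;
    }
    out[r] = n;
  }
  return out;
}

// Piecewise-constant sample path of the burst model: event times and states.
// [[Rcpp::export]]
List ssa_burst_path_cpp(int code, NumericVector par, double mu, double delta,
                        int n0, double t_end, int max_events) {
  std::vector<double> tv;
  std::vector<int> nv;
  const double *p = REAL(par);
  int n = n0;
  double t = 0.0;
  tv.push_back(0.0); nv.push_back(n);
  int frozen = 0;
  for (int ev = 0; ev < max_events; ++ev) {
    double wb = feval(code, p, (double)n) / mu;
    double wd = delta * (double)n;
    double wt = wb + wd;
    if (wt <= 0.0) { frozen = 1; break; }
    double tau = exp_rand() / wt;
    if (t + tau > t_end) break;
    t += tau;
    if (unif_rand() * wt < wb) n += rgeom_burst(mu);
    else n -= 1;
    tv.push_back(t); nv.push_back(n);
  }
  return List::create(_["t"] = wrap(tv), _["n"] = wrap(nv),
                      _["frozen"] = frozen);
}

// First-passage times of the burst model into {n <= lo} U {n >= hi}.
// Returns NA for replicates that do not hit within t_max.
// [[Rcpp::export]]
NumericVector ssa_burst_hitting_cpp(int code, NumericVector par, double mu,
                                    double delta, int n0, int lo, int hi,
                                    double t_max, int n_rep) {
  NumericVector out(n_rep);
  const double *p = REAL(par);
  for (int r = 0; r < n_rep; ++r) {
    int n = n0;
    double t = 0.0;
    double hit = NA_REAL;
    if (n <= lo || n >= hi) { out[r] = 0.0; continue; }
    for (;;) {
      double wb = feval(code, p, (double)n) / mu;
      double wd = delta * (double)n;
      double wt = wb + wd;
      if (wt <= 0.0) break;           // frozen outside the target: never hits
      t += exp_rand() / wt;
      if (t > t_max) break;
      if (unif_rand() * wt < wb) n += rgeom_burst(mu);
      else n -= 1;
      if (n <= lo || n >= hi) { hit = t; break; }
    }
    out[r] = hit;
  }
  return out;
}

// Direct-method SSA for a general elementary network.
// kappa: R stochastic constants; beta: M x R educt coefficients;
// anu: M x R net stoichiometry. Records the state at the requested times
// (piecewise-constant interpolation), one column per species.
// [[Rcpp::export]]
IntegerMatrix ssa_network_cpp(NumericVector kappa, IntegerMatrix beta,
                              IntegerMatrix anu, IntegerVector n0,
                              NumericVector t_record) {
  int M = beta.nrow(), R = beta.ncol(), T = t_record.size();
  IntegerMatrix out(T, M);
  std::vector<int> n(n0.begin(), n0.end());
  std::vector<double> w(R);
  double t = 0.0;
  int ti = 0;
  for (;;) {
    double wt = 0.0;
    for (int j = 0; j < R; ++j) {
      double wj = kappa[j];
      for (int i = 0; i < M; ++i) {
        int b = beta(i, j);
        if (b > 0) {
          // binomial coefficient choose(n_i, b), zero when n_i < b
          double c = 1.0;
          if (n[i] < b) { c = 0.0; }
          else for (int q = 0; q < b; ++q) c *= (double)(n[i] - q) / (double)(q + 1);
          wj *= c;
        }
        if (wj == 0.0) break;
      }
      w[j] = wj;
      wt += wj;
    }
    double tnext = (wt > 0.0) ? t + exp_rand() / wt : R_PosInf;
    while (ti < T && t_record[ti] < tnext) {
      for (int i = 0; i < M; ++i) out(ti, i) = n[i];
      ++ti;
    }
    if (ti >= T || wt <= 0.0) break;
    t = tnext;
    double u = unif_rand() * wt;
    int j = 0;
    double acc = w[0];
    while (j < R - 1 && u > acc) acc += w[++j];
    for (int i = 0; i < M; ++i) {
      n[i] += anu(i, j);
      if (n[i] < 0) n[i] = 0;  // cannot occur for valid propensities
    }
  }
  // any remaining record times (system frozen)
  for (; ti < T; ++ti) for (int i = 0; i < M; ++i) out(ti, i) = n[i];
  return out;
}
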