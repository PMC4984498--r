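#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Two-state Markov (Mk2) pruning likelihood.
//
// Trees arrive as ape postorder edge matrices (1-based ids: tips 1..ntip,
// root ntip+1). The 2x2 transition probability matrix has the closed form
//   P(t) = Pi + (I - Pi) exp(-(q01+q10) t),  Pi = stationary projection,
// so no matrix exponential is needed. Partial likelihoods are rescaled at
// every node; the log scalers accumulate into the returned log-likelihood.
//
// root_prior codes: 0 flat, 1 stationary, 2 obs-weighted (FitzJohn), 3 fixed.
// clamp_node/clamp_state (0 = no clamp) zero out the other state's partial at
// one node, which turns the same pruning pass into a marginal-ASR evaluator.
// ---------------------------------------------------------------------------

static inline void mk2_pmat(double q01, double q10, double t, double P[4]) {
  double q = q01 + q10;
  if (q <= 0.0 || t <= 0.0) {
    P[0] = 1.0; P[1] = 0.0; P[2] = 0.0; P[3] = 1.0;
    return;
  }
  double pi0 = q10 / q, pi1 = q01 / q;
  double e = std::exp(-q * t);
  P[0] = pi0 + pi1 * e;
  P[1] = pi1 * (1.0 - e);
  P[2] = pi0 * (1.0 - e);
  P[3] = pi1 + pi0 * e;
}

static double mk2_core(const IntegerMatrix& edge, const NumericVector& el,
                       int ntip, const IntegerVector& tip_state,
                       double q01, double q10,
                       int root_prior, int root_state,
                       int clamp_node, int clamp_state) {
  int nedge = edge.nrow();
  int nmax = 2 * ntip - 1;
  for (int i = 0; i < nedge; ++i) {
    if (edge(i, 0) > nmax) nmax = edge(i, 0);
    if (edge(i, 1) > nmax) nmax = edge(i, 1);
  }
  std::vector<double> d0(nmax + 1, 1.0), d1(nmax + 1, 1.0);
  for (int i = 1; i <= ntip; ++i) {
    int s = tip_state[i - 1];
    if (s == 0)      { d0[i] = 1.0; d1[i] = 0.0; }
    else if (s == 1) { d0[i] = 0.0; d1[i] = 1.0; }
    else             { d0[i] = 1.0; d1[i] = 1.0; }  // unknown: marginalized
  }
  double logscale = 0.0;
  double P[4];
  for (int i = 0; i < nedge; ++i) {
    int par = edge(i, 0), ch = edge(i, 1);
    if (ch == clamp_node) {
      if (clamp_state == 0) d1[ch] = 0.0; else d0[ch] = 0.0;
    }
    double s = d0[ch] + d1[ch];
    if (!(s > 0.0)) return R_NegInf;
    d0[ch] /= s; d1[ch] /= s;
    logscale += std::log(s);
    mk2_pmat(q01, q10, el[i], P);
    double m0 = P[0] * d0[ch] + P[1] * d1[ch];
    double m1 = P[2] * d0[ch] + P[3] * d1[ch];
    d0[par] *= m0;
    d1[par] *= m1;
  }
  int root = edge(nedge - 1, 0);
  if (root == clamp_node) {
    if (clamp_state == 0) d1[root] = 0.0; else d0[root] = 0.0;
  }
  double r0 = d0[root], r1 = d1[root];
  double s = r0 + r1;
  if (!(s > 0.0)) return R_NegInf;
  double w0, w1;
  switch (root_prior) {
  case 1: {  // stationary
    double q = q01 + q10;
    if (q <= 0.0) { w0 = 0.5; w1 = 0.5; }
    else { w0 = q10 / q; w1 = q01 / q; }
    break;
  }
  case 2:  // obs-weighted
    w0 = r0 / s; w1 = r1 / s;
    break;
  case 3:  // fixed
    w0 = (root_state == 0) ? 1.0 : 0.0;
    w1 = 1.0 - w0;
    break;
  default:
    w0 = 0.5; w1 = 0.5;
  }
  double lik = w0 * r0 + w1 * r1;
  if (!(lik > 0.0)) return R_NegInf;
  return std::log(lik) + logscale;
}

// [[Rcpp::export(name = ".mk2_loglik_cpp")]]
double mk2_loglik_cpp(IntegerMatrix edge, NumericVector el, int ntip,
                      IntegerVector tip_state, double q01, double q10,
                      int root_prior, int root_state,
                      int clamp_node = 0, int clamp_state = 0) {
  return mk2_core(edge, el, ntip, tip_state, q01, q10,
                  root_prior, root_state, clamp_node, clamp_state);
}

// Marginal ancestral states at all internal nodes, by clamping each node to
// each state and re-running the pruning pass. Rows are nodes ntip+1..2ntip-1.
// [[Rcpp::export(name = ".mk2_marginal_cpp")]]
NumericMatrix mk2_marginal_cpp(IntegerMatrix edge, NumericVector el, int ntip,
                               IntegerVector tip_state, double q01, double q10,
                               int root_prior, int root_state) {
  int nint = ntip - 1;
  NumericMatrix out(nint, 2);
  for (int k = 0; k < nint; ++k) {
    int node = ntip + 1 + k;
    double l0 = mk2_core(edge, el, ntip, tip_state, q01, q10,
                         root_prior, root_state, node, 0);
    double l1 = mk2_core(edge, el, ntip, tip_state, q01, q10,
                         root_prior, root_state, node, 1);
    double m = std::max(l0, l1);
    double e0 = std::isfinite(l0) ? std::exp(l0 - m) : 0.0;
    double e1 = std::isfinite(l1) ? std::exp(l1 - m) : 0.0;
    out(k, 0) = e0 / (e0 + e1);
    out(k, 1) = e1 / (e0 + e1);
  }
  return out;
}

// ---------------------------------------------------------------------------
// BiSSE likelihood: coupled extinction/data ODEs integrated branch-wise with
// an embedded Dormand-Prince 5(4) adaptive step, E clamped to [0,1] and
// D clamped non-negative after every accepted step. Parameter vector:
// (lambda0, lambda1, mu0, mu1, q01, q10).
// ---------------------------------------------------------------------------

struct BisseP { double la0, la1, mu0, mu1, q01, q10; };

static inline void bisse_rhs(const BisseP& p, const double y[4], double dy[4]) {
  const double E0 = y[0], E1 = y[1], D0 = y[2], D1 = y[3];
  dy[0] = p.mu0 - (p.la0 + p.mu0 + p.q01) * E0 + p.la0 * E0 * E0 + p.q01 * E1;
  dy[1] = p.mu1 - (p.la1 + p.mu1 + p.q10) * E1 + p.la1 * E1 * E1 + p.q10 * E0;
  dy[2] = -(p.la0 + p.mu0 + p.q01) * D0 + p.q01 * D1 + 2.0 * p.la0 * E0 * D0;
  dy[3] = -(p.la1 + p.mu1 + p.q10) * D1 + p.q10 * D0 + 2.0 * p.la1 * E1 * D1;
}

// Integrates y over [0, len]; returns false on step-size failure.
static bool bisse_integrate(const BisseP& p, double y[4], double len,
                            double rtol, double atol) {
  if (len <= 0.0) return true;
  const double c2 = 1.0/5, c3 = 3.0/10, c4 = 4.0/5, c5 = 8.0/9;
  const double a21 = 1.0/5;
  const double a31 = 3.0/40, a32 = 9.0/40;
  const double a41 = 44.0/45, a42 = -56.0/15, a43 = 32.0/9;
  const double a51 = 19372.0/6561, a52 = -25360.0/2187,
               a53 = 64448.0/6561, a54 = -212.0/729;
  const double a61 = 9017.0/3168, a62 = -355.0/33, a63 = 46732.0/5247,
               a64 = 49.0/176, a65 = -5103.0/18656;
  const double b1 = 35.0/384, b3 = 500.0/1113, b4 = 125.0/192,
               b5 = -2187.0/6784, b6 = 11.0/84;
  const double e1 = b1 - 5179.0/57600, e3 = b3 - 7571.0/16695,
               e4 = b4 - 393.0/640, e5 = b5 + 92097.0/339200,
               e6 = b6 - 187.0/2100, e7 = -1.0/40;
  double t = 0.0;
  double h = len / 10.0;
  if (h > 1.0) h = 1.0;
  double k1[4], k2[4], k3[4], k4[4], k5[4], k6[4], k7[4], yt[4], y5[4];
  int nsteps = 0;
  bisse_rhs(p, y, k1);
  while (t < len) {
    if (++nsteps > 1000000) return false;
    if (h > len - t) h = len - t;
    for (int i = 0; i < 4; ++i) yt[i] = y[i] + h * a21 * k1[i];
    bisse_rhs(p, yt, k2);
    for (int i = 0; i < 4; ++i) yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    bisse_rhs(p, yt, k3);
    for (int i = 0; i < 4; ++i)
      yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    bisse_rhs(p, yt, k4);
    for (int i = 0; i < 4; ++i)
      yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    bisse_rhs(p, yt, k5);
    for (int i = 0; i < 4; ++i)
      yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                          a64 * k4[i] + a65 * k5[i]);
    bisse_rhs(p, yt, k6);
    for (int i = 0; i < 4; ++i)
      y5[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                          b5 * k5[i] + b6 * k6[i]);
    bisse_rhs(p, y5, k7);
    double errn = 0.0;
    for (int i = 0; i < 4; ++i) {
      double err = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                        e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double r = err / sc;
      errn += r * r;
    }
    errn = std::sqrt(errn / 4.0);
    if (errn <= 1.0) {
      t += h;
      for (int i = 0; i < 4; ++i) y[i] = y5[i];
      if (y[0] < 0.0) y[0] = 0.0; else if (y[0] > 1.0) y[0] = 1.0;
      if (y[1] < 0.0) y[1] = 0.0; else if (y[1] > 1.0) y[1] = 1.0;
      if (y[2] < 0.0) y[2] = 0.0;
      if (y[3] < 0.0) y[3] = 0.0;
      for (int i = 0; i < 4; ++i) k1[i] = k7[i];  // FSAL
      double fac = (errn > 1e-12) ? 0.9 * std::pow(errn, -0.2) : 5.0;
      if (fac > 5.0) fac = 5.0;
      h *= fac;
    } else {
      double fac = 0.9 * std::pow(errn, -0.2);
      if (fac < 0.2) fac = 0.2;
      h *= fac;
      if (h < 1e-14 * len) return false;
      bisse_rhs(p, y, k1);  // restart FSAL from current y
    }
    if (!std::isfinite(y[0]) || !std::isfinite(y[2]) || !std::isfinite(y[3]))
      return false;
  }
  return true;
}

// [[Rcpp::export(name = ".bisse_branch_cpp")]]
NumericVector bisse_branch_cpp(NumericVector y0, double len, NumericVector pars,
                               double rtol = 1e-8, double atol = 1e-10) {
  BisseP p = {pars[0], pars[1], pars[2], pars[3], pars[4], pars[5]};
  double y[4] = {y0[0], y0[1], y0[2], y0[3]};
  if (!bisse_integrate(p, y, len, rtol, atol))
    stop("BiSSE branch integration failed");
  return NumericVector::create(y[0], y[1], y[2], y[3]);
}

static double bisse_core(const IntegerMatrix& edge, const NumericVector& el,
                         int ntip, const IntegerVector& tip_state,
                         const BisseP& p, double f0, double f1,
                         bool cond_surv, int root_prior, int root_state,
                         int clamp_node, int clamp_state,
                         double rtol, double atol) {
  int nedge = edge.nrow();
  int nmax = 2 * ntip - 1;
  for (int i = 0; i < nedge; ++i) {
    if (edge(i, 0) > nmax) nmax = edge(i, 0);
    if (edge(i, 1) > nmax) nmax = edge(i, 1);
  }
  std::vector<double> E0(nmax + 1, 0.0), E1(nmax + 1, 0.0);
  std::vector<double> D0(nmax + 1, 1.0), D1(nmax + 1, 1.0);
  std::vector<int> nchild(nmax + 1, 0);
  for (int i = 1; i <= ntip; ++i) {
    int s = tip_state[i - 1];
    E0[i] = 1.0 - f0; E1[i] = 1.0 - f1;
    if (s == 0)      { D0[i] = f0;  D1[i] = 0.0; }
    else if (s == 1) { D0[i] = 0.0; D1[i] = f1;  }
    else             { D0[i] = f0;  D1[i] = f1;  }
  }
  double logscale = 0.0;
  for (int i = 0; i < nedge; ++i) {
    int par = edge(i, 0), ch = edge(i, 1);
    if (ch > ntip) {  // finalize internal node: speciation event
      D0[ch] *= p.la0;
      D1[ch] *= p.la1;
    }
    if (ch == clamp_node) {
      if (clamp_state == 0) D1[ch] = 0.0; else D0[ch] = 0.0;
    }
    double s = D0[ch] + D1[ch];
    if (!(s > 0.0)) return R_NegInf;
    D0[ch] /= s; D1[ch] /= s;
    logscale += std::log(s);
    double y[4] = {E0[ch], E1[ch], D0[ch], D1[ch]};
    if (!bisse_integrate(p, y, el[i], rtol, atol)) return R_NaN;
    double s2 = y[2] + y[3];
    if (!(s2 > 0.0)) return R_NegInf;
    logscale += std::log(s2);
    D0[par] *= y[2] / s2;
    D1[par] *= y[3] / s2;
    if (nchild[par] == 0) { E0[par] = y[0]; E1[par] = y[1]; }
    else { E0[par] = 0.5 * (E0[par] + y[0]); E1[par] = 0.5 * (E1[par] + y[1]); }
    nchild[par] += 1;
  }
  int root = edge(nedge - 1, 0);
  D0[root] *= p.la0;
  D1[root] *= p.la1;
  if (root == clamp_node) {
    if (clamp_state == 0) D1[root] = 0.0; else D0[root] = 0.0;
  }
  double r0 = D0[root], r1 = D1[root];
  double s = r0 + r1;
  if (!(s > 0.0)) return R_NegInf;
  double w0, w1;
  switch (root_prior) {
  case 1: {
    double q = p.q01 + p.q10;
    if (q <= 0.0) { w0 = 0.5; w1 = 0.5; }
    else { w0 = p.q10 / q; w1 = p.q01 / q; }
    break;
  }
  case 2:
    w0 = r0 / s; w1 = r1 / s;
    break;
  case 3:
    w0 = (root_state == 0) ? 1.0 : 0.0;
    w1 = 1.0 - w0;
    break;
  default:
    w0 = 0.5; w1 = 0.5;
  }
  double lik = w0 * r0 + w1 * r1;
  if (cond_surv) {
    double denom = w0 * p.la0 * (1.0 - E0[root]) * (1.0 - E0[root]) +
                   w1 * p.la1 * (1.0 - E1[root]) * (1.0 - E1[root]);
    if (!(denom > 0.0)) return R_NegInf;
    lik /= denom;
  }
  if (!(lik > 0.0)) return R_NegInf;
  return std::log(lik) + logscale;
}

// [[Rcpp::export(name = ".bisse_loglik_cpp")]]
double bisse_loglik_cpp(IntegerMatrix edge, NumericVector el, int ntip,
                        IntegerVector tip_state, NumericVector pars,
                        double f0, double f1, bool cond_surv,
                        int root_prior, int root_state,
                        int clamp_node = 0, int clamp_state = 0,
                        double rtol = 1e-8, double atol = 1e-10) {
  BisseP p = {pars[0], pars[1], pars[2], pars[3], pars[4], pars[5]};
  return bisse_core(edge, el, ntip, tip_state, p, f0, f1, cond_surv,
                    root_prior, root_state, clamp_node, clamp_state,
                    rtol, atol);
}

// [[Rcpp::export(name = ".bisse_marginal_cpp")]]
NumericMatrix bisse_marginal_cpp(IntegerMatrix edge, NumericVector el, int ntip,
                                 IntegerVector tip_state, NumericVector pars,
                                 double f0, double f1, bool cond_surv,
                                 int root_prior, int root_state,
                                 double rtol = 1e-8, double atol = 1e-10) {
  BisseP p = {pars[0], pars[1], pars[2], pars[3], pars[4], pars[5]};
  int nint = ntip - 1;
  NumericMatrix out(nint, 2);
  for (int k = 0; k < nint; ++k) {
    int node = ntip + 1 + k;
    double l0 = bisse_core(edge, el, ntip, tip_state, p, f0, f1, cond_surv,
                           root_prior, root_state, node, 0, rtol, atol);
    double l1 = bisse_core(edge, el, ntip, tip_state, p, f0, f1, cond_surv,
                           root_prior, root_state, node, 1, rtol, atol);
    double m = std::max(l0, l1);
    double e0 = std::isfinite(l0) ? std::exp(l0 - m) : 0.0;
    double e1 = std::isfinite(l1) ? std::exp(l1 - m) : 0.0;
    out(k, 0) = e0 / (e0 + e1);
    out(k, 1) = e1 / (e0 + e1);
  }
  return out;
}
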