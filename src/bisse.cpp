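// BiSSE likelihood core: per-branch integration of the coupled E/D ODE
// system with an adaptive Cash-Karp Runge-Kutta (4/5) stepper, and the
// postorder pruning sweep. State vector y = (E0, E1, D0, D1); time runs
// rootward from the branch's young end.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

struct BissePars {
  double la0, la1, mu0, mu1, q01, q10;
};

static inline void bisse_deriv(const double *y, double *dy, const BissePars &p) {
  const double E0 = y[0], E1 = y[1], D0 = y[2], D1 = y[3];
  dy[0] = p.mu0 - (p.la0 + p.mu0 + p.q01) * E0 + p.la0 * E0 * E0 + p.q01 * E1;
  dy[1] = p.mu1 - (p.la1 + p.mu1 + p.q10) * E1 + p.la1 * E1 * E1 + p.q10 * E0;
  dy[2] = -(p.la0 + p.mu0 + p.q01) * D0 + p.q01 * D1 + 2.0 * p.la0 * E0 * D0;
  dy[3] = -(p.la1 + p.mu1 + p.q10) * D1 + p.q10 * D0 + 2.0 * p.la1 * E1 * D1;
}

// Cash-Karp tableau
static const double b21 = 1.0 / 5.0;
static const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
static const double b41 = 3.0 / 10.0, b42 = -9.0 / 10.0, b43 = 6.0 / 5.0;
static const double b51 = -11.0 / 54.0, b52 = 5.0 / 2.0, b53 = -70.0 / 27.0,
                    b54 = 35.0 / 27.0;
static const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0,
                    b63 = 575.0 / 13824.0, b64 = 44275.0 / 110592.0,
                    b65 = 253.0 / 4096.0;
static const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0, c4 = 125.0 / 594.0,
                    c6 = 512.0 / 1771.0;
static const double dc1 = c1 - 2825.0 / 27648.0, dc3 = c3 - 18575.0 / 48384.0,
                    dc4 = c4 - 13525.0 / 55296.0, dc5 = -277.0 / 14336.0,
                    dc6 = c6 - 1.0 / 4.0;

// one trial Cash-Karp step of size h; returns max scaled error estimate
static double ck_step(const double *y, double h, const BissePars &p,
                      double *yout, double rtol, double atol) {
  double k1[4], k2[4], k3[4], k4[4], k5[4], k6[4], yt[4];
  bisse_deriv(y, k1, p);
  for (int i = 0; i < 4; ++i) yt[i] = y[i] + h * b21 * k1[i];
  bisse_deriv(yt, k2, p);
  for (int i = 0; i < 4; ++i) yt[i] = y[i] + h * (b31 * k1[i] + b32 * k2[i]);
  bisse_deriv(yt, k3, p);
  for (int i = 0; i < 4; ++i)
    yt[i] = y[i] + h * (b41 * k1[i] + b42 * k2[i] + b43 * k3[i]);
  bisse_deriv(yt, k4, p);
  for (int i = 0; i < 4; ++i)
    yt[i] = y[i] + h * (b51 * k1[i] + b52 * k2[i] + b53 * k3[i] + b54 * k4[i]);
  bisse_deriv(yt, k5, p);
  for (int i = 0; i < 4; ++i)
    yt[i] = y[i] + h * (b61 * k1[i] + b62 * k2[i] + b63 * k3[i] +
                        b64 * k4[i] + b65 * k5[i]);
  bisse_deriv(yt, k6, p);
  double errmax = 0.0;
  for (int i = 0; i < 4; ++i) {
    yout[i] = y[i] + h * (c1 * k1[i] + c3 * k3[i] + c4 * k4[i] + c6 * k6[i]);
    double erri = h * (dc1 * k1[i] + dc3 * k3[i] + dc4 * k4[i] +
                       dc5 * k5[i] + dc6 * k6[i]);
    double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(yout[i]));
    errmax = std::max(errmax, std::fabs(erri) / sc);
  }
  return errmax;
}

static void integrate_branch(double *y, double len, const BissePars &p,
                             double rtol, double atol) {
  if (len <= 0.0) return;
  double t = 0.0;
  double h = len;
  int iter = 0;
  while (t < len) {
    if (++iter > 100000) stop("BiSSE ODE integration failed to converge on a branch");
    if (t + h > len) h = len - t;
    double ynew[4];
    double err = ck_step(y, h, p, ynew, rtol, atol);
    if (err <= 1.0) {
      t += h;
      for (int i = 0; i < 4; ++i) y[i] = ynew[i];
      double grow = (err > 1e-12) ? 0.9 * std::pow(err, -0.2) : 5.0;
      h *= std::min(grow, 5.0);
    } else {
      h *= std::max(0.9 * std::pow(err, -0.25), 0.1);
    }
    if (h < 1e-14 * len) stop("BiSSE ODE step size underflow");
  }
  // keep E within [0,1] and clip tiny negative D from roundoff
  for (int i = 0; i < 2; ++i) {
    if (y[i] < 0.0) y[i] = 0.0;
    if (y[i] > 1.0) y[i] = 1.0;
  }
  for (int i = 2; i < 4; ++i) {
    if (y[i] < 0.0 && y[i] > -atol) y[i] = 0.0;
  }
}

// Postorder pruning over the whole tree.
//
// edge: 2-column matrix (parent, child) in postorder; nodes use ape
// numbering (tips 1..ntip, root ntip+1). tip_d: ntip x 2 matrix of initial
// D values. root_mode: 0 = weight states by their root D ("observed"),
// 1 = flat (0.5, 0.5), 2 = supplied root_p. cond_surv: divide by
// sum_i w_i lambda_i (1 - E_i)^2. force_node/force_state (> 0 / >= 0):
// constrain one node (or tip) to a state, for marginal ASR.
// [[Rcpp::export]]
double bisse_loglik_cpp(IntegerMatrix edge, NumericVector edge_len,
                        int ntip, NumericMatrix tip_d, NumericVector pars,
                        NumericVector sampling_f, int root_mode,
                        NumericVector root_p, bool cond_surv,
                        double rtol, double atol,
                        int force_node = -1, int force_state = -1) {
  BissePars p = {pars[0], pars[1], pars[2], pars[3], pars[4], pars[5]};
  int ntot = ntip + edge.nrow() + 2;  // generous bound on node indices
  std::vector<double> E0(ntot, 0.0), E1(ntot, 0.0), D0(ntot, 0.0), D1(ntot, 0.0);
  std::vector<int> seen(ntot, 0);
  double logcomp = 0.0;

  for (int i = 0; i < ntip; ++i) {
    D0[i] = tip_d(i, 0);
    D1[i] = tip_d(i, 1);
    E0[i] = 1.0 - sampling_f[0];
    E1[i] = 1.0 - sampling_f[1];
    if (force_node == i + 1) {
      if (force_state == 0) D1[i] = 0.0; else D0[i] = 0.0;
    }
  }

  int root = ntip;  // 0-based index of ape node ntip+1
  for (int e = 0; e < edge.nrow(); ++e) {
    int par = edge(e, 0) - 1;
    int ch = edge(e, 1) - 1;
    // in postorder every subtree edge of `ch` has been processed, so the
    // node's D is complete here: apply a marginal-ASR state constraint
    // exactly at the node, before integrating its stem branch
    if (force_node == ch + 1 && ch >= ntip) {
      if (force_state == 0) D1[ch] = 0.0; else D0[ch] = 0.0;
    }
    double y[4] = {E0[ch], E1[ch], D0[ch], D1[ch]};
    integrate_branch(y, edge_len[e], p, rtol, atol);
    // per-branch renormalisation: D scales linearly, so dividing by the
    // branch-top sum and accumulating its log keeps every integration
    // starting from O(1) values without changing the likelihood
    {
      double mb = y[2] + y[3];
      if (mb > 0) { y[2] /= mb; y[3] /= mb; logcomp += std::log(mb); }
    }
    if (!seen[par]) {
      E0[par] = y[0]; E1[par] = y[1];
      D0[par] = y[2]; D1[par] = y[3];
      seen[par] = 1;
    } else {
      // combine at the node: D_i <- lambda_i * D_i(left) * D_i(right)
      // (polytomies combine by repeated pairwise products);
      // E depends only on the node's age, so both children agree up to
      // integration error and the first is kept
      D0[par] = p.la0 * D0[par] * y[2];
      D1[par] = p.la1 * D1[par] * y[3];
      seen[par]++;
    }
    // renormalise to avoid under/overflow, with exact log accumulation
    double m = D0[par] + D1[par];
    if (m > 0 && (m < 1e-50 || m > 1e50)) {
      D0[par] /= m; D1[par] /= m;
      logcomp += std::log(m);
    }
  }
  if (force_node == root + 1) {
    if (force_state == 0) D1[root] = 0.0; else D0[root] = 0.0;
  }

  double d0 = D0[root], d1 = D1[root];
  double e0 = E0[root], e1 = E1[root];
  double w0, w1;
  if (root_mode == 0) {
    double s = d0 + d1;
    if (s <= 0) return R_NegInf;
    w0 = d0 / s; w1 = d1 / s;
  } else if (root_mode == 1) {
    w0 = 0.5; w1 = 0.5;
  } else {
    w0 = root_p[0]; w1 = root_p[1];
  }
  double lik = w0 * d0 + w1 * d1;
  if (lik <= 0) return R_NegInf;
  double ll = std::log(lik) + logcomp;
  if (cond_surv) {
    double denom = w0 * p.la0 * (1 - e0) * (1 - e0) +
                   w1 * p.la1 * (1 - e1) * (1 - e1);
    if (denom <= 0) return R_NegInf;
    ll -= std::log(denom);
  }
  return ll;
}

// expose the single-branch integrator for diagnostics
// [[Rcpp::export]]
NumericVector bisse_branch_cpp(NumericVector y0, double len,
                               NumericVector pars, double rtol, double atol) {
  BissePars p = {pars[0], pars[1], pars[2], pars[3], pars[4], pars[5]};
  double y[4] = {y0[0], y0[1], y0[2], y0[3]};
  integrate_branch(y, len, p, rtol, atol);
  return NumericVector::create(y[0], y[1], y[2], y[3]);
}
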