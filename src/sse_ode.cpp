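// Hidden-state SSE likelihood machinery.
//
// The coupled E/D system per combined state i (rates lambda_i, mu_i,
// transition rates q_ij restricted to one-step neighbours):
//   dE_i/dt = mu_i - (lambda_i + mu_i + sum_j q_ij) E_i + lambda_i E_i^2
//             + sum_j q_ij E_j
//   dD_i/dt = -(lambda_i + mu_i + sum_j q_ij) D_i + 2 lambda_i E_i D_i
//             + sum_j q_ij D_j
// integrated along each branch toward the root with an adaptive
// Dormand-Prince 5(4) pair (no external ODE dependency available).

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct SSESys {
  int S;
  std::vector<double> lambda, mu, rtot;  // rtot = lambda+mu+sum_j q_ij
  // flattened sparse transition structure
  std::vector<int> nbr_off, nbr_idx;
  std::vector<double> nbr_rate;
  // integrator workspace (one allocation per likelihood evaluation)
  std::vector<double> k1, k2, k3, k4, k5, k6, k7, yt, ynew;
  double h_prev;  // warm-start step size across branches

  SSESys(const NumericVector &lam, const NumericVector &m,
         const NumericMatrix &Q) {
    S = lam.size();
    lambda.assign(lam.begin(), lam.end());
    mu.assign(m.begin(), m.end());
    rtot.resize(S);
    nbr_off.assign(S + 1, 0);
    for (int i = 0; i < S; ++i) {
      double qt = 0.0;
      for (int j = 0; j < S; ++j) {
        if (j == i) continue;
        double r = Q(i, j);
        if (r > 0.0) {
          nbr_idx.push_back(j);
          nbr_rate.push_back(r);
          qt += r;
        }
      }
      nbr_off[i + 1] = (int)nbr_idx.size();
      rtot[i] = lambda[i] + mu[i] + qt;
    }
    int n = 2 * S;
    k1.resize(n); k2.resize(n); k3.resize(n); k4.resize(n); k5.resize(n);
    k6.resize(n); k7.resize(n); yt.resize(n); ynew.resize(n);
    h_prev = -1.0;
  }

  // y = (E_1..E_S, D_1..D_S)
  inline void deriv(const double *y, double *dy) const {
    const double *E = y, *D = y + S;
    double *dE = dy, *dD = dy + S;
    for (int i = 0; i < S; ++i) {
      double sE = 0.0, sD = 0.0;
      for (int k = nbr_off[i]; k < nbr_off[i + 1]; ++k) {
        int j = nbr_idx[k];
        sE += nbr_rate[k] * E[j];
        sD += nbr_rate[k] * D[j];
      }
      dE[i] = mu[i] - rtot[i] * E[i] + lambda[i] * E[i] * E[i] + sE;
      dD[i] = -rtot[i] * D[i] + 2.0 * lambda[i] * E[i] * D[i] + sD;
    }
  }
};

// Dormand-Prince 5(4) coefficients
const double a21 = 1.0 / 5;
const double a31 = 3.0 / 40, a32 = 9.0 / 40;
const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
             a53 = 64448.0 / 6561, a54 = -212.0 / 729;
const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
             a64 = 49.0 / 176, a65 = -5103.0 / 18656;
const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
             b5 = -2187.0 / 6784, b6 = 11.0 / 84;
// difference between 5th- and embedded 4th-order weights
const double d1 = b1 - 5179.0 / 57600, d3 = b3 - 7571.0 / 16695,
             d4 = b4 - 393.0 / 640, d5 = b5 + 92097.0 / 339200,
             d6 = b6 - 187.0 / 2100, d7 = -1.0 / 40;

// integrates y over [0, len]; returns false on failure
bool dopri5(SSESys &sys, std::vector<double> &y, double len, double rtol,
            double atol) {
  if (len <= 0.0) return true;
  const int n = 2 * sys.S;
  double *k1 = &sys.k1[0], *k2 = &sys.k2[0], *k3 = &sys.k3[0],
         *k4 = &sys.k4[0], *k5 = &sys.k5[0], *k6 = &sys.k6[0],
         *k7 = &sys.k7[0], *yt = &sys.yt[0], *ynew = &sys.ynew[0];
  double t = 0.0;
  double rmax = 1e-8;
  for (int i = 0; i < sys.S; ++i) rmax = std::max(rmax, sys.rtot[i]);
  double h = (sys.h_prev > 0.0) ? sys.h_prev : 0.2 / rmax;
  h = std::min(h, len);
  if (h <= 0.0 || !std::isfinite(h)) h = len / 100.0;
  sys.deriv(&y[0], k1);
  long nsteps = 0;
  while (t < len) {
    if (++nsteps > 10000000L) return false;
    bool clipped = (t + h >= len);
    if (clipped) h = len - t;
    for (int i = 0; i < n; ++i) yt[i] = y[i] + h * a21 * k1[i];
    sys.deriv(yt, k2);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    sys.deriv(yt, k3);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    sys.deriv(yt, k4);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] +
              h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    sys.deriv(yt, k5);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                          a64 * k4[i] + a65 * k5[i]);
    sys.deriv(yt, k6);
    for (int i = 0; i < n; ++i)
      ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                            b5 * k5[i] + b6 * k6[i]);
    sys.deriv(ynew, k7);
    double err = 0.0;
    for (int i = 0; i < n; ++i) {
      double e = h * (d1 * k1[i] + d3 * k3[i] + d4 * k4[i] + d5 * k5[i] +
                      d6 * k6[i] + d7 * k7[i]);
      double sc =
          atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double r = e / sc;
      err += r * r;
    }
    err = std::sqrt(err / n);
    if (!std::isfinite(err)) return false;
    if (err <= 1.0) {
      t += h;
      for (int i = 0; i < n; ++i) y[i] = ynew[i];
      std::swap(sys.k1, sys.k7);  // FSAL
      k1 = &sys.k1[0];
      k7 = &sys.k7[0];
    }
    double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
    fac = std::min(5.0, std::max(0.2, fac));
    h *= fac;
    if (!clipped || err > 1.0) sys.h_prev = h;
    if (h < 1e-14 * len && t < len) return false;
  }
  return true;
}

}  // namespace

// [[Rcpp::export]]
List sse_branch_cpp(NumericVector E0, NumericVector D0, NumericVector lambda,
                    NumericVector mu, NumericMatrix Q, double len,
                    double rtol, double atol) {
  SSESys sys(lambda, mu, Q);
  int S = sys.S;
  std::vector<double> y(2 * S);
  for (int i = 0; i < S; ++i) {
    y[i] = E0[i];
    y[S + i] = D0[i];
  }
  bool ok = dopri5(sys, y, len, rtol, atol);
  NumericVector E(S), D(S);
  for (int i = 0; i < S; ++i) {
    E[i] = y[i];
    D[i] = y[S + i];
  }
  return List::create(_["E"] = E, _["D"] = D, _["ok"] = ok);
}

// Post-order pruning over the whole tree.
// edge: 2-column integer matrix in ape convention (parent, child), already in
// postorder; tipD: ntip x S matrix of tip D initial conditions (row = tip id);
// tipE: shared S-vector of tip E initial conditions (all tips extant).
// root_mode: 0 = fitzjohn, 1 = equal, 2 = fixed (root_probs used).
// [[Rcpp::export]]
List sse_loglik_cpp(IntegerMatrix edge, NumericVector edge_length, int ntip,
                    NumericMatrix tipD, NumericVector tipE,
                    NumericVector lambda, NumericVector mu, NumericMatrix Q,
                    double rtol, double atol, bool condition, int root_mode,
                    NumericVector root_probs) {
  SSESys sys(lambda, mu, Q);
  const int S = sys.S;
  int nedge = edge.nrow();
  int nmax = ntip;
  for (int k = 0; k < nedge; ++k) {
    nmax = std::max(nmax, std::max(edge(k, 0), edge(k, 1)));
  }
  std::vector<std::vector<double> > E(nmax + 1), D(nmax + 1);
  std::vector<int> nchild(nmax + 1, 0);
  for (int tp = 1; tp <= ntip; ++tp) {
    E[tp].assign(tipE.begin(), tipE.end());
    D[tp].resize(S);
    for (int i = 0; i < S; ++i) D[tp][i] = tipD(tp - 1, i);
  }
  double logcomp = 0.0;
  bool failed = false;
  std::vector<double> y(2 * S);
  for (int k = 0; k < nedge && !failed; ++k) {
    int par = edge(k, 0), ch = edge(k, 1);
    if (D[ch].empty()) { failed = true; break; }  // postorder violated
    for (int i = 0; i < S; ++i) {
      y[i] = E[ch][i];
      y[S + i] = D[ch][i];
    }
    if (!dopri5(sys, y, edge_length[k], rtol, atol)) { failed = true; break; }
    double s = 0.0;
    for (int i = 0; i < S; ++i) s += std::max(y[S + i], 0.0);
    if (!(s > 0.0) || !std::isfinite(s)) { failed = true; break; }
    logcomp += std::log(s);
    if (nchild[par] == 0) {
      E[par].resize(S);
      D[par].resize(S);
      for (int i = 0; i < S; ++i) {
        E[par][i] = y[i];
        D[par][i] = std::max(y[S + i], 0.0) / s;
      }
      nchild[par] = 1;
    } else if (nchild[par] == 1) {
      for (int i = 0; i < S; ++i) {
        E[par][i] = 0.5 * (E[par][i] + y[i]);
        D[par][i] *= lambda[i] * std::max(y[S + i], 0.0) / s;
      }
      nchild[par] = 2;
    } else {
      failed = true;  // non-binary node
    }
  }
  if (failed) {
    return List::create(_["loglik"] = R_NegInf, _["ok"] = false);
  }
  int root = edge(nedge - 1, 0);
  std::vector<double> &Dr = D[root], &Er = E[root];
  double dsum = 0.0;
  for (int i = 0; i < S; ++i) dsum += Dr[i];
  if (!(dsum > 0.0) || !std::isfinite(dsum)) {
    return List::create(_["loglik"] = R_NegInf, _["ok"] = false);
  }
  double L = 0.0;
  for (int i = 0; i < S; ++i) {
    double w;
    if (root_mode == 0)
      w = Dr[i] / dsum;  // FitzJohn likelihood-proportional weights
    else if (root_mode == 1)
      w = 1.0 / S;
    else
      w = root_probs[i];
    double term = w * Dr[i];
    if (condition) {
      double surv = lambda[i] * (1.0 - Er[i]) * (1.0 - Er[i]);
      if (surv <= 0.0) continue;
      term /= surv;
    }
    L += term;
  }
  double ll = (L > 0.0) ? std::log(L) + logcomp : R_NegInf;
  NumericVector rE(S), rD(S);
  for (int i = 0; i < S; ++i) {
    rE[i] = Er[i];
    rD[i] = Dr[i];
  }
  return List::create(_["loglik"] = ll, _["ok"] = std::isfinite(ll),
                      _["root_E"] = rE, _["root_D"] = rD,
                      _["log_comp"] = logcomp);
}
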