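// Per-pixel fitting of TCSPC decay histograms.
//
// Model: expected counts in channel k are
//   m_k = N * ( a1 * q_k(tau1) + (1 - a1) * q_k(tau2) )
// where q_k(tau) is the integral of the window-truncated normalized
// exponential over channel k (edges t_k = k*dt, optionally shifted by a
// fixed time offset).
//
// Two objectives, both driven by a damped (Levenberg-Marquardt style)
// iteratively reweighted least-squares loop with analytic Jacobian:
//   POISSON (default): Poisson likelihood, maximised by Fisher scoring --
//     weighted least-squares steps with weights 1/max(m_k, eps) refreshed
//     from the current model; step acceptance monitors the Poisson deviance.
//   NEYMAN: classic weighted least squares with fixed observed-count
//     weights 1/max(y_k, 1).
// The reported reduced chi^2 is the conventional observed-count-weighted
// statistic sum (y-m)^2/max(y,1) / (C - 4) in either case.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

enum Objective { POISSON = 0, NEYMAN = 1 };

struct DecayModel {
  int C;
  double dt;
  double offset;
  double S;               // effective decay span: T - offset
  std::vector<double> s;  // shifted channel edges, length C+1

  DecayModel(int C_, double dt_, double offset_)
      : C(C_), dt(dt_), offset(offset_) {
    s.resize(C + 1);
    for (int k = 0; k <= C; ++k) {
      double v = k * dt - offset;
      s[k] = v > 0 ? v : 0.0;
    }
    S = C * dt - offset;
    if (S <= 0) S = C * dt;
  }

  // channel probabilities q[k] and d q[k]/d tau
  void probs(double tau, std::vector<double>& q,
             std::vector<double>* dq) const {
    double fT = std::exp(-S / tau);
    double D = 1.0 - fT;
    double dD = -(S / (tau * tau)) * fT;
    double fprev = std::exp(-s[0] / tau);
    double dfprev = (s[0] / (tau * tau)) * fprev;
    for (int k = 0; k < C; ++k) {
      double fk = std::exp(-s[k + 1] / tau);
      double dfk = (s[k + 1] / (tau * tau)) * fk;
      double A = fprev - fk;
      q[k] = A / D;
      if (dq) {
        double dA = dfprev - dfk;
        (*dq)[k] = (dA * D - A * dD) / (D * D);
      }
      fprev = fk;
      dfprev = dfk;
    }
  }
};

inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Gaussian elimination with partial pivoting for small n; false if singular.
bool solve_small(std::vector<double>& A, std::vector<double>& b, int n) {
  for (int col = 0; col < n; ++col) {
    int piv = col;
    double best = std::fabs(A[col * n + col]);
    for (int r = col + 1; r < n; ++r) {
      double v = std::fabs(A[r * n + col]);
      if (v > best) { best = v; piv = r; }
    }
    if (best < 1e-300) return false;
    if (piv != col) {
      for (int c = 0; c < n; ++c) std::swap(A[col * n + c], A[piv * n + c]);
      std::swap(b[col], b[piv]);
    }
    double d = A[col * n + col];
    for (int r = col + 1; r < n; ++r) {
      double f = A[r * n + col] / d;
      if (f == 0.0) continue;
      for (int c = col; c < n; ++c) A[r * n + c] -= f * A[col * n + c];
      b[r] -= f * b[col];
    }
  }
  for (int r = n - 1; r >= 0; --r) {
    double acc = b[r];
    for (int c = r + 1; c < n; ++c) acc -= A[r * n + c] * b[c];
    b[r] = acc / A[r * n + r];
  }
  return true;
}

struct FitWork {
  std::vector<double> q1, q2, dq1, dq2, m;
  explicit FitWork(int C) : q1(C), q2(C), dq1(C), dq2(C), m(C) {}
};

// model curve for theta; theta = (tau1, tau2, a1, N), or (tau, N) if single
void model_curve(const DecayModel& mod, const double* theta, bool single_exp,
                 FitWork& wk, bool need_grad) {
  double tau1 = theta[0];
  double tau2 = single_exp ? theta[0] : theta[1];
  double a1 = single_exp ? 1.0 : theta[2];
  double N = single_exp ? theta[1] : theta[3];
  mod.probs(tau1, wk.q1, need_grad ? &wk.dq1 : nullptr);
  if (!single_exp) mod.probs(tau2, wk.q2, need_grad ? &wk.dq2 : nullptr);
  for (int k = 0; k < mod.C; ++k) {
    double mix = single_exp ? wk.q1[k]
                            : (a1 * wk.q1[k] + (1.0 - a1) * wk.q2[k]);
    wk.m[k] = N * mix;
  }
}

// objective value at the current model curve (wk.m must be fresh)
double objective_value(const double* y, const FitWork& wk, int C,
                       Objective obj, const double* wfix) {
  double cost = 0.0;
  if (obj == NEYMAN) {
    for (int k = 0; k < C; ++k) {
      double r = y[k] - wk.m[k];
      cost += wfix[k] * r * r;
    }
  } else {
    for (int k = 0; k < C; ++k) {
      double m = wk.m[k] > 1e-12 ? wk.m[k] : 1e-12;
      cost += 2.0 * (m - y[k]);
      if (y[k] > 0) cost += 2.0 * y[k] * std::log(y[k] / m);
    }
  }
  return cost;
}

// normal equations at theta: JtWJ, JtWr with the objective's weights
void normal_equations(const DecayModel& mod, const double* y,
                      const double* theta, bool single_exp, Objective obj,
                      const double* wfix, FitWork& wk,
                      std::vector<double>& JtJ, std::vector<double>& Jtr) {
  const int C = mod.C;
  int npar = single_exp ? 2 : 4;
  model_curve(mod, theta, single_exp, wk, true);
  std::fill(JtJ.begin(), JtJ.end(), 0.0);
  std::fill(Jtr.begin(), Jtr.end(), 0.0);
  double a1 = single_exp ? 1.0 : theta[2];
  double N = single_exp ? theta[1] : theta[3];
  double J[4];
  for (int k = 0; k < C; ++k) {
    double w = (obj == NEYMAN)
                   ? wfix[k]
                   : 1.0 / (wk.m[k] > 1e-3 ? wk.m[k] : 1e-3);
    double r = y[k] - wk.m[k];
    double mix = single_exp ? wk.q1[k]
                            : (a1 * wk.q1[k] + (1.0 - a1) * wk.q2[k]);
    if (single_exp) {
      J[0] = N * wk.dq1[k];
      J[1] = mix;
    } else {
      J[0] = N * a1 * wk.dq1[k];
      J[1] = N * (1.0 - a1) * wk.dq2[k];
      J[2] = N * (wk.q1[k] - wk.q2[k]);
      J[3] = mix;
    }
    for (int i = 0; i < npar; ++i) {
      Jtr[i] += w * J[i] * r;
      for (int j = i; j < npar; ++j) JtJ[i * npar + j] += w * J[i] * J[j];
    }
  }
  for (int i = 0; i < npar; ++i)
    for (int j = 0; j < i; ++j) JtJ[i * npar + j] = JtJ[j * npar + i];
}

// damped IRLS / LM driver; theta modified in place
double lm_minimize(const DecayModel& mod, const double* y, const double* wfix,
                   double* theta, bool single_exp, Objective obj, FitWork& wk,
                   const double* lo, const double* hi, int maxit,
                   bool& converged, int& niter) {
  int npar = single_exp ? 2 : 4;
  std::vector<double> JtJ(npar * npar), Jtr(npar);
  std::vector<double> A(npar * npar), b(npar);
  model_curve(mod, theta, single_exp, wk, false);
  double cost = objective_value(y, wk, mod.C, obj, wfix);
  double lambda = 1e-3;
  converged = false;
  niter = 0;
  for (int it = 0; it < maxit; ++it) {
    niter = it + 1;
    normal_equations(mod, y, theta, single_exp, obj, wfix, wk, JtJ, Jtr);
    bool stepped = false;
    double newcost = cost;
    double trial[4];
    for (int attempt = 0; attempt < 12; ++attempt) {
      A = JtJ;
      b = Jtr;
      for (int i = 0; i < npar; ++i) {
        double d = JtJ[i * npar + i];
        A[i * npar + i] = d + lambda * (d > 1e-12 ? d : 1e-12);
      }
      if (!solve_small(A, b, npar)) { lambda *= 10.0; continue; }
      for (int i = 0; i < npar; ++i)
        trial[i] = clampd(theta[i] + b[i], lo[i], hi[i]);
      model_curve(mod, trial, single_exp, wk, false);
      double c = objective_value(y, wk, mod.C, obj, wfix);
      if (std::isfinite(c) && c <= cost + 1e-12) {
        newcost = c;
        stepped = true;
        lambda = lambda > 5e-12 ? lambda / 5.0 : 1e-12;
        break;
      }
      lambda *= 10.0;
    }
    if (!stepped) { converged = true; break; }  // no improving direction
    double drop = cost - newcost;
    double maxstep = 0.0;
    for (int i = 0; i < npar; ++i) {
      double rel =
          std::fabs(trial[i] - theta[i]) / (std::fabs(theta[i]) + 1e-12);
      if (rel > maxstep) maxstep = rel;
      theta[i] = trial[i];
    }
    cost = newcost;
    if (drop < 1e-10 * (1.0 + std::fabs(cost)) || maxstep < 1e-9) {
      converged = true;
      break;
    }
  }
  return cost;
}

// log-linear slope of log(y) on channel mid-times over [k0, k1)
double loglin_tau(const double* y, const DecayModel& mod, int k0, int k1) {
  double sx = 0, sy = 0, sxx = 0, sxy = 0;
  int n = 0;
  for (int k = k0; k < k1; ++k) {
    if (y[k] <= 0) continue;
    double t = (k + 0.5) * mod.dt;
    double ly = std::log(y[k]);
    sx += t; sy += ly; sxx += t * t; sxy += t * ly;
    ++n;
  }
  if (n < 3) return NA_REAL;
  double denom = n * sxx - sx * sx;
  if (denom <= 0) return NA_REAL;
  double slope = (n * sxy - sx * sy) / denom;
  if (slope >= -1e-12) return NA_REAL;
  return -1.0 / slope;
}

}  // namespace

// Fit the biexponential decay model to each column of `Y` (channels x
// pixels). `objective` is 0 for Poisson IRLS, 1 for fixed Neyman weights.
// Returns an 8 x npix matrix with rows tau1, tau2, a1, N, chi2_reduced,
// converged, niter, collapsed (1 when the two lifetimes were degenerate and
// the pixel was refit as a single exponential).
// [[Rcpp::export(name = ".fitDecayCpp")]]
NumericMatrix fit_decay_cpp(NumericMatrix Y, double dt, double offset,
                            int maxit, double tie_rel, int objective) {
  const int C = Y.nrow();
  const int npix = Y.ncol();
  if (C < 8) stop("need at least 8 time channels");
  if (dt <= 0) stop("'dt' must be positive");
  Objective obj = objective == 1 ? NEYMAN : POISSON;
  DecayModel mod(C, dt, offset);
  FitWork wk(C);
  NumericMatrix out(8, npix);
  std::vector<double> y(C), wfix(C);
  const double T = C * dt;
  const double lo4[4] = {0.01, 0.01, 0.0, 1e-8};
  double hi4[4] = {T, T, 1.0, 0.0};
  const double lo2[2] = {0.01, 1e-8};
  double hi2[2] = {T, 0.0};

  for (int p = 0; p < npix; ++p) {
    double tot = 0.0;
    for (int k = 0; k < C; ++k) {
      y[k] = Y(k, p);
      if (y[k] < 0) stop("negative photon counts are not allowed");
      wfix[k] = 1.0 / (y[k] > 1.0 ? y[k] : 1.0);
      tot += y[k];
    }
    if (tot <= 0) {
      for (int i = 0; i < 8; ++i) out(i, p) = NA_REAL;
      out(5, p) = 0.0;
      out(6, p) = 0.0;
      out(7, p) = 0.0;
      continue;
    }

    // initialization: two-segment log-linear fit of tail and head
    double tau2_0 = loglin_tau(y.data(), mod, C / 2, C);
    if (!std::isfinite(tau2_0)) tau2_0 = T / 4.0;
    tau2_0 = clampd(tau2_0, 0.05, T);
    int head_end = C / 10 > 6 ? C / 10 : 6;
    double tau1_0 = loglin_tau(y.data(), mod, 0, head_end);
    if (!std::isfinite(tau1_0)) tau1_0 = 0.3 * tau2_0;
    tau1_0 = clampd(tau1_0, 0.02, 0.8 * tau2_0);
    // a1 from the first-channel amplitude ratio
    mod.probs(tau1_0, wk.q1, nullptr);
    mod.probs(tau2_0, wk.q2, nullptr);
    double a1_0 = 0.5;
    double dq0 = wk.q1[0] - wk.q2[0];
    if (std::fabs(dq0) > 1e-12)
      a1_0 = clampd((y[0] / tot - wk.q2[0]) / dq0, 0.05, 0.95);

    double theta[4] = {tau1_0, tau2_0, a1_0, tot};
    hi4[3] = 10.0 * tot + 10.0;
    bool conv = false;
    int niter = 0;
    lm_minimize(mod, y.data(), wfix.data(), theta, false, obj, wk, lo4, hi4,
                maxit, conv, niter);

    double tau1 = theta[0], tau2 = theta[1], a1 = theta[2], N = theta[3];
    if (tau1 > tau2) { std::swap(tau1, tau2); a1 = 1.0 - a1; }

    double collapsed = 0.0;
    if (tau2 - tau1 <= tie_rel * tau2) {
      // unidentifiable pair: refit as a single exponential, report a1 = 1
      double th2[2] = {a1 * tau1 + (1.0 - a1) * tau2, N};
      hi2[1] = hi4[3];
      bool conv1 = false;
      int niter1 = 0;
      lm_minimize(mod, y.data(), wfix.data(), th2, true, obj, wk, lo2, hi2,
                  maxit, conv1, niter1);
      tau1 = tau2 = th2[0];
      a1 = 1.0;
      N = th2[1];
      conv = conv1;
      niter += niter1;
      collapsed = 1.0;
    }

    // conventional observed-count-weighted reduced chi^2 at the solution
    double th_final[4] = {tau1, tau2, a1, N};
    model_curve(mod, th_final, false, wk, false);
    double chi2 = 0.0;
    for (int k = 0; k < C; ++k) {
      double r = y[k] - wk.m[k];
      chi2 += wfix[k] * r * r;
    }

    out(0, p) = tau1;
    out(1, p) = tau2;
    out(2, p) = a1;
    out(3, p) = N;
    out(4, p) = chi2 / (C - 4.0);
    out(5, p) = conv && std::isfinite(chi2) ? 1.0 : 0.0;
    out(6, p) = niter;
    out(7, p) = collapsed;
  }
  return out;
}

// Expected channel fractions of the window-truncated biexponential
// a1*exp(-t/tau1) + (1-a1)*exp(-t/tau2).
// [[Rcpp::export(name = ".decayChannelProbsCpp")]]
NumericVector decay_channel_probs_cpp(int n_channels, double dt, double tau1,
                                      double tau2, double a1, double offset) {
  if (n_channels < 2) stop("need at least 2 channels");
  if (dt <= 0 || tau1 <= 0 || tau2 <= 0)
    stop("dt and lifetimes must be positive");
  if (a1 < 0 || a1 > 1) stop("'a1' must lie in [0, 1]");
  DecayModel mod(n_channels, dt, offset);
  std::vector<double> q1(n_channels), q2(n_channels);
  mod.probs(tau1, q1, nullptr);
  mod.probs(tau2, q2, nullptr);
  NumericVector out(n_channels);
  for (int k = 0; k < n_channels; ++k)
    out[k] = a1 * q1[k] + (1.0 - a1) * q2[k];
  return out;
}
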