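// Adaptive Dormand-Prince 5(4) integration of the two-compartment PK +
// mass-action ligand-binding system. Infusions are zero-order inputs
// switched at exact event times: the integrator never steps across an
// infusion on/off boundary, so the right-hand side is smooth within every
// accepted step. State layout: [C, P, L_1, X_1, ..., L_k, X_k] with C the
// central and P the peripheral drug concentration (nM), L free ligand and
// X drug:ligand complex per ligand.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Model {
  double CL, V1, Q, V2;                    // L/day, L
  int nlig;
  std::vector<double> kon, koff, ksyn, kdeg, kint;

  void rhs(const double *y, double *dy, double rate_in) const {
    const double C = y[0], P = y[1];
    double bind = 0.0;
    for (int i = 0; i < nlig; ++i) {
      const double L = y[2 + 2 * i], X = y[3 + 2 * i];
      const double on = kon[i] * C * L, off = koff[i] * X;
      dy[2 + 2 * i] = ksyn[i] - kdeg[i] * L - on + off;
      dy[3 + 2 * i] = on - off - kint[i] * X;
      bind += on - off;
    }
    dy[0] = rate_in / V1 - (CL + Q) / V1 * C + (Q / V1) * P - bind;
    dy[1] = (Q / V2) * (C - P);
  }
};

// Dormand-Prince coefficients
const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
const double a21 = 1.0 / 5;
const double a31 = 3.0 / 40, a32 = 9.0 / 40;
const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
             a53 = 64448.0 / 6561, a54 = -212.0 / 729;
const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
             a64 = 49.0 / 176, a65 = -5103.0 / 18656;
const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
             b5 = -2187.0 / 6784, b6 = 11.0 / 84;
// embedded 4th-order weights
const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695, e4 = 393.0 / 640,
             e5 = -92097.0 / 339200, e6 = 187.0 / 2100, e7 = 1.0 / 40;

} // namespace

// [[Rcpp::export(name = ".pkpd_integrate")]]
NumericMatrix pkpd_integrate(List pk, NumericMatrix ligands,
                             NumericVector inf_start, NumericVector inf_end,
                             NumericVector inf_rate, NumericVector times,
                             NumericVector y0, double rtol, double atol,
                             double max_steps) {
  Model m;
  m.CL = as<double>(pk["clearance"]);
  m.V1 = as<double>(pk["central_volume"]);
  m.Q  = as<double>(pk["intercompartmental_clearance"]);
  m.V2 = as<double>(pk["peripheral_volume"]);
  m.nlig = ligands.nrow();
  for (int i = 0; i < m.nlig; ++i) {
    m.kon.push_back(ligands(i, 0));
    m.koff.push_back(ligands(i, 1));
    m.ksyn.push_back(ligands(i, 2));
    m.kdeg.push_back(ligands(i, 3));
    m.kint.push_back(ligands(i, 4));
  }
  const int n = y0.size();
  const int nt = times.size();
  NumericMatrix out(nt, n);

  // breakpoints: infusion switch times within the requested span
  std::vector<double> brk;
  for (int i = 0; i < inf_start.size(); ++i) {
    brk.push_back(inf_start[i]);
    brk.push_back(inf_end[i]);
  }
  brk.push_back(times[nt - 1] + 1.0);
  std::sort(brk.begin(), brk.end());

  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n),
      ytmp(n), ynew(n), yerr(n);
  double t = times[0];
  for (int j = 0; j < n; ++j) out(0, j) = y[j];

  double h = 1e-4;
  long steps = 0;
  int it = 1;

  auto rate_at = [&](double tt) {
    double r = 0.0;
    for (int i = 0; i < inf_start.size(); ++i)
      if (tt >= inf_start[i] && tt < inf_end[i]) r += inf_rate[i];
    return r;
  };

  while (it < nt) {
    const double t_target = times[it];
    // next breakpoint strictly after t
    double t_brk = t_target;
    for (double b : brk)
      if (b > t + 1e-12 && b < t_brk) { t_brk = b; break; }
    const double t_stop = std::min(t_target, t_brk);
    const double rate = rate_at(0.5 * (t + t_stop));

    while (t < t_stop - 1e-12) {
      if (++steps > (long)max_steps)
        stop("pkpd_integrate: step limit (%g) exceeded at t = %g; "
             "the system may be too stiff for the requested tolerances",
             max_steps, t);
      double hstep = std::min(h, t_stop - t);
      m.rhs(y.data(), k1.data(), rate);
      for (int j = 0; j < n; ++j) ytmp[j] = y[j] + hstep * a21 * k1[j];
      m.rhs(ytmp.data(), k2.data(), rate);
      for (int j = 0; j < n; ++j)
        ytmp[j] = y[j] + hstep * (a31 * k1[j] + a32 * k2[j]);
      m.rhs(ytmp.data(), k3.data(), rate);
      for (int j = 0; j < n; ++j)
        ytmp[j] = y[j] + hstep * (a41 * k1[j] + a42 * k2[j] + a43 * k3[j]);
      m.rhs(ytmp.data(), k4.data(), rate);
      for (int j = 0; j < n; ++j)
        ytmp[j] = y[j] + hstep * (a51 * k1[j] + a52 * k2[j] + a53 * k3[j] +
                                  a54 * k4[j]);
      m.rhs(ytmp.data(), k5.data(), rate);
      for (int j = 0; j < n; ++j)
        ytmp[j] = y[j] + hstep * (a61 * k1[j] + a62 * k2[j] + a63 * k3[j] +
                                  a64 * k4[j] + a65 * k5[j]);
      m.rhs(ytmp.data(), k6.data(), rate);
      for (int j = 0; j < n; ++j)
        ynew[j] = y[j] + hstep * (b1 * k1[j] + b3 * k3[j] + b4 * k4[j] +
                                  b5 * k5[j] + b6 * k6[j]);
      m.rhs(ynew.data(), k7.data(), rate);
      for (int j = 0; j < n; ++j) {
        const double y4 = y[j] + hstep * (e1 * k1[j] + e3 * k3[j] + e4 * k4[j] +
                                          e5 * k5[j] + e6 * k6[j] + e7 * k7[j]);
        yerr[j] = ynew[j] - y4;
      }
      double err = 0.0;
      for (int j = 0; j < n; ++j) {
        const double sc = atol + rtol * std::max(std::fabs(y[j]),
                                                 std::fabs(ynew[j]));
        const double r = yerr[j] / sc;
        err += r * r;
      }
      err = std::sqrt(err / n);
      if (err <= 1.0) {
        t += hstep;
        y = ynew;
      }
      const double fac =
          std::min(5.0, std::max(0.2, 0.9 * std::pow(std::max(err, 1e-12),
                                                     -0.2)));
      h = hstep * fac;
      if (h < 1e-14)
        stop("pkpd_integrate: step size underflow at t = %g", t);
    }
    t = t_stop;
    if (std::fabs(t - t_target) < 1e-12) {
      for (int j = 0; j < n; ++j) {
        double v = y[j];
        if (v < 0 && v > -10 * atol) v = 0; // clamp solver-level negatives
        out(it, j) = v;
      }
      ++it;
    }
  }
  return out;
}
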