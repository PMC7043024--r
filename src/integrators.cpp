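// Adaptive ODE integration for mass-action reaction networks.
//
// Two controlled embedded steppers are provided:
//  * "cashkarp"   - explicit Runge-Kutta Cash-Karp 4(5)
//  * "rosenbrock" - L-stable linearly implicit Rosenbrock 2(3)
//                   (Shampine-Reichelt scheme), with the analytic
//                   mass-action Jacobian; intended for stiff regimes
//                   (fast binding against hours-long progression curves).
//
// The right-hand side is defined by a stoichiometry matrix (species x
// reactions) and per-reaction reactant indices (1-based, 0 = unused), so
// flux_r = k_r * y[i1] * (y[i2] or 1).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Net {
  int ns, nr;
  const double* stoich;       // ns x nr, column-major
  std::vector<int> i1, i2;    // 0-based, -1 = absent
  const double* k;

  void rhs(const std::vector<double>& y, std::vector<double>& f) const {
    std::fill(f.begin(), f.end(), 0.0);
    for (int r = 0; r < nr; ++r) {
      double flux = k[r] * y[i1[r]];
      if (i2[r] >= 0) flux *= y[i2[r]];
      const double* col = stoich + (size_t)r * ns;
      for (int i = 0; i < ns; ++i)
        if (col[i] != 0.0) f[i] += col[i] * flux;
    }
  }

  // J[i + ns*l] = d f_i / d y_l
  void jac(const std::vector<double>& y, std::vector<double>& J) const {
    std::fill(J.begin(), J.end(), 0.0);
    for (int r = 0; r < nr; ++r) {
      const double* col = stoich + (size_t)r * ns;
      // derivative wrt first reactant
      double d1 = k[r] * (i2[r] >= 0 ? y[i2[r]] : 1.0);
      for (int i = 0; i < ns; ++i)
        if (col[i] != 0.0) J[i + (size_t)ns * i1[r]] += col[i] * d1;
      if (i2[r] >= 0) {
        double d2 = k[r] * y[i1[r]];
        for (int i = 0; i < ns; ++i)
          if (col[i] != 0.0) J[i + (size_t)ns * i2[r]] += col[i] * d2;
      }
    }
  }
};

// In-place LU with partial pivoting; A is n x n column-major.
bool lu_factor(std::vector<double>& A, std::vector<int>& piv, int n) {
  for (int j = 0; j < n; ++j) {
    int p = j;
    double amax = std::fabs(A[j + (size_t)n * j]);
    for (int i = j + 1; i < n; ++i) {
      double v = std::fabs(A[i + (size_t)n * j]);
      if (v > amax) { amax = v; p = i; }
    }
    if (amax == 0.0) return false;
    piv[j] = p;
    if (p != j)
      for (int c = 0; c < n; ++c)
        std::swap(A[j + (size_t)n * c], A[p + (size_t)n * c]);
    double d = A[j + (size_t)n * j];
    for (int i = j + 1; i < n; ++i) {
      double m = A[i + (size_t)n * j] / d;
      A[i + (size_t)n * j] = m;
      if (m != 0.0)
        for (int c = j + 1; c < n; ++c)
          A[i + (size_t)n * c] -= m * A[j + (size_t)n * c];
    }
  }
  return true;
}

void lu_solve(const std::vector<double>& A, const std::vector<int>& piv,
              int n, std::vector<double>& b) {
  for (int j = 0; j < n; ++j) {
    if (piv[j] != j) std::swap(b[j], b[piv[j]]);
    for (int i = j + 1; i < n; ++i) b[i] -= A[i + (size_t)n * j] * b[j];
  }
  for (int j = n - 1; j >= 0; --j) {
    b[j] /= A[j + (size_t)n * j];
    for (int i = 0; i < j; ++i) b[i] -= A[i + (size_t)n * j] * b[j];
  }
}

double err_norm(const std::vector<double>& e, const std::vector<double>& y,
                const std::vector<double>& ynew, double rtol, double atol) {
  double m = 0.0;
  for (size_t i = 0; i < e.size(); ++i) {
    double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
    m = std::max(m, std::fabs(e[i]) / sc);
  }
  return m;
}

// Cash-Karp tableau
const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 3.0 / 5, c5 = 1.0, c6 = 7.0 / 8;
const double a21 = 1.0 / 5;
const double a31 = 3.0 / 40, a32 = 9.0 / 40;
const double a41 = 3.0 / 10, a42 = -9.0 / 10, a43 = 6.0 / 5;
const double a51 = -11.0 / 54, a52 = 5.0 / 2, a53 = -70.0 / 27, a54 = 35.0 / 27;
const double a61 = 1631.0 / 55296, a62 = 175.0 / 512, a63 = 575.0 / 13824,
             a64 = 44275.0 / 110592, a65 = 253.0 / 4096;
const double b1 = 37.0 / 378, b3 = 250.0 / 621, b4 = 125.0 / 594,
             b6 = 512.0 / 1771;
const double db1 = 37.0 / 378 - 2825.0 / 27648,
             db3 = 250.0 / 621 - 18575.0 / 48384,
             db4 = 125.0 / 594 - 13525.0 / 55296,
             db5 = -277.0 / 14336,
             db6 = 512.0 / 1771 - 1.0 / 4;

} // namespace

// [[Rcpp::export(name = ".integrate_mass_action")]]
List integrate_mass_action(NumericMatrix stoich, IntegerMatrix reactant_idx,
                           NumericVector rates, NumericVector y0,
                           NumericVector times, double rtol, double atol,
                           std::string method, double floor_tol,
                           double max_steps) {
  const int ns = stoich.nrow(), nr = stoich.ncol();
  const int nt = times.size();
  Net net;
  net.ns = ns; net.nr = nr; net.stoich = stoich.begin(); net.k = rates.begin();
  net.i1.resize(nr); net.i2.resize(nr);
  for (int r = 0; r < nr; ++r) {
    net.i1[r] = reactant_idx(0, r) - 1;
    net.i2[r] = reactant_idx(1, r) - 1;
  }

  NumericMatrix out(nt, ns);
  std::vector<double> y(y0.begin(), y0.end());
  double t = 0.0;
  int it = 0;
  // emit any leading output times at t = 0
  while (it < nt && times[it] <= 0.0) {
    for (int i = 0; i < ns; ++i) out(it, i) = y[i];
    ++it;
  }
  if (it == nt)
    return List::create(_["y"] = out, _["ok"] = true, _["nsteps"] = 0.0,
                        _["message"] = "");

  const bool stiff = (method == "rosenbrock");
  const double t_end = times[nt - 1];
  std::vector<double> f0(ns), f1(ns), f2(ns), ytmp(ns), ynew(ns), e(ns);
  std::vector<double> k1(ns), k2(ns), k3(ns), k4(ns), k5(ns), k6(ns);
  std::vector<double> J(stiff ? (size_t)ns * ns : 0),
      W(stiff ? (size_t)ns * ns : 0);
  std::vector<int> piv(ns);
  const double ros_d = 1.0 / (2.0 + std::sqrt(2.0));
  const double ros_e32 = 6.0 + std::sqrt(2.0);
  bool have_f0 = false;

  // initial step: conservative estimate from the rhs magnitude
  net.rhs(y, f0);
  have_f0 = true;
  double fmax = 0.0, ymax = 0.0;
  for (int i = 0; i < ns; ++i) {
    fmax = std::max(fmax, std::fabs(f0[i]));
    ymax = std::max(ymax, std::fabs(y[i]));
  }
  double h = (fmax > 0) ? 0.01 * (ymax + atol) / fmax : (t_end - t) / 100.0;
  h = std::min(h, t_end - t);
  if (h <= 0) h = 1e-6;

  double nsteps = 0;
  std::string msg;
  bool ok = true;

  while (it < nt) {
    if (nsteps++ > max_steps) {
      ok = false;
      msg = "step limit exceeded at time " + std::to_string(t);
      break;
    }
    if ((nsteps > 0) && ((long long)nsteps % 100000 == 0))
      Rcpp::checkUserInterrupt();
    double t_next = times[it];
    bool hit = false;
    double h_nat = h; // remember the unclamped proposal
    if (t + h >= t_next) { h = t_next - t; hit = true; }
    if (h < 1e-13 * std::max(1.0, std::fabs(t)) && !hit) {
      ok = false;
      msg = "step size underflow at time " + std::to_string(t);
      break;
    }

    double err;
    if (!stiff) {
      have_f0 = false;
      net.rhs(y, k1);
      for (int i = 0; i < ns; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
      net.rhs(ytmp, k2);
      for (int i = 0; i < ns; ++i)
        ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
      net.rhs(ytmp, k3);
      for (int i = 0; i < ns; ++i)
        ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
      net.rhs(ytmp, k4);
      for (int i = 0; i < ns; ++i)
        ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
      net.rhs(ytmp, k5);
      for (int i = 0; i < ns; ++i)
        ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                              a64 * k4[i] + a65 * k5[i]);
      net.rhs(ytmp, k6);
      for (int i = 0; i < ns; ++i) {
        ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] + b6 * k6[i]);
        e[i] = h * (db1 * k1[i] + db3 * k3[i] + db4 * k4[i] + db5 * k5[i] +
                    db6 * k6[i]);
      }
      err = err_norm(e, y, ynew, rtol, atol);
    } else {
      if (!have_f0) { net.rhs(y, f0); have_f0 = true; }
      net.jac(y, J);
      const double hd = h * ros_d;
      for (size_t i = 0; i < W.size(); ++i) W[i] = -hd * J[i];
      for (int i = 0; i < ns; ++i) W[i + (size_t)ns * i] += 1.0;
      if (!lu_factor(W, piv, ns)) {
        ok = false;
        msg = "singular Rosenbrock matrix at time " + std::to_string(t);
        break;
      }
      k1 = f0;
      lu_solve(W, piv, ns, k1);
      for (int i = 0; i < ns; ++i) ytmp[i] = y[i] + 0.5 * h * k1[i];
      net.rhs(ytmp, f1);
      for (int i = 0; i < ns; ++i) k2[i] = f1[i] - k1[i];
      lu_solve(W, piv, ns, k2);
      for (int i = 0; i < ns; ++i) k2[i] += k1[i];
      for (int i = 0; i < ns; ++i) ynew[i] = y[i] + h * k2[i];
      net.rhs(ynew, f2);
      for (int i = 0; i < ns; ++i)
        k3[i] = f2[i] - ros_e32 * (k2[i] - f1[i]) - 2.0 * (k1[i] - f0[i]);
      lu_solve(W, piv, ns, k3);
      for (int i = 0; i < ns; ++i)
        e[i] = (h / 6.0) * (k1[i] - 2.0 * k2[i] + k3[i]);
      err = err_norm(e, y, ynew, rtol, atol);
    }

    if (err <= 1.0) { // accept
      t += h;
      y.swap(ynew);
      if (stiff) { f0.swap(f2); have_f0 = true; } // f(ynew) already computed
      for (int i = 0; i < ns; ++i)
        if (y[i] < -floor_tol) {
          ok = false;
          msg = "concentration floor violated (species " +
                std::to_string(i + 1) + " = " + std::to_string(y[i]) +
                ") at time " + std::to_string(t);
          break;
        }
      if (!ok) break;
      if (hit) {
        for (int i = 0; i < ns; ++i) out(it, i) = y[i];
        ++it;
        // also emit duplicates / equal following times
        while (it < nt && times[it] <= t) {
          for (int i = 0; i < ns; ++i) out(it, i) = y[i];
          ++it;
        }
      }
    }
    double ord = stiff ? 3.0 : 5.0;
    double fac = (err > 0) ? 0.9 * std::pow(err, -1.0 / ord) : 5.0;
    fac = std::min(5.0, std::max(0.2, fac));
    // a step clamped to an output time must not shrink the natural proposal
    h = (err <= 1.0 && hit) ? std::max(h_nat, h * fac) : h * fac;
  }

  return List::create(_["y"] = out, _["ok"] = ok, _["nsteps"] = nsteps,
                      _["message"] = msg);
}
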