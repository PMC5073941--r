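#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Right-hand side of a compiled polynomial ODE system.  Every term is
//   coeff * theta[par] * prod_f y[idx_f]^pow_f
// with integer powers.  Negative powers only arise in hybrid (conditional
// moment) systems, where closure monomials carry 1/p(mode) factors; such a
// term is dropped when the mode probability falls below `guard`, which
// freezes negligible modes without renormalization.
struct PolySystem {
  int nstate;
  std::vector<int> eq;        // 0-based state index receiving the term
  std::vector<double> coeff;
  std::vector<int> par;       // 0-based theta index, -1 for none
  std::vector<int> fptr;      // CSR offsets into fidx/fpow
  std::vector<int> fidx;      // 0-based state indices of factors
  std::vector<int> fpow;      // integer powers (may be negative)
  double guard;

  void rhs(const std::vector<double> &y, const NumericVector &theta,
           std::vector<double> &dy) const {
    std::fill(dy.begin(), dy.end(), 0.0);
    const size_t nt = eq.size();
    for (size_t t = 0; t < nt; ++t) {
      double v = coeff[t];
      if (par[t] >= 0) v *= theta[par[t]];
      for (int k = fptr[t]; k < fptr[t + 1]; ++k) {
        const double s = y[fidx[k]];
        const int p = fpow[k];
        if (p < 0) {
          if (std::fabs(s) < guard) { v = 0.0; break; }
          for (int q = 0; q < -p; ++q) v /= s;
        } else {
          for (int q = 0; q < p; ++q) v *= s;
        }
      }
      dy[eq[t]] += v;
    }
  }
};

// Dormand-Prince 5(4) adaptive Runge-Kutta with step-size control,
// integrating exactly to each requested output time.
// [[Rcpp::export]]
List dp45_integrate_cpp(int nstate, IntegerVector eq, NumericVector coeff,
                        IntegerVector par, IntegerVector fptr,
                        IntegerVector fidx, IntegerVector fpow,
                        NumericVector theta, NumericVector y0, double t0,
                        NumericVector times, double rtol, double atol,
                        double guard, int max_steps, double ymax) {
  PolySystem sys;
  sys.nstate = nstate;
  sys.eq.assign(eq.begin(), eq.end());
  sys.coeff.assign(coeff.begin(), coeff.end());
  sys.par.assign(par.begin(), par.end());
  sys.fptr.assign(fptr.begin(), fptr.end());
  sys.fidx.assign(fidx.begin(), fidx.end());
  sys.fpow.assign(fpow.begin(), fpow.end());
  sys.guard = guard;

  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                      a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                      a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                      b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  static const double e1 = 35.0 / 384 - 5179.0 / 57600,
                      e3 = 500.0 / 1113 - 7571.0 / 16695,
                      e4 = 125.0 / 192 - 393.0 / 640,
                      e5 = -2187.0 / 6784 + 92097.0 / 339200,
                      e6 = 11.0 / 84 - 187.0 / 2100, e7 = -1.0 / 40;

  const int T = times.size();
  NumericMatrix out(T, nstate);
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(nstate), k2(nstate), k3(nstate), k4(nstate),
      k5(nstate), k6(nstate), k7(nstate), yt(nstate), ynew(nstate);

  double t = t0;
  const double tend = times[T - 1];
  const double span = std::max(tend - t0, 1e-8);
  double h = span / 100.0;
  const double hmin = span * 1e-14;
  int ti = 0, steps = 0;
  bool ok = true;

  // emit any output times at (or numerically below) t0
  while (ti < T && times[ti] <= t0 + hmin) {
    for (int i = 0; i < nstate; ++i) out(ti, i) = y[i];
    ++ti;
  }

  while (ti < T && ok) {
    const double tnext = times[ti];
    if (t + h > tnext) h = tnext - t;
    if (h < hmin) { ok = false; break; }

    sys.rhs(y, theta, k1);
    for (int i = 0; i < nstate; ++i) yt[i] = y[i] + h * a21 * k1[i];
    sys.rhs(yt, theta, k2);
    for (int i = 0; i < nstate; ++i)
      yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    sys.rhs(yt, theta, k3);
    for (int i = 0; i < nstate; ++i)
      yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    sys.rhs(yt, theta, k4);
    for (int i = 0; i < nstate; ++i)
      yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                          a54 * k4[i]);
    sys.rhs(yt, theta, k5);
    for (int i = 0; i < nstate; ++i)
      yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                          a64 * k4[i] + a65 * k5[i]);
    sys.rhs(yt, theta, k6);
    for (int i = 0; i < nstate; ++i)
      ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                            b5 * k5[i] + b6 * k6[i]);
    sys.rhs(ynew, theta, k7);

    bool finite = true;
    double errnorm = 0.0;
    for (int i = 0; i < nstate; ++i) {
      const double err = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                              e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
      const double sc =
          atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      const double r = err / sc;
      errnorm += r * r;
      if (!std::isfinite(ynew[i]) || std::fabs(ynew[i]) > ymax)
        finite = false;
    }
    errnorm = std::sqrt(errnorm / nstate);

    if (finite && errnorm <= 1.0) {
      t += h;
      y = ynew;
      while (ti < T && times[ti] <= t + hmin) {
        for (int i = 0; i < nstate; ++i) out(ti, i) = y[i];
        ++ti;
      }
    }
    double fac = finite ? 0.9 * std::pow(std::max(errnorm, 1e-10), -0.2) : 0.1;
    if (fac < 0.2) fac = 0.2;
    if (fac > 5.0) fac = 5.0;
    h *= fac;
    if (h < hmin) { ok = false; break; }
    if (++steps > max_steps) { ok = false; break; }
    if ((steps & 0xFFF) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["values"] = out, _["success"] = (ok && ti == T),
                      _["steps"] = steps, _["t_reached"] = t);
}
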