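// ODE integrators for kinetic simulation.
//
// ode_dopri5: adaptive Dormand-Prince 5(4) with PI-free standard step
// control, calling back into R for the derivative (the kinetic laws are
// compiled R expressions). Output is sampled exactly on the requested
// grid by clamping steps to grid boundaries.
//
// ode_rk4_mass_action: fixed-step classical RK4 over mass-action rate
// arrays; the independent reference oracle, no R callback involved.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static NumericVector call_deriv(Function& f, double t, NumericVector& y) {
  NumericVector dy = f(t, y);
  if (dy.size() != y.size())
    stop("derivative returned wrong length");
  return dy;
}

// [[Rcpp::export]]
List ode_dopri5(Function deriv, NumericVector y0, NumericVector tgrid,
                double atol, double rtol, double h0, int max_steps) {
  const int n = y0.size(), m = tgrid.size();
  // Dormand-Prince 5(4) tableau
  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5,
                      c5 = 8.0 / 9;
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
  // embedded 4th order
  static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695,
                      e4 = 71.0 / 1920, e5 = -17253.0 / 339200,
                      e6 = 22.0 / 525, e7 = -1.0 / 40;

  NumericMatrix out(m, n);
  NumericVector y = clone(y0);
  for (int j = 0; j < n; ++j) out(0, j) = y[j];

  double span = tgrid[m - 1] - tgrid[0];
  double h = (h0 > 0) ? h0 : span / 100.0;
  int nsteps = 0, naccept = 0, nreject = 0;
  double t = tgrid[0];

  NumericVector k1 = call_deriv(deriv, t, y);
  NumericVector ytmp(n), ynew(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n);

  for (int g = 1; g < m; ++g) {
    double target = tgrid[g];
    while (target - t > 1e-13 * std::max(1.0, std::fabs(target))) {
      if (++nsteps > max_steps)
        stop("maximum number of steps exceeded at t=%g", t);
      bool clipped = false;
      double hs = h;
      if (t + hs > target) { hs = target - t; clipped = true; }

      for (int j = 0; j < n; ++j) ytmp[j] = y[j] + hs * a21 * k1[j];
      k2 = call_deriv(deriv, t + c2 * hs, ytmp);
      for (int j = 0; j < n; ++j)
        ytmp[j] = y[j] + hs * (a31 * k1[j] + a32 * k2[j]);
      k3 = call_deriv(deriv, t + c3 * hs, ytmp);
      for (int j = 0; j < n; ++j)
        ytmp[j] = y[j] + hs * (a41 * k1[j] + a42 * k2[j] + a43 * k3[j]);
      k4 = call_deriv(deriv, t + c4 * hs, ytmp);
      for (int j = 0; j < n; ++j)
        ytmp[j] = y[j] + hs * (a51 * k1[j] + a52 * k2[j] + a53 * k3[j] +
                               a54 * k4[j]);
      k5 = call_deriv(deriv, t + c5 * hs, ytmp);
      for (int j = 0; j < n; ++j)
        ytmp[j] = y[j] + hs * (a61 * k1[j] + a62 * k2[j] + a63 * k3[j] +
                               a64 * k4[j] + a65 * k5[j]);
      k6 = call_deriv(deriv, t + hs, ytmp);
      for (int j = 0; j < n; ++j)
        ynew[j] = y[j] + hs * (b1 * k1[j] + b3 * k3[j] + b4 * k4[j] +
                               b5 * k5[j] + b6 * k6[j]);
      k7 = call_deriv(deriv, t + hs, ynew);  // FSAL

      double errnorm = 0.0;
      for (int j = 0; j < n; ++j) {
        double err = hs * (e1 * k1[j] + e3 * k3[j] + e4 * k4[j] +
                           e5 * k5[j] + e6 * k6[j] + e7 * k7[j]);
        double sk = atol + rtol * std::max(std::fabs(y[j]),
                                           std::fabs(ynew[j]));
        double r = err / sk;
        errnorm += r * r;
      }
      errnorm = std::sqrt(errnorm / n);
      if (!std::isfinite(errnorm))
        stop("non-finite state encountered at t=%g", t);

      if (errnorm <= 1.0) {
        t += hs;
        y = clone(ynew);
        k1 = clone(k7);
        ++naccept;
        double fac = (errnorm == 0.0) ? 5.0
          : std::min(5.0, std::max(0.2, 0.9 * std::pow(errnorm, -0.2)));
        double hnew = hs * fac;
        if (!clipped || hnew > h) h = hnew;
      } else {
        ++nreject;
        h = hs * std::max(0.2, 0.9 * std::pow(errnorm, -0.2));
      }
      if (h < span * 1e-14)
        stop("step size underflow at t=%g", t);
    }
    t = target;
    for (int j = 0; j < n; ++j) out(g, j) = y[j];
  }
  return List::create(_["y"] = out, _["n_steps"] = nsteps,
                      _["n_accept"] = naccept, _["n_reject"] = nreject);
}

static inline double power_term(double y, double ord) {
  if (ord == 0.0) return 1.0;
  if (ord == 1.0) return y;
  if (ord == 2.0) return y * y;
  return std::pow(y, ord);
}

// [[Rcpp::export]]
NumericMatrix ode_rk4_mass_action(NumericMatrix net, NumericMatrix ordR,
                                  NumericMatrix ordP, NumericVector kf,
                                  NumericVector kr, LogicalVector boundary,
                                  NumericVector y0, NumericVector tgrid,
                                  double h) {
  const int n = y0.size(), nr = kf.size(), m = tgrid.size();
  if (h <= 0) stop("step size must be positive");
  NumericMatrix out(m, n);
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(n), k2(n), k3(n), k4(n), yt(n);

  auto f = [&](const std::vector<double>& yy, std::vector<double>& dy) {
    std::fill(dy.begin(), dy.end(), 0.0);
    for (int j = 0; j < nr; ++j) {
      double vf = kf[j], vr = kr[j];
      for (int i = 0; i < n; ++i) {
        if (ordR(i, j) != 0.0) vf *= power_term(yy[i], ordR(i, j));
        if (vr != 0.0 && ordP(i, j) != 0.0)
          vr *= power_term(yy[i], ordP(i, j));
      }
      double v = vf - vr;
      for (int i = 0; i < n; ++i)
        if (net(i, j) != 0.0) dy[i] += net(i, j) * v;
    }
    for (int i = 0; i < n; ++i) if (boundary[i]) dy[i] = 0.0;
  };

  for (int j = 0; j < n; ++j) out(0, j) = y[j];
  double t = tgrid[0];
  for (int g = 1; g < m; ++g) {
    double target = tgrid[g];
    while (t < target - 1e-15 * std::fabs(target)) {
      double hs = std::min(h, target - t);
      f(y, k1);
      for (int i = 0; i < n; ++i) yt[i] = y[i] + 0.5 * hs * k1[i];
      f(yt, k2);
      for (int i = 0; i < n; ++i) yt[i] = y[i] + 0.5 * hs * k2[i];
      f(yt, k3);
      for (int i = 0; i < n; ++i) yt[i] = y[i] + hs * k3[i];
      f(yt, k4);
      for (int i = 0; i < n; ++i)
        y[i] += hs / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      t += hs;
    }
    t = target;
    for (int j = 0; j < n; ++j) out(g, j) = y[j];
  }
  return out;
}
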