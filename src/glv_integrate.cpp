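#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Generalized Lotka-Volterra right-hand side:
//   dx_i/dt = x_i * (r_i + sum_j a_ij * x_j / N) * (1 - N / K),  N = sum_i x_i
// N == 0 is absorbing: derivative is identically zero.
static inline void glv_deriv(const int n, const double *r, const double *A,
                             const double K, const double *x, double *dx) {
  double N = 0.0;
  for (int i = 0; i < n; ++i) N += x[i];
  if (N <= 0.0) {
    for (int i = 0; i < n; ++i) dx[i] = 0.0;
    return;
  }
  const double cap = 1.0 - N / K;
  for (int i = 0; i < n; ++i) {
    double g = r[i];
    // A stored column-major (R matrix): A[i + n*j] = a_ij
    for (int j = 0; j < n; ++j) g += A[i + n * j] * x[j] / N;
    dx[i] = x[i] * g * cap;
  }
}

// Dormand-Prince 5(4) embedded pair, adaptive step size.
// Returns list(X = times x n state matrix, status = 0 ok / 1 failure).
// Negative excursions are floored at 0 (the model preserves non-negativity
// analytically; small negatives are integration error).
// [[Rcpp::export(name = ".glv_integrate_rk45")]]
List glv_integrate_rk45(NumericVector r, NumericMatrix A, double K,
                        NumericVector x0, NumericVector times,
                        double rtol = 1e-6, double atol = 1e-9,
                        int max_steps = 500000) {
  const int n = r.size();
  const int T = times.size();
  NumericMatrix X(T, n);
  int status = 0;

  std::vector<double> x(n), xn(n), dx(n), err(n), tmp(n);
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n);
  for (int i = 0; i < n; ++i) x[i] = x0[i] < 0.0 ? 0.0 : x0[i];
  for (int i = 0; i < n; ++i) X(0, i) = x[i];

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
  const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
               e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

  const double *rp = REAL(r), *Ap = REAL(A);
  double t = times[0];
  double hmax = times[T - 1] - times[0];
  if (hmax <= 0.0) hmax = 1.0;
  double h = hmax / 100.0;
  int steps = 0;
  bool have_k1 = false;

  for (int ti = 1; ti < T; ++ti) {
    const double tend = times[ti];
    while (t < tend) {
      if (++steps > max_steps) { status = 1; break; }
      if (h > tend - t) h = tend - t;
      if (h < 1e-14 * std::max(1.0, std::fabs(t))) { status = 1; break; }

      if (!have_k1) glv_deriv(n, rp, Ap, K, x.data(), k1.data());
      for (int i = 0; i < n; ++i) tmp[i] = x[i] + h * a21 * k1[i];
      glv_deriv(n, rp, Ap, K, tmp.data(), k2.data());
      for (int i = 0; i < n; ++i)
        tmp[i] = x[i] + h * (a31 * k1[i] + a32 * k2[i]);
      glv_deriv(n, rp, Ap, K, tmp.data(), k3.data());
      for (int i = 0; i < n; ++i)
        tmp[i] = x[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
      glv_deriv(n, rp, Ap, K, tmp.data(), k4.data());
      for (int i = 0; i < n; ++i)
        tmp[i] = x[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                             a54 * k4[i]);
      glv_deriv(n, rp, Ap, K, tmp.data(), k5.data());
      for (int i = 0; i < n; ++i)
        tmp[i] = x[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                             a64 * k4[i] + a65 * k5[i]);
      glv_deriv(n, rp, Ap, K, tmp.data(), k6.data());
      for (int i = 0; i < n; ++i)
        xn[i] = x[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                            b5 * k5[i] + b6 * k6[i]);
      glv_deriv(n, rp, Ap, K, xn.data(), k7.data());

      bool finite = true;
      double errnorm = 0.0;
      for (int i = 0; i < n; ++i) {
        if (!std::isfinite(xn[i])) { finite = false; break; }
        const double e = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                              e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
        const double sc =
            atol + rtol * std::max(std::fabs(x[i]), std::fabs(xn[i]));
        const double q = e / sc;
        errnorm += q * q;
      }
      errnorm = finite ? std::sqrt(errnorm / n) : 1e10;

      if (errnorm <= 1.0) {
        t += h;
        for (int i = 0; i < n; ++i) {
          x[i] = xn[i] < 0.0 ? 0.0 : xn[i];
          k1[i] = k7[i];  // FSAL
        }
        // FSAL derivative invalid if we clamped; recompute lazily
        have_k1 = true;
        for (int i = 0; i < n; ++i)
          if (xn[i] < 0.0) { have_k1 = false; break; }
      } else {
        have_k1 = true;  // k1 still valid at unchanged x
      }
      double fac = 0.9 * std::pow(std::max(errnorm, 1e-10), -0.2);
      if (fac > 5.0) fac = 5.0;
      if (fac < 0.2) fac = 0.2;
      h *= fac;
      if (h > hmax) h = hmax;
    }
    if (status != 0) break;
    for (int i = 0; i < n; ++i) X(ti, i) = x[i];
  }

  return List::create(_["X"] = X, _["status"] = status);
}
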