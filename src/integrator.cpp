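#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Right-hand side of the discretized competition model.
// State layout: y = (u_1..u_n, v_1..v_n), column-major for 2D grids.
// dim 0: well-mixed pair; dim 1: periodic ring; dim 2: periodic square torus.
// Dd2 = D / delta^2. onsite collapses the inhibition kernel to c*v_i (control).
static void rhs_eval(const std::vector<double>& y, std::vector<double>& dy,
                     int dim, int n, int side,
                     double alpha, double beta, double c, double Dd2,
                     bool onsite) {
  const double* u = y.data();
  const double* v = y.data() + n;
  double* du = dy.data();
  double* dv = dy.data() + n;
  if (dim == 0) {
    du[0] = u[0] * (alpha - u[0] - v[0] * (1.0 + c));
    dv[0] = v[0] * (beta - u[0] - v[0]);
  } else if (dim == 1) {
    const double c1 = c / 3.0;
    for (int i = 0; i < n; ++i) {
      const int ip = (i + 1 == n) ? 0 : i + 1;
      const int im = (i == 0) ? n - 1 : i - 1;
      const double inhib = onsite ? c * v[i] : c1 * (v[ip] + v[i] + v[im]);
      du[i] = u[i] * (alpha - u[i] - v[i] - inhib)
        + Dd2 * (u[ip] - 2.0 * u[i] + u[im]);
      dv[i] = v[i] * (beta - u[i] - v[i])
        + Dd2 * (v[ip] - 2.0 * v[i] + v[im]);
    }
  } else {
    const double c2 = c / 5.0;
    for (int j = 0; j < side; ++j) {
      const int jp = (j + 1 == side) ? 0 : j + 1;
      const int jm = (j == 0) ? side - 1 : j - 1;
      for (int i = 0; i < side; ++i) {
        const int ip = (i + 1 == side) ? 0 : i + 1;
        const int im = (i == 0) ? side - 1 : i - 1;
        const int k = i + j * side;
        const int kN = im + j * side, kS = ip + j * side;
        const int kW = i + jm * side, kE = i + jp * side;
        const double inhib = onsite ? c * v[k]
          : c2 * (v[k] + v[kN] + v[kS] + v[kW] + v[kE]);
        du[k] = u[k] * (alpha - u[k] - v[k] - inhib)
          + Dd2 * (u[kN] + u[kS] + u[kW] + u[kE] - 4.0 * u[k]);
        dv[k] = v[k] * (beta - u[k] - v[k])
          + Dd2 * (v[kN] + v[kS] + v[kW] + v[kE] - 4.0 * v[k]);
      }
    }
  }
}

// [[Rcpp::export]]
List rhs_cpp(NumericVector u, NumericVector v, int dim, int side,
             double alpha, double beta, double c, double Dd2, bool onsite) {
  const int n = u.size();
  std::vector<double> y(2 * n), dy(2 * n);
  for (int i = 0; i < n; ++i) { y[i] = u[i]; y[n + i] = v[i]; }
  rhs_eval(y, dy, dim, n, side, alpha, beta, c, Dd2, onsite);
  NumericVector du(n), dv(n);
  for (int i = 0; i < n; ++i) { du[i] = dy[i]; dv[i] = dy[n + i]; }
  return List::create(_["du"] = du, _["dv"] = dv);
}

// Cash-Karp embedded Runge-Kutta 4(5) tableau.
static const double B21 = 0.2;
static const double B31 = 3.0 / 40.0, B32 = 9.0 / 40.0;
static const double B41 = 0.3, B42 = -0.9, B43 = 1.2;
static const double B51 = -11.0 / 54.0, B52 = 2.5, B53 = -70.0 / 27.0,
  B54 = 35.0 / 27.0;
static const double B61 = 1631.0 / 55296.0, B62 = 175.0 / 512.0,
  B63 = 575.0 / 13824.0, B64 = 44275.0 / 110592.0, B65 = 253.0 / 4096.0;
static const double C1 = 37.0 / 378.0, C3 = 250.0 / 621.0,
  C4 = 125.0 / 594.0, C6 = 512.0 / 1771.0;
static const double D1 = C1 - 2825.0 / 27648.0, D3 = C3 - 18575.0 / 48384.0,
  D4 = C4 - 13525.0 / 55296.0, D5 = -277.0 / 14336.0, D6 = C6 - 0.25;

// Adaptive RK45 integrator with negativity clamping and convergence
// detection: the running mean (over the last `window` accepted steps) of the
// maximal per-step state change must fall below `conv_tol`.
// [[Rcpp::export]]
List integrate_cpp(NumericVector u0, NumericVector v0, int dim, int side,
                   double alpha, double beta, double c, double D, double delta,
                   double tol, double hmax, double conv_tol, int window,
                   double max_time, double t0, double save_interval,
                   bool onsite) {
  const int n = u0.size();
  const int m = 2 * n;
  const double Dd2 = D / (delta * delta);

  std::vector<double> y(m), ynew(m), yerr(m), ytmp(m);
  std::vector<double> k1(m), k2(m), k3(m), k4(m), k5(m), k6(m);
  for (int i = 0; i < n; ++i) { y[i] = u0[i]; y[n + i] = v0[i]; }

  // circular buffer of per-step max changes for the convergence rule
  std::vector<double> ring(window, 0.0);
  double ring_sum = 0.0;
  int ring_pos = 0;

  std::vector<double> traj;   // rows of (t, y) when save_interval > 0
  double next_save = t0;
  if (save_interval > 0.0) {
    traj.push_back(t0);
    traj.insert(traj.end(), y.begin(), y.end());
    next_save = t0 + save_interval;
  }

  double t = t0;
  double h = std::min(hmax, 1e-2);
  long n_acc = 0, n_rej = 0;
  bool converged = false;
  const double hmin = 1e-14;

  while (t < max_time) {
    if ((n_acc + n_rej) % 16384 == 0) Rcpp::checkUserInterrupt();
    if (t + h > max_time) h = max_time - t;

    rhs_eval(y, k1, dim, n, side, alpha, beta, c, Dd2, onsite);
    for (int i = 0; i < m; ++i) ytmp[i] = y[i] + h * B21 * k1[i];
    rhs_eval(ytmp, k2, dim, n, side, alpha, beta, c, Dd2, onsite);
    for (int i = 0; i < m; ++i)
      ytmp[i] = y[i] + h * (B31 * k1[i] + B32 * k2[i]);
    rhs_eval(ytmp, k3, dim, n, side, alpha, beta, c, Dd2, onsite);
    for (int i = 0; i < m; ++i)
      ytmp[i] = y[i] + h * (B41 * k1[i] + B42 * k2[i] + B43 * k3[i]);
    rhs_eval(ytmp, k4, dim, n, side, alpha, beta, c, Dd2, onsite);
    for (int i = 0; i < m; ++i)
      ytmp[i] = y[i] + h * (B51 * k1[i] + B52 * k2[i] + B53 * k3[i]
                              + B54 * k4[i]);
    rhs_eval(ytmp, k5, dim, n, side, alpha, beta, c, Dd2, onsite);
    for (int i = 0; i < m; ++i)
      ytmp[i] = y[i] + h * (B61 * k1[i] + B62 * k2[i] + B63 * k3[i]
                              + B64 * k4[i] + B65 * k5[i]);
    rhs_eval(ytmp, k6, dim, n, side, alpha, beta, c, Dd2, onsite);

    double errmax = 0.0, minval = 0.0;
    for (int i = 0; i < m; ++i) {
      ynew[i] = y[i] + h * (C1 * k1[i] + C3 * k3[i] + C4 * k4[i] + C6 * k6[i]);
      const double e = h * (D1 * k1[i] + D3 * k3[i] + D4 * k4[i]
                              + D5 * k5[i] + D6 * k6[i]);
      if (std::fabs(e) > errmax) errmax = std::fabs(e);
      if (ynew[i] < minval) minval = ynew[i];
    }
    if (!std::isfinite(errmax) || !std::isfinite(minval))
      stop("non-finite state encountered during integration (t = %g)", t);

    if (errmax > tol || minval < -tol) {
      // reject: shrink (error-based when possible, halve for negativity)
      double fac = (errmax > tol)
        ? std::max(0.1, 0.9 * std::pow(tol / errmax, 0.25)) : 0.5;
      h *= fac;
      if (h < hmin)
        stop("step size underflow at t = %g (state may be unresolvable)", t);
      ++n_rej;
      continue;
    }

    // accept: clamp small negatives (within tol of zero) to exactly zero
    double dmax = 0.0;
    for (int i = 0; i < m; ++i) {
      if (ynew[i] < 0.0) ynew[i] = 0.0;
      const double d = std::fabs(ynew[i] - y[i]);
      if (d > dmax) dmax = d;
    }
    t += h;
    y.swap(ynew);
    ++n_acc;

    ring_sum += dmax - ring[ring_pos];
    ring[ring_pos] = dmax;
    ring_pos = (ring_pos + 1) % window;

    if (save_interval > 0.0) {
      while (t >= next_save - 1e-12) {
        traj.push_back(t);
        traj.insert(traj.end(), y.begin(), y.end());
        next_save += save_interval;
      }
    }

    if (n_acc >= window && ring_sum / window < conv_tol) {
      converged = true;
      break;
    }

    const double grow = (errmax > 0.0)
      ? std::min(5.0, 0.9 * std::pow(tol / errmax, 0.2)) : 5.0;
    h = std::min(hmax, h * grow);
  }

  NumericVector uf(n), vf(n);
  for (int i = 0; i < n; ++i) { uf[i] = y[i]; vf[i] = y[n + i]; }

  List out = List::create(
    _["u"] = uf, _["v"] = vf, _["time"] = t,
    _["converged"] = converged,
    _["n_accepted"] = (double) n_acc, _["n_rejected"] = (double) n_rej,
    _["mean_step_change"] = (n_acc >= window) ? ring_sum / window : NA_REAL);
  if (save_interval > 0.0) {
    const int nrow = traj.size() / (m + 1);
    NumericMatrix tm(nrow, m + 1);
    for (int r = 0; r < nrow; ++r)
      for (int cidx = 0; cidx < m + 1; ++cidx)
        tm(r, cidx) = traj[r * (m + 1) + cidx];
    out["trajectory"] = tm;
  }
  return out;
}
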