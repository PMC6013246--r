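#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Model parameter vector layout (see R/force_models.R, as_param_vector):
//  0..3   internuclear law: sign, alpha, magnitude, cutoff
//  4..7   side law:         sign, alpha, magnitude, cutoff
//  8..11  pole law:         sign, alpha, magnitude, cutoff
//  12     d_ref, 13 Q_SE, 14 nuclear radius r

// finite cutoffs are tapered linearly to zero over the final CUT_W microns
// below c; a sharp Heaviside leaves no continuous equilibrium (nuclei chatter
// on the cutoff surface and the velocity residual cannot converge)
static const double CUT_W = 2.0;

static inline double power_law(double d, double sign, double alpha, double M,
                               double cutoff, double dref) {
  if (d >= cutoff) return 0.0;  // H(c - d) taken as 0 at d == c
  double ratio = d / dref;
  double p;
  if (alpha == -1.0) p = 1.0 / ratio;
  else if (alpha == 0.0) p = 1.0;
  else if (alpha == 1.0) p = ratio;
  else p = std::pow(ratio, alpha);
  double f = sign * M * p;
  if (d > cutoff - CUT_W) f *= (cutoff - d) / CUT_W;
  return f;
}

static inline double size_excl(double d, double diam, double Q) {
  if (d >= diam) return 0.0;
  return Q * (1.0 / (d * d) - 1.0 / (diam * diam));
}

// [[Rcpp::export]]
double cpp_power_law(double d, double sign, double alpha, double M,
                     double cutoff, double dref) {
  return power_law(d, sign, alpha, M, cutoff, dref);
}

// [[Rcpp::export]]
double cpp_size_exclusion(double d, double diam, double Q) {
  return size_excl(d, diam, Q);
}

static const double D_EPS = 1e-9;  // distance floor; repulsion diverges anyway

// plain-array force evaluation; x[i], y[i] positions, writes vx, vy
static void velocities(int n, const double* x, const double* y,
                       const double* p, double b, double l,
                       double* vx, double* vy) {
  const double dref = p[12], Q = p[13], r = p[14];
  const double two_r = 2.0 * r;
  for (int i = 0; i < n; ++i) { vx[i] = 0.0; vy[i] = 0.0; }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double d = std::sqrt(dx * dx + dy * dy);
      if (d < D_EPS) d = D_EPS;
      double F = power_law(d, p[0], p[1], p[2], p[3], dref) +
                 size_excl(d, two_r, Q);
      double fx = F * dx / d, fy = F * dy / d;
      vx[i] += fx; vy[i] += fy;
      vx[j] -= fx; vy[j] -= fy;
    }
  }
  for (int i = 0; i < n; ++i) {
    double dL = b + x[i], dR = b - x[i], dD = l + y[i], dU = l - y[i];
    if (dL < D_EPS) dL = D_EPS;
    if (dR < D_EPS) dR = D_EPS;
    if (dD < D_EPS) dD = D_EPS;
    if (dU < D_EPS) dU = D_EPS;
    // sides, unit vector pointing from the wall toward the nucleus
    vx[i] += power_law(dL, p[4], p[5], p[6], p[7], dref) + size_excl(dL, r, Q);
    vx[i] -= power_law(dR, p[4], p[5], p[6], p[7], dref) + size_excl(dR, r, Q);
    // poles
    vy[i] += power_law(dD, p[8], p[9], p[10], p[11], dref) + size_excl(dD, r, Q);
    vy[i] -= power_law(dU, p[8], p[9], p[10], p[11], dref) + size_excl(dU, r, Q);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_net_velocities(NumericMatrix X, NumericVector par,
                                 double b, double l) {
  int n = X.nrow();
  NumericMatrix V(n, 2);
  std::vector<double> x(n), y(n), vx(n), vy(n);
  for (int i = 0; i < n; ++i) { x[i] = X(i, 0); y[i] = X(i, 1); }
  velocities(n, x.data(), y.data(), REAL(par), b, l, vx.data(), vy.data());
  for (int i = 0; i < n; ++i) { V(i, 0) = vx[i]; V(i, 1) = vy[i]; }
  return V;
}

static inline double max_speed(int n, const double* vx, const double* vy) {
  double m = 0.0;
  for (int i = 0; i < n; ++i) {
    double s = vx[i] * vx[i] + vy[i] * vy[i];
    if (s > m) m = s;
  }
  return std::sqrt(m);
}

static inline bool inside(int n, const double* x, const double* y,
                          double b, double l) {
  for (int i = 0; i < n; ++i) {
    if (x[i] < -b || x[i] > b || y[i] < -l || y[i] > l) return false;
  }
  return true;
}

// Damped Levenberg-Marquardt polish of the force balance V(X) = 0, started
// from the relaxation endpoint. Finite-difference Jacobian; steps are capped
// at step_cap microns and rejected if they leave the rectangle or increase
// the residual. Returns true if the final max per-nucleus speed is below tol.
static bool lm_polish(int n, std::vector<double>& x, std::vector<double>& y,
                      const double* p, double b, double l, double tol) {
  const int m = 2 * n;
  const double h = 1e-6, step_cap = 2.0;
  std::vector<double> vx(n), vy(n), v(m), vtry(m), xt(n), yt(n);
  std::vector<double> J(m * m), A(m * m), g(m), del(m);
  auto eval = [&](std::vector<double>& xx, std::vector<double>& yy,
                  std::vector<double>& out) {
    std::vector<double> wx(n), wy(n);
    velocities(n, xx.data(), yy.data(), p, b, l, wx.data(), wy.data());
    for (int i = 0; i < n; ++i) { out[i] = wx[i]; out[n + i] = wy[i]; }
  };
  eval(x, y, v);
  double mu = 1e-3;
  for (int iter = 0; iter < 80; ++iter) {
    double res = 0.0;
    for (int i = 0; i < n; ++i) {
      double s = v[i] * v[i] + v[n + i] * v[n + i];
      if (s > res) res = s;
    }
    if (std::sqrt(res) < tol) return true;
    // finite-difference Jacobian, column per coordinate
    for (int k = 0; k < m; ++k) {
      xt = x; yt = y;
      if (k < n) xt[k] += h; else yt[k - n] += h;
      eval(xt, yt, vtry);
      for (int r = 0; r < m; ++r) J[r * m + k] = (vtry[r] - v[r]) / h;
    }
    double f0 = 0.0;
    for (int r = 0; r < m; ++r) f0 += v[r] * v[r];
    bool stepped = false;
    for (int inner = 0; inner < 10 && !stepped; ++inner) {
      // A = J^T J + mu I, g = -J^T v
      for (int a = 0; a < m; ++a) {
        g[a] = 0.0;
        for (int r = 0; r < m; ++r) g[a] -= J[r * m + a] * v[r];
        for (int c2 = a; c2 < m; ++c2) {
          double s = 0.0;
          for (int r = 0; r < m; ++r) s += J[r * m + a] * J[r * m + c2];
          A[a * m + c2] = s; A[c2 * m + a] = s;
        }
        A[a * m + a] += mu * (A[a * m + a] > 1e-12 ? A[a * m + a] : 1.0);
      }
      // Gaussian elimination with partial pivoting: A del = g
      std::vector<double> M2(A), rhs(g);
      bool singular = false;
      for (int c2 = 0; c2 < m; ++c2) {
        int piv = c2;
        for (int r = c2 + 1; r < m; ++r)
          if (std::fabs(M2[r * m + c2]) > std::fabs(M2[piv * m + c2])) piv = r;
        if (std::fabs(M2[piv * m + c2]) < 1e-14) { singular = true; break; }
        if (piv != c2) {
          for (int c3 = 0; c3 < m; ++c3) std::swap(M2[piv * m + c3], M2[c2 * m + c3]);
          std::swap(rhs[piv], rhs[c2]);
        }
        for (int r = c2 + 1; r < m; ++r) {
          double fac = M2[r * m + c2] / M2[c2 * m + c2];
          for (int c3 = c2; c3 < m; ++c3) M2[r * m + c3] -= fac * M2[c2 * m + c3];
          rhs[r] -= fac * rhs[c2];
        }
      }
      if (singular) { mu *= 10.0; continue; }
      for (int r = m - 1; r >= 0; --r) {
        double s = rhs[r];
        for (int c3 = r + 1; c3 < m; ++c3) s -= M2[r * m + c3] * del[c3];
        del[r] = s / M2[r * m + r];
      }
      double dn = 0.0;
      for (int r = 0; r < m; ++r) dn += del[r] * del[r];
      dn = std::sqrt(dn);
      double scale = dn > step_cap ? step_cap / dn : 1.0;
      xt = x; yt = y;
      for (int i = 0; i < n; ++i) { xt[i] += scale * del[i]; yt[i] += scale * del[n + i]; }
      if (!inside(n, xt.data(), yt.data(), b, l)) { mu *= 4.0; continue; }
      eval(xt, yt, vtry);
      double f1 = 0.0;
      for (int r = 0; r < m; ++r) f1 += vtry[r] * vtry[r];
      if (std::isfinite(f1) && f1 < f0) {
        x = xt; y = yt; v = vtry;
        mu = std::max(mu / 3.0, 1e-12);
        stepped = true;
      } else {
        mu *= 4.0;
      }
    }
    if (!stepped) return false;  // no descent direction found
  }
  double res = 0.0;
  for (int i = 0; i < n; ++i) {
    double s = v[i] * v[i] + v[n + i] * v[n + i];
    if (s > res) res = s;
  }
  return std::sqrt(res) < tol;
}

// Overdamped relaxation dX/dt = V(X) with an adaptive embedded Euler/Heun
// pair. Per-step position error is held at err_tol (microns); steps that
// leave the rectangle are rejected and retried smaller, never clamped.
// Converged when every velocity 2-norm drops below tol. Stall detection:
// when the residual stops improving between checkpoints (collapsed clusters
// pinned at the size-exclusion contact keep the explicit scheme at its
// stability limit), the run is abandoned as non-converged.
// [[Rcpp::export]]
List cpp_relax(NumericMatrix X0, NumericVector par, double b, double l,
               double tol = 1e-4, double t_max = 1e6,
               int max_steps = 200000, double err_tol = 1e-3,
               int stall_check = 0, double stall_factor = 0.9) {
  int n = X0.nrow();
  const double* p = REAL(par);
  std::vector<double> x(n), y(n), vx(n), vy(n), xe(n), ye(n), v2x(n), v2y(n),
      xh(n), yh(n);
  for (int i = 0; i < n; ++i) { x[i] = X0(i, 0); y[i] = X0(i, 1); }
  velocities(n, x.data(), y.data(), p, b, l, vx.data(), vy.data());
  double t = 0.0, dt = 1e-3;
  int steps = 0, accepted = 0, next_check = stall_check;
  int check_interval = stall_check;
  bool converged = false, stalled = false, polished = false;
  double resid = max_speed(n, vx.data(), vy.data());
  double check_resid = resid;
  while (steps < max_steps && t < t_max) {
    resid = max_speed(n, vx.data(), vy.data());
    if (resid < tol) { converged = true; break; }
    if (stall_check > 0 && accepted >= next_check) {
      if (resid > stall_factor * check_resid && accepted >= 2 * stall_check) {
        // residual no longer improving: try to finish by root-finding; if
        // the polish fails the dynamics are mid-transit, so keep integrating
        // and back off the checkpoint interval
        stalled = true;
        if (lm_polish(n, x, y, p, b, l, tol)) {
          polished = true;
          converged = true;
          velocities(n, x.data(), y.data(), p, b, l, vx.data(), vy.data());
          break;
        }
        check_interval *= 2;
      }
      check_resid = resid;
      next_check = accepted + check_interval;
    }
    for (int i = 0; i < n; ++i) {
      xe[i] = x[i] + dt * vx[i];
      ye[i] = y[i] + dt * vy[i];
    }
    bool ok = inside(n, xe.data(), ye.data(), b, l);
    double err = 0.0;
    if (ok) {
      velocities(n, xe.data(), ye.data(), p, b, l, v2x.data(), v2y.data());
      for (int i = 0; i < n; ++i) {
        double ex = 0.5 * dt * (v2x[i] - vx[i]);
        double ey = 0.5 * dt * (v2y[i] - vy[i]);
        double e = ex * ex + ey * ey;
        if (e > err) err = e;
        xh[i] = x[i] + 0.5 * dt * (vx[i] + v2x[i]);
        yh[i] = y[i] + 0.5 * dt * (vy[i] + v2y[i]);
      }
      err = std::sqrt(err);
      ok = std::isfinite(err) && err <= err_tol &&
           inside(n, xh.data(), yh.data(), b, l);
    }
    ++steps;
    if (!ok) {
      dt *= 0.5;
      if (dt < 1e-12) break;  // hopeless stiffness / boundary pinning
      continue;
    }
    for (int i = 0; i < n; ++i) { x[i] = xh[i]; y[i] = yh[i]; }
    ++accepted;
    t += dt;
    velocities(n, x.data(), y.data(), p, b, l, vx.data(), vy.data());
    double grow = err > 0 ? 0.9 * std::sqrt(err_tol / err) : 2.0;
    if (grow > 2.0) grow = 2.0;
    if (grow < 0.2) grow = 0.2;
    dt *= grow;
    if (dt > t_max) dt = t_max;
  }
  resid = max_speed(n, vx.data(), vy.data());
  if (resid < tol) converged = true;
  // stiff boundary layers (size exclusion, strong tapered cutoffs) make the
  // explicit scheme crawl; if the step budget ran out before the model-time
  // budget, make a final root-finding attempt from the endpoint
  if (!converged && steps >= max_steps && t < t_max) {
    polished = lm_polish(n, x, y, p, b, l, tol);
    if (polished) {
      converged = true;
      velocities(n, x.data(), y.data(), p, b, l, vx.data(), vy.data());
      resid = max_speed(n, vx.data(), vy.data());
    }
  }
  NumericMatrix X(n, 2);
  for (int i = 0; i < n; ++i) { X(i, 0) = x[i]; X(i, 1) = y[i]; }
  return List::create(_["positions"] = X, _["converged"] = converged,
                      _["max_residual"] = resid, _["elapsed"] = t,
                      _["steps"] = steps, _["stalled"] = stalled,
                      _["polished"] = polished);
}
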