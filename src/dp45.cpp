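// Dormand-Prince 5(4) adaptive integrator for the tumour/vasculature/oxygen
// model with piecewise-constant treatment forcing. Forcing is resolved in R
// into segments on which the RT dose rate and HT damage rate are constant,
// so integration within a segment sees a smooth vector field (except for the
// state-dependent hypoxia switch at c = c_min, handled by tight tolerances).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int NDIM = 7; // T, T_S, T_R, T_H, V, c, Lambda

struct Pars {
  double q2, delta, delta_S, c_min, lam, nu, lam_S, mu0, xi,
    eta_R, eta_H, kappa0, g, q1, q3, theta1, theta2, mu_Lambda, k1, k2;
};

static Pars unpack(const NumericVector &p) {
  Pars q;
  q.q2 = p["q2"]; q.delta = p["delta"]; q.delta_S = p["delta_S"];
  q.c_min = p["c_min"]; q.lam = p["lam"]; q.nu = p["nu"];
  q.lam_S = p["lam_S"]; q.mu0 = p["mu0"]; q.xi = p["xi"];
  q.eta_R = p["eta_R"]; q.eta_H = p["eta_H"]; q.kappa0 = p["kappa0"];
  q.g = p["g"]; q.q1 = p["q1"]; q.q3 = p["q3"];
  q.theta1 = p["theta1"]; q.theta2 = p["theta2"];
  q.mu_Lambda = p["mu_Lambda"]; q.k1 = p["k1"]; q.k2 = p["k2"];
  return q;
}

// Right-hand side with constant forcing (R dose rate, beta damage rate,
// ht_on indicator driving repair-protein inactivation).
static inline void rhs(const double *y, double *f, const Pars &p,
                       double R, double beta, double ht_on) {
  const double T = y[0], TS = y[1], TR = y[2], TH = y[3], V = y[4],
    c = y[5], L = y[6];
  const double Sigma = T + TS + TR + TH + V;
  const double fre = 1.0 - Sigma;
  // Heaviside H(c_min - c) = 1 iff c <= c_min (H(0) = 1)
  const double hyp = (c <= p.c_min) ? (p.c_min - c) : 0.0;
  const double mu = p.mu0 * std::exp(-p.mu_Lambda * L);
  f[0] = p.q2 * c * fre * T
    - (p.delta * hyp + p.lam * c * R + p.nu * c * R) * T
    + mu * TS - beta * T;
  f[1] = p.theta2 * p.q2 * c * fre * TS
    - (p.delta_S * hyp + p.lam_S * c * R + mu + p.xi) * TS
    + p.nu * c * R * T - beta * TS;
  f[2] = p.lam * c * R * T + (p.lam_S * c * R + p.xi) * TS - p.eta_R * TR;
  f[3] = beta * (T + TS) - p.eta_H * TH;
  f[4] = p.kappa0 * TH - beta * V;
  f[5] = p.g * (1.0 - c) * V
    - (p.q1 * c * (T + p.theta1 * TS) + p.q3 * c * fre * (T + p.theta2 * TS));
  f[6] = p.k1 * ht_on * (1.0 - L) - p.k2 * L;
}

// Dormand-Prince coefficients
static const double A21 = 1.0 / 5.0;
static const double A31 = 3.0 / 40.0, A32 = 9.0 / 40.0;
static const double A41 = 44.0 / 45.0, A42 = -56.0 / 15.0, A43 = 32.0 / 9.0;
static const double A51 = 19372.0 / 6561.0, A52 = -25360.0 / 2187.0,
  A53 = 64448.0 / 6561.0, A54 = -212.0 / 729.0;
static const double A61 = 9017.0 / 3168.0, A62 = -355.0 / 33.0,
  A63 = 46732.0 / 5247.0, A64 = 49.0 / 176.0, A65 = -5103.0 / 18656.0;
static const double A71 = 35.0 / 384.0, A73 = 500.0 / 1113.0,
  A74 = 125.0 / 192.0, A75 = -2187.0 / 6784.0, A76 = 11.0 / 84.0;
// error = 5th order minus embedded 4th order
static const double E1 = 71.0 / 57600.0, E3 = -71.0 / 16695.0,
  E4 = 71.0 / 1920.0, E5 = -17253.0 / 339200.0, E6 = 22.0 / 525.0,
  E7 = -1.0 / 40.0;

struct Stats {
  long naccept = 0, nreject = 0, nclip_soft = 0, nclip_hard = 0;
};

// One accepted-or-rejected DP45 attempt; returns error norm. k1 must hold
// f(t, y) on entry (FSAL); on acceptance k7 is f at the new point.
static double dp45_attempt(const double *y, const double k[8][NDIM],
                           double h, double *ynew, double *k7,
                           double kst[8][NDIM], const Pars &p,
                           double R, double beta, double ht_on,
                           double rtol, double atol) {
  double yt[NDIM];
  for (int i = 0; i < NDIM; ++i) yt[i] = y[i] + h * A21 * k[1][i];
  rhs(yt, kst[2], p, R, beta, ht_on);
  for (int i = 0; i < NDIM; ++i)
    yt[i] = y[i] + h * (A31 * k[1][i] + A32 * kst[2][i]);
  rhs(yt, kst[3], p, R, beta, ht_on);
  for (int i = 0; i < NDIM; ++i)
    yt[i] = y[i] + h * (A41 * k[1][i] + A42 * kst[2][i] + A43 * kst[3][i]);
  rhs(yt, kst[4], p, R, beta, ht_on);
  for (int i = 0; i < NDIM; ++i)
    yt[i] = y[i] + h * (A51 * k[1][i] + A52 * kst[2][i] + A53 * kst[3][i]
                        + A54 * kst[4][i]);
  rhs(yt, kst[5], p, R, beta, ht_on);
  for (int i = 0; i < NDIM; ++i)
    yt[i] = y[i] + h * (A61 * k[1][i] + A62 * kst[2][i] + A63 * kst[3][i]
                        + A64 * kst[4][i] + A65 * kst[5][i]);
  rhs(yt, kst[6], p, R, beta, ht_on);
  for (int i = 0; i < NDIM; ++i)
    ynew[i] = y[i] + h * (A71 * k[1][i] + A73 * kst[3][i] + A74 * kst[4][i]
                          + A75 * kst[5][i] + A76 * kst[6][i]);
  rhs(ynew, k7, p, R, beta, ht_on);
  double err = 0.0;
  for (int i = 0; i < NDIM; ++i) {
    const double e = h * (E1 * k[1][i] + E3 * kst[3][i] + E4 * kst[4][i]
                          + E5 * kst[5][i] + E6 * kst[6][i] + E7 * k7[i]);
    const double sc = atol + rtol * std::max(std::fabs(y[i]),
                                             std::fabs(ynew[i]));
    const double r = e / sc;
    err += r * r;
  }
  return std::sqrt(err / NDIM);
}

static inline bool finite_vec(const double *y) {
  for (int i = 0; i < NDIM; ++i) if (!std::isfinite(y[i])) return false;
  return true;
}

// Clip tiny negative volumes/fractions produced by round-off; count larger
// violations separately (they indicate a genuine solver problem).
static void clip_state(double *y, Stats &st) {
  for (int i = 0; i < NDIM; ++i) {
    if (y[i] < 0.0) {
      if (y[i] > -1e-14) st.nclip_soft++; else st.nclip_hard++;
      y[i] = 0.0;
    }
  }
  if (y[5] > 1.0 && y[5] < 1.0 + 1e-12) y[5] = 1.0;
  if (y[6] > 1.0 && y[6] < 1.0 + 1e-12) y[6] = 1.0;
}

// Integrate from t to t_target (within one forcing segment), recording
// nothing; y and k1 (FSAL derivative) updated in place.
static void advance(double &t, double t_target, double *y, double kcur[NDIM],
                    double &h, const Pars &p, double R, double beta,
                    double ht_on, double rtol, double atol, Stats &st) {
  double kst[8][NDIM], ynew[NDIM], k7[NDIM];
  const double tiny = 1e-10;
  while (t < t_target - tiny) {
    if (h > t_target - t) h = t_target - t;
    if (h < 1e-12) { t = t_target; break; }
    double kk[8][NDIM];
    for (int i = 0; i < NDIM; ++i) kk[1][i] = kcur[i];
    const double err = dp45_attempt(y, kk, h, ynew, k7, kst, p, R, beta,
                                    ht_on, rtol, atol);
    bool ok = std::isfinite(err) && err <= 1.0 && finite_vec(ynew);
    if (ok) {
      t += h;
      for (int i = 0; i < NDIM; ++i) y[i] = ynew[i];
      clip_state(y, st);
      // FSAL: recompute only if clipping changed the state
      rhs(y, kcur, p, R, beta, ht_on);
      st.naccept++;
      const double fac = (err == 0.0) ? 5.0
        : std::min(5.0, std::max(0.2, 0.9 * std::pow(err, -0.2)));
      h *= fac;
    } else {
      st.nreject++;
      h *= std::isfinite(err) ? std::max(0.1, 0.9 * std::pow(err, -0.2))
                              : 0.1;
      if (h < 1e-13)
        stop("integration step size underflow at t = %f", t);
    }
  }
  t = t_target;
}

//' @noRd
// [[Rcpp::export(name = ".dp45_run")]]
List dp45_run(NumericVector y0, NumericVector params,
              NumericMatrix segments, NumericVector out_times,
              double rtol, double atol) {
  // segments: columns t0, t1, R, beta, ht_on; contiguous, ordered
  const Pars p = unpack(params);
  const int nseg = segments.nrow(), nout = out_times.size();
  NumericMatrix out(nout, NDIM);
  double y[NDIM], kcur[NDIM];
  for (int i = 0; i < NDIM; ++i) y[i] = y0[i];
  Stats st;
  int iout = 0;
  double t = (nseg > 0) ? segments(0, 0) : 0.0;
  // record any output times at/before the start
  while (iout < nout && out_times[iout] <= t + 1e-10) {
    for (int i = 0; i < NDIM; ++i) out(iout, i) = y[i];
    iout++;
  }
  for (int s = 0; s < nseg; ++s) {
    const double t1 = segments(s, 1), R = segments(s, 2),
      beta = segments(s, 3), ht_on = segments(s, 4);
    rhs(y, kcur, p, R, beta, ht_on); // forcing changed: refresh FSAL
    double h = std::min(1.0, t1 - t);
    while (iout < nout && out_times[iout] <= t1 + 1e-10) {
      advance(t, std::min(out_times[iout], t1), y, kcur, h, p, R, beta,
              ht_on, rtol, atol, st);
      for (int i = 0; i < NDIM; ++i) out(iout, i) = y[i];
      iout++;
    }
    advance(t, t1, y, kcur, h, p, R, beta, ht_on, rtol, atol, st);
  }
  NumericVector yfin(NDIM);
  for (int i = 0; i < NDIM; ++i) yfin[i] = y[i];
  return List::create(
    _["states"] = out, _["y_final"] = yfin,
    _["naccept"] = (double)st.naccept, _["nreject"] = (double)st.nreject,
    _["nclip_soft"] = (double)st.nclip_soft,
    _["nclip_hard"] = (double)st.nclip_hard);
}

//' @noRd
// [[Rcpp::export(name = ".dp45_steady")]]
List dp45_steady(NumericVector y0, NumericVector params,
                 double t_max, double f_tol, double rtol, double atol) {
  // untreated relaxation: integrate with no forcing until the sup-norm of
  // the derivative drops below f_tol (checked on every accepted step)
  const Pars p = unpack(params);
  double y[NDIM], kcur[NDIM];
  for (int i = 0; i < NDIM; ++i) y[i] = y0[i];
  rhs(y, kcur, p, 0.0, 0.0, 0.0);
  Stats st;
  double t = 0.0, h = 1.0;
  bool converged = false;
  double kst[8][NDIM], ynew[NDIM], k7[NDIM];
  while (t < t_max) {
    if (h > t_max - t) h = t_max - t;
    double kk[8][NDIM];
    for (int i = 0; i < NDIM; ++i) kk[1][i] = kcur[i];
    const double err = dp45_attempt(y, kk, h, ynew, k7, kst, p, 0, 0, 0,
                                    rtol, atol);
    if (std::isfinite(err) && err <= 1.0 && finite_vec(ynew)) {
      t += h;
      for (int i = 0; i < NDIM; ++i) y[i] = ynew[i];
      clip_state(y, st);
      rhs(y, kcur, p, 0.0, 0.0, 0.0);
      st.naccept++;
      double fmax = 0.0;
      for (int i = 0; i < NDIM; ++i)
        fmax = std::max(fmax, std::fabs(kcur[i]));
      if (fmax < f_tol) { converged = true; break; }
      const double fac = (err == 0.0) ? 5.0
        : std::min(5.0, std::max(0.2, 0.9 * std::pow(err, -0.2)));
      h *= fac;
    } else {
      st.nreject++;
      h *= std::isfinite(err) ? std::max(0.1, 0.9 * std::pow(err, -0.2))
                              : 0.1;
      if (h < 1e-13) stop("steady-state step size underflow at t = %f", t);
    }
  }
  NumericVector yfin(NDIM);
  for (int i = 0; i < NDIM; ++i) yfin[i] = y[i];
  return List::create(_["y"] = yfin, _["t"] = t, _["converged"] = converged,
                      _["naccept"] = (double)st.naccept);
}
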