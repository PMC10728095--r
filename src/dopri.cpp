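#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parameter vector layout (kept in step with .par_order in R/parameters.R)
enum par_idx {
  I_ALPHA_N, I_ALPHA_M, I_K, I_DELTA_NS, I_DELTA_MS, I_DELTA_NF, I_DELTA_MF,
  I_KAPPA_0, I_KAPPA_1, I_KAPPA_2, I_DELTA_T, I_MU, I_DELTA_N, I_DELTA_M,
  I_P1, I_P2, I_ALPHA_NT, I_ALPHA_MT, I_RHO_P, I_RHO_L, I_EPS_C, I_MU_PA,
  I_K_TQ, N_PAR
};

// PD-1/PD-L1 suppression factor F in (0, 1]; F == 1 when the checkpoint is
// blocked. Q = P*L with P = rho_p*T and L = rho_l*(T + eps_c*(N+M)).
static inline double factorF(const double* p, double N, double M, double T,
                             bool blocked) {
  if (blocked) return 1.0;
  double P = p[I_RHO_P] * T;
  double L = p[I_RHO_L] * (T + p[I_EPS_C] * (N + M));
  return 1.0 / (1.0 + P * L / p[I_K_TQ]);
}

// Saturating (FasL, slow) per-capita kill rate: multi-prey Beddington-
// DeAngelis response delta_s*T/(kappa_0 + tumor + kappa_1*T), where `tumor`
// is the total tumor burden sharing the CTLs.
static inline double slow_kill(double T, double delta_s, double k0, double k1,
                               double tumor) {
  if (T <= 0.0) return 0.0;
  return delta_s * T / (k0 + tumor + k1 * T);
}

static void rhs(const double* p, double t, const double* y, double* dy,
                bool blocked, bool frozen_tumor) {
  double N = y[0] > 0.0 ? y[0] : 0.0;
  double M = y[1] > 0.0 ? y[1] : 0.0;
  double T = y[2] > 0.0 ? y[2] : 0.0;
  (void)t;

  double F = factorF(p, N, M, T, blocked);
  double crowd = 1.0 - (N + M) / p[I_K];

  double tumor = N + M;
  double killN = p[I_P1] * p[I_DELTA_NF] * T +
                 (1.0 - p[I_P1]) * slow_kill(T, p[I_DELTA_NS], p[I_KAPPA_0], p[I_KAPPA_1], tumor);
  double killM = p[I_P2] * p[I_DELTA_MF] * T +
                 (1.0 - p[I_P2]) * slow_kill(T, p[I_DELTA_MS], p[I_KAPPA_0], p[I_KAPPA_1], tumor);

  dy[0] = frozen_tumor ? 0.0 : p[I_ALPHA_N] * N * crowd - F * killN * N;
  dy[1] = frozen_tumor ? 0.0 : p[I_ALPHA_M] * M * crowd - F * killM * M;
  dy[2] = p[I_MU] +
          (p[I_ALPHA_NT] * N / (p[I_KAPPA_2] + N) +
           p[I_ALPHA_MT] * M / (p[I_KAPPA_2] + M)) * T -
          p[I_DELTA_T] * T - p[I_DELTA_N] * N * T - p[I_DELTA_M] * M * T;
}

// [[Rcpp::export]]
NumericVector rhs_cpp(NumericVector y, NumericVector par, bool blocked) {
  if (par.size() != N_PAR) stop("parameter vector has wrong length");
  double dy[3];
  rhs(REAL(par), 0.0, REAL(y), dy, blocked, false);
  return NumericVector::create(dy[0], dy[1], dy[2]);
}

// Cubic Hermite interpolation within an accepted step
static inline double hermite(double theta, double h, double y0, double y1,
                             double f0, double f1) {
  double t2 = theta * theta, t3 = t2 * theta;
  double h00 = 2 * t3 - 3 * t2 + 1, h10 = t3 - 2 * t2 + theta;
  double h01 = -2 * t3 + 3 * t2, h11 = t3 - t2;
  return h00 * y0 + h10 * h * f0 + h01 * y1 + h11 * h * f1;
}

// Dormand-Prince 5(4) with:
//  * steps clipped so every requested output time is hit exactly,
//  * terminal-style event on total tumor crossing `clamp_cells` from above:
//    N and M are frozen there (T keeps evolving),
//  * FSAL reuse and standard PI-free step control.
// [[Rcpp::export]]
List integrate_cpp(NumericVector par, NumericVector y0, bool blocked,
                   NumericVector t_out, double rtol = 1e-8, double atol = 1e-2,
                   double clamp_cells = -1.0, double max_steps = 5e6) {
  if (par.size() != N_PAR) stop("parameter vector has wrong length");
  if (y0.size() != 3) stop("state must be (N, M, T)");
  const int n_out = t_out.size();
  if (n_out < 1) stop("need at least one output time");
  const double* p = REAL(par);

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

  NumericMatrix out(n_out, 3);
  double t = t_out[0];
  double t_end = t_out[n_out - 1];
  double y[3] = {y0[0], y0[1], y0[2]};
  bool clamped = false;
  double clamped_at = NA_REAL;

  // clamp immediately if starting at/below the detection limit
  if (clamp_cells > 0 && y[0] + y[1] <= clamp_cells) {
    clamped = true;
    clamped_at = t;
    double tot = y[0] + y[1];
    if (tot > 0) { double s = clamp_cells / tot; y[0] *= s; y[1] *= s; }
    else { y[0] = clamp_cells / 2; y[1] = clamp_cells / 2; }
  }

  int i_out = 0;
  // emit output at t == t_out[0]
  out(0, 0) = y[0]; out(0, 1) = y[1]; out(0, 2) = y[2];
  i_out = 1;

  double k1[3], k2[3], k3[3], k4[3], k5[3], k6[3], k7[3], ytmp[3], ynew[3];
  rhs(p, t, y, k1, blocked, clamped);
  double h = 1e-3;
  long steps = 0;
  int status = 0; // 0 ok, 1 too many steps / step underflow

  while (i_out < n_out) {
    if (++steps > (long)max_steps) { status = 1; break; }
    double t_next = t_out[i_out];
    if (h > t_next - t) h = t_next - t;
    if (h < 1e-14 * std::max(1.0, std::fabs(t))) h = 1e-14 * std::max(1.0, std::fabs(t));

    for (int i = 0; i < 3; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
    rhs(p, t + c2 * h, ytmp, k2, blocked, clamped);
    for (int i = 0; i < 3; ++i) ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    rhs(p, t + c3 * h, ytmp, k3, blocked, clamped);
    for (int i = 0; i < 3; ++i) ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    rhs(p, t + c4 * h, ytmp, k4, blocked, clamped);
    for (int i = 0; i < 3; ++i) ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    rhs(p, t + c5 * h, ytmp, k5, blocked, clamped);
    for (int i = 0; i < 3; ++i) ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] + a64 * k4[i] + a65 * k5[i]);
    rhs(p, t + h, ytmp, k6, blocked, clamped);
    for (int i = 0; i < 3; ++i) ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] + b5 * k5[i] + b6 * k6[i]);
    rhs(p, t + h, ynew, k7, blocked, clamped);

    double err = 0.0;
    for (int i = 0; i < 3; ++i) {
      double e = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      err += (e / sc) * (e / sc);
    }
    err = std::sqrt(err / 3.0);

    if (err <= 1.0) { // accept
      double t_new = t + h;
      // event: total tumor crosses the detection limit from above
      if (clamp_cells > 0 && !clamped &&
          y[0] + y[1] > clamp_cells && ynew[0] + ynew[1] <= clamp_cells) {
        double lo = 0.0, hi = 1.0;
        for (int it = 0; it < 80; ++it) {
          double mid = 0.5 * (lo + hi);
          double Nm = hermite(mid, h, y[0], ynew[0], k1[0], k7[0]);
          double Mm = hermite(mid, h, y[1], ynew[1], k1[1], k7[1]);
          if (Nm + Mm > clamp_cells) lo = mid; else hi = mid;
        }
        double th = 0.5 * (lo + hi);
        double Ne = hermite(th, h, y[0], ynew[0], k1[0], k7[0]);
        double Me = hermite(th, h, y[1], ynew[1], k1[1], k7[1]);
        double Te = hermite(th, h, y[2], ynew[2], k1[2], k7[2]);
        double tot = Ne + Me;
        if (tot > 0) { double s = clamp_cells / tot; Ne *= s; Me *= s; }
        else { Ne = clamp_cells / 2; Me = clamp_cells / 2; }
        y[0] = Ne; y[1] = Me; y[2] = Te > 0 ? Te : 0.0;
        t = t + th * h;
        clamped = true;
        clamped_at = t;
        rhs(p, t, y, k1, blocked, clamped); // restart FSAL with frozen tumor
        h *= 0.5;
        continue;
      }
      t = t_new;
      for (int i = 0; i < 3; ++i) {
        y[i] = ynew[i] > 0.0 ? ynew[i] : 0.0;
        k1[i] = k7[i];
      }
      while (i_out < n_out && std::fabs(t - t_out[i_out]) <= 1e-12 * std::max(1.0, std::fabs(t))) {
        out(i_out, 0) = y[0]; out(i_out, 1) = y[1]; out(i_out, 2) = y[2];
        ++i_out;
      }
      double fac = err > 0 ? 0.9 * std::pow(err, -0.2) : 5.0;
      if (fac > 5.0) fac = 5.0;
      h *= fac;
      if (h > t_end - t && t_end > t) h = t_end - t;
    } else {
      double fac = 0.9 * std::pow(err, -0.2);
      if (fac < 0.2) fac = 0.2;
      h *= fac;
      if (!std::isfinite(h) || h <= 1e-14 * std::max(1.0, t)) { status = 1; break; }
    }
    if (!std::isfinite(y[0]) || !std::isfinite(y[1]) || !std::isfinite(y[2])) {
      status = 1;
      break;
    }
  }

  return List::create(_["times"] = t_out, _["states"] = out,
                      _["clamped_at"] = clamped_at, _["status"] = status,
                      _["t_last"] = t,
                      _["y_last"] = NumericVector::create(y[0], y[1], y[2]));
}
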