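// Euler-Maruyama integrator for the two-cell dialogue model.
//
// State layout (10): A1 I1 X1 Y1 Z1 A2 I2 X2 Y2 Z2.
// Parameter layout (15): tau epsilon alpha beta gamma k a0 i0 x0 k1 k2 kz
// kcext cmedia omega.  The drift is un-scaled by tau; the integrator applies
// tau to both drift and noise.
//
// Noise modes: 0 = off, 1 = "as-printed" (per-channel increment g * dW,
// amplitude tau / Omega), 2 = "chemical-langevin" (sqrt(g) * dW, amplitude
// tau / sqrt(Omega)).  Independent Gaussian channels add in variance, so the
// aggregated per-variable SD is sqrt(sum g^2) resp. sqrt(sum g); drawing one
// normal per variable is distributionally identical to summing the 19
// per-channel increments.  per_channel = true draws all 38 increments in the
// printed channel order (cell 1 channels 1..19, then cell 2) for audit runs.
//
// Draw order is fixed (A1 I1 X1 Y1 Z1 A2 I2 X2 Y2 Z2 per step, or the
// per-channel order above) so trajectories are reproducible from the R seed.
#include <Rcpp.h>
using namespace Rcpp;

static const char *VAR_NAMES[10] = {"A1", "I1", "X1", "Y1", "Z1",
                                    "A2", "I2", "X2", "Y2", "Z2"};

enum Par { TAU, EPS, ALPHA, BETA, GAMMA, K, A0, I0, X0, K1, K2, KZ,
           KCEXT, CMEDIA, OMEGA };

static inline void drift10(const double *u, const double *p, double kd,
                           double *F) {
  for (int c = 0; c < 2; c++) {
    const double A = u[5 * c], I = u[5 * c + 1], X = u[5 * c + 2],
                 Y = u[5 * c + 3], Z = u[5 * c + 4];
    const double Zo = u[5 * (1 - c) + 4];
    const double rel = p[K2] * Y / (A * A * A + 1.0);
    const double hill = p[GAMMA] * A * A / (A * A + p[K]);
    F[5 * c]     = p[A0] - p[ALPHA] * A + p[BETA] * A * A - A * A * A - A * I + A * Z;
    F[5 * c + 1] = p[EPS] * (p[I0] + hill - I);
    F[5 * c + 2] = p[X0] - p[K1] * A * A * X;
    F[5 * c + 3] = p[K1] * A * A * X - rel;
    F[5 * c + 4] = -p[KCEXT] * (Z - p[CMEDIA]) + rel - A * Z + kd * Zo - kd * Z;
  }
}

// Per-channel propensities, evaluated on the state clamped at zero.
// Channel counts per variable: A 6, I 3, X 2, Y 2, Z 6 (19 per cell).
static inline void channels19(const double *u, const double *p, double kd,
                              int cell, double g[19]) {
  double A = u[5 * cell], I = u[5 * cell + 1], X = u[5 * cell + 2],
         Y = u[5 * cell + 3], Z = u[5 * cell + 4];
  double Zo = u[5 * (1 - cell) + 4];
  if (A < 0) A = 0; if (I < 0) I = 0; if (X < 0) X = 0;
  if (Y < 0) Y = 0; if (Z < 0) Z = 0; if (Zo < 0) Zo = 0;
  const double rel = p[K2] * Y / (A * A * A + 1.0);
  const double hill = p[GAMMA] * A * A / (A * A + p[K]);
  g[0] = p[A0];            g[1] = p[ALPHA] * A;   g[2] = p[BETA] * A * A;
  g[3] = A * A * A;        g[4] = A * I;          g[5] = A * Z;
  g[6] = p[EPS] * p[I0];   g[7] = p[EPS] * hill;  g[8] = p[EPS] * I;
  g[9] = p[X0];            g[10] = p[K1] * A * A * X;
  g[11] = p[K1] * A * A * X;  g[12] = rel;
  g[13] = p[KCEXT] * Z;    g[14] = p[KCEXT] * p[CMEDIA];  g[15] = rel;
  g[16] = A * Z;           g[17] = kd * Zo;       g[18] = kd * Z;
}

static const int CH_VAR[19] = {0, 0, 0, 0, 0, 0, 1, 1, 1, 2, 2, 3, 3,
                               4, 4, 4, 4, 4, 4};

static inline double sched_eval(double t, int kind, double d0, double d1,
                                double t0, double t1,
                                const double *bt, const double *bd, int nb) {
  if (kind == 0) return d0;
  if (kind == 1) {
    if (t <= t0) return d0;
    if (t >= t1) return d1;
    return d0 + (d1 - d0) * (t - t0) / (t1 - t0);
  }
  // piecewise-linear breakpoints, constant extrapolation
  if (t <= bt[0]) return bd[0];
  if (t >= bt[nb - 1]) return bd[nb - 1];
  int i = 0;
  while (i < nb - 1 && t > bt[i + 1]) i++;
  const double w = (t - bt[i]) / (bt[i + 1] - bt[i]);
  return bd[i] + w * (bd[i + 1] - bd[i]);
}

// [[Rcpp::export(name = ".em_core")]]
List em_core(NumericVector u0, NumericVector params,
             int sched_kind, double d_start, double d_end,
             double ramp_start, double ramp_end,
             NumericVector break_times, NumericVector break_values,
             double dt, double burn_in, double total_time, int record_stride,
             int noise_mode, bool per_channel, bool mirror_noise,
             bool clamp, bool coupling_off) {
  if (u0.size() != 10) stop("state must have 10 entries");
  if (params.size() != 15) stop("parameter vector must have 15 entries");
  double u[10];
  for (int i = 0; i < 10; i++) u[i] = u0[i];
  double F[10], g1[19], g2[19];
  const double *p = REAL(params);
  const double tau = p[TAU];
  const double amp = (noise_mode == 1) ? tau / p[OMEGA]
                                       : tau / std::sqrt(p[OMEGA]);
  const double sqdt = std::sqrt(dt);
  const long nb = lround(burn_in / dt), nt = lround(total_time / dt);
  const int nrec = (int)(nt / record_stride) + 1;
  NumericMatrix rec(nrec, 10);
  NumericVector times(nrec);
  RNGScope scope;
  int ir = 0;
  for (long s = 0; s <= nb + nt; s++) {
    if (s >= nb && (s - nb) % record_stride == 0 && ir < nrec) {
      times[ir] = (s - nb) * dt;
      for (int i = 0; i < 10; i++) rec(ir, i) = u[i];
      ir++;
    }
    if (s == nb + nt) break;
    const double t = (s < nb) ? 0.0 : (s - nb) * dt;
    const double d = sched_eval(t, sched_kind, d_start, d_end, ramp_start,
                                ramp_end, REAL(break_times),
                                REAL(break_values), break_times.size());
    const double kd = coupling_off ? 0.0 : p[KZ] * std::exp(-d);
    drift10(u, p, kd, F);
    if (noise_mode == 0) {
      for (int i = 0; i < 10; i++) {
        u[i] += tau * F[i] * dt;
        if (clamp && u[i] < 0) u[i] = 0;
      }
    } else if (!per_channel) {
      channels19(u, p, kd, 0, g1);
      channels19(u, p, kd, 1, g2);
      double sd10[10] = {0};
      for (int j = 0; j < 19; j++) {
        const double q1 = (noise_mode == 1) ? g1[j] * g1[j] : g1[j];
        const double q2 = (noise_mode == 1) ? g2[j] * g2[j] : g2[j];
        sd10[CH_VAR[j]] += q1;
        sd10[5 + CH_VAR[j]] += q2;
      }
      double xi[10];
      for (int i = 0; i < 10; i++) xi[i] = norm_rand();
      if (mirror_noise)
        for (int i = 0; i < 5; i++) xi[5 + i] = xi[i];
      for (int i = 0; i < 10; i++) {
        u[i] += tau * F[i] * dt + amp * std::sqrt(sd10[i]) * sqdt * xi[i];
        if (clamp && u[i] < 0) u[i] = 0;
      }
    } else {
      channels19(u, p, kd, 0, g1);
      channels19(u, p, kd, 1, g2);
      double inc[10] = {0};
      for (int j = 0; j < 19; j++) {
        const double w1 = (noise_mode == 1) ? g1[j] : std::sqrt(g1[j]);
        inc[CH_VAR[j]] += w1 * norm_rand();
      }
      for (int j = 0; j < 19; j++) {
        const double w2 = (noise_mode == 1) ? g2[j] : std::sqrt(g2[j]);
        inc[5 + CH_VAR[j]] += w2 * norm_rand();
      }
      if (mirror_noise)
        for (int i = 0; i < 5; i++) inc[5 + i] = inc[i];
      for (int i = 0; i < 10; i++) {
        u[i] += tau * F[i] * dt + amp * inc[i] * sqdt;
        if (clamp && u[i] < 0) u[i] = 0;
      }
    }
    for (int i = 0; i < 10; i++)
      if (!R_finite(u[i]))
        stop("integration failure: non-finite %s at t = %g (step %ld)",
             VAR_NAMES[i], t + dt, s);
  }
  return List::create(_["times"] = times, _["states"] = rec);
}
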