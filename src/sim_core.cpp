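#include <Rcpp.h>
using namespace Rcpp;

// Minimal glucose-insulin plant: 6 states integrated with fixed-step RK4.
//   G   plasma glucose (mg/dL)
//   X   remote insulin action (1/min)
//   Q1  gut glucose mass, compartment 1 (mg)
//   Q2  gut glucose mass, compartment 2 (mg)
//   I1  subcutaneous insulin, compartment 1 (U)
//   I2  subcutaneous insulin, compartment 2 (U)
//
// params: p1, p2, si, f, taum, taui, v, gb, ac, phic
//
// Circadian multiplier m(t) = 1 + ac*sin(2*pi*(t/60 - phic)/24) scales both
// insulin action (X*G term) and the gut transfer rate 1/taum; t is minutes
// of absolute simulation time, phic in hours.

static inline double circ_mult(double t_min, double ac, double phic) {
  return 1.0 + ac * std::sin(2.0 * M_PI * (t_min / 60.0 - phic) / 24.0);
}

static inline void deriv(const double *s, double *ds, double t,
                         const double *p) {
  const double p1 = p[0], p2 = p[1], si = p[2], f = p[3], taum = p[4],
               taui = p[5], v = p[6], gb = p[7], ac = p[8], phic = p[9];
  const double m = circ_mult(t, ac, phic);
  const double G = s[0], X = s[1], Q1 = s[2], Q2 = s[3], I1 = s[4], I2 = s[5];
  ds[0] = -p1 * (G - gb) - m * X * G + f * m * Q2 / (taum * v);
  ds[1] = -p2 * X + p2 * si * I2 / taui;
  ds[2] = -m * Q1 / taum;
  ds[3] = m * (Q1 - Q2) / taum;
  ds[4] = -I1 / taui;
  ds[5] = (I1 - I2) / taui;
}

// [[Rcpp::export]]
NumericVector cpp_derivatives(NumericVector state, NumericVector params,
                              double t_min) {
  if (state.size() != 6) stop("state must have 6 elements");
  double ds[6];
  deriv(REAL(state), ds, t_min, REAL(params));
  NumericVector out(6);
  for (int i = 0; i < 6; ++i) out[i] = ds[i];
  return out;
}

// Integrate a segment of n_min minutes starting at absolute time t0_min.
// Impulses (meal carbs in mg added to Q1, boluses in U added to I1) fire at
// the start of the step whose time equals their offset (minutes, relative to
// t0_min). Returns the per-minute glucose trajectory (n_min + 1 values,
// including the initial state) and the final state.
// step_min is the RK4 step (default 1; used in convergence checks).
// [[Rcpp::export]]
List cpp_sim_segment(NumericVector state, NumericVector params, double t0_min,
                     int n_min, NumericVector meal_offsets_min,
                     NumericVector meal_mg, NumericVector bolus_offsets_min,
                     NumericVector bolus_u, double step_min = 1.0) {
  if (state.size() != 6) stop("state must have 6 elements");
  double s[6], k1[6], k2[6], k3[6], k4[6], tmp[6];
  for (int i = 0; i < 6; ++i) s[i] = state[i];

  int n_steps = (int)std::lround(n_min / step_min);
  NumericVector g_trace(n_min + 1);
  g_trace[0] = s[0];
  int rec_every = (int)std::lround(1.0 / step_min);

  for (int k = 0; k < n_steps; ++k) {
    double t_rel = k * step_min;
    double t = t0_min + t_rel;
    // impulses scheduled within [t_rel, t_rel + step) fire now
    for (int j = 0; j < meal_offsets_min.size(); ++j)
      if (meal_offsets_min[j] >= t_rel && meal_offsets_min[j] < t_rel + step_min)
        s[2] += meal_mg[j];
    for (int j = 0; j < bolus_offsets_min.size(); ++j)
      if (bolus_offsets_min[j] >= t_rel && bolus_offsets_min[j] < t_rel + step_min)
        s[4] += bolus_u[j];

    deriv(s, k1, t, REAL(params));
    for (int i = 0; i < 6; ++i) tmp[i] = s[i] + 0.5 * step_min * k1[i];
    deriv(tmp, k2, t + 0.5 * step_min, REAL(params));
    for (int i = 0; i < 6; ++i) tmp[i] = s[i] + 0.5 * step_min * k2[i];
    deriv(tmp, k3, t + 0.5 * step_min, REAL(params));
    for (int i = 0; i < 6; ++i) tmp[i] = s[i] + step_min * k3[i];
    deriv(tmp, k4, t + step_min, REAL(params));
    for (int i = 0; i < 6; ++i)
      s[i] += step_min / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    // states are masses/actions; numerical undershoot clipped at 0
    for (int i = 1; i < 6; ++i) if (s[i] < 0) s[i] = 0;
    if (!R_finite(s[0]))
      stop("non-finite glucose state at t = %f min", t + step_min);
    if ((k + 1) % rec_every == 0) g_trace[(k + 1) / rec_every] = s[0];
  }

  NumericVector fin(6);
  for (int i = 0; i < 6; ++i) fin[i] = s[i];
  return List::create(_["g"] = g_trace, _["state"] = fin);
}

// Standard online SOM on a rectangular grid with Gaussian neighbourhood and
// exponentially decaying learning rate / radius. W0 is the (rows*cols) x d
// initial weight matrix (row-major over grid: unit k = row*cols + col,
// 0-based); order0 holds 0-based sample indices, one per update step.
// [[Rcpp::export]]
NumericMatrix cpp_som_train(NumericMatrix X, int grid_rows, int grid_cols,
                            IntegerVector order0, double lr0, double lr1,
                            double r0, double r1, NumericMatrix W0) {
  const int d = X.ncol(), n_units = grid_rows * grid_cols;
  if (W0.nrow() != n_units || W0.ncol() != d) stop("W0 dimension mismatch");
  NumericMatrix W = clone(W0);
  const R_xlen_t T = order0.size();

  for (R_xlen_t t = 0; t < T; ++t) {
    const double frac = (T > 1) ? (double)t / (double)(T - 1) : 0.0;
    const double lr = lr0 * std::pow(lr1 / lr0, frac);
    const double rad = r0 * std::pow(r1 / r0, frac);
    const int i = order0[t];
    // BMU: ties broken by smallest (row, col) lexicographic = smallest k
    int bmu = 0;
    double best = R_PosInf;
    for (int k = 0; k < n_units; ++k) {
      double dist = 0.0;
      for (int j = 0; j < d; ++j) {
        const double diff = W(k, j) - X(i, j);
        dist += diff * diff;
      }
      if (dist < best) { best = dist; bmu = k; }
    }
    const int br = bmu / grid_cols, bc = bmu % grid_cols;
    const double two_r2 = 2.0 * rad * rad;
    for (int k = 0; k < n_units; ++k) {
      const int kr = k / grid_cols, kc = k % grid_cols;
      const double g2 = (double)((kr - br) * (kr - br) + (kc - bc) * (kc - bc));
      const double h = std::exp(-g2 / two_r2);
      if (h < 1e-12) continue;
      const double step = lr * h;
      for (int j = 0; j < d; ++j) W(k, j) += step * (X(i, j) - W(k, j));
    }
  }
  return W;
}
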