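#include <Rcpp.h>
using namespace Rcpp;

// Five-dimensional Epileptor neural-mass model plus the auxiliary
// low-pass variable g that realises the exponentially weighted
// integral of x1 feeding the spike-wave subsystem.
//
// State layout: [x1, y1, z, x2, y2, g]
// Parameter layout: [x0, y0, tau0, tau2, I1, I2, gamma]

static inline void epileptor_rhs(const double *s, const double *p,
                                 double istim1, double istim2, double *ds) {
  const double x1 = s[0], y1 = s[1], z = s[2];
  const double x2 = s[3], y2 = s[4], g = s[5];
  const double x0 = p[0], y0 = p[1], tau0 = p[2], tau2 = p[3];
  const double I1 = p[4] + istim1, I2 = p[5] + istim2, gamma = p[6];

  double f1;
  if (x1 < 0.0) {
    f1 = x1 * x1 * x1 - 3.0 * x1 * x1;
  } else {
    const double zm4 = z - 4.0;
    f1 = (x2 - 0.6 * zm4 * zm4) * x1;
  }
  const double f2 = (x2 < -0.25) ? 0.0 : 6.0 * (x2 + 0.25);

  ds[0] = y1 - f1 - z + I1;
  ds[1] = y0 - 5.0 * x1 * x1 - y1;
  ds[2] = (4.0 * (x1 - x0) - z) / tau0;
  ds[3] = -y2 + x2 - x2 * x2 * x2 + I2 + 0.002 * g - 0.3 * (z - 3.5);
  ds[4] = (-y2 + f2) / tau2;
  ds[5] = x1 - gamma * g;
}

// [[Rcpp::export]]
NumericVector epileptor_rhs_cpp(NumericVector state, NumericVector pars,
                                double istim1, double istim2) {
  if (state.size() != 6) stop("state must have 6 components");
  NumericVector out(6);
  epileptor_rhs(state.begin(), pars.begin(), istim1, istim2, out.begin());
  return out;
}

// One classical RK4 step of the drift.
static inline void rk4_step(double *s, const double *p, double dt,
                            double istim1, double istim2) {
  double k1[6], k2[6], k3[6], k4[6], tmp[6];
  epileptor_rhs(s, p, istim1, istim2, k1);
  for (int i = 0; i < 6; ++i) tmp[i] = s[i] + 0.5 * dt * k1[i];
  epileptor_rhs(tmp, p, istim1, istim2, k2);
  for (int i = 0; i < 6; ++i) tmp[i] = s[i] + 0.5 * dt * k2[i];
  epileptor_rhs(tmp, p, istim1, istim2, k3);
  for (int i = 0; i < 6; ++i) tmp[i] = s[i] + dt * k3[i];
  epileptor_rhs(tmp, p, istim1, istim2, k4);
  for (int i = 0; i < 6; ++i)
    s[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// One stochastic Heun (predictor-corrector) drift step; additive noise
// is injected by the caller so the same noise enters predictor and
// corrector implicitly through the increment formulation.
static inline void heun_step(double *s, const double *p, double dt,
                             double istim1, double istim2,
                             const double *noise) {
  double k1[6], k2[6], pred[6];
  epileptor_rhs(s, p, istim1, istim2, k1);
  for (int i = 0; i < 6; ++i) pred[i] = s[i] + dt * k1[i] + noise[i];
  epileptor_rhs(pred, p, istim1, istim2, k2);
  for (int i = 0; i < 6; ++i)
    s[i] += 0.5 * dt * (k1[i] + k2[i]) + noise[i];
}

// Fixed-step integrator.
//
// scheme: 0 = deterministic RK4;
//         1 = RK4 drift + additive Gaussian increments (the default
//             stochastic scheme; collapses exactly onto RK4 when all
//             noise variances are zero);
//         2 = stochastic Heun;
//         3 = Euler-Maruyama (cross-check backend).
//
// Stimulation: pulse onsets given in internal steps; each pulse adds
// (amp1, amp2) to (I1, I2) for `pulse_steps` internal steps.
//
// Noise variances are per unit model time: per-step increments are
// N(0, var * dt). RNG is R's, so set.seed() upstream fixes the path.
// [[Rcpp::export]]
List epileptor_integrate_cpp(NumericVector state0, NumericVector pars,
                             double dt, double n_steps_d, int thin,
                             IntegerVector stim_onsets, int pulse_steps,
                             double amp1, double amp2,
                             NumericVector noise_var, int scheme,
                             double blowup = 1e6) {
  const R_xlen_t n_steps = (R_xlen_t)n_steps_d;
  if (state0.size() != 6) stop("state0 must have 6 components");
  if (n_steps < 1) stop("n_steps must be >= 1");
  if (thin < 1) stop("thin must be >= 1");

  double s[6];
  for (int i = 0; i < 6; ++i) s[i] = state0[i];
  const double *p = pars.begin();

  // per-step noise standard deviations on x1, x2, y2 (state idx 0, 3, 4)
  const double sd1 = std::sqrt(noise_var[0] * dt);
  const double sd2 = std::sqrt(noise_var[1] * dt);
  const double sd3 = std::sqrt(noise_var[2] * dt);
  const bool noisy = (scheme != 0) && (sd1 > 0 || sd2 > 0 || sd3 > 0);

  const R_xlen_t n_out = n_steps / thin;
  NumericMatrix traj(n_out, 6);
  NumericVector t_out(n_out);
  IntegerVector stim_out(n_out);

  // active-pulse bookkeeping
  R_xlen_t next_pulse = 0;
  R_xlen_t pulse_remaining = 0;
  const R_xlen_t n_pulse = stim_onsets.size();

  RNGScope rng;
  double noise[6] = {0, 0, 0, 0, 0, 0};

  for (R_xlen_t step = 0; step < n_steps; ++step) {
    while (next_pulse < n_pulse && stim_onsets[next_pulse] == (int)step) {
      pulse_remaining = pulse_steps;
      ++next_pulse;
    }
    const bool on = pulse_remaining > 0;
    const double i1 = on ? amp1 : 0.0, i2 = on ? amp2 : 0.0;
    if (on) --pulse_remaining;

    if (noisy) {
      noise[0] = sd1 > 0 ? R::rnorm(0.0, sd1) : 0.0;
      noise[3] = sd2 > 0 ? R::rnorm(0.0, sd2) : 0.0;
      noise[4] = sd3 > 0 ? R::rnorm(0.0, sd3) : 0.0;
    }

    switch (scheme) {
    case 0:
      rk4_step(s, p, dt, i1, i2);
      break;
    case 1:
      rk4_step(s, p, dt, i1, i2);
      if (noisy) { s[0] += noise[0]; s[3] += noise[3]; s[4] += noise[4]; }
      break;
    case 2:
      heun_step(s, p, dt, i1, i2, noise);
      break;
    case 3: {
      double ds[6];
      epileptor_rhs(s, p, i1, i2, ds);
      for (int i = 0; i < 6; ++i) s[i] += dt * ds[i] + noise[i];
      break;
    }
    default:
      stop("unknown scheme");
    }

    for (int i = 0; i < 6; ++i) {
      if (!std::isfinite(s[i]) || std::fabs(s[i]) > blowup)
        stop("state blow-up at internal step %d (|state| > %g)",
             (int)(step + 1), blowup);
    }

    if ((step + 1) % thin == 0) {
      const R_xlen_t row = (step + 1) / thin - 1;
      for (int i = 0; i < 6; ++i) traj(row, i) = s[i];
      t_out[row] = (step + 1) * dt;
      stim_out[row] = on ? 1 : 0;
    }
  }

  colnames(traj) = CharacterVector::create("x1", "y1", "z", "x2", "y2", "g");
  return List::create(_["time"] = t_out, _["states"] = traj,
                      _["stim"] = stim_out);
}

// AR(1) background generator used by the synthetic-recordings module;
// written here because sessions are minutes of multi-channel signal at
// 2 kHz and the recursion is the hot loop.
// [[Rcpp::export]]
NumericVector ar1_noise_cpp(double n_d, double phi, double innov_sd) {
  const R_xlen_t n = (R_xlen_t)n_d;
  NumericVector out(n);
  RNGScope rng;
  // start from the stationary distribution
  const double stat_sd = innov_sd / std::sqrt(1.0 - phi * phi);
  double x = R::rnorm(0.0, stat_sd);
  for (R_xlen_t i = 0; i < n; ++i) {
    x = phi * x + R::rnorm(0.0, innov_sd);
    out[i] = x;
  }
  return out;
}
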