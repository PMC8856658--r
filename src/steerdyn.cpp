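#include <Rcpp.h>
using namespace Rcpp;

// Discrete-time conventions shared with the R reference implementations
// (simulate_dynamics(), integrate_pose()):
//   v[i]   = alpha * v[i-1] + beta * u[i],  v[0] = 0 (before the first input)
//   head_i = head_{i-1} + w[i] * dt
//   pos_i  = pos_{i-1} + v[i] * (cos, sin)(head_{i-1} + w[i] * dt / 2) * dt
// The midpoint heading makes the arc error second order in dt.

static inline double clip1(double x) {
  return x > 1.0 ? 1.0 : (x < -1.0 ? -1.0 : x);
}

static inline double wrap_pi(double a) {
  while (a > M_PI) a -= 2.0 * M_PI;
  while (a < -M_PI) a += 2.0 * M_PI;
  return a;
}

// Re-integrate each trial's joystick trace under per-trial filter
// coefficients and input gains; return the endpoint of every trajectory.
// The recorded trace ends when the ORIGINAL trial's speed fell below the
// stopping threshold; under different dynamics the velocity at trace end
// is generally nonzero, so (with coast_steps > 0) the input is extended
// with zeros — hands off the joystick — until the simulated speed also
// drops below v_stop or the cap is reached.
// [[Rcpp::export]]
NumericMatrix cpp_reintegrate(List u_v, List u_w,
                              NumericVector alpha,
                              NumericVector beta_v, NumericVector beta_w,
                              double dt, double v_stop = 0.0,
                              int coast_steps = 0) {
  int n = u_v.size();
  NumericMatrix out(n, 4);  // x, y, r, theta
  for (int j = 0; j < n; ++j) {
    NumericVector uv = u_v[j];
    NumericVector uw = u_w[j];
    double a = alpha[j], bv = beta_v[j], bw = beta_w[j];
    double v = 0.0, w = 0.0, x = 0.0, y = 0.0, h = 0.0;
    int m = uv.size();
    for (int i = 0; i < m + coast_steps; ++i) {
      if (i >= m && std::fabs(v) < v_stop) break;
      v = a * v + (i < m ? bv * uv[i] : 0.0);
      w = a * w + (i < m ? bw * uw[i] : 0.0);
      double hm = h + 0.5 * w * dt;
      x += v * std::cos(hm) * dt;
      y += v * std::sin(hm) * dt;
      h += w * dt;
    }
    out(j, 0) = x;
    out(j, 1) = y;
    out(j, 2) = std::sqrt(x * x + y * y);
    out(j, 3) = std::atan2(y, x);
  }
  return out;
}

// Believed stopping distance under a full-brake rollout of the discrete
// believed dynamics from linear speed v (1-D; matches the propagation
// recursion exactly).
static double brake_rollout(double v, double alpha, double beta,
                            double dt, double v_stop, int cap) {
  double x = 0.0;
  for (int i = 0; i < cap && v > v_stop; ++i) {
    v = alpha * v - beta;
    x += v * dt;
  }
  return x;
}

// One synthetic-agent trial. The agent steers in belief space: it integrates
// its own (noisy, clipped) joystick output under the dynamics implied by its
// internal time-constant estimate, while the actual trajectory integrates
// the same output under the true dynamics. Two-phase linear policy:
// full forward input until the believed distance to the (gain-scaled) aim
// point falls below the believed full-brake stopping distance (an exact
// discrete rollout of the believed dynamics, screened by the cheap
// continuous-time closed form
//   d_brake(v) = tau_bel * (v - vmax_bel * log(1 + v / vmax_bel)) ),
// then full backward input until the believed speed drops below v_stop,
// then hands off. Angular channel: u_w = clip(k_ang * believed bearing
// error), gated off within ang_deadband of the aim point and after the
// believed stop. The trial ends when the actual speed falls below v_stop
// after the believed stop, or at the hard timeout; under fast dynamics a
// target at the extreme of the bearing fan can exceed the plant's capture
// geometry (full-speed turn radius ~2.5 m), leaving the agent circling
// until the timeout — such trials are flagged, not dropped.
// [[Rcpp::export]]
List cpp_agent_trial(double aim_x, double aim_y,
                     double alpha_tr, double beta_v_tr, double beta_w_tr,
                     double alpha_bl, double beta_v_bl, double beta_w_bl,
                     double vmax_bl, double tau_bl,
                     double dt, double v_stop, double k_ang,
                     double ang_deadband,
                     NumericVector noise_v, NumericVector noise_w) {
  int n_max = noise_v.size();
  NumericVector uv(n_max), uw(n_max), v(n_max), w(n_max),
      x(n_max), y(n_max), heading(n_max),
      bx_out(n_max), by_out(n_max);
  double va = 0.0, wa = 0.0, xa = 0.0, ya = 0.0, ha = 0.0;   // actual
  double vb = 0.0, wb = 0.0, xb = 0.0, yb = 0.0, hb = 0.0;   // believed
  int phase = 1;          // 1 forward, 2 brake, 3 hands off
  int stop_index = n_max; // 1-based length of the realised trial
  bool timed_out = true;
  int brake_index = NA_INTEGER;

  for (int i = 0; i < n_max; ++i) {
    double uvc = 0.0, uwc = 0.0;
    if (phase < 3) {
      double dx = aim_x - xb, dy = aim_y - yb;
      double dist = std::sqrt(dx * dx + dy * dy);
      double berr = wrap_pi(std::atan2(dy, dx) - hb);
      uwc = (dist < ang_deadband) ? 0.0 : clip1(k_ang * berr);
      if (phase == 1) {
        double vpos = vb > 0.0 ? vb : 0.0;
        double d_cont = tau_bl * (vpos - vmax_bl * std::log1p(vpos / vmax_bl));
        if (dist <= d_cont + 0.5 &&
            dist <= brake_rollout(vpos, alpha_bl, beta_v_bl, dt, v_stop, n_max)) {
          phase = 2;
          brake_index = i + 1;
        }
      }
      if (phase == 2 && vb <= v_stop) {
        phase = 3;
        uwc = 0.0;
      }
      if (phase < 3) {
        uvc = (phase == 1) ? 1.0 : -1.0;
        uvc = clip1(uvc + noise_v[i]);
        uwc = clip1(uwc + noise_w[i]);
      }
    }
    // believed propagation
    vb = alpha_bl * vb + beta_v_bl * uvc;
    wb = alpha_bl * wb + beta_w_bl * uwc;
    double hmb = hb + 0.5 * wb * dt;
    xb += vb * std::cos(hmb) * dt;
    yb += vb * std::sin(hmb) * dt;
    hb += wb * dt;
    // actual propagation
    va = alpha_tr * va + beta_v_tr * uvc;
    wa = alpha_tr * wa + beta_w_tr * uwc;
    double hma = ha + 0.5 * wa * dt;
    xa += va * std::cos(hma) * dt;
    ya += va * std::sin(hma) * dt;
    ha += wa * dt;

    uv[i] = uvc; uw[i] = uwc;
    v[i] = va; w[i] = wa; x[i] = xa; y[i] = ya; heading[i] = ha;
    bx_out[i] = xb; by_out[i] = yb;

    if (phase == 3 && std::fabs(va) < v_stop) {
      stop_index = i + 1;
      timed_out = false;
      break;
    }
  }
  int k = stop_index;
  return List::create(
      _["u_v"] = uv[Range(0, k - 1)], _["u_w"] = uw[Range(0, k - 1)],
      _["v"] = v[Range(0, k - 1)], _["w"] = w[Range(0, k - 1)],
      _["x"] = x[Range(0, k - 1)], _["y"] = y[Range(0, k - 1)],
      _["heading"] = heading[Range(0, k - 1)],
      _["bel_x"] = bx_out[Range(0, k - 1)], _["bel_y"] = by_out[Range(0, k - 1)],
      _["stop_index"] = stop_index,
      _["brake_index"] = brake_index,
      _["timed_out"] = timed_out);
}

// Sensory-feedback (switch-distance) rollout for one trial: keep the actual
// angular input, replace the linear input with +1 until the simulated
// distance to the aim point first drops below d_switch, then -1 until the
// speed falls below v_stop. Trials that never approach within d_switch are
// stopped at their closest approach and flagged.
// [[Rcpp::export]]
List cpp_switch_rollout(NumericVector u_w_trace,
                        double alpha, double beta_v, double beta_w,
                        double dt, double v_stop,
                        double aim_x, double aim_y,
                        double d_switch, int n_max) {
  double v = 0.0, w = 0.0, x = 0.0, y = 0.0, h = 0.0;
  bool braking = false;
  double best_d = R_PosInf, best_x = 0.0, best_y = 0.0;
  int m = u_w_trace.size();
  bool reached = false;
  double sx = 0.0, sy = 0.0;
  for (int i = 0; i < n_max; ++i) {
    double dx = aim_x - x, dy = aim_y - y;
    double dist = std::sqrt(dx * dx + dy * dy);
    if (dist < best_d) { best_d = dist; best_x = x; best_y = y; }
    if (!braking && dist < d_switch) braking = true;
    double uv = braking ? -1.0 : 1.0;
    double uw = (i < m) ? u_w_trace[i] : 0.0;
    v = alpha * v + beta_v * uv;
    w = alpha * w + beta_w * uw;
    double hm = h + 0.5 * w * dt;
    x += v * std::cos(hm) * dt;
    y += v * std::sin(hm) * dt;
    h += w * dt;
    if (braking && v < v_stop) {
      reached = true;
      sx = x; sy = y;
      break;
    }
  }
  if (!reached) { sx = best_x; sy = best_y; }
  return List::create(_["stop_x"] = sx, _["stop_y"] = sy,
                      _["reached"] = reached);
}
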