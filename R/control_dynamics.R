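# Joystick-to-velocity control dynamics: a first-order leaky integrator
# whose gains are calibrated so that a nominal target displacement is
# reachable in a nominal time regardless of the time constant.

#' Simulation configuration
#'
#' Bundles the constants of the steering simulation: the integration step,
#' the nominal trial duration used for gain calibration, the calibration
#' displacements, and the stopping-speed threshold below which a trial is
#' considered ended.
#'
#' @param dt Time step in seconds. The simulation runs at the visual update
#'   rate, 60 Hz, by default.
#' @param T_nominal Nominal trial duration in seconds used in the gain
#'   calibration (default 8.5 s).
#' @param x_cal Calibration linear displacement in metres (default 4 m, the
#'   mean target distance).
#' @param theta_cal Calibration angular displacement in radians: the angle a
#'   full-time angular bang-bang manoeuvre covers in `T_nominal`. Default
#'   `pi/2`, chosen so that the whole fan of targets (bearings up to 38
#'   degrees, requiring heading changes up to twice that along a smooth
#'   approach path) is reachable at every time constant in the sampling
#'   range; see the package vignette.
#' @param v_stop Stopping-speed threshold in m/s (default 0.01, i.e. 1 cm/s).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 1 / 60, T_nominal = 8.5, x_cal = 4,
                       theta_cal = pi / 2, v_stop = 0.01) {
  stopifnot(dt > 0, T_nominal > 0, x_cal > 0, theta_cal > 0, v_stop > 0)
  structure(list(dt = dt, T_nominal = T_nominal, x_cal = x_cal,
                 theta_cal = theta_cal, v_stop = v_stop),
            class = "sim_config")
}

# log(cosh(z)), stable for |z| up to and beyond 700 where cosh overflows:
# log cosh z = |z| + log1p(exp(-2|z|)) - log 2
log_cosh <- function(z) {
  az <- abs(z)
  az + log1p(exp(-2 * az)) - log(2)
}

#' Per-trial dynamics parameters from a time constant
#'
#' Computes the discrete-time filter coefficient and the input gains of the
#' leaky integrator for a given time constant `tau`, with maximum speeds
#' calibrated so that a bang-bang manoeuvre covers the calibration
#' displacement in the nominal time:
#' \deqn{\alpha = e^{-\Delta t/\tau}, \quad
#'       v_{max}(\tau) = \frac{x}{2\tau}\,\frac{1}{\log\cosh(T/2\tau)},
#'       \quad \beta_v = v_{max}(1-\alpha)}
#' and analogously for the angular channel with the angular calibration
#' displacement.
#'
#' @param tau Time constant in seconds (positive).
#' @param cfg A [sim_config()].
#' @return An object of class `dynamics_params` with fields `tau`, `alpha`,
#'   `beta_v`, `beta_w`, `vmax`, `wmax`.
#' @examples
#' p <- make_dynamics(0.6, sim_config())
#' p$alpha  # exp(-1/36)
#' @export
make_dynamics <- function(tau, cfg = sim_config()) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("'tau' must be a single positive number")
  alpha <- exp(-cfg$dt / tau)
  lc <- log_cosh(cfg$T_nominal / (2 * tau))
  vmax <- cfg$x_cal / (2 * tau) / lc
  wmax <- cfg$theta_cal / (2 * tau) / lc
  structure(list(tau = tau, alpha = alpha,
                 beta_v = vmax * (1 - alpha), beta_w = wmax * (1 - alpha),
                 vmax = vmax, wmax = wmax),
            class = "dynamics_params")
}

#' Bang-bang switching time
#'
#' Time at which a full-positive-then-full-negative control input must switch
#' sign so that velocity returns to zero exactly at the nominal duration
#' `T`: \deqn{s = \tau \log\frac{1 + e^{T/\tau}}{2}.}
#' The switch time does not depend on the maximum speed. Evaluated in a
#' log-sum-exp form, stable for `T/tau` up to at least 1e3.
#'
#' @param tau Time constant in seconds.
#' @param T_nominal Nominal duration in seconds.
#' @return Switch time in seconds, strictly between 0 and `T_nominal`.
#' @export
switching_time <- function(tau, T_nominal) {
  stopifnot(all(tau > 0), all(T_nominal > 0))
  # tau * log((1 + e^{T/tau})/2) = T + tau * (log1p(e^{-T/tau}) - log 2)
  T_nominal + tau * (log1p(exp(-T_nominal / tau)) - log(2))
}

#' Continuous-time bang-bang velocity profile
#'
#' The closed-form solution of the leaky integrator under maximal positive
#' input until the switch time `s` and maximal negative input afterwards:
#' \deqn{v(t)/v_{max} = 1 - e^{-t/\tau} \;(t \le s), \qquad
#'       v(t)/v_{max} = -1 + (2 - e^{-s/\tau})\, e^{-(t-s)/\tau} \;(t > s).}
#' The displacement accumulated by `T` equals
#' \eqn{2 \tau v_{max} \log\cosh(T/2\tau)}.
#'
#' @param tau Time constant in seconds.
#' @param T_nominal Nominal duration in seconds.
#' @param vmax Maximum linear speed in m/s; default is the calibrated value
#'   from [make_dynamics()] with `x_cal = 4`, `T = T_nominal`.
#' @param cfg Optional [sim_config()] supplying the calibration constants
#'   when `vmax` is missing.
#' @return A list with `velocity` (a vectorised function of time in
#'   seconds), `s_switch`, `displacement` (closed-form displacement at
#'   `T_nominal`) and `vmax`.
#' @export
bang_bang_profile <- function(tau, T_nominal, vmax = NULL,
                              cfg = sim_config(T_nominal = T_nominal)) {
  stopifnot(tau > 0, T_nominal > 0)
  if (is.null(vmax)) vmax <- make_dynamics(tau, cfg)$vmax
  stopifnot(vmax > 0)
  s <- switching_time(tau, T_nominal)
  coef2 <- 2 - exp(-s / tau)
  velocity <- function(t) {
    up <- vmax * (1 - exp(-t / tau))
    down <- vmax * (-1 + coef2 * exp(-(t - s) / tau))
    ifelse(t <= s, up, down) * (t >= 0)
  }
  list(velocity = velocity, s_switch = s,
       displacement = 2 * tau * vmax * log_cosh(T_nominal / (2 * tau)),
       vmax = vmax)
}

#' Discrete leaky-integrator simulation
#'
#' Applies the exact discrete recursion
#' \eqn{v_i = \alpha v_{i-1} + \beta_v u^v_i} (and the angular analogue)
#' to a joystick trace, starting from rest. Samples outside `[-1, 1]` are
#' clipped to the hardware bound with a warning.
#'
#' @param u_v,u_w Numeric vectors of equal length: linear and angular
#'   joystick input, dimensionless in `[-1, 1]`.
#' @param params A `dynamics_params` object from [make_dynamics()].
#' @return A list with numeric vectors `v` (m/s) and `w` (rad/s), where the
#'   i-th element is the velocity after input sample i has acted.
#' @export
simulate_dynamics <- function(u_v, u_w, params) {
  stopifnot(inherits(params, "dynamics_params"), length(u_v) == length(u_w))
  if (any(abs(u_v) > 1) || any(abs(u_w) > 1)) {
    warning("joystick input outside [-1, 1]; clipping to the hardware bound")
    u_v <- pmin(pmax(u_v, -1), 1)
    u_w <- pmin(pmax(u_w, -1), 1)
  }
  v <- as.numeric(stats::filter(params$beta_v * u_v, params$alpha,
                                method = "recursive"))
  w <- as.numeric(stats::filter(params$beta_w * u_w, params$alpha,
                                method = "recursive"))
  list(v = v, w = w)
}

#' Integrate planar pose from velocities
#'
#' Unicycle kinematics from the origin facing +x, with a midpoint-heading
#' position update (second-order accurate for circular arcs):
#' \eqn{h_i = h_{i-1} + w_i \Delta t}, and the position advances along the
#' heading evaluated at the midpoint of the step.
#'
#' @param v Linear velocity in m/s.
#' @param w Angular velocity in rad/s (same length as `v`).
#' @param dt Time step in seconds.
#' @return A data.frame with columns `t`, `v`, `w`, `heading`, `x`, `y`,
#'   giving the pose after each step.
#' @export
integrate_pose <- function(v, w, dt) {
  stopifnot(length(v) == length(w), dt > 0)
  n <- length(v)
  heading <- cumsum(w) * dt
  h_prev <- c(0, heading[-n])
  h_mid <- h_prev + 0.5 * w * dt
  x <- cumsum(v * cos(h_mid)) * dt
  y <- cumsum(v * sin(h_mid)) * dt
  data.frame(t = seq_len(n) * dt, v = v, w = w, heading = heading,
             x = x, y = y)
}

# Cartesian endpoint -> polar (distance from origin, signed bearing).
cart2polar <- function(x, y) {
  list(r = sqrt(x^2 + y^2), theta = atan2(y, x))
}

polar2cart <- function(r, theta) {
  list(x = r * cos(theta), y = r * sin(theta))
}
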