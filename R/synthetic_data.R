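# Synthetic sessions: targets, interleaved sensory conditions, a single
# time-constant walk spanning all trials, and steering produced by an agent
# whose internal estimate of the time constant is shrunk toward a prior.

#' Sample target positions
#'
#' Targets are uniform over radial distance 2.5--5.5 m and signed bearing
#' +/-38 degrees, independent across trials (so the mean target distance is
#' 4 m and the mean absolute bearing 19 degrees).
#'
#' @param n Number of targets.
#' @param seed Optional integer seed.
#' @param r_range Radial range in metres.
#' @param theta_max Maximum absolute bearing in radians.
#' @return A data.frame with columns `r` (m) and `theta` (rad).
#' @export
sample_targets <- function(n, seed = NULL, r_range = c(2.5, 5.5),
                           theta_max = 38 * pi / 180) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  data.frame(r = runif(n, r_range[1], r_range[2]),
             theta = runif(n, -theta_max, theta_max))
}

#' Synthetic-agent parameters
#'
#' The agent's internal time-constant estimate on each trial is the
#' closed-form log-space posterior [posterior_tau()] with prior mean
#' `mu_prior` and prior-to-likelihood width ratio `lambda`, plus Gaussian
#' trial-wise jitter on \eqn{\hat\phi} standing in for unmeasurable belief
#' fluctuations. Condition defaults for `lambda` (vestibular 0.3, visual
#' 1.0, combined 0.8) follow the regime in which the three sensory
#' conditions were fitted; `mu_prior` defaults to the marginal mean of the
#' time-constant walk. Intended response gains below one give the generated
#' behaviour a realistic undershooting bias for the analysis stage to
#' estimate.
#'
#' @param condition One of `"vestibular"`, `"visual"`, `"combined"`.
#' @param lambda Prior/likelihood SD ratio (>= 0; `Inf` gives veridical
#'   estimates). Default depends on `condition`.
#' @param mu_prior Prior mean in log-seconds; default `walk_params()$mu_phi`.
#' @param motor_noise_sd SD of i.i.d. Gaussian motor noise added to both
#'   joystick channels before clipping (dimensionless; default 0.05).
#' @param belief_jitter_sd SD (log-s) of trial-wise jitter on the internal
#'   log time-constant estimate (default 0.1).
#' @param target_gain_r,target_gain_theta Intended response gains the agent
#'   aims for (defaults 0.85 and 0.95).
#' @param k_ang Proportional gain of the angular steering channel
#'   (dimensionless, default 2).
#' @param ang_deadband Believed distance (m) below which angular steering is
#'   gated off to avoid bearing flapping at the goal (default 0.1 m).
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(condition = c("vestibular", "visual", "combined"),
                         lambda = NULL, mu_prior = NULL,
                         motor_noise_sd = 0.05, belief_jitter_sd = 0.1,
                         target_gain_r = 0.85, target_gain_theta = 0.95,
                         k_ang = 2, ang_deadband = 0.1) {
  condition <- match.arg(condition)
  if (is.null(lambda))
    lambda <- c(vestibular = 0.3, visual = 1.0, combined = 0.8)[[condition]]
  if (is.null(mu_prior)) mu_prior <- walk_params()$mu_phi
  stopifnot(lambda >= 0, motor_noise_sd >= 0, belief_jitter_sd >= 0,
            target_gain_r > 0, target_gain_theta > 0, k_ang > 0)
  structure(list(condition = condition, lambda = lambda, mu_prior = mu_prior,
                 motor_noise_sd = motor_noise_sd,
                 belief_jitter_sd = belief_jitter_sd,
                 target_gain_r = target_gain_r,
                 target_gain_theta = target_gain_theta,
                 k_ang = k_ang, ang_deadband = ang_deadband),
            class = "agent_params")
}

#' Simulate one synthetic-agent trial
#'
#' Draws the agent's internal time-constant estimate
#' \eqn{\hat\tau = \exp(\hat\phi)} from the shrunk posterior plus belief
#' jitter, then runs the two-phase belief-space steering policy: the agent
#' integrates its own (noisy, clipped) joystick output under the dynamics it
#' believes in, applies full forward input until the believed distance to
#' the gain-scaled target drops below the believed full-brake stopping
#' distance, brakes until its believed speed falls below the stopping
#' threshold, and then hands off. The actual trajectory integrates the same
#' joystick output under the true dynamics; the trial ends when the actual
#' speed falls below the threshold, or is flagged at a hard timeout of
#' `timeout_factor * T_nominal`.
#'
#' @param target A one-row data.frame (or list) with `r` (m) and `theta`
#'   (rad).
#' @param tau True time constant of the trial in seconds.
#' @param agent An [agent_params()] object.
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed (otherwise the current RNG stream is
#'   used).
#' @param timeout_factor Hard timeout in units of `T_nominal` (default 4).
#' @return A list with `summary` (one-row data.frame: condition, `tau`,
#'   `tau_hat_gen`, target and stop coordinates, `timed_out`) and `trace`
#'   (data.frame of the realised time series `t, u_v, u_w, v, w, x, y,
#'   heading`).
#' @export
simulate_agent_trial <- function(target, tau, agent, cfg = sim_config(),
                                 seed = NULL, timeout_factor = 4) {
  stopifnot(inherits(agent, "agent_params"), tau > 0)
  if (!is.null(seed)) set.seed(seed)
  phi_hat <- if (is.infinite(agent$lambda)) log(tau) else
    (agent$lambda^2 * log(tau) + agent$mu_prior) / (agent$lambda^2 + 1)
  if (agent$belief_jitter_sd > 0)
    phi_hat <- phi_hat + rnorm(1, 0, agent$belief_jitter_sd)
  tau_hat <- exp(phi_hat)

  p_true <- make_dynamics(tau, cfg)
  p_bel <- make_dynamics(tau_hat, cfg)
  aim <- polar2cart(agent$target_gain_r * target$r,
                    agent$target_gain_theta * target$theta)
  n_max <- as.integer(round(timeout_factor * cfg$T_nominal / cfg$dt))
  if (agent$motor_noise_sd > 0) {
    noise_v <- rnorm(n_max, 0, agent$motor_noise_sd)
    noise_w <- rnorm(n_max, 0, agent$motor_noise_sd)
  } else {
    noise_v <- noise_w <- numeric(n_max)
  }
  tr <- cpp_agent_trial(aim$x, aim$y,
                        p_true$alpha, p_true$beta_v, p_true$beta_w,
                        p_bel$alpha, p_bel$beta_v, p_bel$beta_w,
                        p_bel$vmax, tau_hat,
                        cfg$dt, cfg$v_stop, agent$k_ang, agent$ang_deadband,
                        noise_v, noise_w)
  k <- tr$stop_index
  stop_pol <- cart2polar(tr$x[k], tr$y[k])
  list(
    summary = data.frame(
      condition = agent$condition, tau = tau, tau_hat_gen = tau_hat,
      target_r = target$r, target_theta = target$theta,
      stop_x = tr$x[k], stop_y = tr$y[k],
      stop_r = stop_pol$r, stop_theta = stop_pol$theta,
      timed_out = tr$timed_out),
    trace = data.frame(
      t = seq_len(k) * cfg$dt, u_v = tr$u_v, u_w = tr$u_w,
      v = tr$v, w = tr$w, x = tr$x, y = tr$y, heading = tr$heading)
  )
}

#' Session configuration
#'
#' @param n_participants Number of synthetic participants (default 15).
#' @param trials_per_condition Trials per sensory condition per participant
#'   (default 483, i.e. about 1450 trials in total).
#' @param walk A [walk_params()] object: one time-constant walk spans all of
#'   a participant's trials, across conditions.
#' @param sim A [sim_config()].
#' @param agents Named list of [agent_params()] for the three conditions;
#'   defaults to the per-condition defaults with `mu_prior` set to the
#'   walk's marginal mean.
#' @param timeout_factor Hard trial timeout in units of `T_nominal`.
#' @return An object of class `session_config`.
#' @export
session_config <- function(n_participants = 15, trials_per_condition = 483,
                           walk = walk_params(), sim = sim_config(),
                           agents = NULL, timeout_factor = 4) {
  stopifnot(n_participants >= 1, trials_per_condition >= 1,
            inherits(walk, "tau_walk_params"), inherits(sim, "sim_config"))
  conds <- c("vestibular", "visual", "combined")
  if (is.null(agents))
    agents <- lapply(stats::setNames(conds, conds), function(cd)
      agent_params(cd, mu_prior = walk$mu_phi))
  stopifnot(setequal(names(agents), conds))
  structure(list(n_participants = n_participants,
                 trials_per_condition = trials_per_condition,
                 walk = walk, sim = sim, agents = agents,
                 timeout_factor = timeout_factor),
            class = "session_config")
}

#' Generate a full synthetic session
#'
#' For each participant, draws a single time-constant walk over all trials,
#' randomly interleaves the three sensory conditions, samples targets, and
#' simulates every trial with the condition's agent parameters.
#'
#' @param cfg A [session_config()].
#' @param seed Integer seed; the whole session is reproducible from
#'   `(cfg, seed)`.
#' @return An object of class `steer_session`: a list with `trials` (one
#'   row per trial: `participant`, `trial`, condition, `tau`,
#'   `tau_hat_gen`, target and stop coordinates, `timed_out`), `traces`
#'   (list of per-trial time-series data.frames, parallel to the rows of
#'   `trials`), `config` and `seed`.
#' @export
generate_session <- function(cfg = session_config(), seed = 1) {
  stopifnot(inherits(cfg, "session_config"))
  seed <- as.integer(seed)
  set.seed(seed)
  conds <- c("vestibular", "visual", "combined")
  n_trials <- 3L * cfg$trials_per_condition
  all_sum <- vector("list", cfg$n_participants)
  traces <- vector("list", cfg$n_participants * n_trials)
  ti <- 0L
  for (p in seq_len(cfg$n_participants)) {
    condition <- sample(rep(conds, cfg$trials_per_condition))
    tau <- sample_tau_sequence(cfg$walk, n_trials)
    targets <- sample_targets(n_trials)
    rows <- vector("list", n_trials)
    for (i in seq_len(n_trials)) {
      tr <- simulate_agent_trial(targets[i, ], tau[i],
                                 cfg$agents[[condition[i]]], cfg$sim,
                                 timeout_factor = cfg$timeout_factor)
      rows[[i]] <- cbind(data.frame(participant = p, trial = i),
                         tr$summary)
      ti <- ti + 1L
      traces[[ti]] <- tr$trace
    }
    all_sum[[p]] <- do.call(rbind, rows)
  }
  trials <- do.call(rbind, all_sum)
  rownames(trials) <- NULL
  structure(list(trials = trials, traces = traces, config = cfg,
                 seed = seed),
            class = "steer_session")
}

#' @export
print.steer_session <- function(x, ...) {
  cat(sprintf("<steer_session> %d participants, %d trials (%s)\n",
              length(unique(x$trials$participant)), nrow(x$trials),
              paste(sprintf("%s: %d", names(table(x$trials$condition)),
                            as.integer(table(x$trials$condition))),
                    collapse = ", ")))
  invisible(x)
}

#' Subset a session by condition and/or participant
#'
#' @param session A `steer_session`.
#' @param condition Optional condition name(s) to keep.
#' @param participant Optional participant id(s) to keep.
#' @return A `steer_session` containing the selected trials and traces.
#' @export
subset_session <- function(session, condition = NULL, participant = NULL) {
  stopifnot(inherits(session, "steer_session"))
  keep <- rep(TRUE, nrow(session$trials))
  if (!is.null(condition)) keep <- keep & session$trials$condition %in% condition
  if (!is.null(participant))
    keep <- keep & session$trials$participant %in% participant
  session$trials <- session$trials[keep, , drop = FALSE]
  rownames(session$trials) <- NULL
  session$traces <- session$traces[keep]
  session
}
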