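# Shared fixtures, built once per test run and cached. Everything is
# generated in code under fixed seeds; no data files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Agent parameter sets with one lambda for all three conditions.
agents_all <- function(lambda, jitter = 0, noise = 0.05,
                       gain_r = 0.85, gain_theta = 0.95) {
  conds <- c("vestibular", "visual", "combined")
  lapply(stats::setNames(conds, conds), function(cd)
    agent_params(cd, lambda = lambda, belief_jitter_sd = jitter,
                 motor_noise_sd = noise, target_gain_r = gain_r,
                 target_gain_theta = gain_theta))
}

# Two participants, 120 trials per condition, default (per-condition) agents.
small_session <- function() fixture("small", function()
  generate_session(session_config(n_participants = 2,
                                  trials_per_condition = 120), seed = 7))

# One participant, single lambda across conditions, no belief jitter.
lambda_session <- function(lambda, tpc = 100, seed = 11, noise = 0.05) {
  key <- paste0("lam", lambda, "_", tpc, "_", seed, "_", noise)
  fixture(key, function()
    generate_session(session_config(n_participants = 1,
                                    trials_per_condition = tpc,
                                    agents = agents_all(lambda, noise = noise)),
                     seed = seed))
}

# Brute-force posterior median over a discretised phi grid (independent
# oracle for the closed-form shrinkage estimate).
grid_posterior_tau <- function(tau, mu_prior, lambda, n_grid = 1e4) {
  sig_l <- 1
  sig_p <- lambda * sig_l
  m <- log(tau)
  lo <- min(mu_prior - 6 * sig_p, m - 6 * sig_l)
  hi <- max(mu_prior + 6 * sig_p, m + 6 * sig_l)
  phi <- seq(lo, hi, length.out = n_grid)
  post <- exp(-(phi - mu_prior)^2 / (2 * sig_p^2) - (m - phi)^2 / (2 * sig_l^2))
  # midpoint cumulative mass: half-step-corrected, O(grid^2) accurate
  cdf <- (cumsum(post) - post / 2) / sum(post)
  exp(stats::approx(cdf, phi, xout = 0.5, ties = "ordered")$y)
}

# A hand-built minimal session around explicit traces (for unit tests of
# analyses that only need the container, not the generator).
manual_session <- function(traces, trials, sim = sim_config()) {
  cfg <- session_config(n_participants = max(trials$participant),
                        trials_per_condition = 1, sim = sim)
  structure(list(trials = trials, traces = traces, config = cfg, seed = 0L),
            class = "steer_session")
}
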