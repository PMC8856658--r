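# The internal-model family: posterior estimates, believed trajectories,
# fitting, validation, comparison.

test_that("closed-form posterior equals its limits and the grid oracle", {
  expect_equal(posterior_tau(2.2, observer_params(0.1, Inf)), 2.2)
  expect_equal(posterior_tau(2.2, observer_params(0.1, 0)), exp(0.1))
  expect_equal(posterior_tau(4, observer_params(0, 1)), 2, tolerance = 1e-12)
  expect_equal(posterior_tau(3, observer_params(log(1.5), 0.3)), 1.588,
               tolerance = 1e-3)
  for (lam in c(0.3, 0.8, 2)) {
    for (tau in c(0.6, 1.4, 3)) {
      closed <- posterior_tau(tau, observer_params(0.29, lam))
      expect_equal(closed, grid_posterior_tau(tau, 0.29, lam),
                   tolerance = 1e-4)
    }
  }
})

test_that("believed stops reproduce identities and mis-belief signs", {
  ses <- subset_session(small_session(), condition = "visual",
                        participant = 1)
  # veridical estimate: believed stop equals the actual stop exactly
  bel <- believed_stops(ses, ses$trials$tau)
  expect_equal(bel$bel_x, ses$trials$stop_x, tolerance = 1e-12)
  expect_equal(bel$bel_y, ses$trials$stop_y, tolerance = 1e-12)
  # believing in a faster-decaying (smaller tau) plant shortens the
  # believed path of the same input
  bel_small <- believed_stops(ses, pmax(ses$trials$tau / 2, 0.05))
  expect_true(all(bel_small$bel_r < bel$bel_r))
  # zero input: believed stop at the origin
  tr0 <- data.frame(t = (1:50) / 60, u_v = 0, u_w = 0, v = 0, w = 0,
                    x = 0, y = 0, heading = 0)
  trials0 <- data.frame(participant = 1, trial = 1, condition = "visual",
                        tau = 1, target_r = 4, target_theta = 0,
                        stop_r = 0, stop_theta = 0, stop_x = 0, stop_y = 0,
                        timed_out = FALSE)
  s0 <- manual_session(list(tr0), trials0)
  b0 <- believed_stops(s0, 1.5)
  expect_equal(b0$bel_r, 0)
})

test_that("static-prior fit is idempotent and respects the likelihood limit", {
  ses <- subset_session(lambda_session(Inf, tpc = 60, seed = 31),
                        condition = "vestibular")
  # timed-out trials have no valid stopping location (a real trial only
  # ends once the speed drops below threshold); exclude them from fitting
  keep <- which(!ses$trials$timed_out)
  ses$trials <- ses$trials[keep, ]
  rownames(ses$trials) <- NULL
  ses$traces <- ses$traces[keep]
  g <- response_gain(ses$trials)
  fit <- fit_static_prior(ses, g)
  # a veridical generator is fitted with a likelihood-dominated observer
  expect_gt(fit$params$lambda, 2)
  # MSE at the fitted parameters beats the prior-dominated corner
  obj <- function(mu, lam) {
    th <- posterior_tau(ses$trials$tau, observer_params(mu, lam))
    steerdyn:::stop_mse(believed_stops(ses, th),
                        steerdyn:::aim_points(ses$trials, g))
  }
  expect_lt(fit$mse, obj(fit$params$mu_prior, 0.01))
  # recomputing the objective at the fitted parameters reproduces it
  expect_equal(obj(fit$params$mu_prior, fit$params$lambda), fit$mse,
               tolerance = 1e-10)
})

test_that("dynamic prior reduces to its algebraic limits", {
  phi <- log(c(1.2, 0.8, 2.5, 1.1, 0.7))
  # lambda = 1 -> k = 1/2: equal weighting of prior and measurement
  path <- steerdyn:::dynamic_prior_path(phi, 1)
  expect_equal(path[2], 0.5 * phi[1] + 0.5 * phi[2], tolerance = 1e-12)
  # lambda -> 0 freezes the prior at the first trial
  expect_equal(steerdyn:::dynamic_prior_path(phi, 1e-9), rep(phi[1], 5),
               tolerance = 1e-12)
  # lambda -> Inf tracks the measurement
  expect_equal(steerdyn:::dynamic_prior_path(phi, 1e9), phi, tolerance = 1e-6)
  ses <- subset_session(small_session(), condition = "visual")
  g <- response_gain(ses$trials)
  bad <- ses
  bad$trials <- bad$trials[rev(seq_len(nrow(bad$trials))), ]
  bad$traces <- rev(bad$traces)
  expect_error(fit_dynamic_prior(bad, g), "chronological")
})

test_that("fixed-tau fit recovers a prior-dominated generator", {
  # narrow walk centred on the believed constant, so that the measured
  # response gain matches the intended one and the objective's premise
  # (believed stops centred on the mean response) holds
  ags <- lapply(stats::setNames(nm = c("vestibular", "visual", "combined")),
                function(cd) agent_params(cd, lambda = 0, mu_prior = log(1.2),
                                          belief_jitter_sd = 0))
  ses <- generate_session(session_config(n_participants = 1,
                                         trials_per_condition = 60,
                                         walk = walk_params(1.0, 1.44),
                                         agents = ags), seed = 17)
  ss <- subset_session(ses, condition = "vestibular")
  g <- response_gain(ss$trials)
  fit <- fit_fixed_tau(ss, g)
  expect_equal(fit$params$tau_fixed, 1.2, tolerance = 0.1 * 1.2)
  # on data with real tau-tracking, the fixed model fits worse than static
  ses1 <- subset_session(lambda_session(1.0, tpc = 100, seed = 19),
                         condition = "visual")
  g1 <- response_gain(ses1$trials)
  expect_gt(fit_fixed_tau(ses1, g1)$mse, fit_static_prior(ses1, g1)$mse)
})

test_that("carry-over estimates inherit the walk's correlation structure", {
  slow <- generate_session(session_config(
    n_participants = 1, trials_per_condition = 60,
    walk = walk_params(tau_phi = 50)), seed = 23)
  fast <- generate_session(session_config(
    n_participants = 1, trials_per_condition = 60,
    walk = walk_params(tau_phi = 0.15)), seed = 23)
  co_slow <- carryover_estimate(slow, "true_tau")
  co_fast <- carryover_estimate(fast, "true_tau")
  expect_gt(cor(co_slow$tau_hat, co_slow$tau), 0.8)
  expect_lt(abs(cor(co_fast$tau_hat, co_fast$tau)), 0.15)
  # posterior variant shrinks toward the fitted prior: less dispersed
  co_post <- carryover_estimate(slow, "posterior",
                                posterior_params = observer_params(0.29, 0.5))
  expect_lt(sd(log(co_post$tau_hat)), sd(log(co_slow$tau_hat)))
  vest_only <- subset_session(slow, condition = "vestibular")
  expect_error(carryover_estimate(vest_only), "visual")
})

test_that("switch-distance model recovers a bang-bang controller", {
  ses <- subset_session(small_session(), condition = "visual",
                        participant = 1)
  ses$trials <- ses$trials[1:60, ]
  ses$traces <- ses$traces[1:60]
  g <- response_gain(ses$trials)
  # rebuild the stops as those of a true switch-distance controller
  cfg <- ses$config$sim
  aim <- steerdyn:::aim_points(ses$trials, g)
  n_max <- as.integer(round(4 * cfg$T_nominal / cfg$dt))
  d_true <- 0.8
  for (i in seq_len(nrow(ses$trials))) {
    dyn <- make_dynamics(ses$trials$tau[i], cfg)
    ro <- steerdyn:::cpp_switch_rollout(ses$traces[[i]]$u_w, dyn$alpha,
                                        dyn$beta_v, dyn$beta_w, cfg$dt,
                                        cfg$v_stop, aim$x[i], aim$y[i],
                                        d_true, n_max)
    ses$trials$stop_x[i] <- ro$stop_x
    ses$trials$stop_y[i] <- ro$stop_y
  }
  ses$trials$stop_r <- sqrt(ses$trials$stop_x^2 + ses$trials$stop_y^2)
  ses$trials$stop_theta <- atan2(ses$trials$stop_y, ses$trials$stop_x)
  fit <- fit_switch_model(ses, g)
  expect_equal(fit$params$switch_mean, d_true, tolerance = 0.05 * d_true)
  expect_lt(fit$mse, 1e-3)
})

test_that("validation equates identity beliefs with the actual statistics", {
  ses <- subset_session(small_session(), condition = "vestibular")
  g <- response_gain(ses$trials)
  bel <- believed_stops(ses, ses$trials$tau)
  rp <- validate_subjective_residuals(ses, bel, g)
  expect_equal(rp$per_participant$r_subj_radial,
               rp$per_participant$r_actual_radial, tolerance = 1e-10)
  expect_equal(rp$per_participant$r_subj_angular,
               rp$per_participant$r_actual_angular, tolerance = 1e-10)
  expect_equal(rp$alpha_model, 0.0085)
  # identical models compare as indistinguishable
  cmp <- compare_models(list(a = rp, b = rp))
  expect_equal(cmp$pairwise$p_radial, 1)
  expect_equal(cmp$pairwise$mean_diff_radial, 0)
})

test_that("percentile bootstrap attains nominal coverage on Gaussian data", {
  set.seed(47)
  hits <- 0L
  n_rep <- 400
  for (i in seq_len(n_rep)) {
    x <- rnorm(15, mean = 1, sd = 1)
    ci <- bootstrap_ci(x, n_boot = 400)
    hits <- hits + (ci["lower"] <= 1 && 1 <= ci["upper"])
  }
  cover <- hits / n_rep
  expect_gt(cover, 0.90)
  expect_lt(cover, 0.98)
})
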