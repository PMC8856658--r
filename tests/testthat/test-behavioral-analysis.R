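# Response gains, residual errors, interaction regressions, the
# no-adaptation null and joystick summaries.

test_that("no-intercept gain equals the closed form and a brute-force oracle", {
  # exact proportional responses
  g <- response_gain(data.frame(r = 1:3, theta = c(0.1, 0.2, 0.3)),
                     data.frame(r = 0.8 * (1:3), theta = 0.8 * c(0.1, 0.2, 0.3)))
  expect_equal(g$g_r, 0.8, tolerance = 1e-12)
  expect_equal(g$r2_r, 1, tolerance = 1e-12)
  # hand-computed normal equation: 12.2 / 14
  g <- response_gain(data.frame(r = 1:3, theta = 1:3),
                     data.frame(r = c(0.8, 1.8, 2.6), theta = c(0.8, 1.8, 2.6)))
  expect_equal(g$g_r, 12.2 / 14, tolerance = 1e-12)
  # brute-force least squares on random data
  set.seed(21)
  x <- runif(40, 1, 5); y <- 0.7 * x + rnorm(40, 0, 0.3)
  gg <- response_gain(data.frame(r = x, theta = x), data.frame(r = y, theta = y))
  brute <- optimize(function(b) sum((y - b * x)^2), c(-5, 5), tol = 1e-12)$minimum
  expect_equal(gg$g_r, brute, tolerance = 1e-8)
  expect_error(response_gain(data.frame(r = c(0, 0), theta = c(0, 0)),
                             data.frame(r = 1:2, theta = 1:2)), "zero")
})

test_that("tertile split is equal-sized, deterministic and tau-ordered", {
  tr <- data.frame(tau = c(3, 1, 2, 5, 4, 6, 8, 7, 9, 10),
                   target_r = rep(4, 10), target_theta = rep(0.1, 10),
                   stop_r = rep(4, 10), stop_theta = rep(0.1, 10))
  tg <- tertile_gains(tr)
  expect_equal(tg$n, c(4L, 3L, 3L))
  expect_true(tg$tau_max[1] <= tg$tau_min[2])
  expect_true(tg$tau_max[2] <= tg$tau_min[3])
  # tau-independent responses give identical gains in all tertiles
  expect_equal(tg$g_r, rep(1, 3))
  # ties broken by trial index: constant tau still yields a 4/3/3 split
  tr$tau <- 1
  expect_equal(tertile_gains(tr)$n, c(4L, 3L, 3L))
  # n = 3: one trial per tertile, slope = response / target
  tr3 <- data.frame(tau = 1:3, target_r = c(2, 3, 4), target_theta = 0.1,
                    stop_r = c(1, 3, 6), stop_theta = 0.1)
  expect_equal(tertile_gains(tr3)$g_r, c(0.5, 1, 1.5))
})

test_that("residual errors follow the definition and the normal equations", {
  tr <- data.frame(target_r = 4, target_theta = 0.2, stop_r = 3.0,
                   stop_theta = 0.1)
  gains <- structure(list(g_r = 0.8, g_theta = 1), class = "gain_estimate")
  eps <- residual_errors(tr, gains)
  expect_equal(eps$eps_r, -0.2, tolerance = 1e-12)
  # residuals of the fitting set are orthogonal to the targets
  set.seed(22)
  tr <- data.frame(target_r = runif(60, 2.5, 5.5),
                   target_theta = runif(60, -0.6, 0.6))
  tr$stop_r <- 0.8 * tr$target_r + rnorm(60, 0, 0.3)
  tr$stop_theta <- 0.9 * tr$target_theta + rnorm(60, 0, 0.05)
  g <- response_gain(tr)
  eps <- residual_errors(tr, g)
  expect_lt(abs(sum(tr$target_r * eps$eps_r)), 1e-9)
  expect_lt(abs(sum(tr$target_theta * eps$eps_theta)), 1e-9)
})

test_that("tau-error statistics behave at the exact and null extremes", {
  set.seed(23)
  tau <- runif(200, 0.6, 3)
  st <- tau_error_stats(0.4 * tau, tau)
  expect_equal(st$r, 1, tolerance = 1e-12)
  expect_equal(st$slope, 0.4, tolerance = 1e-12)
  eps <- rnorm(200)
  st <- tau_error_stats(eps, tau)
  expect_lt(abs(st$r), 3 / sqrt(200))
  expect_error(tau_error_stats(rep(1, 10), runif(10)), "zero-variance")
})

test_that("interaction regression recovers a noiseless generative model", {
  set.seed(24)
  n <- 300
  tr <- data.frame(target_r = runif(n, 2.5, 5.5),
                   target_theta = runif(n, -0.6, 0.6),
                   tau = runif(n, 0.6, 3))
  tr$stop_r <- tr$target_r * (0.7 + 0.1 * tr$tau)
  tr$stop_theta <- tr$target_theta * (0.9 + 0.05 * tr$tau)
  ir <- interaction_regression(tr)
  # undo the SD scaling to compare with the generative coefficients
  b_raw <- ir$b_r * sd(tr$stop_r) / sd(tr$target_r)
  a_raw <- ir$a_r * sd(tr$stop_r) / sd(tr$target_r * tr$tau)
  expect_equal(b_raw, 0.7, tolerance = 1e-6)
  expect_equal(a_raw, 0.1, tolerance = 1e-6)
  # brute-force normal-equation oracle on the scaled variables
  y <- tr$stop_r / sd(tr$stop_r)
  X <- cbind(tr$target_r / sd(tr$target_r),
             (tr$target_r * tr$tau) / sd(tr$target_r * tr$tau))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(c(ir$b_r, ir$a_r)), unname(as.vector(beta)),
               tolerance = 1e-10)
  # no interaction: coefficient and partial correlation vanish
  tr$stop_r <- 0.8 * tr$target_r + rnorm(n, 0, 0.05)
  ir0 <- interaction_regression(tr)
  expect_lt(abs(ir0$a_r), 0.05)
  pc <- ir0$partial
  expect_lt(abs(pc$partial_r[pc$component == "radial" &
                             pc$predictor == "target_x_tau"]), 0.2)
  tr$tau <- 1.7
  expect_error(interaction_regression(tr), "tau")
})

test_that("no-adaptation null detects adapting and non-adapting agents", {
  # the selection band must be respected
  ses <- small_session()
  expect_error(null_no_adaptation(subset_session(ses, condition = "visual"),
                                  tau_tolerance = 1e-6), "tolerance")
  nn <- null_no_adaptation(subset_session(ses, condition = "vestibular"),
                           seed = 3)
  expect_equal(nrow(nn$null), 3)
  expect_true(is.finite(nn$slope_r) && is.finite(nn$slope_theta))
  expect_gt(nn$n_selected, 0)
})

test_that("joystick areas and braking integrate the input magnitudes", {
  dt <- 1 / 60
  n1 <- 5 * 60
  tr1 <- data.frame(t = seq_len(n1) * dt, u_v = 1, u_w = 0, v = 0, w = 0,
                    x = 0, y = 0, heading = 0)
  n2 <- 4 * 60
  tr2 <- data.frame(t = seq_len(n2) * dt,
                    u_v = rep(c(1, -1), c(3 * 60, 60)), u_w = 0.5,
                    v = 0, w = 0, x = 0, y = 0, heading = 0)
  trials <- data.frame(participant = 1, trial = 1:2,
                       condition = c("visual", "visual"), tau = c(1, 2),
                       target_r = 4, target_theta = 0, stop_r = 4,
                       stop_theta = 0, stop_x = 4, stop_y = 0,
                       timed_out = FALSE)
  ses <- manual_session(list(tr1, tr2), trials)
  js <- joystick_summaries(ses)
  expect_equal(js$per_trial$area_v[1], 5, tolerance = 0.05)
  expect_equal(js$per_trial$braking[1], 0)
  expect_equal(js$per_trial$braking[2], 1, tolerance = 0.05)
  expect_equal(js$per_trial$area_w[2], 0.5 * 4, tolerance = 0.05)
})

test_that("summary statistics are invariant to trial order", {
  ses <- subset_session(small_session(), condition = "combined")
  set.seed(31)
  perm <- sample(nrow(ses$trials))
  shuf <- ses
  shuf$trials <- ses$trials[perm, ]
  rownames(shuf$trials) <- NULL
  shuf$traces <- ses$traces[perm]
  g1 <- response_gain(ses$trials); g2 <- response_gain(shuf$trials)
  expect_equal(g1$g_r, g2$g_r, tolerance = 1e-12)
  e1 <- residual_errors(ses$trials, g1); e2 <- residual_errors(shuf$trials, g2)
  expect_equal(tau_error_stats(e1$eps_r, ses$trials$tau)$r,
               tau_error_stats(e2$eps_r, shuf$trials$tau)$r, tolerance = 1e-12)
  i1 <- interaction_regression(ses$trials)
  i2 <- interaction_regression(shuf$trials)
  expect_equal(i1$a_r, i2$a_r, tolerance = 1e-12)
})
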