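# Descriptive analyses of steering responses: no-intercept response gains,
# tau-stratified gains, residual errors and their tau-dependence,
# interaction regressions with partial correlations, the simulated
# no-adaptation null, and joystick-input summaries.

# Slope of the regression through the origin, g = sum(xy) / sum(x^2).
slope_origin <- function(x, y) {
  sxx <- sum(x^2)
  if (sxx == 0) stop("undefined slope: all target values are zero")
  sum(x * y) / sxx
}

# Uncentered R^2 (1 - SSE / sum(y^2)), the standard choice for models
# without an intercept.
r2_uncentered <- function(y, fitted) 1 - sum((y - fitted)^2) / sum(y^2)

#' Response gains
#'
#' Radial and angular response gains: the slopes of no-intercept regressions
#' of the stopping position on the target position, fitted separately for
#' the radial (\eqn{\tilde r} on \eqn{r}) and angular (\eqn{\tilde\theta} on
#' \eqn{\theta}) components. A gain of one is unbiased; below one,
#' undershooting. R-squared is uncentered (computed against
#' \eqn{\sum y^2}, consistent with the absence of an intercept), and
#' `delta_r2` reports the gain in uncentered R-squared from adding an
#' intercept.
#'
#' @param targets data.frame (or list) with columns `r` (m) and `theta`
#'   (rad), or a `steer_session` / trials data.frame with `target_r`,
#'   `target_theta`, `stop_r`, `stop_theta` columns (in which case
#'   `responses` may be omitted).
#' @param responses data.frame with columns `r` and `theta` (the stopping
#'   positions), when `targets` is given as a plain target table.
#' @return An object of class `gain_estimate` with fields `g_r`, `g_theta`,
#'   `r2_r`, `r2_theta`, `delta_r2_r`, `delta_r2_theta`, `n`.
#' @examples
#' response_gain(data.frame(r = 1:3, theta = 1:3),
#'               data.frame(r = c(.8, 1.8, 2.6), theta = c(.8, 1.8, 2.6)))
#' @export
response_gain <- function(targets, responses = NULL) {
  if (inherits(targets, "steer_session")) targets <- targets$trials
  if (is.null(responses)) {
    stopifnot(all(c("target_r", "target_theta", "stop_r", "stop_theta")
                  %in% names(targets)))
    responses <- data.frame(r = targets$stop_r, theta = targets$stop_theta)
    targets <- data.frame(r = targets$target_r, theta = targets$target_theta)
  }
  stopifnot(nrow(targets) >= 1, nrow(targets) == nrow(responses))
  one <- function(x, y) {
    g <- slope_origin(x, y)
    r2 <- r2_uncentered(y, g * x)
    delta <- if (length(x) >= 2)
      r2_uncentered(y, fitted(lm(y ~ x))) - r2 else NA_real_
    list(g = g, r2 = r2, delta = delta)
  }
  rr <- one(targets$r, responses$r)
  aa <- one(targets$theta, responses$theta)
  structure(list(g_r = rr$g, g_theta = aa$g, r2_r = rr$r2, r2_theta = aa$r2,
                 delta_r2_r = rr$delta, delta_r2_theta = aa$delta,
                 n = nrow(targets)),
            class = "gain_estimate")
}

#' @export
print.gain_estimate <- function(x, ...) {
  cat(sprintf("<gain_estimate> n=%d  g_r=%.3f (R2=%.3f)  g_theta=%.3f (R2=%.3f)\n",
              x$n, x$g_r, x$r2_r, x$g_theta, x$r2_theta))
  invisible(x)
}

# Equal-size tertile assignment by tau, ties broken by trial order,
# remainder trials going to the lower groups.
tertile_assign <- function(tau) {
  n <- length(tau)
  sizes <- rep(n %/% 3L, 3L)
  rem <- n %% 3L
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  grp <- integer(n)
  grp[order(tau, seq_along(tau))] <- rep(1:3, times = sizes)
  grp
}

#' Response gains by time-constant tertile
#'
#' Ranks trials by the time constant, splits them into three equal-size
#' groups (ties broken by trial order, remainders to the lower groups), and
#' computes [response_gain()] within each group.
#'
#' @param trials A `steer_session` or its `trials` data.frame.
#' @return A data.frame with one row per tertile (`tertile`, `n`,
#'   `tau_min`, `tau_max`, `tau_mean`, `g_r`, `g_theta`), with the group
#'   assignment and the tau break points attached as attributes
#'   `"assignment"` and `"edges"` (used to bin simulated trajectories in
#'   [null_no_adaptation()]).
#' @export
tertile_gains <- function(trials) {
  if (inherits(trials, "steer_session")) trials <- trials$trials
  stopifnot(nrow(trials) >= 3)
  grp <- tertile_assign(trials$tau)
  rows <- lapply(1:3, function(g) {
    tt <- trials[grp == g, , drop = FALSE]
    ge <- response_gain(tt)
    data.frame(tertile = g, n = nrow(tt), tau_min = min(tt$tau),
               tau_max = max(tt$tau), tau_mean = mean(tt$tau),
               g_r = ge$g_r, g_theta = ge$g_theta)
  })
  out <- do.call(rbind, rows)
  attr(out, "assignment") <- grp
  attr(out, "edges") <- c(out$tau_max[1], out$tau_max[2])
  out
}

#' Per-trial residual errors
#'
#' Deviations of the stopping position from the gain-scaled target (the
#' mean response for that target): \eqn{\varepsilon_{r,i} = \tilde r_i -
#' g_r r_i} and \eqn{\varepsilon_{\theta,i} = \tilde\theta_i -
#' g_\theta \theta_i}.
#'
#' @param trials A `steer_session` or trials data.frame.
#' @param gains A `gain_estimate` fitted on the same condition's trials.
#' @return A data.frame with columns `eps_r` (m) and `eps_theta` (rad).
#' @export
residual_errors <- function(trials, gains) {
  if (inherits(trials, "steer_session")) trials <- trials$trials
  stopifnot(inherits(gains, "gain_estimate"))
  data.frame(eps_r = trials$stop_r - gains$g_r * trials$target_r,
             eps_theta = trials$stop_theta - gains$g_theta * trials$target_theta)
}

#' Correlation of residual errors with the time constant
#'
#' Pearson correlation, univariate regression slope and two-sided p-value
#' for the dependence of a residual-error component on the time constant.
#'
#' @param eps Numeric vector of residual errors.
#' @param tau Numeric vector of time constants (same length).
#' @return A list with `r`, `slope`, `p_value`, `n`.
#' @export
tau_error_stats <- function(eps, tau) {
  stopifnot(length(eps) == length(tau), length(eps) >= 3)
  if (sd(eps) == 0 || sd(tau) == 0)
    stop("undefined correlation: zero-variance input")
  ct <- cor.test(eps, tau, method = "pearson")
  list(r = unname(ct$estimate), slope = cov(eps, tau) / var(tau),
       p_value = ct$p.value, n = length(eps))
}

# Residualize y against the columns of X with no-intercept least squares.
resid_on <- function(y, X) {
  X <- as.matrix(X)
  y - X %*% qr.solve(crossprod(X), crossprod(X, y))
}

#' Interaction regression of responses on target and target-by-tau terms
#'
#' Fits, separately for the radial and angular components, the no-intercept
#' model \eqn{\tilde r = b_r r + a_r r\tau} (and the angular analogue) with
#' every variable scaled by its standard deviation (not centred) so that
#' coefficients are comparable across predictors. Also reports Pearson
#' partial correlations of the response with each of the three predictors
#' (target, \eqn{\tau}, target-by-\eqn{\tau}), computed by residualising
#' response and predictor against the remaining two predictors.
#'
#' @param trials A `steer_session` or trials data.frame.
#' @return A list with standardized coefficients `b_r`, `a_r`, `b_theta`,
#'   `a_theta` and a data.frame `partial` of partial correlations per
#'   component and predictor.
#' @export
interaction_regression <- function(trials) {
  if (inherits(trials, "steer_session")) trials <- trials$trials
  stopifnot(nrow(trials) >= 3)
  if (sd(trials$tau) == 0)
    stop("rank-deficient design: predictor 'tau' is constant, ",
         "target and target*tau are collinear")
  sdiv <- function(x) x / sd(x)
  one <- function(tar, resp) {
    y <- sdiv(resp)
    X <- cbind(target = sdiv(tar), interaction = sdiv(tar * trials$tau))
    beta <- qr.solve(crossprod(X), crossprod(X, y))
    P <- cbind(target = sdiv(tar), tau = sdiv(trials$tau),
               interaction = sdiv(tar * trials$tau))
    pc <- vapply(colnames(P), function(j) {
      others <- P[, setdiff(colnames(P), j), drop = FALSE]
      cor(resid_on(y, others), resid_on(P[, j], others))
    }, numeric(1))
    list(b = beta[1], a = beta[2], partial = pc)
  }
  rr <- one(trials$target_r, trials$stop_r)
  aa <- one(trials$target_theta, trials$stop_theta)
  list(b_r = rr$b, a_r = rr$a, b_theta = aa$b, a_theta = aa$a,
       partial = data.frame(
         component = rep(c("radial", "angular"), each = 3),
         predictor = rep(c("target", "tau", "target_x_tau"), 2),
         partial_r = c(rr$partial, aa$partial)))
}

#' Simulated no-adaptation null gains
#'
#' Builds the null case of steering that ignores the control dynamics:
#' trials whose time constant lies within `tau_tolerance` of the dataset's
#' mean time constant are selected, and each selected trial's joystick
#' trace is re-integrated under time constants drawn (without replacement
#' when possible) from the other trials, with the filter coefficient and
#' calibrated gains recomputed for the substituted time constant. The
#' simulated trajectories are binned by the tertile edges of the actual
#' data, null gains are computed against the original trials' targets, and
#' the actual tertile gains are regressed on the null tertile gains: a
#' slope of 0 indicates perfect adaptation, 1 none.
#'
#' @param session A `steer_session` (traces are required).
#' @param tau_tolerance Half-width of the selection band around the mean
#'   time constant, in seconds (default 0.2).
#' @param n_draws Substituted time constants per selected trial (default
#'   20).
#' @param seed Optional integer seed for the donor draws.
#' @return A list with `actual` and `null` tertile-gain data.frames, the
#'   regression slopes `slope_r` and `slope_theta`, and `n_selected`.
#' @export
null_no_adaptation <- function(session, tau_tolerance = 0.2, n_draws = 20,
                               seed = NULL) {
  stopifnot(inherits(session, "steer_session"))
  if (!is.null(seed)) set.seed(seed)
  trials <- session$trials
  tau_ref <- mean(trials$tau)
  sel <- which(abs(trials$tau - tau_ref) <= tau_tolerance)
  if (length(sel) == 0)
    stop("no trials within ", tau_tolerance, " s of the mean time constant (",
         round(tau_ref, 3), " s); increase 'tau_tolerance'")
  actual <- tertile_gains(trials)
  edges <- attr(actual, "edges")
  cfg <- session$config$sim

  sim_tau <- numeric(0); sim_tr <- integer(0)
  for (i in sel) {
    pool <- trials$tau[-i]
    k <- min(n_draws, length(pool))
    sim_tau <- c(sim_tau, sample(pool, k))
    sim_tr <- c(sim_tr, rep(i, k))
  }
  dyn <- lapply(sim_tau, make_dynamics, cfg = cfg)
  # coast with zero input past the trace end, as the original trial did,
  # so that substituted slow dynamics are not cut short
  ends <- cpp_reintegrate(
    lapply(session$traces[sim_tr], `[[`, "u_v"),
    lapply(session$traces[sim_tr], `[[`, "u_w"),
    vapply(dyn, `[[`, 0, "alpha"),
    vapply(dyn, `[[`, 0, "beta_v"), vapply(dyn, `[[`, 0, "beta_w"),
    cfg$dt, v_stop = cfg$v_stop,
    coast_steps = as.integer(round(4 * cfg$T_nominal / cfg$dt)))
  sim <- data.frame(tau = sim_tau,
                    target_r = trials$target_r[sim_tr],
                    target_theta = trials$target_theta[sim_tr],
                    stop_r = ends[, 3], stop_theta = ends[, 4])
  grp <- cut(sim$tau, c(-Inf, edges, Inf), labels = FALSE)
  null_rows <- lapply(1:3, function(g) {
    ss <- sim[grp == g, , drop = FALSE]
    ge <- response_gain(ss)
    data.frame(tertile = g, n = nrow(ss), tau_mean = mean(ss$tau),
               g_r = ge$g_r, g_theta = ge$g_theta)
  })
  null <- do.call(rbind, null_rows)
  list(actual = actual, null = null,
       slope_r = unname(coef(lm(actual$g_r ~ null$g_r))[2]),
       slope_theta = unname(coef(lm(actual$g_theta ~ null$g_theta))[2]),
       n_selected = length(sel))
}

#' Joystick-input summaries
#'
#' Per-trial trapezoidal areas of the absolute linear and angular joystick
#' input (units: input x seconds), the cumulative braking (area of the
#' negative part of the linear input), and the per-condition Pearson
#' correlation of braking with the time constant.
#'
#' @param session A `steer_session`.
#' @return A list with `per_trial` (data.frame: condition, `tau`, `area_v`,
#'   `area_w`, `braking`) and `braking_tau` (data.frame of per-condition
#'   correlations with p-values).
#' @export
joystick_summaries <- function(session) {
  stopifnot(inherits(session, "steer_session"))
  per <- do.call(rbind, lapply(seq_along(session$traces), function(i) {
    tr <- session$traces[[i]]
    data.frame(
      area_v = pracma::trapz(tr$t, abs(tr$u_v)),
      area_w = pracma::trapz(tr$t, abs(tr$u_w)),
      braking = pracma::trapz(tr$t, pmax(-tr$u_v, 0)))
  }))
  per <- cbind(session$trials[, c("participant", "condition", "tau")], per)
  bt <- do.call(rbind, lapply(split(per, per$condition), function(d) {
    if (nrow(d) < 3 || sd(d$braking) == 0 || sd(d$tau) == 0)
      return(data.frame(condition = d$condition[1], r = NA_real_,
                        p_value = NA_real_, n = nrow(d)))
    ct <- cor.test(d$braking, d$tau)
    data.frame(condition = d$condition[1], r = unname(ct$estimate),
               p_value = ct$p.value, n = nrow(d))
  }))
  rownames(bt) <- NULL
  list(per_trial = per, braking_tau = bt)
}
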