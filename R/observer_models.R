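# Internal-model estimators of the control time constant: static- and
# dynamic-prior Bayesian observers, a fixed estimate, carry-over rules and a
# sensory-feedback (switch-distance) controller, with believed-trajectory
# reconstruction, least-squares fitting, validation and comparison.

#' Observer parameters
#'
#' @param mu_prior Prior mean over \eqn{\phi = \log\tau}, in log-seconds.
#' @param lambda Ratio of prior to likelihood standard deviation
#'   (dimensionless, >= 0; `Inf` makes the likelihood dominate).
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(mu_prior, lambda) {
  stopifnot(is.numeric(mu_prior), length(mu_prior) == 1L, lambda >= 0)
  structure(list(mu_prior = mu_prior, lambda = lambda),
            class = "observer_params")
}

#' Posterior time-constant estimate
#'
#' Closed-form posterior point estimate of the time constant given a
#' measurement centred on the true value. Prior and likelihood are Gaussian
#' over \eqn{\phi = \log\tau}, so the posterior is Gaussian with mean
#' \deqn{\hat\phi = \frac{\lambda^2 \log\tau + \mu_{prior}}{\lambda^2 + 1},
#' \qquad \hat\tau = e^{\hat\phi},}
#' which is simultaneously the posterior median, mean and mode over
#' \eqn{\phi} (hence the posterior median over \eqn{\tau}).
#'
#' @param tau True time constant(s) of the trial(s), in seconds.
#' @param params An [observer_params()] object.
#' @return Estimated time constant(s) \eqn{\hat\tau}, in seconds.
#' @examples
#' posterior_tau(4, observer_params(0, 1))  # geometric mean of 4 and 1 = 2
#' @export
posterior_tau <- function(tau, params) {
  stopifnot(inherits(params, "observer_params"), all(tau > 0))
  if (is.infinite(params$lambda)) return(tau)
  exp((params$lambda^2 * log(tau) + params$mu_prior) / (params$lambda^2 + 1))
}

#' Believed stopping locations
#'
#' Reconstructs each trial's believed stopping location by re-integrating
#' the actual joystick trace under the dynamics implied by the per-trial
#' time-constant estimate. By default the input gains are yoked to the
#' estimate, i.e. recomputed from \eqn{\hat\tau} through the calibration
#' formula exactly as the experiment yokes them to \eqn{\tau} (an observer
#' inferring \eqn{\hat\tau} would assume its calibrated gain); with
#' `gains_mode = "true"` the trial's actual input gains are kept and only
#' the filter coefficient follows \eqn{\hat\tau}.
#'
#' The believed trajectory integrates the joystick input exactly as
#' recorded, over the recorded trial duration. Setting `coast = TRUE`
#' additionally extends the trace with zero input until the re-integrated
#' speed falls below the stopping threshold (the recorded trace ends when
#' the *actual* speed crossed it, so under other dynamics the terminal
#' velocity is generally nonzero); this completed-stop variant is what the
#' no-adaptation null uses.
#'
#' @param session A `steer_session` (traces required).
#' @param tau_hat Numeric vector of per-trial time-constant estimates, in
#'   seconds, parallel to `session$trials` (a scalar is recycled).
#' @param gains_mode `"yoked"` (default) or `"true"`.
#' @param coast Extend each trace with zero input until the re-integrated
#'   speed drops below `v_stop` (default `FALSE`).
#' @return A data.frame with columns `bel_x`, `bel_y`, `bel_r`,
#'   `bel_theta`.
#' @export
believed_stops <- function(session, tau_hat, gains_mode = c("yoked", "true"),
                           coast = FALSE) {
  if (length(tau_hat) == 1L) tau_hat <- rep(tau_hat, nrow(session$trials))
  stopifnot(inherits(session, "steer_session"),
            length(tau_hat) == nrow(session$trials), all(tau_hat > 0))
  gains_mode <- match.arg(gains_mode)
  cfg <- session$config$sim
  dyn_hat <- lapply(tau_hat, make_dynamics, cfg = cfg)
  alpha <- vapply(dyn_hat, `[[`, 0, "alpha")
  if (gains_mode == "yoked") {
    beta_v <- vapply(dyn_hat, `[[`, 0, "beta_v")
    beta_w <- vapply(dyn_hat, `[[`, 0, "beta_w")
  } else {
    dyn_true <- lapply(session$trials$tau, make_dynamics, cfg = cfg)
    beta_v <- vapply(dyn_true, `[[`, 0, "beta_v")
    beta_w <- vapply(dyn_true, `[[`, 0, "beta_w")
  }
  ends <- cpp_reintegrate(lapply(session$traces, `[[`, "u_v"),
                          lapply(session$traces, `[[`, "u_w"),
                          alpha, beta_v, beta_w, cfg$dt,
                          v_stop = cfg$v_stop,
                          coast_steps = if (coast)
                            as.integer(round(4 * cfg$T_nominal / cfg$dt)) else 0L)
  data.frame(bel_x = ends[, 1], bel_y = ends[, 2],
             bel_r = ends[, 3], bel_theta = ends[, 4])
}

# Gain-scaled target positions (the mean stopping location) in Cartesian
# coordinates: radius g_r * r at bearing g_theta * theta.
aim_points <- function(trials, gains) {
  polar2cart(gains$g_r * trials$target_r,
             gains$g_theta * trials$target_theta)
}

# Mean squared Euclidean distance between believed stops and the
# gain-scaled targets (the fitting objective, evaluated in Cartesian
# coordinates).
stop_mse <- function(bel, aim) {
  mean((bel$bel_x - aim$x)^2 + (bel$bel_y - aim$y)^2)
}

new_model_fit <- function(kind, params, mse, tau_hat, believed, n, extra = list()) {
  structure(c(list(kind = kind, params = params, mse = mse,
                   tau_hat = tau_hat, believed = believed, n = n), extra),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  pp <- paste(sprintf("%s=%.4g", names(x$params), unlist(x$params)),
              collapse = ", ")
  cat(sprintf("<model_fit:%s> n=%d  MSE=%.5f m^2  [%s]\n",
              x$kind, x$n, x$mse, pp))
  invisible(x)
}

# Shared plumbing for the MSE fits: pre-extract traces and aims once.
fit_context <- function(session, gains, gains_mode) {
  list(session = session, aim = aim_points(session$trials, gains),
       gains_mode = gains_mode)
}

eval_mse <- function(ctx, tau_hat) {
  bel <- believed_stops(ctx$session, tau_hat, ctx$gains_mode)
  list(mse = stop_mse(bel, ctx$aim), believed = bel)
}

#' Fit the static-prior Bayesian observer
#'
#' Fits \eqn{(\mu_{prior}, \lambda)} by minimising the mean squared
#' Euclidean distance between the believed stopping location (the actual
#' joystick input re-integrated under \eqn{\hat\tau_i =
#' }[posterior_tau()]) and the gain-scaled target, over the trials of one
#' sensory condition. The optimiser is deterministic: a coarse grid over
#' \eqn{\mu_{prior}} (the log-bound range widened by one log-second) and
#' log-spaced \eqn{\lambda}, followed by Nelder--Mead refinement on
#' \eqn{(\mu_{prior}, \log_{10}\lambda)}.
#'
#' @param session A `steer_session`, typically restricted to one condition
#'   via [subset_session()]. Synthetic trials flagged `timed_out` have no
#'   valid stopping location; consider excluding them before fitting small
#'   datasets.
#' @param gains The condition's [response_gain()] estimate.
#' @param gains_mode Passed to [believed_stops()].
#' @param mu_grid,lambda_grid Optional grid overrides.
#' @return A `model_fit` of kind `"static"` with `params$mu_prior` and
#'   `params$lambda`.
#' @export
fit_static_prior <- function(session, gains, gains_mode = "yoked",
                             mu_grid = NULL, lambda_grid = NULL) {
  stopifnot(inherits(session, "steer_session"))
  ctx <- fit_context(session, gains, gains_mode)
  tau <- session$trials$tau
  if (is.null(mu_grid))
    mu_grid <- seq(log(min(tau)) - 1, log(max(tau)) + 1, length.out = 9)
  if (is.null(lambda_grid))
    lambda_grid <- 10^seq(-2, 1, length.out = 9)
  obj <- function(par) {
    op <- observer_params(par[1], 10^par[2])
    eval_mse(ctx, posterior_tau(tau, op))$mse
  }
  grid <- expand.grid(mu = mu_grid, loglam = log10(lambda_grid))
  vals <- apply(grid, 1, obj)
  best <- as.numeric(grid[which.min(vals), ])
  if (sd(log(tau)) < 1e-12) {
    warning("flat objective: all time constants identical; returning grid optimum")
    par <- best
  } else {
    opt <- optim(best, obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-10, maxit = 500))
    par <- opt$par
  }
  op <- observer_params(par[1], 10^par[2])
  tau_hat <- posterior_tau(tau, op)
  ev <- eval_mse(ctx, tau_hat)
  new_model_fit("static", list(mu_prior = op$mu_prior, lambda = op$lambda),
                ev$mse, tau_hat, ev$believed, nrow(session$trials),
                list(gains_mode = gains_mode))
}

# Dynamic-prior trajectory of per-trial estimates: the prior mean is
# updated every trial as mu_i = (1 - k) mu_{i-1} + k phi_i with
# k = lambda^2 / (lambda^2 + 1) and mu_1 = phi_1 (so the estimate on the
# first trial is the true first time constant); the trial-i estimate is
# exp(mu_i), the posterior mean given the previous trial's prior.
dynamic_prior_path <- function(phi, lambda) {
  k <- lambda^2 / (lambda^2 + 1)
  n <- length(phi)
  if (n == 1L) return(phi)
  c(phi[1], as.numeric(stats::filter(k * phi[-1], 1 - k,
                                     method = "recursive", init = phi[1])))
}

#' Fit the dynamic-prior Bayesian observer
#'
#' Single free parameter \eqn{\lambda}; the prior mean over \eqn{\phi}
#' evolves across a participant's trials as a weighted average of the
#' previous prior and the current measurement,
#' \eqn{\mu_{prior,i} = (1-k)\mu_{prior,i-1} + k\,\phi_i} with
#' \eqn{k = \lambda^2/(\lambda^2+1)}, initialised at the first trial's
#' \eqn{\phi}. The same objective and deterministic grid-plus-refinement
#' contract as [fit_static_prior()] applies.
#'
#' @inheritParams fit_static_prior
#' @param lambda_grid Optional log-spaced grid override.
#' @return A `model_fit` of kind `"dynamic"` with `params$lambda` and
#'   `params$prior_weight` (\eqn{1-k}); the per-trial prior means are in
#'   `$prior_mean`.
#' @export
fit_dynamic_prior <- function(session, gains, gains_mode = "yoked",
                              lambda_grid = 10^seq(-2, 1, length.out = 25)) {
  stopifnot(inherits(session, "steer_session"))
  trials <- session$trials
  ord_ok <- all(unlist(tapply(trials$trial, trials$participant,
                              function(x) !is.unsorted(x))))
  if (!ord_ok) stop("trials must be in chronological order within participant")
  ctx <- fit_context(session, gains, gains_mode)
  phi_by_p <- split(log(trials$tau), trials$participant)
  tau_hat_for <- function(lambda) {
    mu <- unsplit(lapply(phi_by_p, dynamic_prior_path, lambda = lambda),
                  trials$participant)
    exp(mu)
  }
  obj <- function(loglam) eval_mse(ctx, tau_hat_for(10^loglam))$mse
  gv <- vapply(log10(lambda_grid), obj, numeric(1))
  i <- which.min(gv)
  lo <- log10(lambda_grid[max(1, i - 1)])
  hi <- log10(lambda_grid[min(length(lambda_grid), i + 1)])
  opt <- if (lo < hi) optimize(obj, c(lo, hi), tol = 1e-6) else
    list(minimum = log10(lambda_grid[i]))
  lambda <- 10^opt$minimum
  k <- lambda^2 / (lambda^2 + 1)
  tau_hat <- tau_hat_for(lambda)
  ev <- eval_mse(ctx, tau_hat)
  new_model_fit("dynamic", list(lambda = lambda, prior_weight = 1 - k),
                ev$mse, tau_hat, ev$believed, nrow(trials),
                list(prior_mean = log(tau_hat), gains_mode = gains_mode))
}

#' Fit the sensory-independent (fixed estimate) model
#'
#' One free parameter: a single time constant \eqn{\hat\tau} used for every
#' trial of the condition. Deterministic log-spaced grid over
#' `tau_range` followed by golden-section refinement.
#'
#' @inheritParams fit_static_prior
#' @param tau_range Search range in seconds (default 0.1--30).
#' @return A `model_fit` of kind `"fixed"` with `params$tau_fixed`.
#' @export
fit_fixed_tau <- function(session, gains, gains_mode = "yoked",
                          tau_range = c(0.1, 30)) {
  stopifnot(inherits(session, "steer_session"))
  ctx <- fit_context(session, gains, gains_mode)
  n <- nrow(session$trials)
  obj <- function(logtau) eval_mse(ctx, rep(exp(logtau), n))$mse
  grid <- seq(log(tau_range[1]), log(tau_range[2]), length.out = 25)
  gv <- vapply(grid, obj, numeric(1))
  i <- which.min(gv)
  opt <- optimize(obj, c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)]),
                  tol = 1e-8)
  tau_fixed <- exp(opt$minimum)
  tau_hat <- rep(tau_fixed, n)
  ev <- eval_mse(ctx, tau_hat)
  new_model_fit("fixed", list(tau_fixed = tau_fixed), ev$mse, tau_hat,
                ev$believed, n, list(gains_mode = gains_mode))
}

#' Carry-over time-constant estimates for vestibular trials
#'
#' Assigns each vestibular trial the time constant of the most recent
#' preceding visual or combined trial of the same participant -- either the
#' true value (`variant = "true_tau"`) or the static-prior posterior
#' estimate of it (`variant = "posterior"`). Vestibular trials with no
#' predecessor are dropped.
#'
#' @param session A full interleaved `steer_session`.
#' @param variant `"true_tau"` or `"posterior"`.
#' @param posterior_params Optional [observer_params()] for the posterior
#'   variant; when `NULL`, a static prior is fitted on the pooled
#'   visual+combined trials.
#' @return A data.frame with one row per evaluable vestibular trial:
#'   `participant`, `trial`, `row` (its row in `session$trials`), `tau`,
#'   `tau_hat`.
#' @export
carryover_estimate <- function(session,
                               variant = c("true_tau", "posterior"),
                               posterior_params = NULL) {
  stopifnot(inherits(session, "steer_session"))
  variant <- match.arg(variant)
  trials <- session$trials
  if (!any(trials$condition %in% c("visual", "combined")))
    stop("carry-over requires visual or combined trials in the dataset")
  if (variant == "posterior" && is.null(posterior_params)) {
    vc <- subset_session(session, condition = c("visual", "combined"))
    fit <- fit_static_prior(vc, response_gain(vc$trials))
    posterior_params <- observer_params(fit$params$mu_prior,
                                        fit$params$lambda)
  }
  out <- lapply(split(seq_len(nrow(trials)), trials$participant), function(ix) {
    ix <- ix[order(trials$trial[ix])]
    cond <- trials$condition[ix]
    pred <- rep(NA_integer_, length(ix))
    last_vc <- NA_integer_
    for (j in seq_along(ix)) {
      if (cond[j] == "vestibular") pred[j] <- last_vc else last_vc <- ix[j]
    }
    keep <- cond == "vestibular" & !is.na(pred)
    if (!any(keep)) return(NULL)
    tau_pred <- trials$tau[pred[keep]]
    data.frame(participant = trials$participant[ix[keep]],
               trial = trials$trial[ix[keep]], row = ix[keep],
               tau = trials$tau[ix[keep]],
               tau_hat = if (variant == "true_tau") tau_pred else
                 posterior_tau(tau_pred, posterior_params))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Fit the sensory feedback (switch-distance) control model
#'
#' A non-inferential controller: for each trial the actual angular input is
#' kept while the linear input is replaced by full forward drive until the
#' simulated position (under the trial's true dynamics) first comes within a
#' fixed switch distance of the gain-scaled target, then full braking until
#' the speed falls below the stopping threshold. The switch distance
#' (`switch_mean`) minimises the mean squared distance between predicted and
#' actual stops; `switch_sd` is the maximum-likelihood normal SD of the
#' per-trial best switch distances. Trials that never approach within the
#' switch distance stop at their closest approach and are flagged.
#'
#' @inheritParams fit_static_prior
#' @param d_range Search range for the switch distance in metres; default
#'   0.01 m to the largest target distance.
#' @return A `model_fit` of kind `"switch"` with `params$switch_mean` and
#'   `params$switch_sd`; predicted stops in `$believed` (same column names
#'   as [believed_stops()] so validation applies unchanged), per-trial best
#'   distances in `$d_best`, unreached flags in `$flagged`.
#' @export
fit_switch_model <- function(session, gains, d_range = NULL) {
  stopifnot(inherits(session, "steer_session"))
  trials <- session$trials
  cfg <- session$config$sim
  aim <- aim_points(trials, gains)
  dyn <- lapply(trials$tau, make_dynamics, cfg = cfg)
  uw <- lapply(session$traces, `[[`, "u_w")
  n_max <- as.integer(round(4 * cfg$T_nominal / cfg$dt))
  rollout <- function(i, d) {
    cpp_switch_rollout(uw[[i]], dyn[[i]]$alpha, dyn[[i]]$beta_v,
                       dyn[[i]]$beta_w, cfg$dt, cfg$v_stop,
                       aim$x[i], aim$y[i], d, n_max)
  }
  n <- nrow(trials)
  sqdist <- function(stop, i)
    (stop$stop_x - trials$stop_x[i])^2 + (stop$stop_y - trials$stop_y[i])^2
  obj <- function(d) mean(vapply(seq_len(n),
                                 function(i) sqdist(rollout(i, d), i),
                                 numeric(1)))
  if (is.null(d_range)) d_range <- c(0.01, max(trials$target_r))
  opt <- optimize(obj, d_range, tol = 1e-4)
  d_mean <- opt$minimum
  d_best <- vapply(seq_len(n), function(i)
    optimize(function(d) sqdist(rollout(i, d), i), d_range, tol = 1e-3)$minimum,
    numeric(1))
  preds <- lapply(seq_len(n), rollout, d = d_mean)
  px <- vapply(preds, `[[`, 0, "stop_x")
  py <- vapply(preds, `[[`, 0, "stop_y")
  flagged <- !vapply(preds, `[[`, TRUE, "reached")
  believed <- data.frame(bel_x = px, bel_y = py,
                         bel_r = sqrt(px^2 + py^2),
                         bel_theta = atan2(py, px))
  new_model_fit("switch",
                list(switch_mean = d_mean,
                     switch_sd = sqrt(mean((d_best - mean(d_best))^2))),
                opt$objective, trials$tau, believed, n,
                list(d_best = d_best, flagged = flagged))
}

#' Validate a model by its subjective residual errors
#'
#' Computes the subjective residual errors (believed stopping positions
#' substituted into the residual-error definition, with the same response
#' gains as the actual data) and their Pearson correlations with the time
#' constant, per participant. A good internal model leaves the subjective
#' residuals uncorrelated with the time constant even when the actual
#' residuals are strongly correlated. When several participants are
#' present, the absolute actual and subjective correlations are compared
#' with a paired Wilcoxon signed-rank test; model-implied correlations are
#' flagged significant at the multiple-comparison-adjusted level p = 0.0085.
#'
#' @param session A `steer_session` (one condition).
#' @param believed A data.frame of believed stops (`bel_r`, `bel_theta`),
#'   e.g. a `model_fit`'s `$believed` or the output of [believed_stops()].
#' @param gains The condition's [response_gain()] estimate.
#' @return A list with `per_participant` (data.frame of actual and
#'   subjective correlations per component), means across participants,
#'   Wilcoxon p-values (`NA` with a single participant), and the
#'   significance threshold used for model-implied correlations.
#' @export
validate_subjective_residuals <- function(session, believed, gains) {
  stopifnot(inherits(session, "steer_session"),
            nrow(believed) == nrow(session$trials))
  trials <- session$trials
  eps_act <- residual_errors(trials, gains)
  bel_tr <- trials
  bel_tr$stop_r <- believed$bel_r
  bel_tr$stop_theta <- believed$bel_theta
  eps_sub <- residual_errors(bel_tr, gains)
  per <- do.call(rbind, lapply(split(seq_len(nrow(trials)),
                                     trials$participant), function(ix) {
    data.frame(
      participant = trials$participant[ix[1]],
      r_actual_radial = cor(eps_act$eps_r[ix], trials$tau[ix]),
      r_subj_radial = cor(eps_sub$eps_r[ix], trials$tau[ix]),
      p_subj_radial = cor.test(eps_sub$eps_r[ix], trials$tau[ix])$p.value,
      r_actual_angular = cor(eps_act$eps_theta[ix], trials$tau[ix]),
      r_subj_angular = cor(eps_sub$eps_theta[ix], trials$tau[ix]),
      p_subj_angular = cor.test(eps_sub$eps_theta[ix], trials$tau[ix])$p.value)
  }))
  rownames(per) <- NULL
  wp <- function(a, b) {
    if (nrow(per) < 2) return(NA_real_)
    if (all(abs(abs(a) - abs(b)) < 1e-12)) return(1)
    wilcox.test(abs(a), abs(b), paired = TRUE, exact = FALSE)$p.value
  }
  list(per_participant = per,
       mean_actual = c(radial = mean(per$r_actual_radial),
                       angular = mean(per$r_actual_angular)),
       mean_subjective = c(radial = mean(per$r_subj_radial),
                           angular = mean(per$r_subj_angular)),
       wilcoxon_p = c(radial = wp(per$r_actual_radial, per$r_subj_radial),
                      angular = wp(per$r_actual_angular, per$r_subj_angular)),
       alpha_model = 0.0085)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples a per-participant statistic with replacement and returns the
#' percentile confidence interval of a summary of it (used for
#' parameter-difference tests across participants).
#'
#' @param x Numeric vector (one value per participant).
#' @param statistic Function summarising a resample (default [mean()]).
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional integer seed.
#' @return Named numeric vector with `lower`, `upper` and `estimate`.
#' @export
bootstrap_ci <- function(x, statistic = mean, n_boot = 2000, conf = 0.95,
                         seed = NULL) {
  stopifnot(length(x) >= 2, n_boot >= 100, conf > 0, conf < 1)
  if (!is.null(seed)) set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i)
    statistic(x[sample.int(length(x), replace = TRUE)]), numeric(1))
  qs <- quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  c(lower = qs[1], upper = qs[2], estimate = statistic(x))
}

#' Compare fitted models by their subjective-residual correlations
#'
#' Tabulates per-model mean subjective-residual correlations and objective
#' MSEs and tests, for every pair of models, whether the per-participant
#' subjective correlations differ (paired Student's t-test), separately for
#' the radial and angular components.
#'
#' @param reports Named list of validation reports from
#'   [validate_subjective_residuals()], one per model, computed on the same
#'   dataset.
#' @param mses Optional named numeric vector of objective MSEs per model.
#' @return A list with `summary` (one row per model) and `pairwise`
#'   (paired t-test p-values per model pair and component).
#' @export
compare_models <- function(reports, mses = NULL) {
  stopifnot(is.list(reports), length(reports) >= 2, !is.null(names(reports)))
  summary <- do.call(rbind, lapply(names(reports), function(m) {
    rp <- reports[[m]]
    data.frame(model = m,
               r_subj_radial = rp$mean_subjective[["radial"]],
               r_subj_angular = rp$mean_subjective[["angular"]],
               mse = if (!is.null(mses)) unname(mses[m]) else NA_real_)
  }))
  pairs <- utils::combn(names(reports), 2, simplify = FALSE)
  pairwise <- do.call(rbind, lapply(pairs, function(pr) {
    a <- reports[[pr[1]]]$per_participant
    b <- reports[[pr[2]]]$per_participant
    tt <- function(x, y) {
      if (length(x) < 2) return(NA_real_)
      if (isTRUE(all.equal(x, y))) return(1)
      t.test(x, y, paired = TRUE)$p.value
    }
    data.frame(model_a = pr[1], model_b = pr[2],
               p_radial = tt(a$r_subj_radial, b$r_subj_radial),
               p_angular = tt(a$r_subj_angular, b$r_subj_angular),
               mean_diff_radial = mean(a$r_subj_radial - b$r_subj_radial),
               mean_diff_angular = mean(a$r_subj_angular - b$r_subj_angular))
  }))
  list(summary = summary, pairwise = pairwise)
}
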