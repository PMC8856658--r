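# Dataset storage and the pipeline driver. A session is stored as a
# directory of plain-text files: trials.csv (one row per trial),
# traces.csv (long time-series table keyed by trial row), manifest.json
# (format version, seed, config echo). CSV dialect: RFC 4180, '.' decimal,
# UTF-8, full round-trip precision. Angles are stored in radians; degree
# conversion happens only at report boundaries.

SESSION_FORMAT_VERSION <- "1.0"

#' Write a session to disk
#'
#' @param session A `steer_session`.
#' @param path Directory to create (or overwrite) with `trials.csv`,
#'   `traces.csv` and `manifest.json`.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "steer_session"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  # doubles are serialised at 17 significant digits, enough for an exact
  # IEEE-754 round trip
  full_prec <- function(d) {
    d[] <- lapply(d, function(col)
      if (is.double(col)) sprintf("%.17g", col) else col)
    d
  }
  trials <- session$trials
  trials$row <- seq_len(nrow(trials))
  readr::write_csv(full_prec(trials), file.path(path, "trials.csv"))
  traces <- do.call(rbind, lapply(seq_along(session$traces), function(i)
    cbind(row = i, session$traces[[i]])))
  readr::write_csv(full_prec(traces), file.path(path, "traces.csv"))
  cfg <- session$config
  manifest <- list(
    format_version = SESSION_FORMAT_VERSION,
    package = "steerdyn",
    seed = session$seed,
    n_trials = nrow(trials),
    units = list(distance = "m", angle = "rad", time = "s"),
    config = list(
      n_participants = cfg$n_participants,
      trials_per_condition = cfg$trials_per_condition,
      timeout_factor = cfg$timeout_factor,
      walk = cfg$walk[c("tau_minus", "tau_plus", "tau_phi")],
      sim = unclass(cfg$sim),
      agents = lapply(cfg$agents, unclass)))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a session from disk
#'
#' Fails loudly on a format-version mismatch, on trial counts that do not
#' match the manifest (e.g. a truncated file), and on trials with no time
#' series.
#'
#' @param path Directory written by [write_session()].
#' @return A `steer_session`.
#' @export
read_session <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("not a session directory (no manifest.json): ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(manifest$format_version, SESSION_FORMAT_VERSION))
    stop("session format version ", manifest$format_version,
         " needs upgrading; this build reads version ", SESSION_FORMAT_VERSION)
  # base read.csv: its double parser is correctly rounded, so the
  # 17-digit serialisation round-trips bit-exactly
  trials <- utils::read.csv(file.path(path, "trials.csv"))
  if (nrow(trials) != manifest$n_trials)
    stop("trials.csv has ", nrow(trials), " rows but the manifest records ",
         manifest$n_trials, "; file is corrupt or truncated")
  traces_long <- utils::read.csv(file.path(path, "traces.csv"))
  tr_split <- split(traces_long[setdiff(names(traces_long), "row")],
                    factor(traces_long$row, levels = seq_len(nrow(trials))))
  missing <- which(vapply(tr_split, nrow, 0L) == 0L)
  if (length(missing))
    stop("missing time series for trial row(s): ",
         paste(head(missing, 5), collapse = ", "))
  cfgl <- manifest$config
  agents <- lapply(names(cfgl$agents), function(cd)
    do.call(agent_params, c(list(condition = cd),
                            cfgl$agents[[cd]][setdiff(names(cfgl$agents[[cd]]),
                                                      "condition")])))
  names(agents) <- names(cfgl$agents)
  cfg <- session_config(
    n_participants = cfgl$n_participants,
    trials_per_condition = cfgl$trials_per_condition,
    walk = do.call(walk_params, cfgl$walk),
    sim = do.call(sim_config, cfgl$sim),
    agents = agents,
    timeout_factor = cfgl$timeout_factor)
  trials$row <- NULL
  rownames(trials) <- NULL
  traces <- lapply(tr_split, function(d) { rownames(d) <- NULL; d })
  names(traces) <- NULL
  structure(list(trials = trials, traces = traces, config = cfg,
                 seed = manifest$seed),
            class = "steer_session")
}

# ---- pipeline -------------------------------------------------------------

pipeline_config_keys <- list(
  session = c("n_participants", "trials_per_condition", "timeout_factor"),
  walk = c("tau_minus", "tau_plus", "tau_phi"),
  sim = c("dt", "T_nominal", "x_cal", "theta_cal", "v_stop"),
  agents = c("vestibular", "visual", "combined"),
  analysis = c("tau_tolerance", "n_draws"),
  fitting = c("models"))

check_config_keys <- function(cfg) {
  bad <- setdiff(names(cfg), names(pipeline_config_keys))
  for (sec in intersect(names(cfg), setdiff(names(pipeline_config_keys), "agents")))
    bad <- c(bad, paste0(sec, ".",
                         setdiff(names(cfg[[sec]]), pipeline_config_keys[[sec]]),
                         recycle0 = TRUE))
  if (!is.null(cfg$agents))
    bad <- c(bad, paste0("agents.",
                         setdiff(names(cfg$agents), pipeline_config_keys$agents),
                         recycle0 = TRUE))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  invisible(cfg)
}

build_session_config <- function(cfg) {
  check_config_keys(cfg)
  walk <- do.call(walk_params, as.list(cfg$walk))
  sim <- do.call(sim_config, as.list(cfg$sim))
  agents <- lapply(stats::setNames(nm = c("vestibular", "visual", "combined")),
                   function(cd) {
    args <- c(list(condition = cd), as.list(cfg$agents[[cd]]))
    if (is.null(args$mu_prior)) args$mu_prior <- walk$mu_phi
    do.call(agent_params, args)
  })
  args <- as.list(cfg$session)
  do.call(session_config,
          c(args, list(walk = walk, sim = sim, agents = agents)))
}

#' Run a pipeline step
#'
#' A programmatic driver covering the whole workflow: `simulate` generates a
#' session and writes it under `out_dir/dataset`; `analyze` writes the
#' behavioural summary tables (gains, tertile gains, residual-error
#' correlations, interaction coefficients, no-adaptation null, joystick
#' summaries) under `out_dir/analysis`; `fit` fits the requested observer
#' models per participant and condition and writes `out_dir/fits/fits.csv`
#' plus a JSON manifest; `validate` writes the subjective-residual
#' validation table; `report` assembles whatever artifacts exist into
#' `out_dir/report.json` (with a warning for missing parts). Every artifact
#' is reproducible from `(config, seed)`.
#'
#' @param command One of `"simulate"`, `"analyze"`, `"fit"`, `"validate"`,
#'   `"report"`.
#' @param config `NULL` for defaults, a named list, or the path of a
#'   YAML/JSON config file with sections `session`, `walk`, `sim`,
#'   `agents`, `analysis`, `fitting`. Unknown keys are an error.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for `simulate`.
#' @param conditions Conditions to analyze/fit (default all three).
#' @return The primary artifact of the step, invisibly.
#' @export
run_pipeline <- function(command = c("simulate", "analyze", "fit",
                                     "validate", "report"),
                         config = NULL, out_dir = "steerdyn-out", seed = 1,
                         conditions = c("vestibular", "visual", "combined")) {
  command <- match.arg(command)
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  check_config_keys(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  message(sprintf("[steerdyn] %s (seed=%d, out=%s)", command, seed, out_dir))

  ds_dir <- file.path(out_dir, "dataset")
  if (command == "simulate") {
    scfg <- build_session_config(config)
    session <- generate_session(scfg, seed = seed)
    write_session(session, ds_dir)
    return(invisible(session))
  }

  session <- read_session(ds_dir)

  if (command == "analyze") {
    adir <- file.path(out_dir, "analysis")
    dir.create(adir, showWarnings = FALSE)
    acfg <- as.list(config$analysis)
    res <- list()
    for (cd in conditions) {
      ss <- subset_session(session, condition = cd)
      g <- response_gain(ss$trials)
      eps <- residual_errors(ss$trials, g)
      st_r <- tau_error_stats(eps$eps_r, ss$trials$tau)
      st_a <- tau_error_stats(eps$eps_theta, ss$trials$tau)
      ir <- interaction_regression(ss$trials)
      res$gains <- rbind(res$gains, data.frame(
        condition = cd, g_r = g$g_r, g_theta = g$g_theta,
        r2_r = g$r2_r, r2_theta = g$r2_theta,
        delta_r2_r = g$delta_r2_r, delta_r2_theta = g$delta_r2_theta))
      res$tertiles <- rbind(res$tertiles,
                            cbind(condition = cd, tertile_gains(ss$trials)))
      res$residual_tau <- rbind(res$residual_tau, data.frame(
        condition = cd, component = c("radial", "angular"),
        r = c(st_r$r, st_a$r), slope = c(st_r$slope, st_a$slope),
        p_value = c(st_r$p_value, st_a$p_value)))
      res$interaction <- rbind(res$interaction, data.frame(
        condition = cd, b_r = ir$b_r, a_r = ir$a_r,
        b_theta = ir$b_theta, a_theta = ir$a_theta))
      nn <- do.call(null_no_adaptation,
                    c(list(ss), acfg, list(seed = seed)))
      res$no_adaptation <- rbind(res$no_adaptation, data.frame(
        condition = cd, slope_r = nn$slope_r, slope_theta = nn$slope_theta,
        n_selected = nn$n_selected))
    }
    js <- joystick_summaries(session)
    res$joystick <- js$braking_tau
    for (nm in names(res))
      readr::write_csv(res[[nm]], file.path(adir, paste0(nm, ".csv")))
    return(invisible(res))
  }

  if (command %in% c("fit", "validate")) {
    models <- config$fitting$models
    if (is.null(models)) models <- "static"
    fdir <- file.path(out_dir, "fits")
    dir.create(fdir, showWarnings = FALSE)
    fits <- NULL
    valid <- NULL
    for (cd in conditions) {
      for (p in unique(session$trials$participant)) {
        ss <- subset_session(session, condition = cd, participant = p)
        g <- response_gain(ss$trials)
        for (m in models) {
          fit <- switch(m,
            static = fit_static_prior(ss, g),
            dynamic = fit_dynamic_prior(ss, g),
            fixed = fit_fixed_tau(ss, g),
            switch = fit_switch_model(ss, g),
            stop("unknown model kind: ", m))
          fits <- rbind(fits, data.frame(
            condition = cd, participant = p, model = m, mse = fit$mse,
            param = names(fit$params),
            value = unlist(fit$params, use.names = FALSE)))
          if (command == "validate") {
            rp <- validate_subjective_residuals(ss, fit$believed, g)
            valid <- rbind(valid, cbind(condition = cd, model = m,
                                        rp$per_participant))
          }
        }
      }
    }
    readr::write_csv(fits, file.path(fdir, "fits.csv"))
    jsonlite::write_json(
      list(models = models, seed = session$seed,
           package_version = as.character(utils::packageVersion("steerdyn"))),
      file.path(fdir, "fit_manifest.json"), auto_unbox = TRUE)
    if (command == "validate") {
      readr::write_csv(valid, file.path(fdir, "validation.csv"))
      return(invisible(valid))
    }
    return(invisible(fits))
  }

  # report
  parts <- list()
  for (f in c("analysis/gains.csv", "analysis/tertiles.csv",
              "analysis/residual_tau.csv", "analysis/interaction.csv",
              "analysis/no_adaptation.csv", "analysis/joystick.csv",
              "fits/fits.csv", "fits/validation.csv")) {
    fp <- file.path(out_dir, f)
    if (file.exists(fp))
      parts[[sub("\\.csv$", "", basename(f))]] <-
        utils::read.csv(fp)
  }
  if (!all(c("gains", "fits") %in% names(parts)))
    warning("partial report: run 'analyze' and 'fit' first for a full report")
  # report boundary: raw angles go out in degrees (gains are unitless)
  parts <- lapply(parts, function(d) {
    for (cl in intersect(names(d), c("target_theta", "stop_theta")))
      d[[cl]] <- d[[cl]] * 180 / pi
    d
  })
  report <- c(list(seed = session$seed,
                   n_trials = nrow(session$trials),
                   angle_unit = "deg"),
              parts)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
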