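#' Read and validate a run configuration
#'
#' YAML schema with four blocks:
#'
#' * `kinetics`: `k1`, `k2`, `k3` (rate constants), optional
#'   `distribution` (`[p2, p1, p0]`), `mab_mg_per_ml`, `molar_mass`,
#'   `excess`.
#' * `vessel`: either `template` (GST-1 / GST-2 / SUM, with optional
#'   `levels`, `rings`, `target_t_mix`) or `flow_map` (path to a JSON
#'   flow map); optional `speed_rpm`, `torque_Nm`, `impeller_diameter_m`.
#' * `feed`: `mode` (batch / constant-rate), `duration`,
#'   `stock_concentration`.
#' * `simulation`: `t_end`, `output_grid`, `seed`.
#'
#' Missing values fall back to the standard study condition (5 mg/mL mAb
#' at 150 kDa, 5x molar payload excess fed over 60 s, default rate
#' constants, GST-2 vessel, 300 s horizon).
#'
#' @param path YAML file path.
#' @return A validated `run_config` list with constructed model objects
#'   (`params`, `dist`, `feed`, `c_mab0`, optionally `network`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(config_error("config file not found: ", path))
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop(config_error("malformed YAML in ",
                                                        path, ": ",
                                                        conditionMessage(e))))
  if (!is.list(cfg)) stop(config_error("config must be a YAML mapping"))
  build_run_config(cfg, dir = dirname(path))
}

config_error <- function(...) {
  structure(class = c("conjmix_config_error", "error", "condition"),
            list(message = paste0(...), call = NULL))
}

build_run_config <- function(cfg, dir = ".") {
  kin <- cfg$kinetics %||% list()
  ves <- cfg$vessel %||% list()
  fee <- cfg$feed %||% list()
  sim <- cfg$simulation %||% list()

  ok <- function(expr, what) {
    tryCatch(expr, error = function(e)
      stop(config_error("invalid ", what, ": ", conditionMessage(e))))
  }
  params <- ok(kinetic_params(kin$k1 %||% 0.797, kin$k2 %||% 1.476,
                              kin$k3 %||% 0.00155), "kinetics block")
  dist <- if (is.null(kin$distribution)) activation_distribution() else
    ok(activation_distribution(kin$distribution[1L], kin$distribution[2L],
                               kin$distribution[3L]), "activation distribution")
  mab <- kin$mab_mg_per_ml %||% 5
  molar_mass <- kin$molar_mass %||% 150000
  excess <- kin$excess %||% 5
  c_mab0 <- ok(molar_from_mass(mab, molar_mass), "mAb concentration")

  duration <- fee$duration %||% 60
  feed <- ok(feed_schedule(total_payload = c_mab0 * excess,
                           duration = duration,
                           stock_concentration = fee$stock_concentration %||% 10),
             "feed block")

  network <- NULL; template <- NULL
  if (!is.null(ves$flow_map)) {
    fp <- ves$flow_map
    if (!file.exists(fp)) fp <- file.path(dir, ves$flow_map)
    if (!file.exists(fp)) stop(config_error("flow map not found: ", ves$flow_map))
    network <- ok(read_flow_map(fp), "flow map")
  } else {
    template <- ok(vessel_template(ves$template %||% "GST-2",
                                   levels = ves$levels %||% 4L,
                                   rings = ves$rings %||% 3L,
                                   target_t_mix = ves$target_t_mix,
                                   total_volume = ves$total_volume),
                   "vessel template")
  }

  list(params = params, dist = dist, feed = feed, c_mab0 = c_mab0,
       mab_mg_per_ml = mab, molar_mass = molar_mass, excess = excess,
       template = template, network = network,
       speed_rpm = ves$speed_rpm, torque_Nm = ves$torque_Nm,
       impeller_diameter_m = ves$impeller_diameter_m,
       re_anchor = ves$re_anchor, re_anchor_rpm = ves$re_anchor_rpm,
       t_end = sim$t_end %||% 300,
       output_grid = sim$output_grid %||% 0.1,
       seed = sim$seed %||% 1L,
       raw = cfg)
}

run_network_of <- function(config) {
  if (!is.null(config$network)) config$network
  else calibrated_vessel(config$template)
}

conservation_report <- function(traj) {
  feed <- attr(traj, "feed")
  c0 <- attr(traj, "c_mab0")
  mab_tot <- traj$A2 + traj$A1 + traj$A0 + traj$M1a + traj$M1b + traj$M2
  fed <- cumulative_fed(feed, traj$time)
  bound <- traj$M1a + traj$M1b + 2 * traj$M2
  drug_err <- abs(traj$D + traj$Dinact + bound - fed)
  list(mab_conservation_rel_err = if (c0 > 0) max(abs(mab_tot - c0)) / c0 else 0,
       drug_balance_rel_err = if (max(fed) > 0) max(drug_err) / max(fed) else 0)
}

#' Run a conjugation simulation from a configuration
#'
#' Runs the ideal-mixed 0D model and, when a vessel is configured, the
#' compartment-network model; writes the trajectory CSV(s) and a summary
#' JSON with final DAR, completion time and conservation checks.
#'
#' @param config a `run_config` (from [read_run_config()]) or a path to a
#'   YAML file.
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @param network_model also run the compartment-network model.
#' @return The summary list, invisibly when writing.
#' @export
cmd_simulate <- function(config, out_dir = NULL, network_model = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  tr0 <- simulate_0d(species_state(config$c_mab0, config$dist), config$params,
                     config$feed, t_end = config$t_end,
                     output_grid = config$output_grid)
  summary <- list(final_dar = tr0$dar[nrow(tr0)],
                  completion_time_s = completion_time(tr0, 0.01),
                  conservation = conservation_report(tr0))
  tr3 <- NULL
  if (network_model) {
    net <- run_network_of(config)
    straj <- simulate_reaction_network(net, config$params, config$c_mab0,
                                       config$feed, t_end = config$t_end,
                                       dist = config$dist)
    tr3 <- volume_average(straj)
    dd <- delta_dar(tr0, tr3)
    summary$network <- list(final_dar = tr3$dar[nrow(tr3)],
                            max_delta_dar = attr(dd, "max_delta"),
                            conservation = conservation_report(tr3))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trajectory_csv(tr0, file.path(out_dir, "trajectory_0d.csv"))
    if (!is.null(tr3))
      write_trajectory_csv(tr3, file.path(out_dir, "trajectory_network.csv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(summary))
  }
  summary
}

#' Compare the three study vessels against the ideal-mixed model
#'
#' Calibrates the GST-1, GST-2 and SUM templates to their target mixing
#' times, runs the configured conjugation in each, and reports the
#' maximum DAR deviation and convergence time per vessel alongside the
#' deviation ordering.
#'
#' @param config a `run_config` or YAML path.
#' @param out_dir output directory; `NULL` skips writing.
#' @param vessels template names to compare.
#' @return Report list with per-vessel metrics and the ordering by
#'   maximum DAR deviation.
#' @export
cmd_compare <- function(config, out_dir = NULL,
                        vessels = c("GST-1", "GST-2", "SUM")) {
  if (is.character(config)) config <- read_run_config(config)
  tr0 <- simulate_0d(species_state(config$c_mab0, config$dist), config$params,
                     config$feed, t_end = config$t_end,
                     output_grid = config$output_grid)
  per <- lapply(vessels, function(v) {
    net <- calibrated_vessel(vessel_template(v))
    tr3 <- volume_average(
      simulate_reaction_network(net, config$params, config$c_mab0,
                                config$feed, t_end = config$t_end,
                                dist = config$dist))
    dd <- delta_dar(tr0, tr3)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(as.data.frame(dd),
                       file.path(out_dir, paste0("delta_dar_", v, ".csv")),
                       row.names = FALSE)
    }
    list(vessel = v, target_t_mix_s = vessel_template(v)$target_t_mix,
         max_delta_dar = attr(dd, "max_delta"),
         t_max_s = attr(dd, "t_max"),
         convergence_time_s = attr(dd, "convergence_time"),
         final_dar = tr3$dar[nrow(tr3)])
  })
  names(per) <- vessels
  ord <- vessels[order(-vapply(per, `[[`, numeric(1), "max_delta_dar"))]
  report <- list(vessels = per, ordering_by_max_delta_dar = ord)
  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "compare_report.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(report))
  }
  report
}

#' Scale-up metrics from a configuration
#'
#' Computes the impeller Reynolds number (from diameter and fluid
#' properties, or rescaled linearly from an anchor value), power per
#' volume when a torque is given (omitted with a warning otherwise), the
#' characteristic reaction time at the configured mean concentrations,
#' and the mixing-regime classification against the vessel's target
#' mixing time.
#'
#' @param config a `run_config` or YAML path.
#' @param out_dir output directory; `NULL` skips writing.
#' @return Metrics list.
#' @export
cmd_metrics <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  m <- list()
  speed <- config$speed_rpm
  if (!is.null(speed)) {
    if (!is.null(config$re_anchor) && !is.null(config$re_anchor_rpm)) {
      m$reynolds <- reynolds_at_speed(config$re_anchor, config$re_anchor_rpm,
                                      speed)
    } else if (!is.null(config$impeller_diameter_m)) {
      m$reynolds <- reynolds_impeller(config$impeller_diameter_m, speed)
    }
    if (!is.null(config$torque_Nm)) {
      vol <- if (!is.null(config$template)) config$template$total_volume
             else sum(config$network$volumes)
      m$power_per_volume_W_m3 <- power_per_volume(config$torque_Nm, speed, vol)
    } else {
      warning("no torque given; P/V omitted")
    }
  }
  m$tau_reaction_s <- reaction_timescale(config$params$k1, config$c_mab0,
                                         config$feed$total_payload)
  t_mix <- if (!is.null(config$template)) config$template$target_t_mix
           else network_mixing_time(config$network)
  m$tau_mixing_s <- t_mix
  ts <- classify_regime(m$tau_reaction_s, t_mix)
  m$regime <- ts$regime
  m$timescale_ratio <- ts$ratio
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(m, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(m))
  }
  m
}

#' Tracer mixing-time study from a configuration
#'
#' Builds (and calibrates) the configured vessel, runs a tracer
#' injection, and reports the global mixing time at the 95 % and 99 %
#' criteria as JSON.
#'
#' @param config a `run_config` or YAML path.
#' @param out_dir output directory; `NULL` skips writing.
#' @param calibrate calibrate the template to its target mixing time
#'   first (default TRUE).
#' @return Report list.
#' @export
cmd_tracer <- function(config, out_dir = NULL, calibrate = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  net <- if (!is.null(config$network)) config$network
         else if (calibrate) calibrated_vessel(config$template)
         else build_template(config$template)
  report <- list(vessel = net$name,
                 mixing_time_95_s = network_mixing_time(net, 0.95),
                 mixing_time_99_s = network_mixing_time(net, 0.99),
                 criterion_convention = "global index, last crossing")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "mixing_report.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(report))
  }
  report
}

#' Fit rate constants to a time-course CSV
#'
#' @param data_csv long-format kinetic CSV (`time_s`, `species`,
#'   `value`).
#' @param config a `run_config` or YAML path supplying the experiment
#'   conditions (initial mAb, feed, distribution).
#' @param out_dir output directory; `NULL` skips writing.
#' @return The [fit_rate_constants()] result.
#' @export
cmd_fit <- function(data_csv, config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  data <- read_kinetic_csv(data_csv, c_mab0 = config$c_mab0,
                           feed = config$feed, dist = config$dist)
  fit <- fit_rate_constants(data, initial_guess = config$params)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(k1 = fit$params$k1, k2 = fit$params$k2, k3 = fit$params$k3,
           r_squared = fit$r_squared,
           ci = as.data.frame(fit$ci), at_bound = as.list(fit$at_bound)),
      file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA)
    return(invisible(fit))
  }
  fit
}

#' Generate synthetic datasets from a configuration
#'
#' Writes a synthetic kinetic time course (and, when a vessel is
#' configured, a synthetic probe trace) using the configured generating
#' parameters and seed.
#'
#' @param config a `run_config` or YAML path.
#' @param out_dir output directory.
#' @param noise_sd relative noise SD (default 0.02).
#' @return List with the generated objects, invisibly.
#' @export
cmd_generate <- function(config, out_dir, noise_sd = 0.02) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  data <- generate_kinetic_dataset(params = config$params, dist = config$dist,
                                   mab_mg_per_ml = config$mab_mg_per_ml,
                                   molar_mass = config$molar_mass,
                                   excess = config$excess,
                                   feed_duration = config$feed$duration,
                                   noise_sd = noise_sd, seed = config$seed)
  write_kinetic_csv(data, file.path(out_dir, "kinetic_timecourse.csv"))
  trace <- NULL
  if (!is.null(config$template) || !is.null(config$network)) {
    net <- run_network_of(config)
    trace <- generate_tracer_trace(net, t_end = 6 * (if (!is.null(config$template))
      config$template$target_t_mix else 30), noise_sd = noise_sd,
      seed = config$seed)
    write_probe_trace(trace, file.path(out_dir, "tracer_trace.csv"))
  }
  invisible(list(kinetic = data, trace = trace))
}
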