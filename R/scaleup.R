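#' Power input per liquid volume
#'
#' Classical scale-up parameter `P/V = 2*pi*N*M / V` from the stationary
#' impeller torque.
#'
#' @param torque stationary impeller torque (N m).
#' @param speed stirrer speed (rpm).
#' @param volume liquid volume (m^3), > 0.
#' @return Power per volume (W/m^3).
#' @examples
#' power_per_volume(0.014146, 400, 0.025)  # ~23.7 W/m^3
#' @export
power_per_volume <- function(torque, speed, volume) {
  if (any(volume <= 0)) stop("volume must be positive")
  if (any(torque < 0)) stop("torque must be non-negative")
  2 * pi * (speed / 60) * torque / volume
}

#' Impeller Reynolds number
#'
#' `Re_imp = rho * N * D^2 / mu` with N in revolutions per second;
#' strictly linear in the stirrer speed.
#'
#' @param diameter impeller diameter (m).
#' @param speed stirrer speed (rpm).
#' @param density fluid density (kg/m^3); default water + 10 % DMSO.
#' @param viscosity dynamic viscosity (kg/m/s); same default medium.
#' @return Dimensionless Reynolds number.
#' @export
reynolds_impeller <- function(diameter, speed, density = 1010.5,
                              viscosity = 0.00106) {
  if (any(viscosity <= 0)) stop("viscosity must be positive")
  stopifnot(diameter > 0, speed >= 0)
  density * (speed / 60) * diameter^2 / viscosity
}

#' Rescale a Reynolds number to another stirrer speed
#'
#' Since Re_imp is linear in speed, a value known at one anchor speed
#' determines it at any other speed of the same vessel and fluid.
#'
#' @param re_anchor Reynolds number at `speed_anchor`.
#' @param speed_anchor anchor stirrer speed (rpm), > 0.
#' @param speed target stirrer speed (rpm).
#' @return Reynolds number at `speed`.
#' @examples
#' reynolds_at_speed(22141, 60, 120)   # 44282
#' reynolds_at_speed(15765, 250, 400)  # 25224
#' @export
reynolds_at_speed <- function(re_anchor, speed_anchor, speed) {
  stopifnot(speed_anchor > 0, re_anchor >= 0, speed >= 0)
  re_anchor * speed / speed_anchor
}

#' Characteristic bimolecular reaction time
#'
#' `tau_R = 1 / (k * (c1 + c2))`: the time scale on which a bimolecular
#' reaction consumes its reactants at representative concentrations.
#'
#' @param rate_constant second-order rate constant (per mM per s), > 0.
#' @param c1,c2 representative concentrations of the two reactants (mM).
#' @return Reaction time scale (s).
#' @examples
#' reaction_timescale(0.797, 0.0333, 0.1667)  # ~6.27 s
#' @export
reaction_timescale <- function(rate_constant, c1, c2) {
  if (rate_constant <= 0) stop("rate constant must be positive")
  if (c1 + c2 <= 0) stop("concentrations must sum to a positive value")
  1 / (rate_constant * (c1 + c2))
}

#' Classify the mixing regime from reaction and mixing time scales
#'
#' A reaction much slower than the vessel homogenization can be treated
#' as ideal-mixed; when the reaction time approaches or falls below the
#' mixing time, local reactant depletion around the feed makes the
#' process mixing-sensitive. The boundary case is assigned conservatively
#' to mixing-sensitive.
#'
#' @param tau_reaction characteristic reaction time (s), > 0.
#' @param tau_mixing mixing time (s), > 0.
#' @param margin how many mixing times the reaction time must exceed to
#'   count as ideal-mixed (default 1).
#' @return A `timescale_pair`: list with `tau_reaction`, `tau_mixing`,
#'   `ratio` and `regime` (`"ideal-mixed"` or `"mixing-sensitive"`).
#' @examples
#' classify_regime(1000, 10)$regime   # ideal-mixed
#' classify_regime(6.27, 32.2)$regime # mixing-sensitive
#' @export
classify_regime <- function(tau_reaction, tau_mixing, margin = 1) {
  stopifnot(tau_reaction > 0, tau_mixing > 0, margin > 0)
  regime <- if (tau_reaction <= margin * tau_mixing)
    "mixing-sensitive" else "ideal-mixed"
  structure(list(tau_reaction = tau_reaction, tau_mixing = tau_mixing,
                 ratio = tau_reaction / tau_mixing, margin = margin,
                 regime = regime),
            class = "timescale_pair")
}

#' @export
print.timescale_pair <- function(x, ...) {
  cat("<timescale_pair> tau_R = ", format(x$tau_reaction, digits = 4),
      " s, tau_mix = ", format(x$tau_mixing, digits = 4),
      " s, ratio ", format(x$ratio, digits = 3), " -> ", x$regime, "\n",
      sep = "")
  invisible(x)
}

#' DAR deviation between ideal-mixed and spatially resolved models
#'
#' Pointwise absolute difference of the two DAR trajectories on a common
#' grid (linear interpolation), with the maximum deviation, the time of
#' the maximum, and the first time after feed end at which the deviation
#' stays below a tolerance permanently (convergence time).
#'
#' @param traj_0d `conj_trajectory` of the ideal-mixed model.
#' @param traj_3d `conj_trajectory` of the network model (volume
#'   averaged); same initial mAb concentration.
#' @param tolerance convergence tolerance on the DAR deviation (default
#'   0.005, about 0.25 % of the target DAR of 2).
#' @return A `delta_dar` object: data frame (`time`, `delta`) with
#'   attributes `max_delta`, `t_max`, `convergence_time`.
#' @export
delta_dar <- function(traj_0d, traj_3d, tolerance = 0.005) {
  c0a <- attr(traj_0d, "c_mab0"); c0b <- attr(traj_3d, "c_mab0")
  if (!is.null(c0a) && !is.null(c0b) &&
      abs(c0a - c0b) > 1e-9 * max(c0a, c0b, 1e-12))
    stop("trajectories have different initial mAb concentrations")
  t0 <- max(traj_0d$time[1L], traj_3d$time[1L])
  t1 <- min(traj_0d$time[nrow(traj_0d)], traj_3d$time[nrow(traj_3d)])
  grid <- sort(unique(c(traj_0d$time[traj_0d$time >= t0 & traj_0d$time <= t1],
                        traj_3d$time[traj_3d$time >= t0 & traj_3d$time <= t1])))
  d0 <- stats::approx(traj_0d$time, traj_0d$dar, xout = grid)$y
  d3 <- stats::approx(traj_3d$time, traj_3d$dar, xout = grid)$y
  delta <- abs(d0 - d3)
  imax <- which.max(delta)
  feed <- attr(traj_0d, "feed")
  t_feed_end <- if (!is.null(feed)) feed$duration else 0
  conv <- Inf
  after <- grid >= t_feed_end
  if (any(after)) {
    d_after <- delta[after]; g_after <- grid[after]
    above <- d_after >= tolerance
    conv <- if (!any(above)) g_after[1L]
            else if (above[length(above)]) Inf
            else g_after[max(which(above)) + 1L]
  }
  structure(data.frame(time = grid, delta = delta),
            max_delta = delta[imax], t_max = grid[imax],
            convergence_time = conv, tolerance = tolerance,
            class = c("delta_dar", "data.frame"))
}

#' One-factor-at-a-time scale-up parameter study
#'
#' Varies stirrer speed (emulated as a proportional scaling of all
#' exchange flows: for frozen-flow transport the mixing time scales as
#' 1/N), payload feed duration, and mAb concentration around a standard
#' condition, one factor at a time, and reports the DAR deviation between
#' the network model and the ideal-mixed 0D model for every run.
#'
#' @param network a calibrated `compartment_network` at the reference
#'   stirrer speed.
#' @param params a [kinetic_params()].
#' @param grid list with any of `speed_rpm`, `feed_duration_s`,
#'   `mab_mg_per_ml` (numeric vectors). Empty entries keep the standard
#'   value. The standard condition itself is always included.
#' @param standard list of the standard condition; defaults to 60 rpm,
#'   60 s feed, 5 mg/mL, 5x molar payload excess, 150 kDa mAb.
#' @param t_end simulation horizon (s); extended automatically for feeds
#'   longer than the default horizon.
#' @param output_grid reporting interval (s).
#' @return Data frame with columns `parameter`, `value`, `max_delta_dar`,
#'   `t_max_s`, `convergence_time_s`, `final_dar`.
#' @export
run_parameter_study <- function(network, params = kinetic_params(),
                                grid = list(),
                                standard = list(speed_rpm = 60,
                                                feed_duration_s = 60,
                                                mab_mg_per_ml = 5,
                                                excess = 5,
                                                molar_mass = 150000,
                                                stock_mM = 10),
                                t_end = 300, output_grid = 0.25) {
  runs <- data.frame(parameter = "standard",
                     value = NA_real_,
                     speed = standard$speed_rpm,
                     duration = standard$feed_duration_s,
                     mab = standard$mab_mg_per_ml)
  add <- function(runs, name, values, field) {
    for (v in values) {
      if (field == "speed" && v == standard$speed_rpm) next
      if (field == "duration" && v == standard$feed_duration_s) next
      if (field == "mab" && v == standard$mab_mg_per_ml) next
      row <- runs[1L, ]
      row$parameter <- name; row$value <- v; row[[field]] <- v
      runs <- rbind(runs, row)
    }
    runs
  }
  runs <- add(runs, "speed_rpm", grid$speed_rpm, "speed")
  runs <- add(runs, "feed_duration_s", grid$feed_duration_s, "duration")
  runs <- add(runs, "mab_mg_per_ml", grid$mab_mg_per_ml, "mab")

  res <- lapply(seq_len(nrow(runs)), function(i) {
    r <- runs[i, ]
    c_mab <- molar_from_mass(r$mab, standard$molar_mass)
    feed <- feed_schedule(total_payload = c_mab * standard$excess,
                          duration = r$duration,
                          stock_concentration = standard$stock_mM)
    horizon <- max(t_end, r$duration + t_end)
    net <- network
    net$flows <- net$flows * (r$speed / standard$speed_rpm)
    tr0 <- simulate_0d(species_state(c_mab), params, feed, horizon,
                       output_grid = output_grid)
    tr3 <- volume_average(
      simulate_reaction_network(net, params, c_mab, feed, t_end = horizon,
                                output_grid = output_grid))
    dd <- delta_dar(tr0, tr3)
    data.frame(parameter = r$parameter, value = r$value,
               max_delta_dar = attr(dd, "max_delta"),
               t_max_s = attr(dd, "t_max"),
               convergence_time_s = attr(dd, "convergence_time"),
               final_dar = tr3$dar[nrow(tr3)])
  })
  do.call(rbind, res)
}
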