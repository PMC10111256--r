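#' Kinetic rate constants for the DAR-2 conjugation model
#'
#' Container for the three rate constants of the site-specific DAR-2
#' conjugation reaction network: two consecutive bimolecular conjugation
#' steps (mAb + drug -> mono-conjugate, mono-conjugate + drug ->
#' bi-conjugate) and a parallel first-order payload inactivation ("drug
#' sink", e.g. maleimide hydrolysis).
#'
#' Default values are the calibrated constants for the site-specific
#' cysteine conjugation system the model was developed on.
#'
#' @param k1 second-order rate constant of the first conjugation step
#'   (per mM per s).
#' @param k2 second-order rate constant of the second conjugation step
#'   (per mM per s).
#' @param k3 first-order drug-inactivation rate constant (per s).
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params()
#' kinetic_params(k1 = 1, k2 = 2, k3 = 0)
#' @export
kinetic_params <- function(k1 = 0.797, k2 = 1.476, k3 = 0.00155) {
  stopifnot(is.numeric(k1), is.numeric(k2), is.numeric(k3),
            length(k1) == 1L, length(k2) == 1L, length(k3) == 1L)
  if (k1 < 0 || k2 < 0 || k3 < 0)
    stop("rate constants must be non-negative")
  structure(list(k1 = unname(k1), k2 = unname(k2), k3 = unname(k3)),
            class = "kinetic_params")
}

#' Cysteine activation distribution
#'
#' Fractions of antibody carrying two, one or zero conjugation-competent
#' (activated) cysteines after the functionalization step. Antibodies with
#' fewer than two activated sites cap the attainable DAR below the
#' theoretical value of 2.
#'
#' @param p2,p1,p0 fractions of mAb with two / one / zero activated
#'   cysteines; must be in \[0, 1\] and sum to 1.
#' @return An object of class `activation_distribution`.
#' @examples
#' activation_distribution(0.8859, 0.0860, 0.0281)
#' @export
activation_distribution <- function(p2 = 1, p1 = 0, p0 = 0) {
  p <- c(p2 = p2, p1 = p1, p0 = p0)
  if (any(p < 0) || any(p > 1))
    stop("activation fractions must lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-9)
    stop("activation fractions must sum to 1 (got ", format(sum(p)), ")")
  structure(as.list(p), class = "activation_distribution")
}

# Species order used throughout: unconjugated mAb with 2/1/0 activated
# cysteines, mono-conjugate with one remaining site (from A2), terminal
# mono-conjugate (from A1), bi-conjugate, free drug, inactivated drug.
species_names <- function() c("A2", "A1", "A0", "M1a", "M1b", "M2", "D", "Dinact")

#' Initial species state
#'
#' Builds the initial concentration vector for a conjugation simulation
#' from a total mAb concentration and an activation distribution. All
#' conjugate and drug species start at zero; drug enters via the feed.
#'
#' @param c_mab total mAb concentration (mM).
#' @param dist an [activation_distribution()]; the default puts all mAb in
#'   the doubly-activated pool (the 3-reaction model).
#' @return Named numeric vector over the eight model species (mM).
#' @export
species_state <- function(c_mab, dist = activation_distribution()) {
  stopifnot(is.numeric(c_mab), length(c_mab) == 1L, c_mab >= 0)
  if (!inherits(dist, "activation_distribution"))
    stop("`dist` must be an activation_distribution")
  c(A2 = c_mab * dist$p2, A1 = c_mab * dist$p1, A0 = c_mab * dist$p0,
    M1a = 0, M1b = 0, M2 = 0, D = 0, Dinact = 0)
}

#' Fed-batch payload addition schedule
#'
#' Describes how the payload (linker-drug) is added to the vessel: all at
#' once at t = 0 ("batch") or at constant rate over a feeding period
#' ("constant-rate" semibatch). `total_payload` is the vessel-basis
#' concentration the payload would reach if fully mixed and unreacted.
#'
#' @param total_payload final vessel-basis payload concentration (mM).
#' @param duration feeding duration (s); 0 selects batch mode.
#' @param mode `"batch"` or `"constant-rate"`; inferred from `duration`
#'   when omitted.
#' @param stock_concentration payload stock concentration (mM); used for
#'   volume-fraction bookkeeping, default 10 mM.
#' @return An object of class `feed_schedule`.
#' @examples
#' feed_schedule(total_payload = 0.1667, duration = 60)
#' feed_schedule(total_payload = 0.3333, duration = 0)  # batch
#' @export
feed_schedule <- function(total_payload, duration = 0,
                          mode = if (duration == 0) "batch" else "constant-rate",
                          stock_concentration = 10) {
  stopifnot(is.numeric(total_payload), is.numeric(duration),
            duration >= 0, total_payload >= 0, stock_concentration > 0)
  mode <- match.arg(mode, c("batch", "constant-rate"))
  if ((mode == "batch") != (duration == 0))
    stop("batch mode requires duration = 0 and vice versa")
  structure(list(mode = mode, duration = duration,
                 total_payload = total_payload,
                 stock_concentration = stock_concentration),
            class = "feed_schedule")
}

#' Cumulative payload fed at time t
#'
#' @param feed a [feed_schedule()].
#' @param t time (s), vectorized.
#' @return Cumulative fed payload (mM, vessel basis).
#' @export
cumulative_fed <- function(feed, t) {
  if (feed$mode == "batch") {
    ifelse(t >= 0, feed$total_payload, 0)
  } else {
    feed$total_payload * pmin(pmax(t, 0), feed$duration) / feed$duration
  }
}

#' Convert a mass concentration to molar concentration
#'
#' @param mass_conc mass concentration (mg/mL).
#' @param molar_mass molar mass (g/mol); 150,000 g/mol is a typical IgG.
#' @return Concentration in mM.
#' @examples
#' molar_from_mass(5, 150000)   # 0.0333 mM
#' @export
molar_from_mass <- function(mass_conc, molar_mass) {
  stopifnot(is.numeric(mass_conc), is.numeric(molar_mass))
  if (any(mass_conc < 0)) stop("mass concentration must be non-negative")
  if (any(molar_mass <= 0)) stop("molar mass must be positive")
  mass_conc / molar_mass * 1000
}

#' Payload volume fraction added to the vessel
#'
#' Volume of payload stock added relative to the vessel liquid volume,
#' assuming the stock is dosed to reach `excess` payload molecules per
#' antibody.
#'
#' @param mab_mg_per_ml mAb concentration (mg/mL).
#' @param molar_mass mAb molar mass (g/mol).
#' @param excess molar payload excess over mAb.
#' @param stock_mM payload stock concentration (mM).
#' @return Volume fraction in percent.
#' @examples
#' payload_volume_fraction(5, 150000, 5, 10)  # 1.67 %
#' @export
payload_volume_fraction <- function(mab_mg_per_ml, molar_mass = 150000,
                                    excess = 5, stock_mM = 10) {
  c_mab <- molar_from_mass(mab_mg_per_ml, molar_mass)
  100 * c_mab * excess / stock_mM
}

#' Mass-action reaction rates of the conjugation network
#'
#' Time derivatives of the eight model species under the DAR-2 conjugation
#' scheme: A2 and A1 conjugate with free drug at rate k1, the
#' intermediate mono-conjugate M1a conjugates its remaining site at rate
#' k2, and free drug is inactivated at rate k3. The feed source is not
#' included here; the simulators add it. The six mAb-species derivatives
#' sum to zero (antibody conservation).
#'
#' @param state named numeric vector over the model species (mM).
#' @param params a [kinetic_params()].
#' @return Named numeric vector of derivatives (mM/s).
#' @examples
#' st <- species_state(0.0333)
#' st["D"] <- 0.1667
#' reaction_rates(st, kinetic_params())
#' @export
reaction_rates <- function(state, params) {
  # tolerate solver excursions below zero up to ~100x the absolute tolerance
  if (any(state < -1e-8))
    stop("negative species concentration in rate evaluation")
  s <- pmax(state, 0)
  k1 <- params$k1; k2 <- params$k2; k3 <- params$k3
  D <- s[["D"]]
  r1a <- k1 * s[["A2"]] * D   # A2 + D -> M1a
  r1b <- k1 * s[["A1"]] * D   # A1 + D -> M1b
  r2  <- k2 * s[["M1a"]] * D  # M1a + D -> M2
  r3  <- k3 * D               # drug sink
  c(A2 = -r1a, A1 = -r1b, A0 = 0,
    M1a = r1a - r2, M1b = r1b, M2 = r2,
    D = -r1a - r1b - r2 - r3, Dinact = r3)
}

ode_rhs_0d <- function(t, y, parms) {
  dy <- reaction_rates(y, parms$params)
  dy[["D"]] <- dy[["D"]] + parms$feed_rate
  list(dy)
}

#' Simulate the ideal-mixed fed-batch conjugation reaction (0D model)
#'
#' Integrates the conjugation reaction network in a single well-mixed
#' volume with batch or constant-rate payload addition. Volume change from
#' payload addition is neglected (the added volume is under 2 % of the
#' vessel). Integration is piecewise over the feed and post-feed phases so
#' the feed-rate discontinuity never crosses a solver step.
#'
#' @param initial named species vector from [species_state()] (mM).
#' @param params a [kinetic_params()].
#' @param feed a [feed_schedule()].
#' @param t_end simulation horizon (s).
#' @param output_grid reporting interval (s), default 0.1.
#' @param times optional explicit output times (s); overrides
#'   `output_grid` (0 is prepended if absent).
#' @param rtol,atol solver tolerances.
#' @return A `conj_trajectory`: data frame with columns `time`, the eight
#'   species (mM), and `dar`, plus attributes `c_mab0`, `params`, `feed`.
#' @examples
#' tr <- simulate_0d(species_state(0.0333), kinetic_params(),
#'                   feed_schedule(0.1667, duration = 60), t_end = 300)
#' tail(tr$dar, 1)
#' @export
simulate_0d <- function(initial, params, feed, t_end = max(times),
                        output_grid = 0.1, times = NULL,
                        rtol = 1e-8, atol = 1e-10) {
  stopifnot(t_end > 0, output_grid > 0)
  if (!inherits(params, "kinetic_params")) stop("`params` must be kinetic_params")
  if (!inherits(feed, "feed_schedule")) stop("`feed` must be a feed_schedule")
  y0 <- initial[species_names()]
  if (anyNA(y0)) stop("`initial` must name all model species")
  if (feed$mode == "batch") y0[["D"]] <- y0[["D"]] + feed$total_payload

  if (is.null(times)) {
    times <- seq(0, t_end, by = output_grid)
    if (times[length(times)] < t_end) times <- c(times, t_end)
  } else {
    if (any(diff(times) <= 0)) stop("output times must be strictly increasing")
    if (times[1L] > 0) times <- c(0, times)
    t_end <- times[length(times)]
  }

  integrate_phase <- function(y, tt, feed_rate) {
    if (length(tt) < 2L) return(NULL)
    out <- deSolve::ode(y = y, times = tt, func = ode_rhs_0d,
                        parms = list(params = params, feed_rate = feed_rate),
                        method = "lsoda", rtol = rtol, atol = atol)
    if (attr(out, "istate")[1L] < 0) stop("ODE solver failed")
    out
  }

  if (feed$mode == "batch" || feed$duration >= t_end) {
    rate <- if (feed$mode == "batch") 0 else feed$total_payload / feed$duration
    out <- integrate_phase(y0, times, rate)
    res <- as.data.frame(out)
  } else {
    t_feed <- unique(c(times[times <= feed$duration], feed$duration))
    rate <- feed$total_payload / feed$duration
    out1 <- integrate_phase(y0, t_feed, rate)
    y_mid <- out1[nrow(out1), -1L]
    t_post <- unique(c(feed$duration, times[times > feed$duration]))
    out2 <- integrate_phase(unlist(y_mid), t_post, 0)
    res <- as.data.frame(rbind(out1[t_feed %in% times, , drop = FALSE],
                               out2[-1L, , drop = FALSE]))
  }
  names(res)[1L] <- "time"
  # clip solver round-off; anything more negative is a genuine failure
  sp <- species_names()
  neg <- vapply(res[sp], min, numeric(1))
  if (any(neg < -1e-8)) stop("negative state beyond tolerance")
  res[sp] <- lapply(res[sp], pmax, 0)
  c_mab0 <- sum(y0[c("A2", "A1", "A0", "M1a", "M1b", "M2")])
  res$dar <- if (c_mab0 > 0) (res$M1a + res$M1b + 2 * res$M2) / c_mab0 else 0
  structure(res, c_mab0 = c_mab0, params = params, feed = feed,
            class = c("conj_trajectory", "data.frame"))
}

#' Drug-to-antibody ratio of a species state
#'
#' DAR = (mono-conjugates + 2 x bi-conjugate) / total initial mAb.
#'
#' @param state named species vector (mM).
#' @param c_mab0 total initial mAb concentration (mM), > 0.
#' @return DAR (dimensionless, in \[0, 2\] for this chemistry).
#' @examples
#' st <- species_state(0.1)
#' st[["M2"]] <- 0.1; st[["A2"]] <- 0
#' dar(st, 0.1)  # 2
#' @export
dar <- function(state, c_mab0) {
  if (c_mab0 <= 0) stop("c_mab0 must be positive")
  (state[["M1a"]] + state[["M1b"]] + 2 * state[["M2"]]) / c_mab0
}

#' Time to conjugate the activated antibody pool
#'
#' First time at which the unconjugated activated mAb (A2 + A1) falls to a
#' given fraction of its initial value, with linear interpolation between
#' reported points. Formalizes "reaction complete" for a chosen residual.
#'
#' @param traj a `conj_trajectory` from [simulate_0d()] or a volume-averaged
#'   network trajectory.
#' @param residual_fraction residual fraction of activated mAb, in (0, 1).
#' @return Completion time (s), or `Inf` if the residual is never reached.
#' @export
completion_time <- function(traj, residual_fraction = 0.01) {
  stopifnot(residual_fraction > 0, residual_fraction < 1)
  if (nrow(traj) == 0L) stop("empty trajectory")
  act0 <- traj$A2[1L] + traj$A1[1L]
  if (act0 <= 0) return(0)
  frac <- (traj$A2 + traj$A1) / act0
  below <- frac <= residual_fraction
  if (!any(below)) return(Inf)
  i <- which(below)[1L]
  if (i == 1L) return(traj$time[1L])
  # linear interpolation across the crossing
  t0 <- traj$time[i - 1L]; t1 <- traj$time[i]
  f0 <- frac[i - 1L]; f1 <- frac[i]
  if (f0 == f1) return(t1)
  t0 + (f0 - residual_fraction) / (f0 - f1) * (t1 - t0)
}

#' @export
print.conj_trajectory <- function(x, ...) {
  cat("<conj_trajectory> ", nrow(x), " points, t in [",
      x$time[1L], ", ", x$time[nrow(x)], "] s, final DAR ",
      format(x$dar[nrow(x)], digits = 4), "\n", sep = "")
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' Columns: `time_s`, the eight species (mM) and `DAR`; one header row.
#'
#' @param traj a `conj_trajectory`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  out <- data.frame(time_s = traj$time, traj[species_names()],
                    DAR = traj$dar, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
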