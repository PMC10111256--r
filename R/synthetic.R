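#' Synthetic quenched-sample conjugation time course
#'
#' Generates a noisy species-fraction time course as a reversed-phase
#' chromatography assay would report it: the ideal-mixed 0D model is run
#' as ground truth, sampled at the requested times (quenching is taken as
#' perfect sampling at the nominal time), and multiplicative Gaussian
#' noise is applied to every value, truncated at zero. Relative noise
#' mimics chromatographic peak-area variability.
#'
#' @param params generating [kinetic_params()].
#' @param dist generating [activation_distribution()]; default is the
#'   calibrated distribution of the study antibody (88.59 / 8.60 / 2.81 %
#'   of mAb with two / one / zero activated cysteines).
#' @param mab_mg_per_ml mAb concentration (mg/mL), default 5.
#' @param molar_mass mAb molar mass (g/mol), default 150,000.
#' @param excess molar payload excess, default 5.
#' @param feed_duration payload feed duration (s); 0 for batch. Default
#'   60 s.
#' @param times sample times (s); default 20 samples over one hour,
#'   denser during the rise phase.
#' @param noise_sd relative noise SD (default 0.02); 0 gives the exact
#'   model values.
#' @param seed RNG seed for reproducibility.
#' @param include_drug also observe the free drug concentration (mM).
#' @return A [kinetic_dataset()] (fractional units) with the generating
#'   parameters stored as attribute `truth`.
#' @export
generate_kinetic_dataset <- function(params = kinetic_params(),
                                     dist = activation_distribution(0.8859, 0.0860, 0.0281),
                                     mab_mg_per_ml = 5, molar_mass = 150000,
                                     excess = 5, feed_duration = 60,
                                     times = default_sample_times(),
                                     noise_sd = 0.02, seed = 1L,
                                     include_drug = FALSE) {
  stopifnot(noise_sd >= 0, all(times > 0))
  if (any(diff(times) <= 0)) stop("sampling times must be strictly increasing")
  c_mab0 <- molar_from_mass(mab_mg_per_ml, molar_mass)
  feed <- feed_schedule(total_payload = c_mab0 * excess,
                        duration = feed_duration)
  tr <- simulate_0d(species_state(c_mab0, dist), params, feed, times = times)
  tr <- tr[match(times, tr$time), , drop = FALSE]
  obs <- data.frame(unconjugated = (tr$A2 + tr$A1 + tr$A0) / c_mab0,
                    mono = (tr$M1a + tr$M1b) / c_mab0,
                    bi = tr$M2 / c_mab0)
  if (include_drug) obs$drug <- tr$D
  if (noise_sd > 0) {
    set.seed(seed)
    noisy <- as.matrix(obs) *
      (1 + matrix(stats::rnorm(length(as.matrix(obs)), sd = noise_sd),
                  nrow = nrow(obs)))
    obs[] <- pmax(noisy, 0)
  }
  out <- kinetic_dataset(times, obs, c_mab0 = c_mab0, feed = feed,
                         dist = dist, units = "fraction",
                         noise_sd = noise_sd)
  attr(out, "truth") <- list(params = params, dist = dist, seed = seed)
  out
}

#' Default kinetic sampling times
#'
#' Twenty quench times over one hour, denser during the rise phase of the
#' conjugation (first five minutes) where the rate constants are
#' informed.
#'
#' @return Numeric vector of sample times (s).
#' @export
default_sample_times <- function() {
  c(5, 10, 20, 30, 45, 60, 80, 100, 130, 160, 200, 250, 300,
    420, 600, 900, 1500, 2100, 2800, 3600)
}

#' Synthetic conductivity probe trace
#'
#' Emulates an external conductivity measurement of a salt-spike mixing
#' experiment: a tracer is injected into the vessel's feed compartment,
#' the probe-compartment concentration is recorded, shifted by the tubing
#' dead time, and additive Gaussian noise (relative to the settled
#' signal) is applied.
#'
#' @param network a [compartment_network()].
#' @param t_end trace duration before the dead-time shift (s).
#' @param dead_time tubing transport delay (s).
#' @param noise_sd additive noise SD as a fraction of the settled signal.
#' @param injection_mass tracer amount (mol).
#' @param output_grid sampling interval (s).
#' @param seed RNG seed.
#' @return A [probe_trace()] with the noise-free trace as attribute
#'   `truth`.
#' @export
generate_tracer_trace <- function(network, t_end = 120, dead_time = 0,
                                  noise_sd = 0, injection_mass = 1e-3,
                                  output_grid = 0.1, seed = 1L) {
  stopifnot(noise_sd >= 0, t_end > 0)
  tr <- simulate_tracer(network, injection_mass = injection_mass,
                        t_end = t_end, output_grid = output_grid)
  sig <- tr$conc[, network$probe_index]
  times <- tr$times + dead_time
  if (noise_sd > 0) {
    set.seed(seed)
    sig_noisy <- sig + stats::rnorm(length(sig), sd = noise_sd * tr$c_inf)
  } else sig_noisy <- sig
  out <- probe_trace(times, sig_noisy, dead_time = dead_time)
  attr(out, "truth") <- probe_trace(times, sig, dead_time = dead_time)
  out
}
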