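#' Variance-based global mixing index
#'
#' Volume-weighted homogenization index
#' `1 - (1/V) * sum_i V_i * (c_i/c_inf - 1)^2`. The index equals 1 iff
#' the field is perfectly homogeneous; early after a concentrated
#' injection it can be strongly negative (the squared deviation is not
#' rooted), which is intentional: only the approach to 1 matters.
#'
#' @param concentrations per-compartment concentrations.
#' @param volumes per-compartment volumes (same length).
#' @param c_inf asymptotic volume-mean concentration, > 0.
#' @return Dimensionless index (at most 1).
#' @examples
#' mixing_index_global(c(1, 1), c(1, 1), 1)   # 1
#' mixing_index_global(c(2, 0), c(1, 1), 1)   # 0
#' @export
mixing_index_global <- function(concentrations, volumes, c_inf) {
  if (c_inf <= 0) stop("c_inf must be positive")
  if (length(concentrations) != length(volumes))
    stop("concentrations and volumes must have equal length")
  1 - sum(volumes * (concentrations / c_inf - 1)^2) / sum(volumes)
}

#' Mixing curve of a tracer simulation
#'
#' Evaluates the global mixing index at every output time of a tracer
#' trajectory.
#'
#' @param tracer a `tracer_trajectory` from [simulate_tracer()].
#' @return A `mixing_curve` data frame with columns `time` and `index`,
#'   with the asymptotic mean as attribute `c_inf`.
#' @export
mixing_curve <- function(tracer) {
  V <- tracer$network$volumes
  idx <- apply(tracer$conc, 1L, mixing_index_global,
               volumes = V, c_inf = tracer$c_inf)
  structure(data.frame(time = tracer$times, index = idx),
            c_inf = tracer$c_inf,
            class = c("mixing_curve", "data.frame"))
}

#' Criterion-based global mixing time
#'
#' Earliest time after which the mixing index stays at or above the
#' criterion (last-crossing convention, robust to transient
#' re-crossings), with linear interpolation between reported points.
#'
#' @param curve a `mixing_curve` (or data frame with `time` and `index`).
#' @param criterion homogenization criterion in (0, 1), default 0.95.
#' @return Mixing time (s); 0 if the curve starts above the criterion,
#'   `Inf` if it never settles above it.
#' @export
mixing_time_global <- function(curve, criterion = 0.95) {
  stopifnot(criterion > 0, criterion < 1)
  if (nrow(curve) == 0L) stop("empty mixing curve")
  idx <- curve$index; tt <- curve$time
  below <- idx < criterion
  if (!any(below)) return(0)
  if (below[length(below)]) return(Inf)
  i <- max(which(below))  # last point below criterion
  t0 <- tt[i]; t1 <- tt[i + 1L]
  y0 <- idx[i]; y1 <- idx[i + 1L]
  if (y1 == y0) return(t1)
  t0 + (criterion - y0) / (y1 - y0) * (t1 - t0)
}

#' Probe trace
#'
#' A local concentration or conductivity signal versus time, as produced
#' by an external conductivity loop in a salt-spike experiment. The dead
#' time is the transport delay through the tubing to the sensor.
#'
#' @param times sample times (s), strictly increasing.
#' @param signal probe signal (arbitrary units).
#' @param dead_time transport delay to the sensor (s), non-negative.
#' @return An object of class `probe_trace`.
#' @export
probe_trace <- function(times, signal, dead_time = 0) {
  stopifnot(length(times) == length(signal), dead_time >= 0)
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  structure(list(times = as.numeric(times), signal = as.numeric(signal),
                 dead_time = dead_time),
            class = "probe_trace")
}

#' Mixing time from a probe trace
#'
#' Subtracts the sensor dead time, then returns the earliest time after
#' which the signal stays within a two-sided band around its final value:
#' for a 95 % criterion the signal must remain within +/- 5 % of the
#' final value (last-crossing convention, linear interpolation).
#'
#' @param trace a [probe_trace()] (or list with `times`, `signal`,
#'   `dead_time`).
#' @param band criterion in (0, 1), e.g. 0.95; the band half-width is
#'   `1 - band`.
#' @param final_value the settled signal value; defaults to the last
#'   sample.
#' @return Mixing time (s), dead-time corrected.
#' @export
mixing_time_probe <- function(trace, band = 0.95,
                              final_value = trace$signal[length(trace$signal)]) {
  stopifnot(band > 0, band < 1)
  if (final_value <= 0) stop("final value must be positive")
  tt <- trace$times - (trace$dead_time %||% 0)
  keep <- tt >= 0
  tt <- tt[keep]; sig <- trace$signal[keep]
  if (length(tt) == 0L) stop("trace empty after dead-time correction")
  dev <- abs(sig / final_value - 1)
  tol <- 1 - band
  outside <- dev > tol
  if (!any(outside)) return(0)
  if (outside[length(outside)]) stop("trace never settles within the band")
  i <- max(which(outside))
  t0 <- tt[i]; t1 <- tt[i + 1L]
  d0 <- dev[i]; d1 <- dev[i + 1L]
  if (d0 == d1) return(t1)
  t0 + (d0 - tol) / (d0 - d1) * (t1 - t0)
}

#' Relative error between experimental and simulated mixing times
#'
#' @param experimental experimental value (s), > 0.
#' @param simulated simulated value (s).
#' @return Relative error in percent: `100 * |exp - sim| / exp`.
#' @examples
#' relative_error(49.0, 45.2)  # 7.8 %
#' @export
relative_error <- function(experimental, simulated) {
  if (any(experimental <= 0)) stop("experimental value must be positive")
  100 * abs(experimental - simulated) / experimental
}

#' Read a probe trace from CSV
#'
#' Expected columns: `time_s`, `signal`.
#'
#' @param path CSV file path.
#' @param dead_time sensor dead time (s).
#' @return A `probe_trace`.
#' @export
read_probe_trace <- function(path, dead_time = 0) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "signal") %in% names(d)))
    stop("trace CSV must have columns time_s, signal")
  probe_trace(d$time_s, d$signal, dead_time)
}

#' Write a probe trace to CSV
#'
#' @param trace a `probe_trace`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_probe_trace <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$times, signal = trace$signal),
                   path, row.names = FALSE)
  invisible(path)
}
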