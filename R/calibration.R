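#' Kinetic time-course dataset
#'
#' Observed conjugation time course: quenched samples analyzed for the
#' unconjugated, mono-conjugated and bi-conjugated antibody species
#' (optionally also free drug), expressed either as fractions of the
#' total antibody pool or in mM.
#'
#' @param times sample times (s), strictly increasing.
#' @param observations data frame with columns among `unconjugated`,
#'   `mono`, `bi`, `drug`; one row per sample time.
#' @param c_mab0 total initial mAb concentration (mM).
#' @param feed the [feed_schedule()] used in the experiment.
#' @param dist the [activation_distribution()] of the antibody pool.
#' @param units `"fraction"` (of `c_mab0`; drug still in mM) or `"mM"`.
#' @param noise_sd optional relative noise SD of the measurements.
#' @return An object of class `kinetic_dataset`.
#' @export
kinetic_dataset <- function(times, observations, c_mab0, feed,
                            dist = activation_distribution(),
                            units = c("fraction", "mM"), noise_sd = NA) {
  units <- match.arg(units)
  stopifnot(length(times) == nrow(observations), c_mab0 > 0)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  known <- c("unconjugated", "mono", "bi", "drug")
  if (!all(names(observations) %in% known))
    stop("observation columns must be among: ", paste(known, collapse = ", "))
  if (units == "fraction") {
    mab_cols <- intersect(names(observations), c("unconjugated", "mono", "bi"))
    tot <- rowSums(observations[mab_cols])
    # slack widens with the declared noise level of the measurements
    eps <- max(0.25, 5 * if (is.na(noise_sd)) 0 else noise_sd)
    if (any(observations[mab_cols] < -1e-9) || any(tot > 1 + eps))
      stop("fractional observations must lie in [0, 1] and sum to about 1")
  }
  structure(list(times = as.numeric(times),
                 observations = as.data.frame(observations),
                 c_mab0 = c_mab0, feed = feed, dist = dist,
                 units = units, noise_sd = noise_sd),
            class = "kinetic_dataset")
}

# model prediction of the observed columns at the dataset's sample times
predict_dataset <- function(params, data) {
  tr <- simulate_0d(species_state(data$c_mab0, data$dist), params, data$feed,
                    times = data$times)
  tr <- tr[match(data$times, tr$time), , drop = FALSE]
  scale <- if (data$units == "fraction") data$c_mab0 else 1
  pred <- data.frame(unconjugated = (tr$A2 + tr$A1 + tr$A0) / scale,
                     mono = (tr$M1a + tr$M1b) / scale,
                     bi = tr$M2 / scale,
                     drug = tr$D)
  pred[names(data$observations)]
}

#' Fit conjugation rate constants to a kinetic time course
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt) between the
#' ideal-mixed 0D model and an observed time course. Parameters are
#' fitted on the log scale, which enforces positivity; five log-spaced
#' starts around the initial guess guard against local minima and make
#' the fit deterministic given the data and guess. Each observed species
#' is weighted by the inverse of its observed maximum so species of
#' different magnitude contribute comparably.
#'
#' @param data a [kinetic_dataset()] with at least 6 time points spanning
#'   the rise phase.
#' @param initial_guess a [kinetic_params()] starting point.
#' @param fixed named logical vector over `k1`, `k2`, `k3`; fixed
#'   parameters are held at the guess value.
#' @param n_starts number of log-spaced multi-start guesses (default 5).
#' @return A `fit_result`: list with `params` (fitted
#'   [kinetic_params()]), `ci` (approximate 95 % intervals from the
#'   residual covariance), `r_squared`, `residuals`, `at_bound` flags,
#'   and the converged `nls.lm` object as `fit`.
#' @export
fit_rate_constants <- function(data, initial_guess = kinetic_params(),
                               fixed = c(k1 = FALSE, k2 = FALSE, k3 = FALSE),
                               n_starts = 5L) {
  if (!inherits(data, "kinetic_dataset")) stop("`data` must be a kinetic_dataset")
  if (length(data$times) < 6L)
    stop("need at least 6 time points to calibrate rate constants")
  if (data$feed$total_payload <= 0) stop("degenerate feed: no payload added")
  fixed <- fixed[c("k1", "k2", "k3")]
  free <- names(fixed)[!fixed]
  if (length(free) == 0L) stop("no free parameters requested")
  if ("k3" %in% free && !("drug" %in% names(data$observations))) {
    needed <- data$c_mab0 * (2 * data$dist$p2 + data$dist$p1)
    if (data$feed$total_payload > 20 * needed)
      warning("k3 is structurally unidentifiable: no free-drug ",
              "observations and saturating payload excess")
  }

  obs <- data$observations
  # per-species weights 1/max(observed), floored at 5 % of the overall
  # observation scale so a species that stays near zero (e.g. bi-conjugate
  # when k2 ~ 0) cannot dominate the objective with an unbounded weight
  obs_scale <- max(vapply(obs, function(x) max(abs(x)), numeric(1)), 1e-12)
  wts <- vapply(obs, function(x) 1 / max(max(abs(x)), 0.05 * obs_scale),
                numeric(1))
  obs_mat <- as.matrix(obs)
  guess <- unlist(initial_guess[c("k1", "k2", "k3")])
  lb <- log(1e-8); ub <- log(1e4)

  resid_fun <- function(theta) {
    k <- guess
    k[free] <- exp(theta)
    pred <- try(predict_dataset(kinetic_params(k[["k1"]], k[["k2"]], k[["k3"]]),
                                data), silent = TRUE)
    if (inherits(pred, "try-error"))
      return(rep(1e6, length(obs_mat)))
    as.numeric((as.matrix(pred) - obs_mat) %*% diag(wts, length(wts)))
  }

  start_factors <- 10^seq(-1, 1, length.out = n_starts)
  best <- NULL
  for (f in start_factors) {
    theta0 <- pmin(pmax(log(pmax(guess[free], 1e-8) * f), lb), ub)
    fit <- try(minpack.lm::nls.lm(
      par = theta0, fn = resid_fun, lower = rep(lb, length(free)),
      upper = rep(ub, length(free)),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("rate-constant fit failed to converge from any start")

  k_hat <- guess
  k_hat[free] <- exp(best$par)
  params <- kinetic_params(k_hat[["k1"]], k_hat[["k2"]], k_hat[["k3"]])
  at_bound <- stats::setNames(rep(FALSE, 3L), c("k1", "k2", "k3"))
  at_bound[free] <- best$par < lb + 1 | best$par > ub - 1

  # approximate 95% CI on the log scale from a heteroscedasticity-aware
  # sandwich covariance: the 1/max species weights do not model the
  # point-wise noise variance, so the plain residual covariance would be
  # overconfident under relative measurement noise. When the dataset
  # declares its relative noise SD the point variances are taken from the
  # model (sd * |prediction|); otherwise squared residuals stand in.
  ci <- matrix(NA_real_, 3L, 2L,
               dimnames = list(c("k1", "k2", "k3"), c("lower", "upper")))
  dof <- length(obs_mat) - length(free)
  cov_try <- try({
    r0 <- resid_fun(best$par)
    h <- 1e-5
    J <- vapply(seq_along(free), function(j) {
      tp <- best$par; tp[j] <- tp[j] + h
      tm <- best$par; tm[j] <- tm[j] - h
      (resid_fun(tp) - resid_fun(tm)) / (2 * h)
    }, numeric(length(r0)))
    if (!is.null(data$noise_sd) && !is.na(data$noise_sd) && data$noise_sd > 0) {
      pred0 <- predict_dataset(kinetic_params(k_hat[["k1"]], k_hat[["k2"]],
                                              k_hat[["k3"]]), data)
      sig <- as.numeric(abs(as.matrix(pred0)) %*% diag(wts, length(wts))) *
        data$noise_sd
      dfree <- length(r0) - length(free)
    } else {
      sig <- r0 * sqrt(length(r0) / max(dof, 1L))
      dfree <- max(dof, 1L)
    }
    A <- solve(crossprod(J))
    V <- A %*% crossprod(J * sig) %*% A
    list(se = sqrt(pmax(diag(V), 0)), dfree = dfree)
  }, silent = TRUE)
  if (!inherits(cov_try, "try-error")) {
    tq <- stats::qt(0.975, max(cov_try$dfree, 1L))
    ci[free, "lower"] <- exp(best$par - tq * cov_try$se)
    ci[free, "upper"] <- exp(best$par + tq * cov_try$se)
  }

  pred <- predict_dataset(params, data)
  structure(list(params = params, ci = ci,
                 r_squared = r_squared(pred, obs),
                 residuals = as.matrix(pred) - obs_mat,
                 at_bound = at_bound, free = free, fit = best),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> k1 = ", format(x$params$k1, digits = 5),
      ", k2 = ", format(x$params$k2, digits = 5),
      ", k3 = ", format(x$params$k3, digits = 5),
      " (R^2 = ", format(x$r_squared, digits = 4), ")\n", sep = "")
  if (any(x$at_bound))
    cat("  at bound: ", paste(names(x$at_bound)[x$at_bound], collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Activation distribution from the reaction end state
#'
#' Antibodies with zero activated cysteines never conjugate and those
#' with one stop at the mono-conjugate, so at full conversion the final
#' unconjugated / mono / bi fractions map directly onto the activation
#' distribution (p0, p1, p2).
#'
#' @param final_fractions numeric vector `c(unconjugated, mono, bi)` at
#'   reaction end; non-negative, summing to about 1 (renormalized).
#' @return An [activation_distribution()].
#' @examples
#' fit_activation_distribution(c(0.0281, 0.0860, 0.8859))
#' @export
fit_activation_distribution <- function(final_fractions) {
  f <- as.numeric(final_fractions)
  if (length(f) != 3L || any(f < 0))
    stop("need three non-negative fractions (unconjugated, mono, bi)")
  s <- sum(f)
  if (s <= 0 || abs(s - 1) > 0.05)
    stop("final fractions are not normalizable (sum = ", format(s), ")")
  f <- f / s
  activation_distribution(p2 = f[3L], p1 = f[2L], p0 = f[1L])
}

#' Coefficient of determination over all observed species jointly
#'
#' `1 - SS_res / SS_tot` with both sums taken over every observed value
#' of every species.
#'
#' @param model model predictions (vector, matrix or data frame).
#' @param observed observations, congruent with `model`; at least 3
#'   values.
#' @return R-squared (at most 1).
#' @export
r_squared <- function(model, observed) {
  m <- as.numeric(as.matrix(model))
  o <- as.numeric(as.matrix(observed))
  if (length(m) != length(o)) stop("model and observations must be congruent")
  if (length(o) < 3L) stop("need at least 3 observations")
  ss_tot <- sum((o - mean(o))^2)
  if (ss_tot == 0) stop("observations have zero total variance")
  1 - sum((o - m)^2) / ss_tot
}

#' Read a kinetic dataset from long-format CSV
#'
#' Expected columns: `time_s`, `species` (unconjugated / mono / bi /
#' drug), `value`, optional `sd`.
#'
#' @param path CSV file path.
#' @param c_mab0 total initial mAb concentration (mM).
#' @param feed the [feed_schedule()] of the run.
#' @param dist antibody [activation_distribution()].
#' @param units `"fraction"` or `"mM"`.
#' @return A `kinetic_dataset`.
#' @export
read_kinetic_csv <- function(path, c_mab0, feed,
                             dist = activation_distribution(),
                             units = "fraction") {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "species", "value") %in% names(d)))
    stop("dataset CSV must have columns time_s, species, value")
  wide <- stats::reshape(d[c("time_s", "species", "value")],
                         idvar = "time_s", timevar = "species",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide <- wide[order(wide$time_s), , drop = FALSE]
  kinetic_dataset(wide$time_s, wide[setdiff(names(wide), "time_s")],
                  c_mab0 = c_mab0, feed = feed, dist = dist, units = units)
}

#' Write a kinetic dataset to long-format CSV
#'
#' @param data a `kinetic_dataset`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_kinetic_csv <- function(data, path) {
  obs <- data$observations
  long <- data.frame(
    time_s = rep(data$times, times = ncol(obs)),
    species = rep(names(obs), each = length(data$times)),
    value = unlist(obs, use.names = FALSE))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
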