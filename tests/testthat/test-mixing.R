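test_that("global mixing index evaluates the variance formula", {
  expect_equal(mixing_index_global(c(1, 1, 1), c(2, 1, 1), 1), 1)
  expect_equal(mixing_index_global(c(2, 0), c(1, 1), 1), 0)
  expect_error(mixing_index_global(c(1), c(1), 0), "positive")
  expect_error(mixing_index_global(c(1, 2), c(1), 1), "equal length")
})

test_that("mixing index is invariant to uniform concentration rescaling", {
  set.seed(7)
  for (i in 1:20) {
    cvec <- stats::runif(6, 0, 2)
    v <- stats::runif(6, 0.5, 2)
    ci <- mean(cvec)
    s <- stats::runif(1, 0.1, 10)
    expect_equal(mixing_index_global(cvec, v, ci),
                 mixing_index_global(s * cvec, v, s * ci), tolerance = 1e-12)
  }
})

test_that("two-compartment mixing curve and times match the closed form", {
  V <- 1e-3; q <- 1e-4                  # 1 L each, 0.1 L/s
  net <- two_compartment(V, q)
  tr <- simulate_tracer(net, injection_mass = 2e-3, t_end = 20,
                        output_grid = 0.01)
  mc <- mixing_curve(tr)
  lam <- 2 * q / V
  expect_lt(max(abs(mc$index - (1 - exp(-2 * lam * mc$time)))), 1e-5)
  # t(0.95) = ln(20)/(2 lam), t(0.99) = ln(100)/(2 lam)
  expect_equal(mixing_time_global(mc, 0.95), log(20) / (2 * lam),
               tolerance = 0.005)
  expect_equal(mixing_time_global(mc, 0.99), log(100) / (2 * lam),
               tolerance = 0.005)
  expect_equal(mixing_time_global(mc, 0.95), 7.489, tolerance = 1e-3)
  expect_equal(mixing_time_global(mc, 0.99), 11.513, tolerance = 1e-3)
  # monotone in the criterion, and settled curves end within [0.999, 1]
  expect_gt(mixing_time_global(mc, 0.99), mixing_time_global(mc, 0.95))
  expect_gte(1, mc$index[nrow(mc)])
  expect_gte(mc$index[nrow(mc)], 0.999)
})

test_that("an already homogeneous curve has zero mixing time", {
  mc <- structure(data.frame(time = 0:10, index = rep(1, 11)),
                  class = c("mixing_curve", "data.frame"))
  expect_equal(mixing_time_global(mc), 0)
  mc$index <- rep(0.5, 11)
  expect_equal(mixing_time_global(mc), Inf)
})

test_that("probe mixing time inverts an exponential approach analytically", {
  tau <- 10
  tt <- seq(0, 120, by = 0.01)
  tr <- probe_trace(tt, 1 - exp(-tt / tau))
  # |signal/final - 1| = exp(-t/tau) = 0.05  =>  t = tau ln(20)
  expect_equal(mixing_time_probe(tr, 0.95, final_value = 1), tau * log(20),
               tolerance = 1e-3)
  expect_equal(mixing_time_probe(tr, 0.95, final_value = 1), 29.96,
               tolerance = 1e-3)
  # dead-time correction is a pure shift
  tr_delayed <- probe_trace(tt + 5, 1 - exp(-tt / tau), dead_time = 5)
  expect_equal(mixing_time_probe(tr_delayed, 0.95, final_value = 1),
               tau * log(20), tolerance = 1e-3)
  # a trace already at its final value settles immediately
  flat <- probe_trace(tt, rep(2, length(tt)))
  expect_equal(mixing_time_probe(flat, 0.95), 0)
  # a drifting trace never settles
  drift <- probe_trace(tt, 1 + 0.2 * tt)
  expect_error(mixing_time_probe(drift, 0.95, final_value = 1), "settle")
})

test_that("relative error reproduces the printed SUM validation value", {
  expect_equal(relative_error(49.0, 45.2), 7.755, tolerance = 1e-3)
  expect_equal(round(relative_error(49.0, 45.2), 1), 7.8)
  expect_equal(relative_error(10, 10), 0)
  expect_equal(relative_error(9.1, 8.1), 10.989, tolerance = 1e-3)
  expect_error(relative_error(0, 1), "positive")
})

test_that("probe traces round-trip through CSV", {
  tr <- probe_trace(seq(0, 5, 0.5), stats::runif(11), dead_time = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_probe_trace(tr, path)
  back <- read_probe_trace(path, dead_time = 2)
  expect_equal(back$times, tr$times)
  expect_equal(back$signal, tr$signal)
})
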