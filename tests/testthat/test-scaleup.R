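test_that("power per volume evaluates 2*pi*N*M/V", {
  expect_equal(power_per_volume(0, 100, 0.01), 0)
  expect_equal(power_per_volume(0.1, 60, 0.022), 2 * pi * 0.1 / 0.022)
  expect_equal(power_per_volume(0.1, 60, 0.022), 28.56, tolerance = 1e-3)
  # torque implied by the SUM's published power density
  expect_equal(power_per_volume(0.014146, 400, 0.025), 23.71, tolerance = 1e-3)
  expect_error(power_per_volume(0.1, 60, 0), "positive")
})

test_that("impeller Reynolds number is linear in speed", {
  expect_equal(reynolds_impeller(0.081, 0), 0)
  re60 <- reynolds_impeller(0.081, 60)
  expect_equal(reynolds_impeller(0.081, 120), 2 * re60)
  # anchor rescaling reproduces the published multi-speed values exactly
  expect_equal(reynolds_at_speed(22141, 60, 120), 44282)
  expect_equal(reynolds_at_speed(22141, 60, 80), 29521.33, tolerance = 1e-6)
  expect_equal(reynolds_at_speed(15765, 250, 400), 25224)
  expect_equal(reynolds_at_speed(15765, 250, 0), 0)
})

test_that("bimolecular reaction time scale follows 1/(k (c1 + c2))", {
  expect_equal(reaction_timescale(1, 0.5, 0.5), 1)
  expect_equal(reaction_timescale(0.797, 0.0333, 0.1667), 6.27,
               tolerance = 1e-3)
  expect_gt(reaction_timescale(0.1, 1, 1), reaction_timescale(10, 1, 1))
  expect_error(reaction_timescale(0, 1, 1), "positive")
  expect_error(reaction_timescale(1, 0, 0), "positive")
})

test_that("regime classification separates reaction- and mixing-limited cases", {
  expect_identical(classify_regime(1000, 10)$regime, "ideal-mixed")
  expect_identical(classify_regime(6.27, 32.2)$regime, "mixing-sensitive")
  # tie at margin 1 is assigned conservatively
  expect_identical(classify_regime(5, 5)$regime, "mixing-sensitive")
  expect_equal(classify_regime(10, 5)$ratio, 2)
})

test_that("identical trajectories give zero DAR deviation", {
  tr <- std_traj()
  dd <- delta_dar(tr, tr)
  expect_true(all(dd$delta == 0))
  expect_equal(attr(dd, "max_delta"), 0)
  expect_equal(attr(dd, "convergence_time"), 60)  # feed end
})

test_that("DAR deviation rejects incompatible initial concentrations", {
  tr <- std_traj()
  other <- simulate_0d(species_state(2 * std_cmab()), kinetic_params(),
                       std_feed(), t_end = 300, output_grid = 0.25)
  expect_error(delta_dar(tr, other), "initial mAb")
})

test_that("parameter study reproduces the feed, concentration and speed trends", {
  net <- calibrated_vessel(vessel_template("GST-2"))
  ps <- run_parameter_study(net,
                            grid = list(speed_rpm = 120,
                                        feed_duration_s = c(0, 300),
                                        mab_mg_per_ml = 10))
  std <- ps[ps$parameter == "standard", ]
  expect_equal(nrow(ps), 5L)
  # batch feeding deviates most, slow feeding least
  expect_gt(ps$max_delta_dar[ps$value %in% 0 & ps$parameter == "feed_duration_s"],
            std$max_delta_dar)
  expect_lt(ps$max_delta_dar[ps$value %in% 300 & ps$parameter == "feed_duration_s"],
            std$max_delta_dar)
  # faster stirring (stronger exchange) reduces the deviation
  expect_lt(ps$max_delta_dar[ps$parameter == "speed_rpm"], std$max_delta_dar)
  # doubling the mAb concentration increases it
  expect_gt(ps$max_delta_dar[ps$parameter == "mab_mg_per_ml"], std$max_delta_dar)
  # endpoint invariance: every run reaches the same final DAR
  expect_lt(diff(range(ps$final_dar)), 1e-3)
  expect_true(all(is.finite(ps$convergence_time_s)))
})
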