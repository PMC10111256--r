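# shared fixtures: the standard study condition and small analytic networks

std_cmab <- function() molar_from_mass(5, 150000)   # 0.0333 mM

std_feed <- function() feed_schedule(total_payload = std_cmab() * 5,
                                     duration = 60)

std_traj <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_0d(species_state(std_cmab()), kinetic_params(),
                            std_feed(), t_end = 300, output_grid = 0.25)
    cache
  }
})

# two equal compartments (volume V each) with symmetric exchange q:
# tracer relaxation rate 2q/V, mixing index 1 - exp(-4qt/V)
two_compartment <- function(V = 1e-3, q = 1e-4) {
  compartment_network(volumes = c(V, V),
                      flows = matrix(c(0, q, q, 0), 2, 2),
                      feed_index = 1L, probe_index = 2L,
                      name = "two-compartment")
}

expect_balanced <- function(net) {
  expect_true(all(abs(rowSums(net$flows) - colSums(net$flows)) <=
                    1e-12 * max(rowSums(net$flows), 1)))
}

conservation_errors <- function(traj) {
  c0 <- attr(traj, "c_mab0")
  feed <- attr(traj, "feed")
  mab <- traj$A2 + traj$A1 + traj$A0 + traj$M1a + traj$M1b + traj$M2
  fed <- cumulative_fed(feed, traj$time)
  drug <- traj$D + traj$Dinact + traj$M1a + traj$M1b + 2 * traj$M2
  list(mab = max(abs(mab - c0)) / c0,
       drug = if (max(fed) > 0) max(abs(drug - fed)) / max(fed) else 0)
}
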