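test_that("passive length constant reproduces the published 1581 um", {
  expect_equal(passive_length_constant(axon_geometry(radius_um = 5)),
               1581, tolerance = 2e-4)
  # square-root scaling in R_m and closed form at other radii
  g1 <- axon_geometry(radius_um = 5)
  g4 <- axon_geometry(radius_um = 5, r_m = 4 * g1$r_m)
  expect_equal(passive_length_constant(g4), 2 * passive_length_constant(g1))
  expect_equal(passive_length_constant(axon_geometry(radius_um = 20)),
               sqrt(8e3 * 20e-4 / 160) * 1e4)
})

test_that("passive steady-state profile matches the analytic cable solution", {
  geom <- axon_geometry(radius_um = 5)
  m <- passive_model(geom)
  st <- solve_rest(m)
  stim <- stimulus_train(1, amplitude_nA = 0.2, width_ms = 500)
  sim <- simulate_axon(m, stim, t_end_ms = 501, dt = 0.05, state = st)
  dv <- sim$state$v - st$v
  pred <- passive_profile_analytic(geom, 0.2)
  interior <- 3:(geom$n_comp - 2)
  expect_lt(max(abs(dv[interior] - pred[interior]) / pred[interior]), 0.02)
})

test_that("the resting model stays at rest without stimulation", {
  m <- axon_model("gh_block", pump = "constant", ipump_const = 1.4)
  st <- solve_rest(m)
  sim <- simulate_axon(m, NULL, t_end_ms = 1000, dt = 0.025, state = st)
  expect_equal(length(sim$spikes1$t_cross), 0)
  expect_lt(max(abs(sim$state$v - st$v)), 0.1)
  # spatially uniform rest
  expect_lt(diff(range(st$v)), 0.01)
})

test_that("a single pulse elicits exactly one propagating spike", {
  sim <- shared_fixture("single_spike")
  expect_equal(length(sim$spikes1$t_cross), 1)
  expect_equal(length(sim$spikes2$t_cross), 1)
  expect_gt(sim$spikes2$t_cross, sim$spikes1$t_cross)
  # the trace-based detector agrees with the online one
  cr <- detect_crossings(sim$trace)
  expect_equal(length(cr$site1), 1)
  expect_equal(cr$site1, sim$spikes1$t_cross, tolerance = 1e-6)
  expect_equal(cr$site2, sim$spikes2$t_cross, tolerance = 1e-6)
})

test_that("halving the time step changes the single-spike delay by < 1%", {
  rest <- shared_fixture("rest_gh")
  m <- axon_model("gh_block")
  d <- vapply(c(0.0125, 0.00625), function(dt) {
    sim <- simulate_axon(m, stimulus_train(5), t_end_ms = 100, dt = dt,
                         state = rest)
    (sim$spikes2$t_cross[1] - sim$spikes1$t_cross[1])
  }, 0)
  expect_lt(abs(d[1] - d[2]) / d[2], 0.01)
})

test_that("discretization is direction symmetric", {
  rest <- shared_fixture("rest_gh")
  m <- axon_model("gh_block")
  fwd <- simulate_axon(m, stimulus_train(5), t_end_ms = 120, state = rest)
  bwd <- simulate_axon(m, stimulus_train(5), t_end_ms = 120, state = rest,
                       stim_comp = m$geometry$n_comp)
  # backward propagation: site 2 leads, and the site-to-site delay mirrors
  d_fwd <- fwd$spikes2$t_cross[1] - fwd$spikes1$t_cross[1]
  d_bwd <- bwd$spikes1$t_cross[1] - bwd$spikes2$t_cross[1]
  expect_gt(d_bwd, 0)
  expect_lt(abs(d_fwd - d_bwd), 2 * fwd$dt)
})

test_that("single-spike delay scales approximately linearly with length", {
  m1 <- axon_model("gh_block")
  g2 <- axon_geometry(radius_um = m1$geometry$radius_um, length_cm = 2,
                      n_comp = 201)
  m2 <- axon_model("gh_block", geometry = g2)
  d <- vapply(list(m1, m2), function(m) {
    rest <- relax_to_rest(m, duration_s = 30)
    sim <- simulate_axon(m, stimulus_train(5), t_end_ms = 200, state = rest)
    sim$spikes2$t_cross[1] - sim$spikes1$t_cross[1]
  }, 0)
  expect_lt(abs(d[2] / d[1] - 2), 0.1) # within 5% per length doubling
})

test_that("excited-state conductance and kappa behave as expected", {
  sim <- shared_fixture("single_spike")
  pc <- spike_peak_conductance(sim)
  expect_equal(nrow(pc), 1)
  expect_gt(pc$g_total, 1) # strongly excited vs ~0.2 mS/cm2 at rest
  expect_equal(pc$r_total, 1 / pc$g_total)
  expect_lt(pc$kappa, 0.1) # excited-state resistance << resting
  # no spikes -> empty result
  quiet <- simulate_axon(axon_model("gh_block", pump = "constant",
                                    ipump_const = 1.4), NULL, t_end_ms = 50)
  expect_equal(nrow(spike_peak_conductance(quiet)), 0)
  # hand-checked values: leak only, and a fully open Na channel
  m <- axon_model("gh_block")
  fake <- sim
  gp <- matrix(0, 1, length(m$gates),
               dimnames = list(NULL, names(m$gates)))
  fake$spikes1$gates_peak <- gp
  expect_equal(spike_peak_conductance(fake)$g_total, 0.125)
  gp[1, c("Na.m", "Na.h")] <- 1
  fake$spikes1$gates_peak <- gp
  expect_equal(spike_peak_conductance(fake)$g_total, 14.125)
})

test_that("a numerical blow-up is reported with time and place", {
  m <- axon_model("gh_block")
  st <- solve_rest(m)
  st$v[] <- 300 # start beyond the guard; leak alone decays far too slowly
  st$gates[] <- 0
  expect_error(simulate_axon(m, NULL, t_end_ms = 10, state = st),
               "blow-up")
})

test_that("the pump carries about a third of the sodium current under
           sustained stimulation", {
  # drive at a high rate until the sodium balance equilibrates, then
  # compare time averages over a measurement segment
  m <- axon_model("gh_block")
  rest <- relax_to_rest(m)
  spin <- poisson_train(19, 250, seed = 13)
  s1 <- simulate_axon(m, spin, t_end_ms = 250e3 + 100, state = rest)
  meas <- poisson_train(19, 120, seed = 14)
  s2 <- simulate_axon(m, meas, t_end_ms = 120e3 + 100, state = s1$state)
  expect_equal(s2$mean_ipump, -s2$mean_ina / 3, tolerance = 0.1)
})
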