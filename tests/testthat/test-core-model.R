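test_that("gating steady states hit their published midpoints and limits", {
  expect_equal(gate_steady_state("Na.m", -48), 0.5)
  expect_equal(gate_steady_state("Na.h", -47), 0.5)
  expect_equal(gate_steady_state("Kd.m", -47), 0.5)
  expect_equal(gate_steady_state("A.m", -63), 0.5)
  expect_equal(gate_steady_state("A.h", -80), 0.5)
  expect_equal(gate_steady_state("Kd.m", 1e3), 1, tolerance = 1e-12)
  expect_equal(gate_steady_state("Kd.m", -1e3), 0, tolerance = 1e-12)
  expect_error(gate_steady_state("no_such_gate", -60), "unknown gate")
})

test_that("time constants match the published forms", {
  expect_equal(gate_time_constant("Na.h", -42), 10) # 10/cosh(0)
  expect_equal(gate_time_constant("h_ctrl.m", -100), 3700)
  expect_equal(gate_time_constant("h_DA.m", 0), 3800)
  expect_equal(gate_time_constant("A.h", -50), 50)
  # A-current activation tau saturates at 18 + 58 ms for V -> -Inf
  expect_equal(gate_time_constant("A.m", -1e4), 76, tolerance = 1e-10)
  # I_Ks is the I_Kd voltage dependence slowed 5000-fold
  v <- seq(-90, 0, by = 7)
  expect_equal(gate_time_constant("Ks.m", v), 5000 * gate_time_constant("Kd.m", v))
  expect_equal(gate_steady_state("Ks.m", v), gate_steady_state("Kd.m", v))
})

test_that("steady states stay in [0,1] and time constants positive on a grid", {
  v <- seq(-120, 60, by = 0.5)
  for (g in c("Na.m", "Na.h", "Kd.m", "A.m", "A.h", "h_ctrl.m", "h_DA.m",
              "Ks.m", "HHNa.m", "HHNa.h", "HHK.n")) {
    xi <- gate_steady_state(g, v)
    expect_true(all(xi >= 0 & xi <= 1), info = g)
    expect_true(all(gate_time_constant(g, v) > 0), info = g)
  }
})

test_that("opening/closing rates satisfy alpha + beta = 1/tau", {
  v <- seq(-100, 40, by = 11)
  for (g in c("Na.m", "Na.h", "A.m", "HHNa.m", "HHK.n")) {
    r <- gate_rates(g, v)
    expect_equal(r$alpha + r$beta, 1 / gate_time_constant(g, v),
                 tolerance = 1e-12, info = g)
  }
  # at the midpoint the two rates are equal
  r <- gate_rates("Na.m", -48)
  expect_equal(r$alpha, r$beta)
  expect_equal(r$alpha, 0.5 / gate_time_constant("Na.m", -48))
  # 1/tau_h(-42) = 0.1/ms
  r <- gate_rates("Na.h", -42)
  expect_equal(r$alpha + r$beta, 0.1)
})

test_that("single-gate relaxation matches the closed-form exponential", {
  # the integrator's per-step gate update is exponential Euler, which is
  # exact at frozen voltage; iterating it must track the closed form
  v <- -55
  x0 <- 0.9
  dt <- 0.025
  for (g in c("Na.h", "A.m", "Kd.m")) {
    tau <- gate_time_constant(g, v)
    xinf <- gate_steady_state(g, v)
    a <- exp(-dt / tau)
    x <- x0
    for (i in 1:400) x <- xinf + (x - xinf) * a
    expect_equal(x, gate_relax(g, v, x0, 400 * dt), tolerance = 1e-9, info = g)
    expect_lt(abs(x - gate_relax(g, v, x0, 10)) / gate_relax(g, v, x0, 10), 1e-6)
  }
})

test_that("channel current follows gbar m^p h^q (V - E)", {
  expect_equal(channel_current(-70, m = 0.3, h = 0.7, gbar = 3, erev = -70,
                               p = 4, q = 1), 0)
  expect_equal(channel_current(-20, m = 1, h = 1, gbar = 3, erev = -70,
                               p = 1, q = 1), 150)
  # Na example: 14 * 0.5^3 * 0.5 * (0 - 50) = -43.75
  expect_equal(channel_current(0, m = 0.5, h = 0.5, gbar = 14, erev = 50,
                               p = 3, q = 1), -43.75)
  expect_error(channel_current(0, m = -0.1, h = 1, gbar = 1, erev = 0),
               "negative gate")
})

test_that("pump current is a saturating sigmoid in intracellular sodium", {
  pp <- pump_spec()
  expect_equal(pump_current(78, pp), pp$i_max / 2)
  expect_equal(pump_current(1e4, pp), pp$i_max, tolerance = 1e-9)
  # quarter activation at Na_half - Na_S log(3)
  expect_equal(pump_current(78 - 2 * log(3), pp), pp$i_max / 4)
  na <- seq(40, 120, by = 2)
  expect_true(all(diff(pump_current(na, pp)) > 0))
  expect_true(all(pump_current(na, pp) > 0))
  expect_error(pump_current(-1, pp), "positive")
})

test_that("sodium balance is zero when the pump carries a third of I_Na", {
  pp <- pump_spec()
  expect_equal(sodium_balance_rate(-3, 1, pp), 0)
  expect_equal(sodium_balance_rate(0, 0, pp), 0)
  r1 <- sodium_balance_rate(-10, 1, pp)
  r2 <- sodium_balance_rate(-10, 1, pump_spec(alpha = 2 * pp$alpha))
  expect_equal(r1, 2 * r2)
  # influx (inward I_Na, pump off) raises [Na+]_in
  expect_gt(sodium_balance_rate(-5, 0, pp), 0)
})

test_that("sodium Nernst potential has slope 58 mV per decade and is
           scale invariant", {
  expect_equal(nernst_sodium(10, 100), 58)
  expect_equal(nernst_sodium(42, 42), 0)
  expect_equal(nernst_sodium(1, 100), 116)
  expect_equal(nernst_sodium(3 * 13, 3 * 479), nernst_sodium(13, 479))
  expect_error(nernst_sodium(-1, 100), "positive")
})

test_that("the bundled parameter fixture matches the implementation
           key for key", {
  pf <- yaml::read_yaml(system.file("extdata", "model_parameters.yaml",
                                    package = "axondelay"))
  # Table-1 values against the assembled variants
  m <- axon_model("control", geometry = axon_geometry(radius_um = 5))
  ch <- setNames(m$channels, vapply(m$channels, `[[`, "", "name"))
  expect_equal(ch$Na$gbar, pf$channels$Na$gbar)
  expect_true(ch$Na$dynamic_erev)
  expect_equal(ch$Kd$erev, pf$channels$Kd$erev)
  expect_equal(ch$Leak$gbar, pf$channels$Leak$gbar)
  expect_equal(ch$A$gbar, pf$channels$A$gbar)
  expect_equal(ch$h$gbar, pf$channels$h_ctrl$gbar)
  expect_equal(ch$h$erev, pf$channels$h_ctrl$erev)
  mda <- axon_model("da")
  hda <- mda$channels[[which(vapply(mda$channels, `[[`, "", "name") == "h")]]
  expect_equal(hda$gbar, pf$channels$h_DA$gbar)
  expect_equal(hda$erev, pf$channels$h_DA$erev)
  # Table-2 gate midpoints and slopes via the steady-state curves
  for (g in names(pf$gates)) {
    spec <- pf$gates[[g]]
    expect_equal(gate_steady_state(g, spec$v_half), 0.5, info = g)
    slope_num <- (gate_steady_state(g, spec$v_half + 0.01) -
                    gate_steady_state(g, spec$v_half - 0.01)) / 0.02
    sgn <- if (spec$kind == "activation") 1 else -1
    expect_equal(slope_num, sgn * 0.25 / spec$slope, tolerance = 1e-5,
                 info = g)
    if (!is.null(spec$tau_const))
      expect_equal(gate_time_constant(g, -60), spec$tau_const, info = g)
  }
  # pump constants
  pp <- pump_spec()
  expect_equal(pp$i_max, pf$pump$i_max)
  expect_equal(pp$na_half, pf$pump$na_half)
  expect_equal(pp$na_s, pf$pump$na_s)
  expect_equal(pp$alpha, pf$pump$alpha)
  expect_equal(pp$vol, pf$pump$vol_um3)
  # published passive geometry
  geom <- axon_geometry()
  expect_equal(geom$radius_um, pf$geometry$radius_um)
  expect_equal(geom$r_i, pf$geometry$r_i_ohm_cm)
  expect_equal(geom$n_comp, pf$geometry$n_comp)
})
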