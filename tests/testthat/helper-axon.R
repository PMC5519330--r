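# Shared simulation fixtures, computed lazily and cached for the session.
# The heavy protocol runs are reused across test files; everything is
# generated in code at fixed seeds.

.axon_cache <- new.env(parent = emptyenv())

shared_fixture <- function(name) {
  if (!is.null(.axon_cache[[name]])) return(.axon_cache[[name]])
  val <- switch(name,
    # settled resting state of the gh = 0 model (full silent pre-run)
    rest_gh = relax_to_rest(axon_model("gh_block")),
    # one propagated spike with a full-resolution trace
    single_spike = {
      sim <- simulate_axon(axon_model("gh_block"),
                           stimulus_train(10), t_end_ms = 120,
                           state = shared_fixture("rest_gh"),
                           trace_dt_ms = NULL)
      sim
    },
    # the main characterization run: gh = 0 model, 10 Hz Poisson, 300 s
    gh300 = poisson_protocol(axon_model("gh_block"), rate_hz = 10,
                             duration_s = 300, seed = 42),
    ctrl300 = poisson_protocol(axon_model("control"), rate_hz = 10,
                               duration_s = 300, seed = 42),
    da300 = poisson_protocol(axon_model("da"), rate_hz = 10,
                             duration_s = 300, seed = 42),
    hh120 = poisson_protocol(axon_model("hh"), rate_hz = 10,
                             duration_s = 120, seed = 42, prerun_s = 20),
    ks300 = poisson_protocol(axon_model("ks"), rate_hz = 10,
                             duration_s = 300, seed = 42, prerun_s = 30),
    recovery = {
      gh <- shared_fixture("gh300")
      ip_lo <- mean_pump_current(gh$sim, c(0, 60))
      ip_hi <- mean_pump_current(gh$sim, c(240, 300))
      list(ip_lo = ip_lo, ip_hi = ip_hi,
           lo = recovery_cycle(axon_model("gh_block"), ip_lo),
           hi = recovery_cycle(axon_model("gh_block"), ip_hi))
    },
    stop("unknown fixture '", name, "'"))
  .axon_cache[[name]] <- val
  val
}

# a passive version of the axon (all active conductances zeroed)
passive_model <- function(geometry = axon_geometry()) {
  m <- axon_model("gh_block", pump = "none", geometry = geometry)
  for (k in seq_along(m$channels))
    if (m$channels[[k]]$name != "Leak") m$channels[[k]]$gbar <- 0
  m
}

# analytic steady-state profile of a sealed passive cable with current
# injected at the x = 0 end: V(x) = I r_a lambda cosh((L-x)/lambda)/sinh(L/lambda)
passive_profile_analytic <- function(geom, i_nA) {
  lam_cm <- passive_length_constant(geom) * 1e-4
  r_a <- geom$r_i / (pi * (geom$radius_um * 1e-4)^2) # Ohm/cm
  x <- (seq_len(geom$n_comp) - 0.5) * geom$dx_cm
  i_uA <- i_nA * 1e-3
  # uA * Ohm/cm * cm -> uV -> mV
  i_uA * r_a * lam_cm * cosh((geom$length_cm - x) / lam_cm) /
    sinh(geom$length_cm / lam_cm) * 1e-3
}
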