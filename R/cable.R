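# kernel configuration: gate lookup tables sampled on a fine voltage grid
.V_TAB_MIN <- -150
.V_TAB_MAX <- 100
.V_TAB_STEP <- 0.01

.build_kernel_cfg <- function(model, stimulus, dt, n_steps,
                              trace_stride, sample_stride, slow_stride,
                              stim_comp = 1L) {
  geom <- model$geometry
  gn <- names(model$gates)
  vgrid <- seq(.V_TAB_MIN, .V_TAB_MAX, by = .V_TAB_STEP)
  xinf_tab <- matrix(0, length(vgrid), length(gn))
  afac_tab <- matrix(0, length(vgrid), length(gn))
  for (j in seq_along(gn)) {
    g <- model$gates[[gn[j]]]
    xinf_tab[, j] <- g$xinf(vgrid)
    afac_tab[, j] <- exp(-dt / g$tau(vgrid))
  }
  gi <- function(nm) if (is.na(nm)) -1L else match(nm, gn) - 1L
  ch <- model$channels
  pp <- model$pump_pars

  onsets <- if (is.null(stimulus)) numeric(0) else stimulus$onset_ms
  amp_nA <- if (is.null(stimulus)) 1 else stimulus$amplitude_nA
  width_ms <- if (is.null(stimulus)) 1 else stimulus$width_ms

  # mM change per ms per uA/cm2 of compartment current density
  na_conv <- geom$area_cm2 * 1e-6 / (pp$alpha * pp$faraday * pp$vol * 1e-15)

  sites <- round(c(0.3, 0.7) * (geom$n_comp - 1))
  list(
    n_comp = geom$n_comp, dt = dt, n_steps = as.double(n_steps),
    cm = geom$c_m, g_couple = geom$g_couple,
    gbar = vapply(ch, `[[`, 0, "gbar"),
    erev = vapply(ch, function(c_) ifelse(is.na(c_$erev), 0, c_$erev), 0),
    p = vapply(ch, `[[`, 0L, "p"), q = vapply(ch, `[[`, 0L, "q"),
    gate_m = vapply(ch, function(c_) gi(c_$gate_m), 0L),
    gate_h = vapply(ch, function(c_) gi(c_$gate_h), 0L),
    i_na = .na_channel_index(model) - 1L,
    xinf_tab = xinf_tab, afac_tab = afac_tab,
    v_tab_min = .V_TAB_MIN, v_tab_step = .V_TAB_STEP,
    pump_mode = switch(model$pump, none = 0L, dynamic = 1L, constant = 2L),
    pump_imax = pp$i_max, pump_na_half = pp$na_half, pump_na_s = pp$na_s,
    ipump_const = model$ipump_const,
    na_conv = na_conv, na_out = pp$na_out, ena_scale = model$ena_scale,
    slow_stride = as.integer(slow_stride),
    stim_onset_step = round(onsets / dt),
    stim_width_steps = as.double(max(1, round(width_ms / dt))),
    stim_amp_density = amp_nA * 1e-3 / geom$area_cm2, # nA -> uA/cm2
    stim_comp = as.integer(stim_comp) - 1L,
    site1 = as.integer(sites[1]), site2 = as.integer(sites[2]),
    threshold = model$threshold_mV,
    trace_stride = as.double(trace_stride),
    sample_stride = as.double(sample_stride))
}

#' Integrate the axon cable equation
#'
#' Advances the discretized cable model under a stimulus train, using an
#' implicit scheme (backward-Euler diffusion/membrane step, exponential-Euler
#' gates) with sealed ends; the stimulus current is injected into the first
#' compartment. Spike threshold crossings, trough/peak voltages and gate
#' snapshots at the two recording sites (0.3 L and 0.7 L) are collected
#' online; the membrane-potential trace at the recording sites and the
#' pump/\[Na+\]_in series are sampled at the requested resolutions.
#'
#' @param model an [axon_model()].
#' @param stimulus a [stimulus_train()] or `NULL` for a stimulus-free run.
#' @param t_end_ms duration of this integration segment (ms).
#' @param dt time step (ms), default 0.0125 (half the 0.025 ms ceiling,
#'   at which the step-halving delay convergence is well under 1%).
#' @param state initial `sim_state`; defaults to [solve_rest()] of the
#'   model. State chains across calls (no reset between protocol segments).
#' @param trace_dt_ms sampling interval of the voltage trace, or `NULL`
#'   to record every step; `NA` disables trace recording.
#' @param sample_dt_ms sampling interval of the pump/\[Na+\] series (ms).
#' @param slow_dt_ms refresh interval of the slow variables (pump current
#'   and Nernst E_Na) (ms).
#' @param stim_comp compartment receiving the stimulus (1-based; default
#'   the first compartment, per the stimulation protocol).
#' @return an `axon_sim` object: `spikes1`/`spikes2` (per-site spike
#'   tables), `trace`, `samples`, time-averaged `mean_ina`/`mean_ipump`
#'   at the first recording site, and the final `state`.
#' @export
simulate_axon <- function(model, stimulus = NULL, t_end_ms, dt = 0.0125,
                          state = NULL, trace_dt_ms = NA,
                          sample_dt_ms = 10, slow_dt_ms = 0.5,
                          stim_comp = 1L) {
  stopifnot(inherits(model, "axon_model"), t_end_ms > 0, dt > 0)
  if (!is.null(stimulus)) {
    stopifnot(inherits(stimulus, "stimulus_train"))
    if (length(stimulus$onset_ms) && max(stimulus$onset_ms) > t_end_ms)
      stop("stimulus extends beyond t_end_ms")
  }
  if (is.null(state)) state <- solve_rest(model)
  n_steps <- ceiling(t_end_ms / dt)
  trace_stride <- if (is.null(trace_dt_ms)) 1
    else if (is.na(trace_dt_ms)) 0 else max(1, round(trace_dt_ms / dt))
  out <- .cable_run(
    .build_kernel_cfg(model, stimulus, dt, n_steps,
                      trace_stride = trace_stride,
                      sample_stride = max(1, round(sample_dt_ms / dt)),
                      slow_stride = max(1, round(slow_dt_ms / dt)),
                      stim_comp = stim_comp),
    state)
  res <- list(
    spikes1 = out$spikes1, spikes2 = out$spikes2,
    trace = if (trace_stride > 0)
      data.frame(t_ms = out$trace$t_ms, v1 = out$trace$v1, v2 = out$trace$v2)
      else NULL,
    samples = data.frame(t_ms = out$samples$t_ms, ipump = out$samples$ipump,
                         na_in = out$samples$na_in),
    mean_ina = out$mean_ina, mean_ipump = out$mean_ipump,
    state = structure(out$state, class = "sim_state"),
    model = model, stimulus = stimulus, dt = dt, t0_ms = state$t_ms)
  class(res) <- "axon_sim"
  res
}

#' @export
print.axon_sim <- function(x, ...) {
  cat("<axon_sim>", x$model$variant, "|", length(x$spikes1$t_cross),
      "spike(s) at site 1,", length(x$spikes2$t_cross), "at site 2\n")
  invisible(x)
}

#' Relax the model to its resting state
#'
#' Integrates without stimulation (default 100 s, mirroring the
#' stimulus-free pre-run used before every protocol) at a coarse step,
#' then verifies that the membrane potential has settled (max |dV/dt|
#' below `tol_dvdt`) and is spatially uniform. Dynamic-pump models start
#' from a uniform holding potential (gates at steady state, \[Na+\]_in at
#' its configured initial value) and relax along the pump's slow
#' trajectory; fixed-pump variants start from the [solve_rest()] root.
#'
#' @param model an [axon_model()].
#' @param duration_s stimulus-free interval (s).
#' @param dt integration step (ms); coarse is adequate without spikes.
#' @param tol_dvdt settledness tolerance (mV/ms).
#' @param v_init holding potential initializing the dynamic-pump relax
#'   (mV).
#' @return the settled `sim_state` (time reset to 0 for protocol use).
#' @export
relax_to_rest <- function(model, duration_s = 100, dt = 0.1, tol_dvdt = 1e-3,
                          v_init = -65) {
  st0 <- if (model$pump == "dynamic")
    .make_state(model, v_init, .na_init(model)) else solve_rest(model)
  sim <- simulate_axon(model, NULL, t_end_ms = duration_s * 1e3, dt = dt,
                       state = st0, sample_dt_ms = 1000)
  # finite-difference dV/dt over one further millisecond
  probe <- simulate_axon(model, NULL, t_end_ms = 1, dt = dt, state = sim$state,
                         sample_dt_ms = 1000)
  dvdt <- max(abs(probe$state$v - sim$state$v)) / 1
  if (dvdt > tol_dvdt)
    stop(sprintf("no resting equilibrium: max |dV/dt| = %.2g mV/ms after %g s",
                 dvdt, duration_s))
  st <- probe$state
  st$t_ms <- 0
  st
}

#' Per-spike total membrane conductance in the excited state
#'
#' From the gate snapshots taken at each spike's peak at the first recording
#' site, computes the total membrane conductance
#' \eqn{g_{total} = \sum \bar g m^p h^q + g_{leak}}, its reciprocal
#' `R_total` (the excited-state membrane resistance of unit area used by
#' the Matsumoto-Tasaki velocity estimate), the resting-state resistance
#' `R_rest` and their ratio `kappa`.
#'
#' @param sim an `axon_sim` with at least one complete spike.
#' @param rest_state optional `sim_state` defining the resting gate values;
#'   defaults to [solve_rest()] of the simulation's model.
#' @return data frame with one row per spike: `g_total` (mS/cm^2),
#'   `r_total` (kOhm cm^2), `r_rest`, `kappa`; zero rows when the
#'   simulation contains no spike.
#' @export
spike_peak_conductance <- function(sim, rest_state = NULL) {
  stopifnot(inherits(sim, "axon_sim"))
  model <- sim$model
  gp <- sim$spikes1$gates_peak
  if (is.null(dim(gp)) || nrow(gp) == 0)
    return(data.frame(g_total = numeric(0), r_total = numeric(0),
                      r_rest = numeric(0), kappa = numeric(0)))
  if (is.null(rest_state)) rest_state <- solve_rest(model)
  g_of <- function(gates_row) {
    gt <- 0
    for (c_ in model$channels) {
      act <- 1
      if (!is.na(c_$gate_m)) act <- gates_row[[c_$gate_m]]^c_$p
      if (c_$q > 0 && !is.na(c_$gate_h)) act <- act * gates_row[[c_$gate_h]]^c_$q
      gt <- gt + c_$gbar * act
    }
    gt
  }
  gn <- names(model$gates)
  colnames(gp) <- gn
  g_total <- apply(gp, 1, function(r) g_of(as.list(r)))
  g_rest <- g_of(as.list(rest_state$gates[1, ]))
  data.frame(g_total = g_total, r_total = 1 / g_total,
             r_rest = 1 / g_rest, kappa = g_rest / g_total)
}
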