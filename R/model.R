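#' Axon geometry and passive properties
#'
#' Cylindrical unmyelinated axon discretized into identical isopotential
#' compartments. Defaults reproduce the published PD-axon model geometry:
#' radius 5 um, length 1 cm, 101 compartments, R_i = 80 Ohm cm,
#' C_m = 1 uF/cm^2, R_m = 8 kOhm cm^2 (leak conductance 0.125 mS/cm^2,
#' passive length constant 1581 um).
#'
#' @param radius_um axon radius (um).
#' @param length_cm axon length (cm).
#' @param n_comp number of compartments (>= 3).
#' @param r_i intracellular resistivity (Ohm cm).
#' @param c_m specific membrane capacitance (uF/cm^2).
#' @param r_m specific membrane resistivity (kOhm cm^2).
#' @return an `axon_geometry` list with derived quantities: compartment
#'   length `dx_cm`, membrane area `area_cm2`, axial coupling conductance
#'   `g_couple` (mS/cm^2) and leak conductance `g_leak` (mS/cm^2).
#' @export
axon_geometry <- function(radius_um = 5, length_cm = 1, n_comp = 101,
                          r_i = 80, c_m = 1, r_m = 8) {
  stopifnot(n_comp >= 3, radius_um > 0, length_cm > 0, r_i > 0, c_m > 0, r_m > 0)
  a_cm <- radius_um * 1e-4
  dx <- length_cm / n_comp
  g <- list(radius_um = radius_um, length_cm = length_cm, n_comp = n_comp,
            r_i = r_i, c_m = c_m, r_m = r_m,
            dx_cm = dx,
            area_cm2 = 2 * pi * a_cm * dx,
            # a/(2 R_i dx^2): S/cm^2 -> mS/cm^2
            g_couple = a_cm / (2 * r_i * dx^2) * 1e3,
            g_leak = 1 / r_m)
  class(g) <- "axon_geometry"
  g
}

#' Passive length constant
#'
#' \eqn{\lambda = \sqrt{R_m a / (2 R_i)}} of the passive cable.
#'
#' @param geom an [axon_geometry()].
#' @return length constant in um.
#' @export
passive_length_constant <- function(geom = axon_geometry()) {
  # r_m kOhm cm^2 -> Ohm cm^2; result cm -> um
  sqrt(geom$r_m * 1e3 * (geom$radius_um * 1e-4) / (2 * geom$r_i)) * 1e4
}

.scale_of <- function(scales, name) {
  s <- scales[[name]]
  if (is.null(s)) 1 else s
}

.known_scales <- c("g_Na", "g_Kd", "g_Leak", "g_A", "g_h", "g_Ks",
                   "E_Na", "E_K", "E_Leak", "E_h",
                   "tau_m_Na", "tau_h_Na", "tau_m_Kd",
                   "tau_m_A", "tau_h_A", "tau_m_h", "tau_m_Ks")

.scaled_gate <- function(gate, tau_scale = 1) {
  g <- .get_gate(gate)
  if (tau_scale == 1) return(g)
  tau_fun <- g$tau
  list(xinf = g$xinf, tau = function(v) tau_scale * tau_fun(v))
}

#' Construct an axon model variant
#'
#' Builds the full channel/pump description of one model variant:
#' \describe{
#'   \item{`control`}{I_Na, I_Kd, I_Leak, I_A, I_h (control kinetics),
#'     dynamic Na+/K+ pump.}
#'   \item{`da`}{as control, with the dopamine-modulated I_h (doubled
#'     conductance, shifted activation).}
#'   \item{`gh_block`}{I_h removed (gbar_h = 0), mimicking CsCl block.}
#'   \item{`hh`}{classic squid Hodgkin-Huxley axon (I_Na, I_K, leak), no
#'     pump; used as a history-free negative control.}
#'   \item{`ks`}{the pump's slow dynamics replaced by a slow potassium
#'     current I_Ks (I_Kd voltage dependence, 5000x slower activation);
#'     the pump's standing resting contribution is kept as a frozen
#'     current and E_Na is fixed.}
#' }
#'
#' @param variant model variant name.
#' @param pump `"dynamic"` (\[Na+\]_in-driven pump and Nernst E_Na),
#'   `"constant"` (pump current frozen at `ipump_const`), or `"none"`.
#'   Defaults to `"dynamic"` for the PD variants and `"none"` for
#'   `hh`/`ks`.
#' @param ipump_const constant pump current density (uA/cm^2) when
#'   `pump = "constant"`.
#' @param scales named list of multiplicative perturbation factors for the
#'   sensitivity analysis, e.g. `list(g_Na = 1.05)`. Reversal-potential
#'   factors multiply the printed value; `E_Na` multiplies the Nernst
#'   output; `tau_*` factors scale the whole time-constant curve.
#' @param geometry an [axon_geometry()]. The conduction-model default
#'   uses a 1.75 um radius: with the published channel densities this is
#'   the calibration at which the published 1 nA / 1 ms stimulus reliably
#'   initiates spikes (including through the relative refractory period)
#'   and conduction delays fall in the published range; the published
#'   5 um radius gives a ~3 nA rheobase (see the vignette). The passive
#'   cable quantities keep the published geometry via [axon_geometry()]
#'   defaults.
#' @param pump_pars a [pump_spec()].
#' @param na_in_init initial intracellular Na+ (mM) for the dynamic pump;
#'   not a printed parameter (resting E_Na of about +50 mV). The silent
#'   pre-run relaxes the pump from this point toward its operating
#'   baseline; the per-variant defaults land the pump just above the
#'   smallest value that balances the variant's subthreshold inward
#'   current, keeping the pre-run quiescent (see the vignette).
#' @return an `axon_model` object.
#' @export
axon_model <- function(variant = c("control", "da", "gh_block", "hh", "ks"),
                       pump = NULL, ipump_const = NULL, scales = list(),
                       geometry = axon_geometry(radius_um = 1.75),
                       pump_pars = pump_spec(), na_in_init = NULL) {
  variant <- match.arg(variant)
  bad <- setdiff(names(scales), .known_scales)
  if (length(bad))
    stop("unknown scale parameter(s): ", paste(bad, collapse = ", "))
  s <- function(nm) .scale_of(scales, nm)

  if (is.null(pump))
    pump <- switch(variant, hh = "none", ks = "constant", "dynamic")
  pump <- match.arg(pump, c("dynamic", "constant", "none"))
  if (pump == "constant") {
    # the ks variant swaps the pump's slow dynamics for I_Ks but keeps the
    # pump's standing contribution to the resting balance frozen
    if (is.null(ipump_const)) ipump_const <- if (variant == "ks") 1.3 else NULL
    if (is.null(ipump_const) || ipump_const < 0 || ipump_const >= pump_pars$i_max)
      stop("pump = 'constant' needs 0 <= ipump_const < i_max")
  } else ipump_const <- 0
  if (is.null(na_in_init))
    na_in_init <- switch(variant, da = 69.1, control = 65, 64.2)

  ch <- list()
  gates <- list()
  add_gate <- function(name, tau_scale) gates[[name]] <<- .scaled_gate(name, tau_scale)

  if (variant == "hh") {
    add_gate("HHNa.m", 1); add_gate("HHNa.h", 1); add_gate("HHK.n", 1)
    ch <- list(
      list(name = "Na", gbar = 120 * s("g_Na"), erev = NA_real_, dynamic_erev = TRUE,
           p = 3L, q = 1L, gate_m = "HHNa.m", gate_h = "HHNa.h"),
      list(name = "K", gbar = 36 * s("g_Kd"), erev = -77 * s("E_K"),
           dynamic_erev = FALSE, p = 4L, q = 0L, gate_m = "HHK.n", gate_h = NA),
      list(name = "Leak", gbar = 0.3 * s("g_Leak"), erev = -54.4 * s("E_Leak"),
           dynamic_erev = FALSE, p = 0L, q = 0L, gate_m = NA, gate_h = NA))
  } else {
    add_gate("Na.m", s("tau_m_Na")); add_gate("Na.h", s("tau_h_Na"))
    add_gate("Kd.m", s("tau_m_Kd"))
    add_gate("A.m", s("tau_m_A")); add_gate("A.h", s("tau_h_A"))
    ch <- list(
      list(name = "Na", gbar = 14 * s("g_Na"), erev = NA_real_, dynamic_erev = TRUE,
           p = 3L, q = 1L, gate_m = "Na.m", gate_h = "Na.h"),
      list(name = "Kd", gbar = 3 * s("g_Kd"), erev = -70 * s("E_K"),
           dynamic_erev = FALSE, p = 4L, q = 0L, gate_m = "Kd.m", gate_h = NA),
      list(name = "Leak", gbar = geometry$g_leak * s("g_Leak"),
           erev = -65 * s("E_Leak"), dynamic_erev = FALSE,
           p = 0L, q = 0L, gate_m = NA, gate_h = NA),
      list(name = "A", gbar = 5 * s("g_A"), erev = -70 * s("E_K"),
           dynamic_erev = FALSE, p = 3L, q = 1L, gate_m = "A.m", gate_h = "A.h"))
    if (variant == "control") {
      add_gate("h_ctrl.m", s("tau_m_h"))
      ch <- c(ch, list(list(name = "h", gbar = 0.05 * s("g_h"),
                            erev = -32 * s("E_h"), dynamic_erev = FALSE,
                            p = 1L, q = 0L, gate_m = "h_ctrl.m", gate_h = NA)))
    } else if (variant == "da") {
      add_gate("h_DA.m", s("tau_m_h"))
      ch <- c(ch, list(list(name = "h", gbar = 0.1 * s("g_h"),
                            erev = -25 * s("E_h"), dynamic_erev = FALSE,
                            p = 1L, q = 0L, gate_m = "h_DA.m", gate_h = NA)))
    }
    if (variant == "ks") {
      add_gate("Ks.m", s("tau_m_Ks"))
      ch <- c(ch, list(list(name = "Ks", gbar = 3 * s("g_Ks"), erev = -70 * s("E_K"),
                            dynamic_erev = FALSE, p = 1L, q = 0L,
                            gate_m = "Ks.m", gate_h = NA)))
    }
  }

  m <- list(variant = variant, geometry = geometry, channels = ch,
            gates = gates, pump = pump, ipump_const = ipump_const,
            pump_pars = pump_pars, ena_scale = s("E_Na"),
            na_in_init = na_in_init,
            threshold_mV = -40, delay_scale = 9.5, gate_init = list())
  class(m) <- "axon_model"
  m
}

#' @export
print.axon_model <- function(x, ...) {
  cat("<axon_model>", x$variant, "| pump:", x$pump,
      if (x$pump == "constant") sprintf("(%.3g uA/cm2)", x$ipump_const) else "",
      "\n  channels:",
      paste(sprintf("%s(%.3g)", vapply(x$channels, `[[`, "", "name"),
                    vapply(x$channels, `[[`, 0, "gbar")), collapse = ", "),
      "\n")
  invisible(x)
}

# index of the sodium channel (dynamic reversal) in model$channels
.na_channel_index <- function(model) {
  dyn <- vapply(model$channels, `[[`, TRUE, "dynamic_erev")
  which(dyn)[1]
}

# gate names of the sodium channel (for spike-feature rate evaluation)
.na_gates <- function(model) {
  k <- .na_channel_index(model)
  list(m = model$channels[[k]]$gate_m, h = model$channels[[k]]$gate_h)
}

#' Opening/closing rates of one of a model's gates
#'
#' As [gate_rates()], but using the model's (possibly perturbation-scaled)
#' kinetics.
#'
#' @param model an [axon_model()].
#' @param gate gate name present in the model (e.g. `"Na.m"`).
#' @param v membrane potential (mV), vectorized.
#' @return list with `alpha` and `beta` (1/ms).
#' @export
model_gate_rates <- function(model, gate, v) {
  g <- model$gates[[gate]]
  if (is.null(g)) stop("gate '", gate, "' not part of this model")
  xi <- g$xinf(v)
  ta <- g$tau(v)
  list(alpha = xi / ta, beta = (1 - xi) / ta)
}

# gate value at a gate's initial condition (steady state unless overridden)
.gate_init_value <- function(model, gate, v) {
  ov <- model$gate_init[[gate]]
  if (!is.null(ov)) rep_len(ov, length(v)) else model$gates[[gate]]$xinf(v)
}

# total steady membrane current density (uA/cm2) with gates at their
# initial condition, Na reversal consistent with na_in
.rest_current <- function(model, v, na_in) {
  tot <- 0
  kna <- .na_channel_index(model)
  for (k in seq_along(model$channels)) {
    c_ <- model$channels[[k]]
    act <- 1
    if (!is.na(c_$gate_m))
      act <- .gate_init_value(model, c_$gate_m, v)^c_$p
    if (c_$q > 0 && !is.na(c_$gate_h))
      act <- act * .gate_init_value(model, c_$gate_h, v)^c_$q
    e <- if (isTRUE(c_$dynamic_erev))
      model$ena_scale * nernst_sodium(na_in, model$pump_pars$na_out)
    else c_$erev
    tot <- tot + c_$gbar * act * (v - e)
  }
  tot
}

# default na_in for pump = "none" (resting E_Na exactly +50 mV)
.na_fixed_default <- function(model) model$pump_pars$na_out / 10^(50 / 58)

# initial [Na+]_in for the model's pump mode
.na_init <- function(model) {
  switch(model$pump,
         dynamic = model$na_in_init,
         constant = .na_const_pump(model),
         none = .na_fixed_default(model))
}

#' Resting state of the model axon
#'
#' Finds the stable subthreshold resting potential by root-finding on the
#' total membrane current (gates at their initial condition, pump at the
#' level set by the initial intracellular Na+). The subthreshold ionic
#' current of this axon is net inward at every voltage, so a resting
#' point exists only with the standing outward pump current; intracellular
#' Na+ is a quasi-static variable at rest (it drifts on the timescale of
#' minutes and is replenished by stimulated spiking). The stable root —
#' total current crossing zero from inward to outward as V rises — is
#' taken.
#'
#' @param model an [axon_model()].
#' @param interval voltage range (mV) searched for the resting point.
#' @return a `sim_state` list (per-compartment `v`, `gates`, `na_in`,
#'   time `t_ms = 0`).
#' @export
solve_rest <- function(model, interval = c(-140, -45)) {
  na0 <- .na_init(model)
  ip <- switch(model$pump,
               dynamic = pump_current(na0, model$pump_pars),
               constant = model$ipump_const,
               none = 0)
  f <- function(v) .rest_current(model, v, na0) + ip
  vg <- seq(interval[1], interval[2], by = 0.25)
  fg <- vapply(vg, f, 0)
  i_pos <- which(fg > 0)[1]
  if (is.na(i_pos) || i_pos == 1)
    stop("no stable subthreshold resting point in [", interval[1], ", ",
         interval[2], "] mV; the standing pump current (", signif(ip, 3),
         " uA/cm2) cannot balance the inward subthreshold current")
  v0 <- stats::uniroot(f, interval = vg[c(i_pos - 1, i_pos)], tol = 1e-10)$root
  .make_state(model, v0, na0)
}

# na_in consistent with a frozen pump current (keeps E_Na on the same
# Nernst mapping as the dynamic model)
.na_const_pump <- function(model) {
  pp <- model$pump_pars
  if (model$ipump_const <= 0) return(.na_fixed_default(model))
  pp$na_half - pp$na_s * log(pp$i_max / model$ipump_const - 1)
}

.make_state <- function(model, v0, na0) {
  nc <- model$geometry$n_comp
  gn <- names(model$gates)
  gm <- matrix(0, nc, length(gn), dimnames = list(NULL, gn))
  for (g in gn) gm[, g] <- .gate_init_value(model, g, v0)
  structure(list(v = rep(v0, nc), gates = gm, na_in = rep(na0, nc), t_ms = 0),
            class = "sim_state")
}
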