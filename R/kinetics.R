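#' @useDynLib axondelay, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

sigm <- function(x) 1 / (1 + exp(-x))

## Gating kinetics registry.
##
## Each gate is described by its steady-state curve x_inf(V) and voltage-
## dependent time constant tau_x(V) (ms). The PD-axon currents use Boltzmann
## steady states and reciprocal-cosh or sigmoid time constants; the classic
## squid Na/K gates are expressed through their canonical alpha/beta rate
## functions and converted to the x_inf/tau form (an exact identity).
.gate_registry <- list(
  Na.m = list(
    xinf = function(v) sigm((v + 48) / 8.5),
    tau  = function(v) 0.132 / cosh((v + 27) / 7.5) +
                       0.003 / (1 + exp(-(v + 27) / 5))
  ),
  Na.h = list(
    xinf = function(v) sigm(-(v + 47) / 6),
    tau  = function(v) 10 / cosh((v + 42) / 15)
  ),
  Kd.m = list(
    xinf = function(v) sigm((v + 47) / 10),
    tau  = function(v) 50 / cosh((v + 73) / 15)
  ),
  A.m = list(
    xinf = function(v) sigm((v + 63) / 15),
    tau  = function(v) 18 + 58 / (1 + exp((v + 61) / 20))
  ),
  A.h = list(
    xinf = function(v) sigm(-(v + 80) / 8),
    tau  = function(v) rep_len(50, length(v))
  ),
  h_ctrl.m = list(
    xinf = function(v) sigm(-(v + 80) / 5.5),
    tau  = function(v) rep_len(3700, length(v))
  ),
  h_DA.m = list(
    xinf = function(v) sigm(-(v + 75) / 12.5),
    tau  = function(v) rep_len(3800, length(v))
  ),
  Ks.m = list( # I_Kd voltage dependence, 5000x slower
    xinf = function(v) sigm((v + 47) / 10),
    tau  = function(v) 250000 / cosh((v + 73) / 15)
  ),
  HHNa.m = list(
    xinf = function(v) .hh_xinf(.hh_am, .hh_bm, v),
    tau  = function(v) .hh_tau(.hh_am, .hh_bm, v)
  ),
  HHNa.h = list(
    xinf = function(v) .hh_xinf(.hh_ah, .hh_bh, v),
    tau  = function(v) .hh_tau(.hh_ah, .hh_bh, v)
  ),
  HHK.n = list(
    xinf = function(v) .hh_xinf(.hh_an, .hh_bn, v),
    tau  = function(v) .hh_tau(.hh_an, .hh_bn, v)
  )
)

# canonical squid rate functions (1/ms), -65 mV resting convention;
# vtrap handles the removable singularity of the linoid forms
.vtrap <- function(x, y) ifelse(abs(x / y) < 1e-6, y * (1 - x / y / 2), x / (exp(x / y) - 1))
.hh_am <- function(v) 0.1 * .vtrap(-(v + 40), 10)
.hh_bm <- function(v) 4 * exp(-(v + 65) / 18)
.hh_ah <- function(v) 0.07 * exp(-(v + 65) / 20)
.hh_bh <- function(v) 1 / (1 + exp(-(v + 35) / 10))
.hh_an <- function(v) 0.01 * .vtrap(-(v + 55), 10)
.hh_bn <- function(v) 0.125 * exp(-(v + 65) / 80)
.hh_xinf <- function(a, b, v) a(v) / (a(v) + b(v))
.hh_tau <- function(a, b, v) 1 / (a(v) + b(v))

.get_gate <- function(gate) {
  g <- .gate_registry[[gate]]
  if (is.null(g))
    stop("unknown gate '", gate, "'; available: ",
         paste(names(.gate_registry), collapse = ", "))
  g
}

#' Gating-variable steady state
#'
#' Steady-state activation/inactivation value \eqn{x_\infty(V)} of one
#' Hodgkin-Huxley gate of the axon model.
#'
#' @param gate gate name, e.g. `"Na.m"`, `"Na.h"`, `"Kd.m"`, `"A.m"`,
#'   `"A.h"`, `"h_ctrl.m"`, `"h_DA.m"`, `"Ks.m"`, or the squid gates
#'   `"HHNa.m"`, `"HHNa.h"`, `"HHK.n"`.
#' @param v membrane potential (mV), vectorized.
#' @return steady-state gate value in \[0, 1\].
#' @export
gate_steady_state <- function(gate, v) {
  stopifnot(all(is.finite(v)))
  .get_gate(gate)$xinf(v)
}

#' Gating-variable time constant
#'
#' @inheritParams gate_steady_state
#' @return time constant (ms), strictly positive.
#' @export
gate_time_constant <- function(gate, v) {
  stopifnot(all(is.finite(v)))
  .get_gate(gate)$tau(v)
}

#' Opening and closing rates of a gate
#'
#' Converts the \eqn{x_\infty, \tau_x} description into the equivalent
#' opening/closing rates \eqn{\alpha = x_\infty/\tau_x},
#' \eqn{\beta = (1-x_\infty)/\tau_x}, so that \eqn{\alpha+\beta = 1/\tau_x}.
#'
#' @inheritParams gate_steady_state
#' @return list with numeric vectors `alpha` and `beta` (1/ms).
#' @export
gate_rates <- function(gate, v) {
  g <- .get_gate(gate)
  xi <- g$xinf(v)
  ta <- g$tau(v)
  list(alpha = xi / ta, beta = (1 - xi) / ta)
}

#' Exact relaxation of a single gate at fixed voltage
#'
#' Closed-form solution of \eqn{dx/dt = (x_\infty - x)/\tau_x} at constant
#' voltage; this is also the update rule the integrator applies per step
#' (exponential Euler), which is exact for frozen voltage.
#'
#' @inheritParams gate_steady_state
#' @param x0 initial gate value.
#' @param t elapsed time (ms), vectorized.
#' @export
gate_relax <- function(gate, v, x0, t) {
  g <- .get_gate(gate)
  xi <- g$xinf(v)
  xi + (x0 - xi) * exp(-t / g$tau(v))
}

#' Ionic current density of one channel
#'
#' \eqn{I = \bar g\, m^p h^q (V - E_{rev})}; positive current is outward.
#'
#' @param v membrane potential (mV).
#' @param m,h gate values in \[0, 1\] (`h` ignored when `q = 0`).
#' @param gbar maximal conductance (mS/cm^2).
#' @param erev reversal potential (mV).
#' @param p,q activation/inactivation exponents.
#' @return current density (uA/cm^2).
#' @export
channel_current <- function(v, m, h = 1, gbar, erev, p = 1, q = 0) {
  if (any(m < 0) || any(h < 0)) stop("negative gate value")
  gbar * m^p * (if (q > 0) h^q else 1) * (v - erev)
}

#' Na+/K+ pump current
#'
#' Sigmoidal activation by intracellular sodium:
#' \eqn{I_{pump} = I_{max}/(1 + \exp(([Na]_{1/2} - [Na]_{in})/[Na]_S))}.
#' Always outward (hyperpolarizing), monotone increasing in `na_in`.
#'
#' @param na_in intracellular Na+ concentration (mM), > 0.
#' @param pump a [pump_spec()] parameter list.
#' @return current density in the units of `pump$i_max`.
#' @export
pump_current <- function(na_in, pump = pump_spec()) {
  if (any(na_in <= 0)) stop("na_in must be positive")
  pump$i_max / (1 + exp((pump$na_half - na_in) / pump$na_s))
}

#' Na+/K+ pump parameter set
#'
#' Defaults are the published PD-axon values. `i_max` is kept as printed
#' (2 mA/cm^2 = 2000 uA/cm^2); the pump operates far below saturation, on
#' the exponential tail of its activation sigmoid. `na_out` and the implied
#' resting `na_in` are not printed for this model; `na_out` is set to a
#' marine-crustacean extracellular value and `na_in` follows from requiring
#' a resting Na+ reversal near +50 mV (see the package vignette).
#'
#' @param i_max maximal pump current density (uA/cm^2).
#' @param na_half `[Na+]_in` at half activation (mM).
#' @param na_s sensitivity scale (mM).
#' @param alpha dimensionless scale factor of the Na+ balance.
#' @param vol compartment volume (um^3).
#' @param faraday Faraday constant (C/mol).
#' @param na_out extracellular Na+ (mM), held constant.
#' @export
pump_spec <- function(i_max = 2000, na_half = 78, na_s = 2, alpha = 7.4,
                      vol = 7850, faraday = 96485, na_out = 479) {
  stopifnot(na_s > 0, vol > 0, na_out > 0)
  list(i_max = i_max, na_half = na_half, na_s = na_s, alpha = alpha,
       vol = vol, faraday = faraday, na_out = na_out)
}

#' Rate of change of intracellular Na+
#'
#' \eqn{d[Na]_{in}/dt = -(I_{Na} + 3 I_{pump})/(\alpha F \cdot Vol)} with the
#' currents expressed as total compartment currents (uA). At steady state
#' the pump extrudes one third of the Na+ current
#' (\eqn{I_{pump} = -I_{Na}/3}, 3 Na+ out per cycle).
#'
#' @param i_na,i_pump total compartment currents (uA; inward negative).
#' @param pump a [pump_spec()].
#' @return d\[Na\]_in/dt in mM/ms.
#' @export
sodium_balance_rate <- function(i_na, i_pump, pump = pump_spec()) {
  # uA -> C/ms: 1e-9; vol um^3 -> L: 1e-15; mol/L -> mM: 1e3
  conv <- 1e-9 / (pump$alpha * pump$faraday * pump$vol * 1e-15) * 1e3
  -(i_na + 3 * i_pump) * conv
}

#' Sodium Nernst potential
#'
#' \eqn{E_{Na} = 58 \log_{10}([Na]_{out}/[Na]_{in})} (mV).
#'
#' @param na_in,na_out Na+ concentrations (mM), > 0.
#' @export
nernst_sodium <- function(na_in, na_out) {
  if (any(na_in <= 0) || any(na_out <= 0)) stop("concentrations must be positive")
  58 * log10(na_out / na_in)
}
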