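---
title: "Modeling the history-dependence of spike conduction delay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the history-dependence of spike conduction delay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(axondelay)
```

## The scientific problem

Axonal conduction velocity is not constant: during ongoing activity each
spike travels at a speed set by the axon's recent history. In the
unmyelinated motor axon modeled here (the pyloric dilator axon of the
crustacean stomatogastric system is the reference biology), two distinct
timescales shape the conduction delay measured between two points along
the axon:

* a **slow timescale (STS)** effect — over minutes of repetitive firing,
  the electrogenic Na+/K+ pump is driven by accumulated intracellular
  Na+, its outward current hyperpolarizes the resting (trough) potential,
  and both the mean delay and the delay variability grow;
* a **fast timescale (FTS)** effect — each spike's delay depends
  non-monotonically on the instantaneous stimulus frequency
  F_inst = 1/(preceding interval): intermediate intervals conduct fastest
  (supernormal phase, residual depolarization of the trough), short
  intervals conduct slowly (relative refractory phase, residual Na+
  channel inactivation and K+ conductance), and long intervals expose the
  hyperpolarized baseline.

`axondelay` implements the conductance-based multicompartment model of
this axon, the stimulation protocols (Poisson trains, paired pulses,
parabolic bursts), the spike/delay metrics, the STS/FTS analyses, the
published closed-form velocity estimates (Matsumoto–Tasaki, Muratov), the
empirical delay regressions on Na+ gating rates or on spike trough/peak
voltages, a parameter-sensitivity battery, and a surrogate spike-feature
generator used to test the analysis layer without the PDE solver.

## The model

The membrane potential obeys the cable equation

$$\frac{a}{2 R_i}\frac{\partial^2 V}{\partial x^2}
  = C_m \frac{\partial V}{\partial t} + \sum I_{ion} + I_{pump} + I_{app}(t),$$

discretized into 101 identical isopotential compartments with sealed
(zero-flux) ends; the stimulus (rectangular 1 nA / 1 ms pulses) enters the
first compartment. Every ionic current has Hodgkin–Huxley form
$I = \bar g\, m^p h^q (V - E_{rev})$ with first-order gates
$dx/dt = (x_\infty(V) - x)/\tau_x(V)$. The full variant carries fast Na+
(m³h, dynamic Nernst reversal), delayed-rectifier K+ (m⁴, E = −70 mV),
leak (E = −65 mV, g = 1/R_m = 0.125 mS/cm²), a transient A-type K+
current (m³h, E = −70 mV), and a hyperpolarization-activated inward
current I_h (E = −32 mV at control, −25 mV with the dopamine-modulated
kinetics and doubled conductance). Steady-state curves are Boltzmann
sigmoids; voltage-dependent time constants are reciprocal-cosh or sigmoid
forms (see `gate_steady_state()`, `gate_time_constant()`); all parameter
values are the published ones.

The Na+/K+ pump is a sigmoid of intracellular Na+,
$I_{pump} = I_{max}/(1 + \exp(([Na]_{1/2} - [Na]_{in})/[Na]_S))$
(always outward), and intracellular Na+ follows
$d[Na]_{in}/dt = -(I_{Na} + 3 I_{pump})/(\alpha F \, Vol)$ with the
currents as total compartment currents, so that at flux balance the pump
carries one third of the Na+ current (3 Na+ extruded per net charge).
E_Na is recomputed from the Nernst equation as Na+ accumulates.

Model variants (`axon_model()`): `control`, `da` (dopamine-modulated
I_h), `gh_block` (I_h removed), `hh` (classic squid axon as a
history-free control), and `ks` (the pump's slow dynamics replaced by a
slow K+ current with the delayed-rectifier voltage dependence and a
5000-fold slower time constant).

## Numerical scheme

The integrator (Rcpp) advances the gates by exponential Euler — exact for
the linear gate equation at frozen voltage — and then solves the membrane
equation, linear in the new voltages once the conductances are known, by
a Crank–Nicolson step with the axial coupling treated implicitly (Thomas
tridiagonal solve). Gate kinetics are evaluated from lookup tables
sampled at 0.01 mV; the slow variables (pump current, E_Na) are refreshed
every 0.5 ms. The default step is dt = 0.0125 ms, half the conventional
0.025 ms ceiling: the gate–voltage staggering is first-order in the
stiff spike upstroke, and at 0.0125 ms the step-halving change of a
single-spike delay is below 1% (it is not at 0.025 ms). Conduction delay
is measured between the −40 mV upward crossings at 0.3 L and 0.7 L with
sub-sample interpolation, and multiplied by 9.5 to map the 0.4 cm
measurement distance onto the biological axon length; peak-based delays
agree with threshold-based ones to well under 1%.

## Calibration choices the source leaves open

Reconstructing the model from its published tables required settling
several points the tables do not determine; these are the package's own
design decisions, all configurable:

**Axon radius for the conduction model (1.75 µm default).** The published
passive geometry (radius 5 µm, R_m = 8 kΩ cm², R_i = 80 Ω cm) yields the
published λ = 1581 µm, and `axon_geometry()` keeps those defaults.
However, cable theory (and the solver) give a ~16 MΩ input resistance at
a sealed end, so a 1 nA / 1 ms pulse depolarizes the stimulated end by
only ~6 mV after axial spread — a ~3 nA rheobase — while the protocols
require the published 1 nA pulse to fire reliably, including inside the
relative refractory period. At a 1.75 µm radius (input resistance scales
as $a^{-3/2}$) the same pulse delivers ~29 mV, initiation is robust
through the refractory zone, and the conduction delays (~34 ms scaled)
fall where the published regression coefficients place them. The passive
checks are run on the published geometry; the conduction model defaults
to the smaller radius.

**The pump operating point.** The subthreshold ionic current of the
published channel set is net inward at every voltage (leak reverses at
−65 mV while the A- and delayed-rectifier currents reverse at −70 mV and
are nearly shut below −60 mV, and the Na+ window current grows above
−70 mV), so a resting state exists only on the hyperpolarized side of
−70 mV and only while the standing pump current exceeds roughly
1.2 µA/cm². During the silent 100 s pre-run the pump decays
hyperbolically toward this marginal level — with the published
$\alpha F\,Vol$ the decay takes almost exactly 100 s from any strong
starting point, which is presumably why the published protocol uses a
100 s pre-run "to remove transients". The unprinted initial
[Na+]_in (`na_in_init`) is set per variant (64.2–69.1 mM, resting E_Na
near +50 mV) so each variant lands just above its own stability floor,
quiescent, at stimulation onset. `I_max,pump` is kept exactly as printed
(2 mA/cm²); the pump then operates on the exponential tail of its
activation sigmoid, far below half-saturation.

**The slow-K substitution (`ks`).** With the pump removed entirely the
channel set has no resting state (the slow K+ current cannot supply
standing outward current near its own reversal). The variant therefore
freezes the pump's standing resting contribution (1.3 µA/cm² by default)
and adds I_Ks on top; the slow conductance then builds up over minutes of
stimulation, depressing the spike peak and raising the mean delay while
leaving the trough — and hence the delay variability — nearly unchanged,
which is the substitution's point.

**The dopamine variant rides its stability edge.** The enlarged,
depolarized-activating I_h adds standing inward current, raising the
pump level required for quiescence to nearly the largest value the silent
pre-run can deliver. The DA model is therefore the most excitable
variant and can fire sporadically between stimuli; `build_spike_series()`
keeps one propagated spike per stimulus and reports how many extra
crossings were dropped.

**F_inst bookkeeping.** F_inst is defined from stimulus timing (not from
site-recorded spike times). When a stimulus occasionally fails to fire
(deep refractory period), the next spike's F_inst is taken against the
previous spike-evoking stimulus — identical to the preceding-interval
definition whenever every pulse fires. The first spike of a protocol has
no F_inst and is excluded from frequency-resolved analyses.

**Burst parabola.** With 19 spikes per burst there are 18 intervals, so
the inverted-parabola instantaneous-frequency profile places its 63 Hz
vertex between the two middle intervals; the end intervals sit exactly at
32 Hz (31.25 ms) and the middle ones within 0.5% of 1/63 s. The implied
burst duration is ~350 ms.

## Analyses

* `binned_delay_stats()` — D_mean and CV-D in 20 s bins (STS summary).
* `fts_quadratic_fit()` — unbinned least-squares quadratic of delay vs
  F_inst per epoch; reported by its vertex (F_min, D_min) and the vertex
  curvature κ_min = 2a (ms/Hz²), the measure of FTS nonlinearity.
  "Minute 1" and "minute 5" are the [0, 60) s and [240, 300) s windows.
* `recovery_cycle()` — paired-pulse trials (default 30 log-spaced ISIs,
  10 ms–10 s) from an identical rest at a frozen pump current; the two
  pump levels used for comparison are the mean dynamic pump over minute 1
  and minute 5 of the matching Poisson run (`mean_pump_current()`).
* `paired_pulse_predictor()` — cubic fit of recovery-curve delay vs
  F_inst, used to predict per-spike Poisson delays from F_inst alone.
  Frequencies outside the fitted range are clamped to its boundary; this
  clamping is the main cost of the prediction when the Poisson train
  contains intervals shorter than the 10 ms paired-pulse floor.
* `matsumoto_tasaki_velocity()` / `muratov_velocity()` — the closed-form
  single-spike estimates, applied per spike via the excited-state
  conductance snapshot and the trough voltage respectively
  (`published_equation_delays()`). In the Muratov estimate h₀ is taken at
  steady state for the trough voltage (the instantaneous simulated
  inactivation is available as an alternative input).
* `fit_linear_combination()` / `rank_rate_pairs()` /
  `voltage_delay_regression()` — the empirical two-feature delay
  regressions (d = c₁x + c₂y + c₃) on reciprocal gating rates
  (1/α_m(V_T), 1/β_m(V_P), 1/α_h(V_T), 1/β_h(V_P)) or on reciprocal
  voltages (1/V_T, 1/V_P; the reciprocal reading is the one consistent
  with the published coefficient magnitudes). Coefficients are found with
  Powell's conjugate-direction method (implemented in the package, with
  Brent line searches) from a zero start; the objective is convex, so the
  closed-form least-squares solution serves as an exact cross-check on
  every fit.
* `run_sensitivity()` — ±5%/±10% single-parameter perturbations at a
  frozen pump current, same stimulus seed across all runs (paired
  design), summarized by the least-squares slope of fractional attribute
  change against fractional parameter change through the five points.
  The default battery uses 45–60 s epochs: at constant pump the
  attributes are stationary, so a shorter epoch adds noise but no bias.

## The surrogate generator

`generate_surrogate()` emulates the statistical structure of the
simulated spike-feature series in milliseconds: a trough voltage with a
slow exponential pump-like drift (4 mV, τ = 60 s by default) plus an
ISI-kernel summation term (3 mV, τ = 80 ms), a peak voltage with an
ISI-kernel depression term (15 mV, τ = 25 ms, mirroring the strong peak
depression the model shows at short intervals), and delays from the
reciprocal-voltage law (defaults are the published coefficients) plus
Gaussian noise. The fast kernels grow with the accumulated drift
(0.15 per mV by default), as the biophysical model's do — this is also
what makes the delay variability grow along with the mean. The surrogate
shares the spike-series schema, so every downstream stage runs on it
unchanged; it does not emulate membrane waveforms or conduction failures,
so passing surrogate-based tests validates the analysis layer, not the
biophysics.

## What the reconstruction reproduces, and where it falls short

With all kinetic parameters as printed, the package reproduces: the
quiescent pre-run and stable baseline; reliable 1 nA initiation; ~34 ms
scaled delays; the recovery cycle with relative refractory (≲ 20 ms) and
supernormal (~30–150 ms) phases, uniformly slower at the higher pump
level; the rising mean delay under sustained Poisson stimulation and its
absence in the squid-axon control; the slow-K substitution raising the
mean delay with flat variability; the strict κ_min ordering
DA < control < I_h-block; voltage-regression coefficients remarkably
close to the published ones (c₁ ≈ 4.3·10³, c₂ ≈ 3.4·10², c₃ ≈ 80 against
4072.88, 302.36, 82.94) with R² ≈ 0.98; and the failure of both
closed-form velocity equations to track the slow delay drift.

Known shortfalls, all traceable to the narrow gap between the pump's
stability floor (~1.2 µA/cm², set by the subthreshold inward current) and
its 10 Hz flux equilibrium (~1.5 µA/cm²): the STS rise of D_mean is a few
percent rather than tens of percent, so the delay variability (CV-D),
dominated by the fast-timescale spread, does not rise measurably across
bins (and decreases along a frozen-pump grid); the κ_min magnitudes are
several-fold below the published 0.003–0.009 ms/Hz²; the paired-pulse
cubic predicts the Poisson delays with R² ≈ 0.84 rather than ≈ 0.94
(much of the gap is the clamped extrapolation for intervals below the
10 ms paired-pulse floor); and only two of the six gating-rate pairs
reach R² > 0.9 rather than five. A larger pump-level excursion would
require either a weaker subthreshold Na+ window current or a leak
reversal at or below the K+ reversal, i.e. a departure from the printed
values, which the package declines to make.

## Problem sizes

The shipped tests and the acceptance script use: full 100 s pre-runs at a
0.1 ms step; 300 s Poisson protocols at the 0.0125 ms default step for
the three I_h variants; a 120 s squid-control run and a 300 s slow-K run;
30-point recovery grids at two pump levels; a four-level frozen-pump
grid with 45 s epochs; and 50-seed surrogate-recovery batteries. On one
CPU the whole test suite runs in roughly ten minutes and the acceptance
script in under ten.
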