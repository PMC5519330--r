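# axondelay

Spike conduction delay in unmyelinated axons is history-dependent: each
spike's travel time depends on what the axon did over the preceding
milliseconds *and* over the preceding minutes. `axondelay` is a
conductance-based multicompartment model of such an axon — patterned on
the pyloric dilator motor axon of the crustacean stomatogastric nervous
system — together with the complete analysis pipeline for characterizing
and predicting that history-dependence.

The model integrates the cable equation

    (a / 2R_i) ∂²V/∂x² = C_m ∂V/∂t + Σ I_ion + I_pump + I_app(t)

over 101 compartments with Hodgkin–Huxley-type currents
(I = ḡ mᵖ hᵠ (V − E_rev): fast Na⁺ with dynamic Nernst reversal,
delayed-rectifier and A-type K⁺, leak, hyperpolarization-activated I_h)
and an electrogenic Na⁺/K⁺ pump,
I_pump = I_max / (1 + exp(([Na⁺]_½ − [Na⁺]_in)/[Na⁺]_S)), driven by
intracellular Na⁺ accumulation, d[Na⁺]_in/dt = −(I_Na + 3 I_pump)/(αF·Vol).

Two phenomena emerge and are quantified by the package:

* **slow timescale** — the pump current grows over minutes of repetitive
  firing, hyperpolarizes the baseline, and raises the mean conduction
  delay (D_mean, computed in 20 s bins together with the coefficient of
  variation CV-D);
* **fast timescale** — delay depends non-monotonically on the
  instantaneous stimulus frequency F_inst (supernormal/refractory
  recovery cycle), summarized by a quadratic fit's minimum (F_min,
  D_min) and vertex curvature κ_min.

On top of the simulator: Poisson / paired-pulse / parabolic-burst
protocol generators, recovery-cycle analysis at frozen pump levels with
a cubic delay-vs-F_inst predictor, the Matsumoto–Tasaki and Muratov
closed-form velocity estimates, empirical delay regressions on Na⁺
gating rates (d = c₁/α_m(V_T) + c₂/β_h(V_P) + c₃) or on spike
trough/peak voltages (d = c₁/V_T + c₂/V_P + c₃) fitted with Powell's
method, a ±5 %/±10 % parameter-sensitivity battery, and a fast surrogate
spike-feature generator for testing the analysis layer.

## Worked example

Simulate the I_h-blocked variant under 60 s of 10 Hz Poisson stimulation
(after its standard 100 s silent pre-run), and look at the delay history:

```r
library(axondelay)
model <- axon_model("gh_block")
run <- poisson_protocol(model, rate_hz = 10, duration_s = 60, seed = 1)

head(as.data.frame(run$series)[, c("t_stim_ms","delay_ms","Finst_Hz","VT_mV","VP_mV")], 3)
#>   t_stim_ms delay_ms  Finst_Hz     VT_mV    VP_mV
#> 1  75.51818 33.08159        NA -71.89970 27.64184
#> 2 193.68246 32.95592  8.462794 -71.65856 27.21912
#> 3 208.25313 35.20049 68.631011 -70.14465 20.81976

binned_delay_stats(run$series)
#>   bin_start_s bin_end_s   n d_mean_ms       cv_d
#> 1           0        20 192  33.32942 0.03875923
#> 2          20        40 197  33.54412 0.04093676
#> 3          40        60 173  33.65812 0.03606078

fts_quadratic_fit(run$series)
#> <fts_fit> n = 561 | F_min = 16.5 Hz, D_min = 33.11 ms, kappa_min = 0.001311 ms/Hz^2

voltage_delay_regression(run$series)
#> <regression_fit> voltage_pair (1/VT, 1/VP): c = (4700, 313, 86.93), R^2 = 0.9859, n = 562
```

Reading the output: each 1 nA/1 ms pulse evokes one spike whose
conduction delay (threshold crossings at 0.3 L and 0.7 L, scaled ×9.5 to
the biological axon length) is ~33 ms. The spike at 208 ms follows its
predecessor by 14.6 ms (F_inst ≈ 69 Hz): its trough rides 1.7 mV above
baseline (summation) while its peak is depressed by 6 mV (Na⁺
inactivation), and it conducts ~2 ms slower (relative refractory). The
binned means rise as the pump builds up; the quadratic delay–frequency
fit has an interior minimum; and the reciprocal trough/peak-voltage
regression explains ~99 % of the delay variance with coefficients of the
same magnitude as the gating-rate mechanism they proxy.

The vignette (`vignettes/delay-history.Rmd`) describes the model, the
numerical scheme, and every calibration decision in detail.

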