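# Published parameter set of the PD-axon conduction model, key for key.
# Conductances in mS/cm2, potentials in mV, concentrations in mM,
# time constants in ms. Gate steady states are Boltzmann sigmoids
# 1/(1 + exp(sign * (V - v_half)/slope)) with sign = -1 for activation.
channels:
  Na:   {gbar: 14,    erev: dynamic}
  Kd:   {gbar: 3,     erev: -70}
  Leak: {gbar: 0.125, erev: -65}
  A:    {gbar: 5,     erev: -70}
  h_ctrl: {gbar: 0.05, erev: -32}
  h_DA:   {gbar: 0.1,  erev: -25}
  Ks:   {gbar: 3,     erev: -70}
gates:
  Na.m:     {kind: activation,   v_half: -48, slope: 8.5, p: 3}
  Na.h:     {kind: inactivation, v_half: -47, slope: 6,   q: 1}
  Kd.m:     {kind: activation,   v_half: -47, slope: 10,  p: 4}
  A.m:      {kind: activation,   v_half: -63, slope: 15,  p: 3}
  A.h:      {kind: inactivation, v_half: -80, slope: 8,   q: 1, tau_const: 50}
  h_ctrl.m: {kind: inactivation, v_half: -80, slope: 5.5, p: 1, tau_const: 3700}
  h_DA.m:   {kind: inactivation, v_half: -75, slope: 12.5, p: 1, tau_const: 3800}
  Ks.m:     {kind: activation,   v_half: -47, slope: 10,  p: 1}
pump:
  i_max: 2000        # printed as 2 mA/cm2
  na_half: 78
  na_s: 2
  alpha: 7.4
  vol_um3: 7850
  faraday: 96485
geometry:
  radius_um: 5       # published passive geometry (lambda = 1581 um)
  length_cm: 1
  n_comp: 101
  r_i_ohm_cm: 80
  c_m_uF_cm2: 1
  r_m_kohm_cm2: 8
stimulus:
  amplitude_nA: 1
  width_ms: 1
  threshold_mV: -40
  delay_scale: 9.5
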