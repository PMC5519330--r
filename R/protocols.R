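#' Run a full Poisson stimulation protocol
#'
#' The standard characterization protocol: a stimulus-free pre-run
#' (default 100 s) to remove initial-condition transients, followed by
#' Poisson stimulation at the given mean rate, with per-spike features
#' extracted. State carries over from the pre-run with no reset.
#'
#' @param model an [axon_model()].
#' @param rate_hz mean stimulation rate (Hz).
#' @param duration_s stimulation duration (s).
#' @param seed stimulus seed.
#' @param prerun_s stimulus-free pre-run duration (s).
#' @param dt integration step for the stimulated segment (ms).
#' @param prerun_dt coarser step for the spike-free pre-run (ms).
#' @return list with `sim` (the stimulated `axon_sim`), `series` (the
#'   `spike_series` with gating-rate features), and `stimulus`.
#' @export
poisson_protocol <- function(model, rate_hz = 10, duration_s = 300, seed = 1,
                             prerun_s = 100, dt = 0.0125, prerun_dt = 0.1) {
  rest <- relax_to_rest(model, duration_s = prerun_s, dt = prerun_dt)
  stim <- poisson_train(rate_hz, duration_s, seed = seed)
  sim <- simulate_axon(model, stim, t_end_ms = duration_s * 1e3 + 150,
                       dt = dt, state = rest)
  list(sim = sim, series = gate_rate_features(build_spike_series(sim, stim)),
       stimulus = stim)
}

#' Run a parabolic-burst stimulation protocol
#'
#' @inheritParams poisson_protocol
#' @param n_bursts number of bursts (1 Hz burst rate).
#' @param ... further arguments to [parabolic_burst_train()].
#' @export
burst_protocol <- function(model, n_bursts = 300, prerun_s = 100,
                           dt = 0.0125, prerun_dt = 0.1, ...) {
  rest <- relax_to_rest(model, duration_s = prerun_s, dt = prerun_dt)
  stim <- parabolic_burst_train(n_bursts = n_bursts, ...)
  sim <- simulate_axon(model, stim, t_end_ms = max(stim$onset_ms) + 150,
                       dt = dt, state = rest)
  list(sim = sim, series = gate_rate_features(build_spike_series(sim, stim)),
       stimulus = stim)
}
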