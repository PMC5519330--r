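#' Surrogate spike-feature generator parameters
#'
#' The surrogate emulates the statistical structure of the simulated
#' spike-feature series without running the cable model, so the analysis
#' and regression stages can be exercised in milliseconds. Per spike,
#' \deqn{V_T = V_{T0} - drift(t) + g(t)\, A_{sum} e^{-ISI/\tau_{sum}}}
#' \deqn{V_P = V_{P0} - g(t)\, A_{dep} e^{-ISI/\tau_{dep}}}
#' \deqn{d = c_1/V_T + c_2/V_P + c_3 + \epsilon}
#' where \eqn{drift(t) = A_{drift}(1 - e^{-t/\tau_{drift}})} is the slow
#' pump-like baseline hyperpolarization, the two single-exponential ISI
#' kernels produce the fast supernormal (trough summation) and refractory
#' (peak depression) effects, and \eqn{g(t) = 1 + \gamma\, drift(t)}
#' lets the fast-timescale kernels deepen as the baseline hyperpolarizes,
#' as the biophysical model's do (this also makes delay variability grow
#' along with the mean). Defaults use the published voltage-regression
#' coefficients and drift/kernel magnitudes in the few-mV range typical
#' of the axon.
#'
#' @param c1,c2,c3 true coefficients of the reciprocal-voltage delay law
#'   (ms mV, ms mV, ms).
#' @param vt0,vp0 baseline trough and peak voltages (mV).
#' @param drift_mV,drift_tau_s slow hyperpolarization amplitude (mV) and
#'   time constant (s).
#' @param sum_mV,sum_tau_ms trough-summation kernel amplitude (mV) and
#'   ISI scale (ms).
#' @param dep_mV,dep_tau_ms peak-depression kernel amplitude (mV) and ISI
#'   scale (ms).
#' @param fts_gain_per_mV growth of the fast kernels per mV of
#'   accumulated drift (1/mV).
#' @param noise_sd_ms additive Gaussian delay noise SD (ms).
#' @export
surrogate_params <- function(c1 = 4072.88, c2 = 302.36, c3 = 82.94,
                             vt0 = -65, vp0 = 40,
                             drift_mV = 4, drift_tau_s = 60,
                             sum_mV = 3, sum_tau_ms = 80,
                             dep_mV = 15, dep_tau_ms = 25,
                             fts_gain_per_mV = 0.15,
                             noise_sd_ms = 0.1) {
  stopifnot(noise_sd_ms >= 0, drift_tau_s > 0, sum_tau_ms > 0, dep_tau_ms > 0)
  structure(list(c1 = c1, c2 = c2, c3 = c3, vt0 = vt0, vp0 = vp0,
                 drift_mV = drift_mV, drift_tau_s = drift_tau_s,
                 sum_mV = sum_mV, sum_tau_ms = sum_tau_ms,
                 dep_mV = dep_mV, dep_tau_ms = dep_tau_ms,
                 fts_gain_per_mV = fts_gain_per_mV,
                 noise_sd_ms = noise_sd_ms),
            class = "surrogate_params")
}

.surrogate_features <- function(p, t_ms, isi_ms) {
  drift <- p$drift_mV * (1 - exp(-t_ms / (p$drift_tau_s * 1e3)))
  gain <- 1 + p$fts_gain_per_mV * drift
  ksum <- ifelse(is.finite(isi_ms), exp(-isi_ms / p$sum_tau_ms), 0)
  kdep <- ifelse(is.finite(isi_ms), exp(-isi_ms / p$dep_tau_ms), 0)
  vt <- p$vt0 - drift + gain * p$sum_mV * ksum
  vp <- p$vp0 - gain * p$dep_mV * kdep
  if (any(vt >= -1))
    stop("surrogate parameters drive V_T above -1 mV; delay law undefined")
  list(vt = vt, vp = vp)
}

#' Generate a surrogate spike-feature series
#'
#' @param params a [surrogate_params()].
#' @param stimulus a [stimulus_train()]; every pulse yields one spike.
#' @param seed RNG seed for the delay noise.
#' @return a `spike_series` data frame (same columns as the simulated
#'   series, with placeholder crossing times consistent with the delays).
#' @export
generate_surrogate <- function(params, stimulus, seed = 1) {
  stopifnot(inherits(params, "surrogate_params"),
            inherits(stimulus, "stimulus_train"))
  t <- stimulus$onset_ms
  stopifnot(!is.unsorted(t, strictly = TRUE))
  isi <- c(Inf, diff(t))
  f <- .surrogate_features(params, t, isi)
  delay <- params$c1 / f$vt + params$c2 / f$vp + params$c3
  delay <- delay + .with_seed(seed, stats::rnorm(length(t), 0, params$noise_sd_ms))
  t1 <- t + 1
  out <- data.frame(
    t_stim_ms = t, t1_ms = t1, t2_ms = t1 + delay / 9.5,
    tpeak1_ms = t1 + 0.5, tpeak2_ms = t1 + 0.5 + delay / 9.5,
    delay_ms = delay, delay_peak_ms = delay,
    Finst_Hz = 1e3 / isi, VT_mV = f$vt, VP_mV = f$vp,
    ENa_mV = 50, hT = NA_real_)
  out$Finst_Hz[1] <- NA_real_
  structure(out, class = c("spike_series", "data.frame"),
            params = params, seed = seed)
}

#' Surrogate recovery-cycle series
#'
#' Conditioning/test feature pairs for an ISI grid, built from the same
#' delay law (conditioning spikes carry the rest features; test spikes
#' the ISI-kernel features), for end-to-end testing of the paired-pulse
#' predictor without simulation.
#'
#' @param params a [surrogate_params()].
#' @param isi_ms ISI grid (ms).
#' @param t_ms epoch time at which the trials nominally occur (sets the
#'   drift state; 0 = fresh).
#' @return a `recovery_curve`-shaped data frame with `isi_ms`, `Finst_Hz`,
#'   `delay_cond_ms`, `delay_test_ms`, `VT_mV`, `VP_mV`.
#' @export
recovery_surrogate <- function(params, isi_ms = 10^seq(1, 4, length.out = 30),
                               t_ms = 0) {
  f0 <- .surrogate_features(params, t_ms, Inf)
  d0 <- params$c1 / f0$vt + params$c2 / f0$vp + params$c3
  ft <- .surrogate_features(params, rep(t_ms, length(isi_ms)), isi_ms)
  dt_ <- params$c1 / ft$vt + params$c2 / ft$vp + params$c3
  structure(data.frame(isi_ms = isi_ms, Finst_Hz = 1e3 / isi_ms,
                       delay_cond_ms = d0, delay_test_ms = dt_,
                       VT_mV = ft$vt, VP_mV = ft$vp, failed = FALSE),
            class = c("recovery_curve", "data.frame"), params = params)
}
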