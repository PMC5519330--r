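#' Binned delay statistics (slow-timescale summary)
#'
#' Mean conduction delay (D_mean) and its coefficient of variation (CV-D)
#' in consecutive time bins (default 20 s) over the stimulation epoch.
#'
#' @param series a `spike_series`.
#' @param bin_s bin width (s).
#' @param t_range optional c(start, end) of the epoch (s); defaults to
#'   \[0, last stimulus\] rounded up to a whole bin.
#' @return data frame `bin_start_s`, `bin_end_s`, `n`, `d_mean_ms`, `cv_d`;
#'   empty bins yield `NA`, not zero.
#' @export
binned_delay_stats <- function(series, bin_s = 20, t_range = NULL) {
  t_s <- series$t_stim_ms / 1e3
  if (is.null(t_range))
    t_range <- c(0, ceiling(max(t_s) / bin_s) * bin_s)
  breaks <- seq(t_range[1], t_range[2], by = bin_s)
  if (breaks[length(breaks)] < t_range[2]) breaks <- c(breaks, t_range[2])
  bin <- cut(t_s, breaks, right = FALSE, labels = FALSE)
  out <- data.frame(bin_start_s = breaks[-length(breaks)],
                    bin_end_s = breaks[-1])
  out$n <- vapply(seq_len(nrow(out)), function(b) sum(bin == b, na.rm = TRUE), 0L)
  out$d_mean_ms <- vapply(seq_len(nrow(out)), function(b) {
    d <- series$delay_ms[which(bin == b)]
    if (length(d)) mean(d) else NA_real_
  }, 0)
  out$cv_d <- vapply(seq_len(nrow(out)), function(b) {
    d <- series$delay_ms[which(bin == b)]
    if (length(d) >= 2) stats::sd(d) / mean(d) else NA_real_
  }, 0)
  out
}

#' Quadratic fit of delay versus instantaneous frequency (fast timescale)
#'
#' Least-squares fit of \eqn{d = a F^2 + b F + c} to the (unbinned) spikes
#' of an epoch. Summarized by the vertex frequency `F_min = -b/2a`, the
#' minimum delay `D_min = c - b^2/4a`, and the curvature at the vertex
#' `kappa_min = 2a` (ms/Hz^2): larger curvature, stronger non-monotonic
#' frequency dependence.
#'
#' @param series a `spike_series` (spikes without a defined F_inst are
#'   dropped).
#' @param epoch_s optional half-open stimulus-time window \[start, end) in
#'   seconds, e.g. `c(0, 60)` for minute 1, `c(240, 300)` for minute 5.
#' @param min_spikes minimum number of usable spikes.
#' @return an `fts_fit` list: coefficients `a`, `b`, `c`, `F_min_Hz`,
#'   `D_min_ms`, `kappa_min`, `n`, `valid` (`FALSE` when the parabola has
#'   no interior minimum, i.e. `a <= 0`), `f_range_Hz`.
#' @export
fts_quadratic_fit <- function(series, epoch_s = NULL, min_spikes = 10) {
  d <- as.data.frame(series)[, c("t_stim_ms", "Finst_Hz", "delay_ms")]
  if (!is.null(epoch_s))
    d <- d[d$t_stim_ms >= epoch_s[1] * 1e3 & d$t_stim_ms < epoch_s[2] * 1e3, ]
  d <- d[is.finite(d$Finst_Hz), ]
  if (nrow(d) < min_spikes)
    stop("need at least ", min_spikes, " spikes with defined F_inst")
  fit <- stats::lm(delay_ms ~ Finst_Hz + I(Finst_Hz^2), data = d)
  cf <- stats::coef(fit)
  a <- unname(cf[3]); b <- unname(cf[2]); cc <- unname(cf[1])
  fr <- range(d$Finst_Hz)
  # a well-formed minimum needs upward curvature AND a vertex inside the
  # observed frequency range (a near-linear fit puts it far outside)
  valid <- is.finite(a) && a > 0 &&
    -b / (2 * a) > fr[1] && -b / (2 * a) < fr[2]
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((d$delay_ms - mean(d$delay_ms))^2)
  structure(list(a = a, b = b, c = cc,
                 F_min_Hz = if (valid) -b / (2 * a) else NA_real_,
                 D_min_ms = if (valid) cc - b^2 / (4 * a) else NA_real_,
                 kappa_min = 2 * a, n = nrow(d), valid = valid,
                 f_range_Hz = fr,
                 r_squared = r2),
            class = "fts_fit")
}

#' @export
print.fts_fit <- function(x, ...) {
  cat(sprintf(
    "<fts_fit> n = %d | F_min = %.1f Hz, D_min = %.2f ms, kappa_min = %.4g ms/Hz^2%s\n",
    x$n, x$F_min_Hz, x$D_min_ms, x$kappa_min,
    if (!x$valid) " [no interior minimum]" else ""))
  invisible(x)
}

#' Recovery cycle from paired-pulse simulations at constant pump current
#'
#' Runs one conditioning + test pulse pair per inter-stimulus interval,
#' every trial starting from the identical resting state of the model with
#' its pump frozen at `ipump_const` (mimicking a given level of prior
#' activity). Conduction velocity is the scaled propagation distance over
#' the measured delay. ISIs where the test spike slows below the
#' conditioning baseline form the relative refractory phase; ISIs where it
#' is faster form the supernormal phase.
#'
#' @param model an [axon_model()] (its pump setting is overridden).
#' @param ipump_const frozen pump current density (uA/cm^2).
#' @param isi_ms ISI grid (ms).
#' @param dt integration step (ms).
#' @param settle_s stimulus-free settling time at the frozen pump before
#'   trials (s); long enough for the slow h-current gate.
#' @param tail_ms post-test simulated margin (ms).
#' @return a `recovery_curve` data frame: `isi_ms`, `Finst_Hz`,
#'   `delay_cond_ms`, `delay_test_ms`, `v_cond`, `v_test` (m/s), `phase`
#'   (refractory / supernormal / recovered), `failed`; the conditioning
#'   baseline velocity and the trial spike features are attached as
#'   attributes (`series` holds the per-trial test-spike features).
#' @export
recovery_cycle <- function(model, ipump_const, isi_ms = 10^seq(1, 4, length.out = 30),
                           dt = 0.0125, settle_s = 30, tail_ms = 80) {
  cmodel <- axon_model(model$variant, pump = "constant",
                       ipump_const = ipump_const, scales = list(),
                       geometry = model$geometry, pump_pars = model$pump_pars)
  rest <- relax_to_rest(cmodel, duration_s = settle_s)
  dist_cm <- 0.4 * cmodel$geometry$length_cm * cmodel$delay_scale
  trials <- paired_pulse_set(isi_ms)
  rows <- lapply(seq_along(trials), function(i) {
    st <- trials[[i]]
    sim <- simulate_axon(cmodel, st, t_end_ms = max(st$onset_ms) + tail_ms,
                         dt = dt, state = rest, sample_dt_ms = 1e6)
    ser <- tryCatch(build_spike_series(sim, st), error = function(e) NULL)
    if (is.null(ser) || nrow(ser) < 2)
      return(data.frame(isi_ms = isi_ms[i], Finst_Hz = 1e3 / isi_ms[i],
                        delay_cond_ms = NA, delay_test_ms = NA,
                        v_cond = NA, v_test = NA, VT_mV = NA, VP_mV = NA,
                        failed = TRUE))
    data.frame(isi_ms = isi_ms[i], Finst_Hz = 1e3 / isi_ms[i],
               delay_cond_ms = ser$delay_ms[1], delay_test_ms = ser$delay_ms[2],
               v_cond = dist_cm / ser$delay_ms[1] * 10, # cm/ms -> m/s
               v_test = dist_cm / ser$delay_ms[2] * 10,
               VT_mV = ser$VT_mV[2], VP_mV = ser$VP_mV[2],
               failed = FALSE)
  })
  out <- do.call(rbind, rows)
  v0 <- stats::median(out$v_cond, na.rm = TRUE)
  tol <- 1e-3 * v0
  out$phase <- ifelse(out$failed, NA,
                 ifelse(out$v_test < v0 - tol, "refractory",
                   ifelse(out$v_test > v0 + tol, "supernormal", "recovered")))
  structure(out, class = c("recovery_curve", "data.frame"),
            v_baseline = v0, ipump_const = ipump_const, model = cmodel)
}

#' Cubic delay-versus-frequency predictor from a recovery curve
#'
#' Fits test-pulse delay against F_inst = 1/ISI with a cubic polynomial
#' and uses it to predict the delay of each spike of another series from
#' that spike's F_inst alone. Frequencies outside the fitted range are
#' clamped to its boundary (and flagged).
#'
#' @param curve a [recovery_cycle()] result (or any data frame with
#'   `Finst_Hz` and `delay_test_ms`).
#' @return a `paired_pulse_predictor` object with elements `fit` (lm),
#'   `f_range_Hz`, and methods via [predict_delay()].
#' @export
paired_pulse_predictor <- function(curve) {
  d <- as.data.frame(curve)
  d <- d[!is.na(d$delay_test_ms), ]
  fit <- stats::lm(delay_test_ms ~ Finst_Hz + I(Finst_Hz^2) + I(Finst_Hz^3),
                   data = d)
  structure(list(fit = fit, f_range_Hz = range(d$Finst_Hz), train = d),
            class = "paired_pulse_predictor")
}

#' Predict per-spike delays and score against observations
#'
#' @param object a `paired_pulse_predictor`.
#' @param series a `spike_series` (or recovery curve) with `Finst_Hz`;
#'   spikes without F_inst are dropped.
#' @return data frame `Finst_Hz`, `delay_obs_ms`, `delay_pred_ms`,
#'   `extrapolated`; the coefficient of determination against the observed
#'   delays is attached as attribute `r_squared`.
#' @export
predict_delay <- function(object, series) {
  stopifnot(inherits(object, "paired_pulse_predictor"))
  d <- as.data.frame(series)
  dcol <- if ("delay_ms" %in% names(d)) "delay_ms" else "delay_test_ms"
  d <- d[is.finite(d$Finst_Hz), ]
  f <- pmin(pmax(d$Finst_Hz, object$f_range_Hz[1]), object$f_range_Hz[2])
  pred <- stats::predict(object$fit, data.frame(Finst_Hz = f))
  obs <- d[[dcol]]
  out <- data.frame(Finst_Hz = d$Finst_Hz, delay_obs_ms = obs,
                    delay_pred_ms = as.numeric(pred),
                    extrapolated = d$Finst_Hz != f)
  attr(out, "r_squared") <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  out
}

#' Epoch-mean pump current of a simulation
#'
#' Time-average of the recorded dynamic pump current over a stimulus-time
#' window; used to freeze the pump at "minute-1" or "minute-5" levels for
#' recovery-cycle and sensitivity runs.
#'
#' @param sim an `axon_sim` with dynamic pump samples.
#' @param epoch_s c(start, end) window in seconds of protocol time.
#' @return mean pump current density (uA/cm^2).
#' @export
mean_pump_current <- function(sim, epoch_s) {
  s <- sim$samples
  keep <- s$t_ms >= epoch_s[1] * 1e3 & s$t_ms < epoch_s[2] * 1e3
  if (!any(keep)) stop("no pump samples in the requested epoch")
  mean(s$ipump[keep])
}
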