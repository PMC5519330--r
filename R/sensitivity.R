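#' Delay-history attributes of one simulation
#'
#' The five scalar attributes used by the sensitivity analysis:
#' `d_mean_ms` and `cv_d` (mean and coefficient of variation of delay in
#' the final 20 s of the epoch, the slow-timescale attributes) and
#' `F_min_Hz`, `D_min_ms`, `kappa_min` from the quadratic delay-frequency
#' fit over the whole epoch (the fast-timescale attributes).
#'
#' @param series a `spike_series`.
#' @param final_bin_s width of the terminal window for D_mean/CV-D (s).
#' @return named numeric vector of the five attributes (NA where a spike
#'   shortage or an invalid fit prevents evaluation).
#' @export
delay_attributes <- function(series, final_bin_s = 20) {
  t_end <- max(series$t_stim_ms) / 1e3
  last <- series[series$t_stim_ms / 1e3 >= t_end - final_bin_s, ]
  d_mean <- if (nrow(last)) mean(last$delay_ms) else NA_real_
  cv <- if (nrow(last) >= 2) stats::sd(last$delay_ms) / d_mean else NA_real_
  qf <- tryCatch(fts_quadratic_fit(series), error = function(e) NULL)
  c(d_mean_ms = d_mean, cv_d = cv,
    F_min_Hz = if (!is.null(qf) && qf$valid) qf$F_min_Hz else NA_real_,
    D_min_ms = if (!is.null(qf) && qf$valid) qf$D_min_ms else NA_real_,
    kappa_min = if (!is.null(qf)) qf$kappa_min else NA_real_)
}

#' One perturbed sensitivity run
#'
#' Rebuilds the model with a single parameter multiplied by `scale`, runs
#' the given Poisson stimulus from rest at a frozen pump current (so the
#' attributes are stationary and the epoch length only sets the noise),
#' and measures the delay-history attributes. The same stimulus (same
#' seed) is reused across all perturbations, pairing away train-sampling
#' variance.
#'
#' @param variant model variant name (see [axon_model()]).
#' @param parameter one of the scale-parameter names of [axon_model()]
#'   (e.g. `"g_Na"`, `"E_K"`, `"tau_h_Na"`).
#' @param scale multiplicative factor (1 = reference).
#' @param stimulus the shared [stimulus_train()].
#' @param ipump_const frozen pump current density (uA/cm^2).
#' @param dt integration step (ms).
#' @param settle_s pre-trial settling time at the frozen pump (s).
#' @return attribute vector as in [delay_attributes()] (all NA if the
#'   perturbed model fails to spike).
#' @export
perturbed_run <- function(variant, parameter, scale, stimulus, ipump_const,
                          dt = 0.0125, settle_s = 30) {
  scales <- if (scale == 1) list() else stats::setNames(list(scale), parameter)
  if (!parameter %in% .known_scales)
    stop("unknown parameter '", parameter, "'")
  model <- axon_model(variant, pump = "constant", ipump_const = ipump_const,
                      scales = scales)
  rest <- relax_to_rest(model, duration_s = settle_s)
  sim <- simulate_axon(model, stimulus,
                       t_end_ms = max(stimulus$onset_ms) + 100,
                       dt = dt, state = rest)
  ser <- tryCatch(build_spike_series(sim, stimulus), error = function(e) NULL)
  if (is.null(ser) || nrow(ser) < 10)
    return(c(d_mean_ms = NA_real_, cv_d = NA_real_, F_min_Hz = NA_real_,
             D_min_ms = NA_real_, kappa_min = NA_real_))
  delay_attributes(ser)
}

#' Sensitivity slope from fractional changes
#'
#' Ordinary least-squares slope of fractional attribute change against
#' fractional parameter change through the five perturbation points
#' (the reference sits at the origin). A slope of 1 means a +-5%/10%
#' parameter change moves the attribute by +-5%/10%.
#'
#' @param dp_over_p fractional parameter changes (e.g.
#'   `c(-0.1, -0.05, 0, 0.05, 0.1)`).
#' @param dattr_over_attr matching fractional attribute changes.
#' @return list `slope`, `residual_sd`, `n_points`, `partial` (TRUE when
#'   missing attributes reduced the design).
#' @export
sensitivity_slope <- function(dp_over_p, dattr_over_attr) {
  keep <- is.finite(dp_over_p) & is.finite(dattr_over_attr)
  n <- sum(keep)
  if (n < 2)
    return(list(slope = NA_real_, residual_sd = NA_real_, n_points = n,
                partial = TRUE))
  fit <- stats::lm(dattr_over_attr[keep] ~ dp_over_p[keep])
  list(slope = unname(stats::coef(fit)[2]),
       residual_sd = stats::sigma(fit),
       n_points = n, partial = n < length(dp_over_p))
}

#' Parameter-perturbation sensitivity battery
#'
#' For each parameter, runs the model at scale factors 0.90, 0.95, 1.00,
#' 1.05, 1.10 under the identical Poisson stimulus and frozen pump
#' current, and fits the sensitivity slope of every delay-history
#' attribute.
#'
#' @inheritParams perturbed_run
#' @param parameters parameter names to perturb.
#' @param scales perturbation factors (must include 1).
#' @return long-format data frame: `parameter`, `attribute`,
#'   `pump_context` (the frozen pump level), `slope`, `residual_sd`,
#'   `n_points`.
#' @export
run_sensitivity <- function(variant, parameters, stimulus, ipump_const,
                            scales = c(0.90, 0.95, 1.00, 1.05, 1.10),
                            dt = 0.0125, settle_s = 30) {
  stopifnot(1 %in% scales)
  rows <- list()
  for (p in parameters) {
    attrs <- lapply(scales, function(s)
      perturbed_run(variant, p, s, stimulus, ipump_const, dt = dt,
                    settle_s = settle_s))
    ref <- attrs[[which(scales == 1)[1]]]
    mat <- do.call(rbind, attrs)
    for (a in colnames(mat)) {
      sl <- sensitivity_slope(scales - 1, (mat[, a] - ref[[a]]) / ref[[a]])
      rows[[length(rows) + 1]] <- data.frame(
        parameter = p, attribute = a, pump_context = ipump_const,
        slope = sl$slope, residual_sd = sl$residual_sd,
        n_points = sl$n_points)
    }
  }
  do.call(rbind, rows)
}
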