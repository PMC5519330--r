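#' Matsumoto-Tasaki conduction-velocity estimate
#'
#' Closed-form single-spike velocity from the excited-state membrane
#' resistance: \eqn{v = \sqrt{d/(8 R_{total} R_i C_m^2)}}, with the full
#' form carrying the correction \eqn{(1-\kappa)^2/(1+\kappa)} under the
#' root, where \eqn{\kappa = R_{total}/R_{rest}} (at \eqn{\kappa = 0} the
#' two coincide).
#'
#' @param r_total excited-state membrane resistance of unit area
#'   (kOhm cm^2), e.g. from [spike_peak_conductance()].
#' @param geom an [axon_geometry()].
#' @param kappa ratio R_total/R_rest (default 0, the simplified form).
#' @return velocity (m/s).
#' @export
matsumoto_tasaki_velocity <- function(r_total, geom = axon_geometry(), kappa = 0) {
  if (any(r_total <= 0)) stop("r_total must be positive")
  d_m <- 2 * geom$radius_um * 1e-6
  r_si <- r_total * 1e3 * 1e-4      # kOhm cm^2 -> Ohm m^2
  ri_si <- geom$r_i * 1e-2          # Ohm cm -> Ohm m
  cm_si <- geom$c_m * 1e-2          # uF/cm^2 -> F/m^2
  sqrt(d_m / (8 * r_si * ri_si * cm_si^2) * (1 - kappa)^2 / (1 + kappa))
}

#' Muratov conduction-velocity estimate
#'
#' Analytic velocity for a Hodgkin-Huxley axon from the sodium activation
#' rate and resting inactivation:
#' \deqn{v = \frac{2}{3}\left(\frac{r^4 \bar\alpha_m^3 \bar g_{Na} h_0}
#'   {16 R_i^4 C_m^5}\right)^{1/8}}
#' with \eqn{\bar\alpha_m = \alpha_m(E_{Na}) - \alpha_m(V_{rest})} and
#' \eqn{h_0} the resting inactivation. During repetitive activity the
#' trough voltage before each spike stands in for the resting potential.
#'
#' @param v_rest resting (or per-spike trough) potential (mV).
#' @param model an [axon_model()] supplying the sodium kinetics and gbar.
#' @param e_na sodium reversal potential (mV); per-spike values may be
#'   supplied for the dynamic-reversal model.
#' @param h0 `"steady"` (default: \eqn{h_\infty(V_{rest})}) or
#'   `"instantaneous"`, in which case `h_inst` supplies the simulated
#'   inactivation value at the trough.
#' @param h_inst instantaneous h values (same length as `v_rest`).
#' @return velocity (m/s).
#' @export
muratov_velocity <- function(v_rest, model, e_na = 50,
                             h0 = c("steady", "instantaneous"),
                             h_inst = NULL) {
  h0 <- match.arg(h0)
  ng <- .na_gates(model)
  kna <- .na_channel_index(model)
  alpha_ena <- model_gate_rates(model, ng$m, e_na)$alpha * 1e3   # 1/s
  alpha_rest <- model_gate_rates(model, ng$m, v_rest)$alpha * 1e3
  abar <- alpha_ena - alpha_rest
  hv <- if (h0 == "steady") model$gates[[ng$h]]$xinf(v_rest)
        else { stopifnot(!is.null(h_inst)); h_inst }
  if (any(abar <= 0) || any(hv <= 0))
    stop("Muratov estimate undefined: need alpha_m(E_Na) > alpha_m(V_rest) and h0 > 0")
  r_m <- model$geometry$radius_um * 1e-6
  gna <- model$channels[[kna]]$gbar * 10  # mS/cm^2 -> S/m^2
  ri <- model$geometry$r_i * 1e-2
  cm <- model$geometry$c_m * 1e-2
  (2 / 3) * (r_m^4 * abar^3 * gna * hv / (16 * ri^4 * cm^5))^(1 / 8)
}

#' Per-spike delays implied by the published velocity equations
#'
#' Applies the Matsumoto-Tasaki estimate (from each spike's excited-state
#' conductance) and the Muratov estimate (from each spike's trough voltage
#' and sodium reversal) to a simulated series, converting velocity to the
#' scaled conduction delay over the recording distance.
#'
#' @param series a `spike_series` carrying gate-peak snapshots.
#' @param sim the `axon_sim` the series came from (for the conductance
#'   snapshots); optional if `series` still has its `gates_peak` attribute.
#' @return the series with columns `delay_mt_ms` and `delay_muratov_ms`.
#' @export
published_equation_delays <- function(series, sim = NULL) {
  model <- attr(series, "model")
  geom <- model$geometry
  dist_cm <- 0.4 * geom$length_cm * model$delay_scale
  if (!is.null(sim)) {
    pc <- spike_peak_conductance(sim)
  } else {
    gp <- attr(series, "gates_peak")
    stopifnot(!is.null(gp))
    fake <- list(spikes1 = list(gates_peak = gp), model = model)
    class(fake) <- "axon_sim"
    pc <- spike_peak_conductance(fake)
  }
  n <- nrow(series)
  v_mt <- matsumoto_tasaki_velocity(pc$r_total, geom)
  series$delay_mt_ms <- dist_cm * 1e-2 / v_mt[seq_len(n)] * 1e3 # m / (m/s) -> ms
  v_mu <- muratov_velocity(series$VT_mV, model, e_na = series$ENa_mV)
  series$delay_muratov_ms <- dist_cm * 1e-2 / v_mu * 1e3
  series
}

#' Two-feature linear delay regression
#'
#' Fits \eqn{d = c_1 x + c_2 y + c_3} by minimizing the sum of squared
#' residuals with Powell's conjugate-direction method (zero start), and
#' cross-checks against the closed-form least-squares solution — the
#' objective is convex, so both must coincide.
#'
#' @param x,y feature vectors.
#' @param delay observed delays (ms).
#' @param features character names of the two features (for reporting).
#' @param kind predictor kind label.
#' @return a `regression_fit`: `coef` (c1, c2, c3), `r_squared`,
#'   `coef_ls` (closed form), `powell_ls_gap` (max relative coefficient
#'   difference), `collinear` flag.
#' @export
fit_linear_combination <- function(x, y, delay, features = c("x", "y"),
                                   kind = "linear_pair") {
  keep <- is.finite(x) & is.finite(y) & is.finite(delay)
  x <- x[keep]; y <- y[keep]; d <- delay[keep]
  if (length(d) < 10) stop("need at least 10 spikes with finite features")
  X <- cbind(x, y, 1)
  qrX <- qr(X)
  collinear <- qrX$rank < 3
  coef_ls <- as.numeric(qr.coef(qrX, d))
  if (collinear) {
    coef_ls <- as.numeric(MASS::ginv(X) %*% d)
    coef_pw <- coef_ls
    gap <- NA_real_
  } else {
    # scale features so Powell's isotropic start behaves well
    sx <- stats::sd(x); sy <- stats::sd(y)
    obj <- function(p) sum((d - p[1] * x / sx - p[2] * y / sy - p[3])^2)
    pw <- powell_minimize(obj, c(0, 0, 0), tol = 1e-15)
    coef_pw <- c(pw$par[1] / sx, pw$par[2] / sy, pw$par[3])
    gap <- max(abs(coef_pw - coef_ls) / pmax(abs(coef_ls), 1e-12))
  }
  pred <- X %*% coef_ls
  r2 <- 1 - sum((d - pred)^2) / sum((d - mean(d))^2)
  structure(list(kind = kind, features = features,
                 coef = stats::setNames(coef_pw, c("c1", "c2", "c3")),
                 coef_ls = stats::setNames(coef_ls, c("c1", "c2", "c3")),
                 powell_ls_gap = gap, collinear = collinear,
                 r_squared = r2, n = length(d)),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> %s (%s, %s): c = (%.4g, %.4g, %.4g), R^2 = %.4f, n = %d%s\n",
              x$kind, x$features[1], x$features[2],
              x$coef[1], x$coef[2], x$coef[3], x$r_squared, x$n,
              if (isTRUE(x$collinear)) " [collinear]" else ""))
  invisible(x)
}

#' Rank all two-feature sodium-rate regressions
#'
#' Fits the delay series with every unordered pair of the four reciprocal
#' gating-rate features 1/alpha_m(V_T), 1/beta_m(V_P), 1/alpha_h(V_T),
#' 1/beta_h(V_P), ordered by goodness of fit, and flags which pairs
#' qualitatively capture both the slow drift (rising binned mean of the
#' prediction, like the data) and the fast non-monotonic frequency
#' dependence (convex quadratic of the prediction vs F_inst).
#'
#' @param series a `spike_series` with gate-rate features (see
#'   [gate_rate_features()]; they are added if missing).
#' @return list of `regression_fit` objects, decreasing R^2, each with
#'   elements `captures_sts` and `captures_fts`.
#' @export
rank_rate_pairs <- function(series) {
  if (!"inv_alpha_m" %in% names(series)) series <- gate_rate_features(series)
  feats <- c("inv_alpha_m", "inv_beta_m", "inv_alpha_h", "inv_beta_h")
  pairs <- utils::combn(feats, 2, simplify = FALSE)
  fits <- lapply(pairs, function(pr) {
    ft <- fit_linear_combination(series[[pr[1]]], series[[pr[2]]],
                                 series$delay_ms, features = pr,
                                 kind = "rate_pair")
    keep <- is.finite(series[[pr[1]]]) & is.finite(series[[pr[2]]]) &
      is.finite(series$delay_ms)
    sub <- series[keep, ]
    pred <- ft$coef_ls[1] * sub[[pr[1]]] + ft$coef_ls[2] * sub[[pr[2]]] +
      ft$coef_ls[3]
    psr <- sub
    psr$delay_ms <- pred
    bins <- binned_delay_stats(psr)
    bm <- bins$d_mean_ms[is.finite(bins$d_mean_ms)]
    ft$captures_sts <- length(bm) >= 2 &&
      stats::coef(stats::lm(bm ~ seq_along(bm)))[2] > 0
    qf <- tryCatch(fts_quadratic_fit(psr), error = function(e) NULL)
    ft$captures_fts <- !is.null(qf) && qf$valid &&
      qf$F_min_Hz > qf$f_range_Hz[1] && qf$F_min_Hz < qf$f_range_Hz[2]
    ft
  })
  fits[order(vapply(fits, `[[`, 0, "r_squared"), decreasing = TRUE)]
}

#' Reciprocal trough/peak-voltage delay regression
#'
#' The empirical voltage equation
#' \eqn{d = c_1/V_T + c_2/V_P + c_3} (voltages in mV, V_T negative):
#' within the narrow voltage ranges visited by the trough and the peak,
#' the sodium gating rates are nearly linear in voltage, so the voltages
#' stand in for the gating-rate features. Once the model axon is fixed,
#' the fitted coefficients transfer across stimulation patterns.
#'
#' @param series a `spike_series` (rows with zero voltages are skipped).
#' @param ablate `"none"`, `"fix_VP"` or `"fix_VT"`: the single-variable
#'   variants in which the other voltage is frozen at its mean.
#' @return a `regression_fit` (kind `voltage_pair`), with the frozen-value
#'   bookkeeping attached when ablated.
#' @export
voltage_delay_regression <- function(series, ablate = c("none", "fix_VP", "fix_VT")) {
  ablate <- match.arg(ablate)
  vt <- series$VT_mV
  vp <- series$VP_mV
  keep <- vt != 0 & vp != 0
  vt <- vt[keep]; vp <- vp[keep]
  if (ablate == "fix_VP") vp <- rep(mean(vp), length(vp))
  if (ablate == "fix_VT") vt <- rep(mean(vt), length(vt))
  fit <- fit_linear_combination(1 / vt, 1 / vp, series$delay_ms[keep],
                                features = c("1/VT", "1/VP"),
                                kind = paste0("voltage_pair",
                                              if (ablate != "none") paste0(":", ablate)))
  fit$frozen <- switch(ablate, none = NULL,
                       fix_VP = c(VP_mV = mean(series$VP_mV[keep])),
                       fix_VT = c(VT_mV = mean(series$VT_mV[keep])))
  fit$ablate <- ablate
  fit
}

#' Apply a voltage (or rate-pair) regression to new spike features
#'
#' @param fit a `regression_fit` from [voltage_delay_regression()] or
#'   [fit_linear_combination()].
#' @param series a `spike_series` (or recovery-curve test-spike table)
#'   with the fit's feature columns (`VT_mV`/`VP_mV` for voltage fits).
#' @return data frame with `delay_pred_ms` (and `r_squared` attribute when
#'   observed delays are present).
#' @export
apply_regression <- function(fit, series) {
  stopifnot(inherits(fit, "regression_fit"))
  if (startsWith(fit$kind, "voltage_pair")) {
    vt <- series$VT_mV
    vp <- series$VP_mV
    if (!is.null(fit$frozen)) {
      if (fit$ablate == "fix_VP") vp <- rep(fit$frozen[["VP_mV"]], length(vp))
      if (fit$ablate == "fix_VT") vt <- rep(fit$frozen[["VT_mV"]], length(vt))
    }
    x <- 1 / vt; y <- 1 / vp
  } else {
    x <- series[[fit$features[1]]]
    y <- series[[fit$features[2]]]
  }
  pred <- fit$coef[1] * x + fit$coef[2] * y + fit$coef[3]
  out <- data.frame(delay_pred_ms = as.numeric(pred))
  obs <- if ("delay_ms" %in% names(series)) series$delay_ms
         else series[["delay_test_ms"]]
  if (!is.null(obs)) {
    keep <- is.finite(obs) & is.finite(pred)
    out$delay_obs_ms <- obs
    attr(out, "r_squared") <- 1 - sum((obs[keep] - pred[keep])^2) /
      sum((obs[keep] - mean(obs[keep]))^2)
  }
  out
}
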