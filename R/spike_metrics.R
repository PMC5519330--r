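#' Detect upward threshold crossings in a recorded trace
#'
#' Finds the upward crossings of the spike-detection threshold (default
#' -40 mV) in the sampled voltage trace of each recording site, with
#' sub-sample timing by linear interpolation between the bracketing
#' samples. This is the reference (trace-based) detector; the integrator
#' also performs the identical detection online at full resolution.
#'
#' @param trace data frame with columns `t_ms`, `v1`, `v2` (or a single
#'   `v` column).
#' @param threshold_mV detection threshold (mV).
#' @return list of numeric crossing-time vectors, one per voltage column.
#' @export
detect_crossings <- function(trace, threshold_mV = -40) {
  vcols <- intersect(c("v1", "v2", "v"), names(trace))
  stopifnot(length(vcols) >= 1, "t_ms" %in% names(trace))
  out <- lapply(vcols, function(cn) {
    v <- trace[[cn]]
    t <- trace$t_ms
    i <- which(v[-length(v)] < threshold_mV & v[-1] >= threshold_mV)
    t[i] + (t[i + 1] - t[i]) * (threshold_mV - v[i]) / (v[i + 1] - v[i])
  })
  names(out) <- sub("^v", "site", vcols)
  out
}

#' Build the per-spike feature series of a simulation
#'
#' Pairs the k-th threshold crossing at the first recording site with the
#' k-th at the second (propagation preserves order), and assembles the
#' per-spike features used by all downstream analyses:
#' conduction delay (crossing-time difference, scaled by the model's
#' biological-length factor, default 9.5), the instantaneous stimulus
#' frequency F_inst = 1000 / preceding inter-stimulus interval (undefined
#' for the first spike), the trough voltage V_T (minimum at site 1 between
#' the previous spike and the crossing) and the peak voltage V_P.
#'
#' @param sim an `axon_sim` from [simulate_axon()].
#' @param stimulus the [stimulus_train()] that produced it; defaults to the
#'   one stored in `sim`.
#' @return a `spike_series` data frame with columns `t_stim_ms`, `t1_ms`,
#'   `t2_ms`, `tpeak1_ms`, `tpeak2_ms`, `delay_ms`, `delay_peak_ms`,
#'   `Finst_Hz`, `VT_mV`, `VP_mV`, `ENa_mV`, `hT`; the model is attached
#'   as an attribute.
#' @export
build_spike_series <- function(sim, stimulus = NULL) {
  stopifnot(inherits(sim, "axon_sim"))
  if (is.null(stimulus)) stimulus <- sim$stimulus
  s1 <- sim$spikes1
  s2 <- sim$spikes2
  n1 <- length(s1$t_cross)
  n2 <- length(s2$t_cross)
  # drop a spike still in flight between the sites at the end of the segment
  if (n1 == n2 + 1 && n1 > 0) n1 <- n1 - 1
  if (n1 != n2)
    stop("unequal spike counts between recording sites (", n1, " vs ", n2,
         "): conduction failure is not modeled")
  model <- sim$model
  if (n1 == 0) {
    out <- data.frame(t_stim_ms = numeric(0), t1_ms = numeric(0),
                      t2_ms = numeric(0), tpeak1_ms = numeric(0),
                      tpeak2_ms = numeric(0), delay_ms = numeric(0),
                      delay_peak_ms = numeric(0), Finst_Hz = numeric(0),
                      VT_mV = numeric(0), VP_mV = numeric(0),
                      ENa_mV = numeric(0), hT = numeric(0))
    return(structure(out, class = c("spike_series", "data.frame"),
                     model = model))
  }
  idx <- seq_len(n1)
  t1 <- s1$t_cross[idx]
  t2 <- s2$t_cross[idx]
  if (any(t2 <= t1)) stop("site-2 crossing does not follow site-1 crossing")

  # associate each spike with the latest stimulus onset at or before it;
  # F_inst is the reciprocal interval to the previous spike-evoking
  # stimulus (identical to the previous-stimulus interval when every
  # pulse fires, as in the reference protocols)
  onsets <- stimulus$onset_ms
  k_stim <- findInterval(t1, onsets)
  if (any(k_stim == 0)) stop("spike precedes the first stimulus pulse")
  t_stim <- onsets[k_stim]
  finst <- c(NA_real_, 1e3 / diff(t_stim))

  # sodium-channel h at the trough (optional Muratov input)
  gh_name <- .na_gates(model)$h
  gtr <- s1$gates_trough
  colnames(gtr) <- names(model$gates)
  out <- data.frame(
    t_stim_ms = t_stim, t1_ms = t1, t2_ms = t2,
    tpeak1_ms = s1$t_peak[idx], tpeak2_ms = s2$t_peak[idx],
    delay_ms = (t2 - t1) * model$delay_scale,
    delay_peak_ms = (s2$t_peak[idx] - s1$t_peak[idx]) * model$delay_scale,
    Finst_Hz = finst,
    VT_mV = s1$v_trough[idx], VP_mV = s1$v_peak[idx],
    ENa_mV = s1$e_na[idx],
    hT = if (!is.na(gh_name)) gtr[idx, gh_name] else NA_real_)
  if (any(out$VP_mV <= out$VT_mV)) stop("spike peak not above trough")
  ngp <- min(nrow(s1$gates_peak), n1)
  gp <- s1$gates_peak[seq_len(ngp), , drop = FALSE]
  # one propagated spike per stimulus: rare extra crossings within the
  # same inter-stimulus interval (spontaneous events) are dropped
  dup <- duplicated(k_stim)
  if (any(dup)) {
    out <- out[!dup, ]
    gp <- gp[!dup[seq_len(nrow(gp))], , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, class = c("spike_series", "data.frame"), model = model,
            n_dropped = sum(dup), gates_peak = gp)
}

#' Sodium-gating rate features of each spike
#'
#' Evaluates the opening rates of the Na+ activation and inactivation
#' gates at the trough voltage and their closing rates at the peak
#' voltage, and appends the reciprocals (units ms):
#' `inv_alpha_m` = 1/alpha_m(V_T), `inv_beta_m` = 1/beta_m(V_P),
#' `inv_alpha_h` = 1/alpha_h(V_T), `inv_beta_h` = 1/beta_h(V_P).
#' Rates below `underflow` are recorded as missing rather than infinite.
#'
#' @param series a `spike_series`.
#' @param model the model whose (possibly perturbed) kinetics to use;
#'   defaults to the one attached to `series`.
#' @param underflow smallest usable rate (1/ms).
#' @return the series with the four feature columns filled.
#' @export
gate_rate_features <- function(series, model = attr(series, "model"),
                               underflow = 1e-9) {
  stopifnot(inherits(series, "spike_series"), !is.null(model))
  ng <- .na_gates(model)
  inv <- function(r) ifelse(is.finite(r) & r > underflow, 1 / r, NA_real_)
  rm_t <- model_gate_rates(model, ng$m, series$VT_mV)
  rh_t <- model_gate_rates(model, ng$h, series$VT_mV)
  rm_p <- model_gate_rates(model, ng$m, series$VP_mV)
  rh_p <- model_gate_rates(model, ng$h, series$VP_mV)
  series$inv_alpha_m <- inv(rm_t$alpha)
  series$inv_beta_m <- inv(rm_p$beta)
  series$inv_alpha_h <- inv(rh_t$alpha)
  series$inv_beta_h <- inv(rh_p$beta)
  series
}

#' Write / read a spike-feature series as CSV
#'
#' @param series a `spike_series`.
#' @param path file path.
#' @export
write_spike_series <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_series
#' @export
read_spike_series <- function(path) {
  df <- utils::read.csv(path)
  structure(df, class = c("spike_series", "data.frame"))
}
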