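#' Timed current-pulse train
#'
#' A stimulus is a sequence of identical rectangular current pulses
#' (default 1 nA, 1 ms) injected into the first compartment.
#'
#' @param onset_ms strictly increasing pulse onset times (ms), >= 0,
#'   separated by at least 2 ms (pulse width + guard).
#' @param amplitude_nA pulse amplitude (nA).
#' @param width_ms pulse width (ms).
#' @param label free-text protocol label.
#' @param seed RNG seed used to generate the train, if stochastic.
#' @export
stimulus_train <- function(onset_ms, amplitude_nA = 1, width_ms = 1,
                           label = "custom", seed = NA_integer_) {
  onset_ms <- as.numeric(onset_ms)
  if (length(onset_ms)) {
    stopifnot(all(onset_ms >= 0), !is.unsorted(onset_ms, strictly = TRUE))
    if (length(onset_ms) > 1 && min(diff(onset_ms)) < 2)
      stop("inter-pulse intervals must be >= 2 ms")
  }
  structure(list(onset_ms = onset_ms, amplitude_nA = amplitude_nA,
                 width_ms = width_ms, label = label,
                 seed = suppressWarnings(as.integer(seed))),
            class = "stimulus_train")
}

#' @export
print.stimulus_train <- function(x, ...) {
  cat("<stimulus_train>", x$label, "|", length(x$onset_ms), "pulse(s),",
      x$amplitude_nA, "nA /", x$width_ms, "ms\n")
  invisible(x)
}

# run expr with a locally-seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (!is.na(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
  }
  expr
}

#' Homogeneous Poisson stimulus train
#'
#' Exponentially distributed inter-pulse intervals at the given mean rate;
#' intervals shorter than the 2 ms floor (pulse width + guard) are redrawn,
#' which perturbs the distribution negligibly at the rates used here
#' (5-19 Hz). Deterministic for a fixed seed.
#'
#' @param rate_hz mean stimulation rate (Hz).
#' @param duration_s train duration (s).
#' @param seed RNG seed.
#' @param t0_ms offset of the first possible pulse (ms).
#' @export
poisson_train <- function(rate_hz, duration_s, seed = 1, t0_ms = 0) {
  stopifnot(rate_hz > 0, duration_s > 0)
  mean_isi <- 1e3 / rate_hz # ms
  # redrawing below the 2 ms floor shifts the mean interval to floor + 1/rate
  if (2 / (2 + mean_isi) > 0.05)
    stop("rate too high: the 2 ms minimum interval would distort the mean ",
         "rate by more than 5%")
  dur_ms <- duration_s * 1e3
  onsets <- .with_seed(seed, {
    n_guess <- ceiling(rate_hz * duration_s + 6 * sqrt(rate_hz * duration_s)) + 10
    ts <- numeric(0)
    t <- t0_ms
    repeat {
      isi <- stats::rexp(n_guess, rate = 1 / mean_isi)
      isi <- isi[isi >= 2]
      if (!length(isi)) next
      ts <- c(ts, t + cumsum(isi))
      t <- ts[length(ts)]
      if (t > dur_ms) break
    }
    ts[ts <= dur_ms]
  })
  stimulus_train(onsets, label = sprintf("poisson_%gHz", rate_hz), seed = seed)
}

#' Paired-pulse stimulus set
#'
#' One conditioning + test pulse pair per inter-stimulus interval, each
#' trial meant to be run from an identical initial (rest) state.
#'
#' @param isi_ms inter-stimulus intervals (ms), each >= 2 ms. The default
#'   grid is 30 log-spaced points spanning 10 ms to 10 s.
#' @param t0_ms conditioning-pulse onset within each trial (ms).
#' @return list of two-pulse [stimulus_train()] objects, named by ISI.
#' @export
paired_pulse_set <- function(isi_ms = 10^seq(1, 4, length.out = 30),
                             t0_ms = 10) {
  stopifnot(all(isi_ms >= 2))
  out <- lapply(isi_ms, function(d)
    stimulus_train(c(t0_ms, t0_ms + d), label = sprintf("paired_%gms", d)))
  names(out) <- sprintf("%g", isi_ms)
  out
}

#' Parabolic burst stimulus train
#'
#' Repeated bursts mimicking the pyloric-dilator neuron's natural rhythmic
#' firing: within each burst the instantaneous frequency of successive
#' intervals follows an inverted parabola rising from `f_start_hz` to
#' `f_peak_hz` at the burst midpoint and back.
#'
#' @param n_bursts number of bursts.
#' @param period_s burst repetition period (s).
#' @param n_spikes pulses per burst (odd, so that the peak frequency falls
#'   on the middle interval).
#' @param f_start_hz,f_peak_hz instantaneous frequency at the burst edges
#'   and midpoint (Hz).
#' @export
parabolic_burst_train <- function(n_bursts = 300, period_s = 1, n_spikes = 19,
                                  f_start_hz = 32, f_peak_hz = 63) {
  stopifnot(n_spikes %% 2 == 1, n_spikes >= 3, f_peak_hz >= f_start_hz)
  # inverted parabola over the interval index, vertex (f_peak) at the burst
  # midpoint, endpoints exactly at f_start; with an even interval count the
  # two middle intervals flank the vertex symmetrically
  k <- seq_len(n_spikes - 1)
  k_mid <- n_spikes / 2
  f <- f_start_hz + (f_peak_hz - f_start_hz) * (1 - ((k - k_mid) / (1 - k_mid))^2)
  isi <- 1e3 / f
  burst_dur <- sum(isi)
  if (period_s * 1e3 < burst_dur + 2)
    stop("burst period shorter than burst duration (", round(burst_dur), " ms)")
  within <- c(0, cumsum(isi))
  onsets <- as.vector(outer(within, (seq_len(n_bursts) - 1) * period_s * 1e3, "+"))
  stimulus_train(sort(onsets), label = "burst", seed = NA_integer_)
}

#' Write / read a stimulus train as a two-column table
#'
#' Plain-text serialization: a `# key: value` header block (label, seed,
#' amplitude, width) followed by `onset_ms,amplitude_nA` rows; reading
#' round-trips exactly.
#'
#' @param train a [stimulus_train()].
#' @param path file path.
#' @export
write_stimulus <- function(train, path) {
  hdr <- c(sprintf("# label: %s", train$label),
           sprintf("# seed: %s", train$seed),
           sprintf("# amplitude_nA: %.17g", train$amplitude_nA),
           sprintf("# width_ms: %.17g", train$width_ms),
           "onset_ms,amplitude_nA")
  writeLines(c(hdr, sprintf("%.17g,%.17g", train$onset_ms,
                            rep(train$amplitude_nA, length(train$onset_ms)))),
             path)
  invisible(path)
}

#' @rdname write_stimulus
#' @export
read_stimulus <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^# %s: ", key), "",
                           grep(sprintf("^# %s:", key), hdr, value = TRUE))
  body <- utils::read.csv(text = lines[!grepl("^#", lines)])
  stimulus_train(body$onset_ms,
                 amplitude_nA = as.numeric(get("amplitude_nA")),
                 width_ms = as.numeric(get("width_ms")),
                 label = get("label"),
                 seed = suppressWarnings(as.integer(get("seed"))))
}
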