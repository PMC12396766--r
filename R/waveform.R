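# Pulsatile waveforms: Doppler-like peak-velocity traces and flow-rate
# waveforms used as boundary conditions.

#' Construct a flow waveform
#'
#' A periodic waveform sampled over one cardiac cycle. `time_s` must be
#' strictly increasing within `[0, period)`; the sample at t = period is the
#' sample at t = 0 (periodic closure is implicit).
#'
#' @param time_s sample times in seconds.
#' @param value sample values (mm/s for `peak_velocity`, mL/min for
#'   `flow_rate`).
#' @param heart_rate_bpm heart rate in beats per minute; the period is
#'   60/heart_rate seconds.
#' @param kind `"peak_velocity"` or `"flow_rate"`.
#' @return A `flow_waveform`: data frame with columns `time_s`, `value` and
#'   attributes `period_s`, `heart_rate_bpm`, `kind`.
#' @export
flow_waveform <- function(time_s, value, heart_rate_bpm,
                          kind = c("peak_velocity", "flow_rate")) {
  kind <- match.arg(kind)
  period <- 60 / heart_rate_bpm
  if (length(time_s) != length(value)) stop("time and value lengths differ")
  if (any(!is.finite(value))) stop("waveform values must be finite")
  if (any(diff(time_s) <= 0)) stop("sample times must be strictly increasing")
  if (min(time_s) < 0 || max(time_s) >= period)
    stop("sample times must lie within [0, period)")
  wf <- data.frame(time_s = time_s, value = value)
  attr(wf, "period_s") <- period
  attr(wf, "heart_rate_bpm") <- heart_rate_bpm
  attr(wf, "kind") <- kind
  class(wf) <- c("flow_waveform", "data.frame")
  wf
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf("flow_waveform (%s): %d samples, period %.4f s (%g bpm)\n",
              attr(x, "kind"), nrow(x), attr(x, "period_s"),
              attr(x, "heart_rate_bpm")))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
              min(x$value), max(x$value), mean(x$value)))
  invisible(x)
}

#' Synthesize a Doppler-like pulsatile waveform
#'
#' Generates a strictly positive periodic peak-velocity waveform
#' `v(t) = peak * (1 - pulsatility * w(t))` where `w(t)` is a seeded random
#' harmonic pulse shape normalized to `[0, 1]`. The sampled maximum equals
#' `peak_velocity` exactly and the minimum equals
#' `peak_velocity * (1 - pulsatility)`, so any `pulsatility < 1` precludes
#' flow reversal at the inlet.
#'
#' @param peak_velocity peak velocity in mm/s (> 0).
#' @param heart_rate_bpm heart rate in beats per minute (default 450, the
#'   murine rate under anesthesia).
#' @param pulsatility in `[0, 1)`: relative depth of the diastolic trough.
#' @param n_harmonics number of random harmonics in the pulse shape.
#' @param n_samples samples per cycle.
#' @param seed integer RNG seed; the waveform is deterministic given the seed.
#' @return a `flow_waveform` of kind `peak_velocity`.
#' @export
synth_waveform <- function(peak_velocity, heart_rate_bpm = 450,
                           pulsatility = 0.4, n_harmonics = 3,
                           n_samples = 200, seed = 0) {
  if (!is.finite(peak_velocity) || peak_velocity <= 0)
    stop("peak_velocity must be positive")
  if (pulsatility < 0 || pulsatility >= 1)
    stop("pulsatility must be in [0, 1): values >= 1 would reverse the inlet flow")
  period <- 60 / heart_rate_bpm
  t <- seq(0, period, length.out = n_samples + 1)[seq_len(n_samples)]
  if (pulsatility == 0) {
    return(flow_waveform(t, rep(peak_velocity, n_samples), heart_rate_bpm))
  }
  rng <- .seeded_rng(seed)
  amp <- 1 / seq_len(n_harmonics)^2 * (1 + 0.2 * rng(n_harmonics))
  phase <- 2 * pi * rng(n_harmonics)
  raw <- rep(0, n_samples)
  for (k in seq_len(n_harmonics))
    raw <- raw + amp[k] * cos(2 * pi * k * t / period + phase[k])
  w <- (raw - min(raw)) / (max(raw) - min(raw))  # in [0,1], 0 at systolic peak
  v <- peak_velocity * (1 - pulsatility * w)
  flow_waveform(t, v, heart_rate_bpm)
}

# local RNG that does not disturb the global .Random.seed
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- NULL
  function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    if (is.null(env$state)) {
      set.seed(seed)
    } else {
      assign(".Random.seed", env$state, envir = globalenv())
    }
    out <- stats::runif(n)
    env$state <- get(".Random.seed", globalenv())
    out
  }
}

#' Phase-averaged waveform from a multi-cycle record
#'
#' Extracts `n_cycles` consecutive cycles from a raw periodic record,
#' phase-aligns cycles 2..n to the first by circular cross-correlation, and
#' averages them, emulating the usual Doppler practice of averaging three
#' consecutive cardiac cycles. The record's cycle period is checked against
#' the autocorrelation-estimated period and must agree within 5%.
#'
#' @param time_s,value the raw record (uniformly sampled, spanning at least
#'   `n_cycles` periods).
#' @param heart_rate_bpm nominal heart rate defining the cycle period.
#' @param n_cycles number of cycles to average (default 3).
#' @param n_phase number of phase points of the returned single-cycle
#'   waveform.
#' @param kind passed to [flow_waveform()].
#' @return a `flow_waveform` over one period.
#' @export
cycle_average <- function(time_s, value, heart_rate_bpm, n_cycles = 3,
                          n_phase = 200, kind = "peak_velocity") {
  period <- 60 / heart_rate_bpm
  dt <- diff(time_s)
  if (any(abs(dt - dt[1]) > 1e-9 * period))
    stop("record must be uniformly sampled")
  span <- time_s[length(time_s)] - time_s[1] + dt[1]
  if (span < n_cycles * period * (1 - 1e-9))
    stop(sprintf("record spans %.3f s but %d cycles require %.3f s",
                 span, n_cycles, n_cycles * period))
  # estimated period from the autocorrelation peak nearest the nominal lag
  v0 <- value - mean(value)
  lag_nom <- period / dt[1]
  lags <- seq.int(max(2, floor(lag_nom * 0.7)),
                  min(length(value) - 1, ceiling(lag_nom * 1.3)))
  ac <- vapply(lags, function(L) {
    a <- v0[seq_len(length(v0) - L)]
    b <- v0[seq_len(length(v0) - L) + L]
    sum(a * b)
  }, numeric(1))
  lag_est <- lags[which.max(ac)]
  if (stats::sd(v0) > 1e-12 * max(abs(value)) &&
      abs(lag_est * dt[1] - period) / period > 0.05)
    stop(sprintf(
      "cycle period mismatch > 5%%: nominal %.4f s, record suggests %.4f s",
      period, lag_est * dt[1]))
  ns <- round(lag_nom)
  phase_t <- seq(0, period, length.out = n_phase + 1)[seq_len(n_phase)]
  cyc <- matrix(NA_real_, n_phase, n_cycles)
  ref <- NULL
  for (k in seq_len(n_cycles)) {
    idx <- seq.int((k - 1) * ns + 1, length.out = ns)
    tt <- (time_s[idx] - time_s[idx[1]]) %% period
    ord <- order(tt)
    y <- stats::approx(c(tt[ord], period), c(value[idx][ord], value[idx][ord][1]),
                       xout = phase_t, rule = 2)$y
    if (k == 1) {
      ref <- y
      cyc[, k] <- y
    } else {
      # circular cross-correlation alignment against the first cycle
      shifts <- seq_len(n_phase) - 1
      cc <- vapply(shifts, function(s0) {
        sum(ref * y[((seq_len(n_phase) - 1 + s0) %% n_phase) + 1])
      }, numeric(1))
      s_best <- shifts[which.max(cc)]
      cyc[, k] <- y[((seq_len(n_phase) - 1 + s_best) %% n_phase) + 1]
    }
  }
  flow_waveform(phase_t, rowMeans(cyc), heart_rate_bpm, kind = kind)
}

# periodic interpolant of a flow_waveform: function of time (s)
waveform_fun <- function(wf) {
  period <- attr(wf, "period_s")
  t <- c(wf$time_s, period)
  v <- c(wf$value, wf$value[1])
  f <- stats::splinefun(t, v, method = "periodic")
  function(tt) f(tt %% period)
}
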