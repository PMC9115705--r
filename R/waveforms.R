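#' Uniformly sampled pressure or flow trace
#'
#' @param samples numeric vector of pressure (mmHg) or flow (ml/min) values.
#' @param rate sampling rate (Hz).
#' @param channel one of `"RV_pressure"`, `"PA_pressure"`, `"PA_flow"`.
#' @param t0 time of the first sample (s).
#' @return A list of class `"pressure_trace"`.
#' @examples
#' tr <- pressure_trace(sin(seq(0, 2 * pi, length.out = 100)), rate = 100)
#' trace_times(tr)[1:3]
#' @export
pressure_trace <- function(samples, rate,
                           channel = c("RV_pressure", "PA_pressure", "PA_flow"),
                           t0 = 0) {
  channel <- match.arg(channel)
  if (!is.numeric(samples) || length(samples) < 2L) {
    stop("'samples' must be a numeric vector of length >= 2", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("invalid input: trace contains non-finite samples", call. = FALSE)
  }
  .chk_pos(rate, "rate")
  structure(list(samples = as.numeric(samples), rate = rate,
                 channel = channel, t0 = t0),
            class = "pressure_trace")
}

#' Sample times of a trace
#' @param trace a [pressure_trace()].
#' @return numeric vector of times (s), same length as the samples.
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1L) / trace$rate
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat(sprintf("<pressure_trace> %s: %d samples @ %g Hz (%.3f s), range [%.4g, %.4g]\n",
              x$channel, length(x$samples), x$rate,
              length(x$samples) / x$rate, min(x$samples), max(x$samples)))
  invisible(x)
}

#' One cardiac cycle's timing landmarks
#'
#' @param t_start ejection onset (s).
#' @param t_es end of RV ejection / end-systole (s).
#' @param t_ed end of the cycle (next ejection onset) (s).
#' @return A list of class `"beat_window"`; the ejection period is
#'   `t_es - t_start`.
#' @export
beat_window <- function(t_start, t_es, t_ed) {
  if (!(t_start < t_es && t_es < t_ed)) {
    stop("beat window requires t_start < t_es < t_ed", call. = FALSE)
  }
  structure(list(t_start = t_start, t_es = t_es, t_ed = t_ed),
            class = "beat_window")
}

# centred first derivative, smoothed by a centred moving average of
# odd length spanning roughly `width_s` seconds
.smoothed_derivative <- function(samples, rate, width_s) {
  n <- length(samples)
  d <- numeric(n)
  d[2:(n - 1)] <- (samples[3:n] - samples[1:(n - 2)]) * rate / 2
  d[1] <- d[2]; d[n] <- d[n - 1]
  w <- max(3L, as.integer(round(width_s * rate)))
  if (w %% 2L == 0L) w <- w + 1L
  if (w >= n) w <- if (n %% 2L == 0L) n - 1L else n - 2L
  if (w >= 3L) {
    k <- rep(1 / w, w)
    sm <- stats::filter(d, k, sides = 2)
    half <- (w - 1L) %/% 2L
    sm[seq_len(half)] <- sm[half + 1L]
    sm[(n - half + 1L):n] <- sm[n - half]
    d <- as.numeric(sm)
  }
  d
}

#' Segment an RV pressure trace into beats
#'
#' Detects cardiac cycles from the smoothed first derivative of the RV
#' pressure waveform: ejection onset at each prominent derivative maximum
#' (the steep systolic upstroke) and end-systole at the trough (most
#' negative point) of the derivative within the cycle.  Detection works on
#' the derivative only and is therefore invariant to a constant pressure
#' offset.
#'
#' @param rv an RV-pressure [pressure_trace()].
#' @param smooth_width derivative smoothing window (s); default 0.015.
#' @param min_rr minimum spacing between successive ejection onsets (s).
#' @param min_beats minimum number of full cycles required; fewer detected
#'   cycles is an error.
#' @return A list of [beat_window()] objects, one per full detected cycle.
#' @examples
#' wf <- generate_beat_waveforms(
#'   hemo_state(hr = 75, mpap = 47, pp = 30, sv = 74, mrv_ep = 52,
#'              rv_edp = 8, rv_edv = 160),
#'   rate = 1000, n_beats = 8)
#' length(segment_beats(wf$rv_pressure))
#' @export
segment_beats <- function(rv, smooth_width = 0.015, min_rr = 0.25,
                          min_beats = 5L) {
  stopifnot(inherits(rv, "pressure_trace"))
  if (rv$channel != "RV_pressure") {
    stop("segment_beats expects an RV_pressure trace", call. = FALSE)
  }
  x <- rv$samples
  n <- length(x)
  d <- .smoothed_derivative(x, rv$rate, smooth_width)
  dmax <- max(d)
  if (!(dmax > 0) || (max(x) - min(x)) < sqrt(.Machine$double.eps)) {
    stop("insufficient data: no cardiac cycles detectable in trace",
         call. = FALSE)
  }
  thr <- 0.4 * dmax
  min_gap <- max(2L, as.integer(round(min_rr * rv$rate)))
  # local maxima of the smoothed derivative above threshold, separated by
  # at least min_gap samples (greedy, in descending amplitude order)
  cand <- which(d >= thr)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[d[cand] >= d[cand - 1L] & d[cand] >= d[cand + 1L]]
  cand <- cand[order(d[cand], decreasing = TRUE)]
  onsets <- integer(0)
  for (i in cand) {
    if (!length(onsets) || all(abs(onsets - i) >= min_gap)) {
      onsets <- c(onsets, i)
    }
  }
  onsets <- sort(onsets)
  if (length(onsets) >= 2L) {
    period <- stats::median(diff(onsets))
  } else {
    period <- NA_real_
  }
  windows <- list()
  t <- trace_times(rv)
  n_on <- length(onsets)
  for (k in seq_len(n_on)) {
    i0 <- onsets[k]
    if (k < n_on) {
      i1 <- onsets[k + 1L]
    } else {
      # trailing beat: accept if the trace extends over most of one period
      if (is.na(period) || (n - i0) < 0.9 * period) break
      i1 <- min(n, i0 + as.integer(round(period)))
    }
    seg <- d[i0:i1]
    i_es <- i0 + which.min(seg) - 1L
    if (i_es <= i0 || i_es >= i1) next
    windows[[length(windows) + 1L]] <- beat_window(t[i0], t[i_es], t[i1])
  }
  if (length(windows) < min_beats) {
    stop("insufficient data: ", length(windows),
         " full cycle(s) detected, need >= ", min_beats, call. = FALSE)
  }
  windows
}

# nearest sample index for a time on the trace grid
.t_index <- function(trace, t) {
  i <- as.integer(round((t - trace$t0) * trace$rate)) + 1L
  pmin(pmax(i, 1L), length(trace$samples))
}

#' Ensemble-average a trace over detected beats
#'
#' Averages `n_beats` consecutive beats pointwise after resampling each
#' beat (by linear interpolation) onto the time grid of the shortest
#' selected beat, giving one representative steady-state beat.
#'
#' @param trace a [pressure_trace()] (any channel) sharing the time base of
#'   the windows.
#' @param windows beat windows from [segment_beats()].
#' @param n_beats number of beats to average (default 5).
#' @param start index of the first beat to use (default 1).
#' @return A [pressure_trace()] of one averaged beat starting at time 0.
#' @export
ensemble_average <- function(trace, windows, n_beats = 5L, start = 1L) {
  stopifnot(inherits(trace, "pressure_trace"))
  if (n_beats < 1L) stop("'n_beats' must be >= 1", call. = FALSE)
  if (start < 1L || start + n_beats - 1L > length(windows)) {
    stop("requested beats exceed the available windows", call. = FALSE)
  }
  use <- windows[start:(start + n_beats - 1L)]
  durs <- vapply(use, function(w) w$t_ed - w$t_start, numeric(1))
  t_grid <- seq(0, min(durs), by = 1 / trace$rate)
  tt <- trace_times(trace)
  acc <- matrix(NA_real_, nrow = length(t_grid), ncol = length(use))
  for (j in seq_along(use)) {
    acc[, j] <- stats::approx(tt, trace$samples, xout = use[[j]]$t_start + t_grid,
                              rule = 2)$y
  }
  pressure_trace(rowMeans(acc), rate = trace$rate, channel = trace$channel,
                 t0 = 0)
}

#' Mean RV pressure over the ejection period
#'
#' Arithmetic mean of the RV pressure samples between ejection onset and
#' end-systole of one beat.
#'
#' @param rv an RV-pressure [pressure_trace()].
#' @param window a [beat_window()] inside the trace extent.
#' @return mean ejection pressure (mmHg).
#' @export
mean_ejection_pressure <- function(rv, window) {
  stopifnot(inherits(rv, "pressure_trace"), inherits(window, "beat_window"))
  tt <- trace_times(rv)
  if (window$t_start < tt[1] - 1e-9 || window$t_es > tt[length(tt)] + 1e-9) {
    stop("window lies outside the trace extent", call. = FALSE)
  }
  i0 <- .t_index(rv, window$t_start)
  i1 <- .t_index(rv, window$t_es)
  if (i1 <= i0) stop("empty ejection window", call. = FALSE)
  mean(rv$samples[i0:i1])
}
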