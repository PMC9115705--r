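#' Parameters of the parametric pulmonary flow profile
#'
#' The profile stands in for instantaneous pulmonary arterial flow when only
#' scalar hemodynamics are available (the clinical situation).  Within one
#' cycle of duration `t_ed`, forward flow follows a damped half-sine over the
#' ejection period; the sine's negative lobe just past `t_es` models
#' pulmonary valve regurgitation, which is ramped linearly to zero so the
#' whole regurgitant window lasts `t_reg` seconds; flow is zero for the rest
#' of diastole.
#'
#' @param sv stroke volume (ml).
#' @param t_es time at which RV ejection ends (s, from ejection onset).
#' @param t_ed cycle duration (s); `t_ed = 60 / HR`.
#' @param amplitude the dimensionless amplitude factor `A`; calibrated by
#'   [calibrate_amplitude()] so that the cycle-mean flow equals cardiac
#'   output.  Default 1 (uncalibrated).
#' @param t_reg duration of pulmonary valve regurgitation (s), default 0.04.
#' @param decay exponential damping rate (1/s), default 3.
#' @return A list of class `"flow_params"`.
#' @examples
#' p <- flow_params(sv = 60, t_es = 0.30, t_ed = 0.8)
#' invented_flow(0.15, p)
#' @export
flow_params <- function(sv, t_es, t_ed, amplitude = 1, t_reg = 0.04,
                        decay = 3) {
  .chk_pos(sv, "sv"); .chk_pos(t_es, "t_es"); .chk_pos(t_ed, "t_ed")
  .chk_pos(amplitude, "amplitude"); .chk_pos(t_reg, "t_reg")
  .chk_pos(decay, "decay")
  if (t_es >= t_ed) stop("t_es must be < t_ed", call. = FALSE)
  if (t_es + t_reg > t_ed) {
    stop("regurgitant window extends past the cycle end (t_es + t_reg > t_ed)",
         call. = FALSE)
  }
  structure(list(sv = sv, t_es = t_es, t_ed = t_ed, amplitude = amplitude,
                 t_reg = t_reg, decay = decay),
            class = "flow_params")
}

#' Evaluate the parametric pulmonary flow profile
#'
#' Piecewise, with `h = t_reg / 2` (0.02 s at the default):
#' * `0 <= t <= t_es + h`: `A * SV * exp(-decay * t) * sin(pi * t / t_es)` —
#'   the sine runs negative past `t_es` (regurgitation);
#' * `t_es + h < t <= t_es + 2h`: the value at `t_es + h` ramped linearly to
#'   zero, i.e. multiplied by `1 - (t - t_es - h) / h`;
#' * `t_es + 2h < t <= t_ed`: zero.
#'
#' The profile is continuous at both branch joints by construction.
#'
#' @param t time(s) within the cycle (s); vectorised.
#' @param params a [flow_params()].
#' @return flow (ml/min), same length as `t`.
#' @export
invented_flow <- function(t, params) {
  stopifnot(inherits(params, "flow_params"))
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop("'t' must be finite numeric", call. = FALSE)
  }
  if (any(t < 0) || any(t > params$t_ed + 1e-12)) {
    stop("'t' must lie within [0, t_ed]", call. = FALSE)
  }
  h <- params$t_reg / 2
  base <- function(tt) {
    params$amplitude * params$sv * exp(-params$decay * tt) *
      sin(pi * tt / params$t_es)
  }
  q <- numeric(length(t))
  b1 <- t <= params$t_es + h
  b2 <- !b1 & t <= params$t_es + 2 * h
  q[b1] <- base(t[b1])
  if (any(b2)) {
    q[b2] <- base(params$t_es + h) * (1 - (t[b2] - params$t_es - h) / h)
  }
  q
}

#' Calibrate the flow-profile amplitude to cardiac output
#'
#' Sets the amplitude factor so that the time-average of the profile over
#' the whole cycle `[0, t_ed]` (diastolic zero flow included) equals the
#' subject's cardiac output.  Because the profile is linear in the
#' amplitude, `A = CO / mean(profile at A = 1)`; the mean is computed by
#' trapezoidal quadrature on a uniform grid.
#'
#' @param params a [flow_params()].
#' @param co cardiac output (ml/min).
#' @param rate evaluation grid rate (Hz), default 1000.
#' @return `params` with `amplitude` replaced by the calibrated value.
#' @examples
#' p <- calibrate_amplitude(flow_params(sv = 60, t_es = 0.3, t_ed = 0.8),
#'                          co = 4500)
#' p$amplitude
#' @export
calibrate_amplitude <- function(params, co, rate = 1000) {
  stopifnot(inherits(params, "flow_params"))
  .chk_pos(co, "co"); .chk_pos(rate, "rate")
  unit <- params
  unit$amplitude <- 1
  tt <- seq(0, params$t_ed, by = 1 / rate)
  if (tt[length(tt)] < params$t_ed) tt <- c(tt, params$t_ed)
  q <- invented_flow(tt, unit)
  m <- .trapz(tt, q) / params$t_ed
  if (!(m > 0)) {
    stop("degenerate profile: unit-amplitude mean flow is not positive ",
         "(t_es too short relative to the regurgitant window)", call. = FALSE)
  }
  params$amplitude <- co / m
  params
}

# trapezoidal integral of y(x) on an arbitrary grid
.trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
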