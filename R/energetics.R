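#' Couple oxygen consumption to mechanical energy
#'
#' Total mechanical energy per beat from oxygen consumed per beat, at the
#' theoretical yield of oxidative phosphorylation with mixed substrates
#' (20.2 J per ml O2).  Anaerobic (glycolytic) contribution is treated as
#' negligible.
#'
#' @param o2_per_beat oxygen consumed (ml O2 per beat).
#' @param constants a [rv_constants()] set.
#' @return energy (J per beat).
#' @export
total_mechanical_energy <- function(o2_per_beat, constants = rv_constants()) {
  if (any(o2_per_beat < 0)) stop("oxygen volume must be >= 0", call. = FALSE)
  constants$k_o2 * o2_per_beat
}

#' Oxygen consumption rate implied by a power output
#'
#' @param tpo total power output (J/min).
#' @param constants a [rv_constants()] set.
#' @return oxygen consumption rate (ml O2/min).
#' @seealso [power_from_o2_rate()] for the inverse.
#' @export
o2_rate_from_power <- function(tpo, constants = rv_constants()) {
  if (any(tpo < 0)) stop("power must be >= 0", call. = FALSE)
  tpo / constants$k_o2
}

#' Power output implied by an oxygen consumption rate
#'
#' @param o2_rate oxygen consumption rate (ml O2/min).
#' @param constants a [rv_constants()] set.
#' @return power (J/min).
#' @export
power_from_o2_rate <- function(o2_rate, constants = rv_constants()) {
  if (any(o2_rate < 0)) stop("rate must be >= 0", call. = FALSE)
  o2_rate * constants$k_o2
}

#' Rate of oxygen delivery to the RV free wall
#'
#' `1.34 * OEF * Q_RCA * Sa * Chb`: hemoglobin carrying capacity times
#' extraction fraction, right coronary flow, arterial saturation and
#' hemoglobin concentration.
#'
#' @param oxy an [oxy_state()].
#' @param constants a [rv_constants()] set.
#' @return delivery rate usable by the RV (ml O2/min).
#' @export
oxygen_delivery_rate <- function(oxy, constants = rv_constants()) {
  stopifnot(inherits(oxy, "oxy_state"))
  constants$k_hb * oxy$oef * oxy$q_rca * oxy$sa * oxy$chb
}

#' Isovolumic power, original formulation
#'
#' `HR * mRV_EP * (RV_EDV - V0) * 1.33e-4`: the work of raising the entire
#' end-diastolic volume to mean ejection pressure, every beat.
#'
#' @param h a [hemo_state()].
#' @param constants a [rv_constants()] set.
#' @return power (J/min).
#' @export
isovolumic_power_elbeery <- function(h, constants = rv_constants()) {
  stopifnot(inherits(h, "hemo_state"))
  if (h$rv_edv <= h$v0) stop("rv_edv must exceed v0", call. = FALSE)
  h$hr * h$mrv_ep * (h$rv_edv - h$v0) * constants$k_mmhgml
}

#' Isovolumic power, adjusted formulation
#'
#' `HR * (mRV_EP - RV_EDP) * RV_ESV * 1.33e-4`: charges only the residual
#' (end-systolic) volume, over the pressure rise the RV itself performs —
#' a lower bound on isovolumic work, appropriate when venous congestion
#' elevates end-diastolic pressure.
#'
#' @inheritParams isovolumic_power_elbeery
#' @return power (J/min).
#' @export
isovolumic_power_adjusted <- function(h, constants = rv_constants()) {
  stopifnot(inherits(h, "hemo_state"))
  if (h$mrv_ep <= h$rv_edp) {
    stop("non-physiologic state: mrv_ep <= rv_edp", call. = FALSE)
  }
  h$hr * (h$mrv_ep - h$rv_edp) * h$rv_esv * constants$k_mmhgml
}

#' Stroke power from pressure and flow waveforms
#'
#' Per beat, the trapezoidal integral of instantaneous PA pressure times PA
#' flow over the ejection window, divided by that beat's ejection period and
#' converted from mmHg*ml/min to J/min; the returned value is the mean over
#' the first `n_beats` beats (a resting steady-state estimate).
#'
#' @param pa_pressure PA-pressure [pressure_trace()].
#' @param pa_flow PA-flow [pressure_trace()] on the same time base
#'   (same rate and start time).
#' @param windows beat windows from [segment_beats()] on the simultaneous RV
#'   trace.
#' @param constants a [rv_constants()] set.
#' @param n_beats number of beats averaged (default 5).
#' @param include_regurg_tail extend the integration window to
#'   `t_es + t_reg` so the negative regurgitant lobe of a parametric flow
#'   profile is captured (default `TRUE`); use `FALSE` for measured flow,
#'   integrating over `[t_start, t_es]` only.
#' @return stroke power (J/min).
#' @export
stroke_power_integrated <- function(pa_pressure, pa_flow, windows,
                                    constants = rv_constants(),
                                    n_beats = 5L,
                                    include_regurg_tail = TRUE) {
  stopifnot(inherits(pa_pressure, "pressure_trace"),
            inherits(pa_flow, "pressure_trace"))
  if (pa_pressure$rate != pa_flow$rate ||
      abs(pa_pressure$t0 - pa_flow$t0) > 1e-9 ||
      length(pa_pressure$samples) != length(pa_flow$samples)) {
    stop("invalid input: pressure and flow traces must share a time base",
         call. = FALSE)
  }
  if (length(windows) < n_beats) {
    stop("need at least ", n_beats, " beat windows", call. = FALSE)
  }
  tt <- trace_times(pa_pressure)
  per_beat <- vapply(windows[seq_len(n_beats)], function(w) {
    t_hi <- if (include_regurg_tail) w$t_es + constants$t_reg else w$t_es
    t_hi <- min(t_hi, tt[length(tt)])
    i0 <- .t_index(pa_pressure, w$t_start)
    i1 <- .t_index(pa_pressure, t_hi)
    if (i1 <= i0) stop("degenerate ejection window", call. = FALSE)
    idx <- i0:i1
    integrand <- pa_pressure$samples[idx] * pa_flow$samples[idx]
    T_ej <- w$t_es - w$t_start
    .trapz(tt[idx], integrand) / T_ej
  }, numeric(1))
  mean(per_beat) * constants$k_mmhgml
}

#' Closed-form stroke power (zeroth harmonic plus oscillatory estimate)
#'
#' `HR * mPAP * SV * 1.33e-4 + 0.156 * PP`: the first term is the
#' non-pulsatile (zeroth-harmonic) stroke power, the second estimates the
#' oscillatory stroke power lost to pressure/flow pulsation as proportional
#' to PA pulse pressure.  Used when instantaneous PA flow is not measured.
#'
#' @inheritParams isovolumic_power_elbeery
#' @return a named list with `useful` (zeroth harmonic, J/min), `pulsatile`
#'   (oscillatory, J/min) and `total` (their sum).
#' @export
stroke_power_adjusted <- function(h, constants = rv_constants()) {
  stopifnot(inherits(h, "hemo_state"))
  useful <- h$hr * h$mpap * h$sv * constants$k_mmhgml
  pulsatile <- constants$k_osc * h$pp
  list(useful = useful, pulsatile = pulsatile, total = useful + pulsatile)
}

#' Useful (non-pulsatile) stroke power
#'
#' Mean PA pressure times cardiac output, converted to J/min: the stroke
#' power that produces forward flow into the pulmonary artery.
#'
#' @inheritParams isovolumic_power_elbeery
#' @return power (J/min).
#' @export
useful_stroke_power <- function(h, constants = rv_constants()) {
  stopifnot(inherits(h, "hemo_state"))
  h$mpap * h$co * constants$k_mmhgml
}

#' Total RV power output
#'
#' Sum of isovolumic and stroke power for the chosen model variant.
#' The `"elbeery"` variant uses the original isovolumic formulation; the
#' `"adjusted"` variant uses the lower-bound isovolumic formulation.  Stroke
#' power comes either from the closed-form estimate (scalar hemodynamics,
#' the clinical route) or from waveform integration (`stroke_source =
#' "integrated"`, the route used when instantaneous PA flow is measured).
#'
#' @param h a [hemo_state()].
#' @param variant `"elbeery"` or `"adjusted"`.
#' @param stroke_source `"closed_form"` or `"integrated"`.
#' @param pa_pressure,pa_flow,windows required when
#'   `stroke_source = "integrated"`; see [stroke_power_integrated()].
#' @param constants a [rv_constants()] set.
#' @param ... further arguments passed to [stroke_power_integrated()].
#' @return A list of class `"power_breakdown"` with components `variant`,
#'   `isovolumic`, `stroke`, `useful_stroke`, `pulsatile_stroke` and `total`
#'   (all J/min); `total = isovolumic + stroke` exactly.
#' @examples
#' h <- hemo_state(hr = 75, mpap = 47.4, pp = 38, sv = 74.7, mrv_ep = 52.4,
#'                 rv_edp = 8, rv_edv = 162.4)
#' total_power_output(h, variant = "adjusted")
#' @export
total_power_output <- function(h, variant = c("adjusted", "elbeery"),
                               stroke_source = c("closed_form", "integrated"),
                               pa_pressure = NULL, pa_flow = NULL,
                               windows = NULL,
                               constants = rv_constants(), ...) {
  variant <- match.arg(variant)
  stroke_source <- match.arg(stroke_source)
  iso <- switch(variant,
                elbeery  = isovolumic_power_elbeery(h, constants),
                adjusted = isovolumic_power_adjusted(h, constants))
  useful <- useful_stroke_power(h, constants)
  if (stroke_source == "closed_form") {
    sp <- stroke_power_adjusted(h, constants)
    stroke <- sp$total
    pulsatile <- sp$pulsatile
  } else {
    if (is.null(pa_pressure) || is.null(pa_flow) || is.null(windows)) {
      stop("integrated stroke power needs pa_pressure, pa_flow and windows",
           call. = FALSE)
    }
    stroke <- stroke_power_integrated(pa_pressure, pa_flow, windows,
                                      constants, ...)
    pulsatile <- stroke - useful
  }
  structure(list(variant = variant, isovolumic = iso, stroke = stroke,
                 useful_stroke = useful, pulsatile_stroke = pulsatile,
                 total = iso + stroke),
            class = "power_breakdown")
}

#' @export
print.power_breakdown <- function(x, ...) {
  cat(sprintf("RV power breakdown (%s model), J/min:\n", x$variant))
  cat(sprintf("  isovolumic       %8.2f\n", x$isovolumic))
  cat(sprintf("  stroke           %8.2f  (useful %.2f + pulsatile %.2f)\n",
              x$stroke, x$useful_stroke, x$pulsatile_stroke))
  cat(sprintf("  total            %8.2f\n", x$total))
  invisible(x)
}

#' RV mechanical efficiency
#'
#' Useful (non-pulsatile) stroke power divided by total power output: the
#' fraction of the RV's total energy expenditure that produces forward flow.
#'
#' @param breakdown a `"power_breakdown"` from [total_power_output()].
#' @param h the same subject's [hemo_state()].
#' @param constants a [rv_constants()] set.
#' @return efficiency (fraction; in (0, 1] for physiologic inputs).
#' @export
rv_efficiency <- function(breakdown, h, constants = rv_constants()) {
  stopifnot(inherits(breakdown, "power_breakdown"))
  if (!(breakdown$total > 0)) {
    stop("efficiency undefined: total power output is not positive",
         call. = FALSE)
  }
  useful_stroke_power(h, constants) / breakdown$total
}
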