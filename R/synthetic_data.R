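#' Draw from a truncated normal by inverse-CDF
#'
#' Used by the cohort generators so that every field is drawn inside its
#' physiologic support while keeping the stated mean/sd on the latent
#' normal.  Fully deterministic given the RNG state.
#'
#' @param n number of draws.
#' @param mean,sd latent normal parameters.
#' @param lower,upper truncation bounds.
#' @return numeric vector of length `n`.
#' @keywords internal
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      stop("invalid spec: degenerate distribution outside its bounds",
           call. = FALSE)
    }
    return(rep(mean, n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (phi - plo <= 0) {
    stop("invalid spec: truncation bounds leave empty support", call. = FALSE)
  }
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

.tn <- function(mean, sd, lower = -Inf, upper = Inf) {
  list(mean = mean, sd = sd, lower = lower, upper = upper)
}

# Published group-wise marginals for the idiopathic-PAH cohort
# (mean +/- sd by NYHA class): mPAP (mmHg), CO (L/min), EF, right coronary
# mean blood flow (ml/min), OEF.  Fields the summary table does not report
# (HR, PP, RV_EDP, Sa, Chb, the ejection-pressure gradient) carry documented
# physiologic defaults; see the methods vignette.
.default_group_params <- function() {
  list(
    NYHA_II = list(
      mpap_mmHg     = .tn(47.4, 11.7, 21, 110),
      co_l_min      = .tn(5.6, 0.9, 1.5, 12),
      ef_frac       = .tn(0.46, 0.133, 0.08, 0.80),
      q_rca_ml_min  = .tn(47.5, 15.5, 8, 150),
      oef_frac      = .tn(0.60, 0.15, 0.10, 1.00),
      hr_bpm        = .tn(78, 11, 45, 130),
      rv_edp_mmHg   = .tn(8, 3, 1, 20),
      sa_frac       = .tn(0.95, 0.02, 0.75, 1.00),
      chb_g_ml      = .tn(0.145, 0.015, 0.08, 0.22),
      pp_over_mpap  = .tn(0.80, 0.10, 0.40, 1.30),
      ep_grad_mmHg  = .tn(5, 1.5, 1, 10)
    ),
    NYHA_III = list(
      mpap_mmHg     = .tn(58.8, 13.3, 21, 120),
      co_l_min      = .tn(4.2, 1.1, 1.2, 10),
      ef_frac       = .tn(0.31, 0.035, 0.08, 0.80),
      q_rca_ml_min  = .tn(64.6, 20.8, 8, 160),
      oef_frac      = .tn(0.70, 0.16, 0.10, 1.00),
      hr_bpm        = .tn(82, 12, 45, 135),
      rv_edp_mmHg   = .tn(12, 4, 1, 20),
      sa_frac       = .tn(0.93, 0.03, 0.70, 1.00),
      chb_g_ml      = .tn(0.145, 0.015, 0.08, 0.22),
      pp_over_mpap  = .tn(0.80, 0.10, 0.40, 1.30),
      ep_grad_mmHg  = .tn(5, 1.5, 1, 10)
    ),
    NYHA_IV = list(
      mpap_mmHg     = .tn(65.3, 22.9, 21, 140),
      co_l_min      = .tn(3.5, 1.4, 1.0, 9),
      ef_frac       = .tn(0.19, 0.044, 0.06, 0.80),
      q_rca_ml_min  = .tn(55.2, 12.6, 8, 150),
      oef_frac      = .tn(0.90, 0.08, 0.10, 1.00),
      hr_bpm        = .tn(86, 13, 45, 140),
      rv_edp_mmHg   = .tn(14, 5, 1, 20),
      sa_frac       = .tn(0.91, 0.04, 0.65, 1.00),
      chb_g_ml      = .tn(0.145, 0.015, 0.08, 0.22),
      pp_over_mpap  = .tn(0.80, 0.10, 0.40, 1.30),
      ep_grad_mmHg  = .tn(5, 1.5, 1, 10)
    )
  )
}

#' Specification of a synthetic clinical cohort
#'
#' Per-NYHA-class truncated-normal parameters for every independently drawn
#' field, plus the oxygen-coupling noise model.  Dependent quantities
#' (SV, RV volumes, PP, mRV_EP) are derived, not drawn, so every generated
#' record is internally consistent.  Myocardial oxygen consumption is
#' generated from the chosen model variant's total power output through the
#' energy-coupling constant with multiplicative noise, plus an optional
#' anaerobic (oxygen-independent) power offset.
#'
#' @param n_per_group named integer vector of subjects per class; the
#'   default mirrors the published cohort (8 / 4 / 3).
#' @param noise_cv coefficient of variation of the multiplicative noise on
#'   generated oxygen consumption (default 0.05).
#' @param anaerobic_offset oxygen-independent power (J/min) added to total
#'   power before conversion (default 0).
#' @param mvo2_variant model variant whose total power generates MVO2,
#'   `"adjusted"` (default) or `"elbeery"`.
#' @param group_params optional replacement for the per-class distribution
#'   list; same structure as the default (see source).
#' @param constants a [rv_constants()] set.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_per_group = c(NYHA_II = 8, NYHA_III = 4, NYHA_IV = 3),
                        noise_cv = 0.05, anaerobic_offset = 0,
                        mvo2_variant = c("adjusted", "elbeery"),
                        group_params = NULL,
                        constants = rv_constants()) {
  mvo2_variant <- match.arg(mvo2_variant)
  params <- .default_group_params()
  if (!is.null(group_params)) {
    for (g in names(group_params)) {
      if (!g %in% names(params)) stop("unknown group: ", g, call. = FALSE)
      params[[g]][names(group_params[[g]])] <- group_params[[g]]
    }
  }
  if (is.null(names(n_per_group)) ||
      !all(names(n_per_group) %in% names(params))) {
    stop("'n_per_group' must be named with NYHA_II/NYHA_III/NYHA_IV",
         call. = FALSE)
  }
  if (noise_cv < 0) stop("'noise_cv' must be >= 0", call. = FALSE)
  if (anaerobic_offset < 0) stop("'anaerobic_offset' must be >= 0", call. = FALSE)
  structure(list(n_per_group = n_per_group, noise_cv = noise_cv,
                 anaerobic_offset = anaerobic_offset,
                 mvo2_variant = mvo2_variant, group_params = params,
                 constants = constants),
            class = "cohort_spec")
}

#' Generate a synthetic clinical cohort
#'
#' Draws each subject's independent fields from the class-specific truncated
#' normals, derives the dependent hemodynamics (`SV = CO/HR`,
#' `RV_EDV = SV/EF`, `RV_ESV = RV_EDV - SV`, `PP` and `mRV_EP` from mPAP),
#' computes both model variants' power breakdowns and efficiencies, and
#' generates myocardial oxygen consumption from the coupling model.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer RNG seed; the same seed reproduces the cohort
#'   exactly.
#' @return A data frame with one row per subject: identifiers, all scalar
#'   hemodynamic and oxygen fields (units in the column names), the power
#'   breakdowns of both variants, efficiencies, and `mvo2_ml_min`.
#' @examples
#' coh <- generate_clinical_cohort(cohort_spec(), seed = 1)
#' coh[, c("group", "mpap_mmHg", "tpo_adjusted_j_min", "mvo2_ml_min")]
#' @export
generate_clinical_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(as.integer(seed))
  out <- list()
  for (g in names(spec$n_per_group)) {
    n <- spec$n_per_group[[g]]
    if (n < 1) next
    p <- spec$group_params[[g]]
    draw <- function(f) rtruncnorm(n, p[[f]]$mean, p[[f]]$sd,
                                   p[[f]]$lower, p[[f]]$upper)
    mpap <- draw("mpap_mmHg")
    co_l <- draw("co_l_min")
    ef <- draw("ef_frac")
    q_rca <- draw("q_rca_ml_min")
    oef <- draw("oef_frac")
    hr <- draw("hr_bpm")
    rv_edp <- draw("rv_edp_mmHg")
    sa <- draw("sa_frac")
    chb <- draw("chb_g_ml")
    pp <- draw("pp_over_mpap") * mpap
    mrv_ep <- mpap + draw("ep_grad_mmHg")
    co <- co_l * 1000
    sv <- co / hr
    rv_edv <- sv / ef
    rv_esv <- rv_edv - sv
    out[[g]] <- data.frame(
      subject_id = sprintf("%s_%03d", g, seq_len(n)),
      group = g,
      hr_bpm = hr, mpap_mmHg = mpap, pp_mmHg = pp, sv_ml = sv,
      co_ml_min = co, mrv_ep_mmHg = mrv_ep, rv_edp_mmHg = rv_edp,
      rv_edv_ml = rv_edv, rv_esv_ml = rv_esv, ef_frac = ef,
      sa_frac = sa, oef_frac = oef, q_rca_ml_min = q_rca, chb_g_ml = chb,
      stringsAsFactors = FALSE
    )
  }
  coh <- do.call(rbind, out)
  rownames(coh) <- NULL
  coh <- compute_cohort_energetics(coh, constants = spec$constants)
  src <- if (spec$mvo2_variant == "adjusted") coh$tpo_adjusted_j_min else
    coh$tpo_elbeery_j_min
  eps <- stats::rnorm(nrow(coh), 0, spec$noise_cv)
  coh$mvo2_ml_min <- src / spec$constants$k_o2 * (1 + eps) +
    spec$anaerobic_offset / spec$constants$k_o2
  coh
}

#' Compute per-subject energetics for a cohort table
#'
#' Adds both model variants' closed-form power breakdowns, efficiencies,
#' predicted oxygen consumption rates and the oxygen delivery rate to a
#' cohort data frame (columns as produced by [generate_clinical_cohort()]
#' or read by [read_cohort_table()]).
#'
#' @param coh cohort data frame.
#' @param constants a [rv_constants()] set.
#' @return `coh` with the energetic columns appended.
#' @export
compute_cohort_energetics <- function(coh, constants = rv_constants()) {
  need <- c("hr_bpm", "mpap_mmHg", "pp_mmHg", "sv_ml", "co_ml_min",
            "mrv_ep_mmHg", "rv_edp_mmHg", "rv_edv_ml", "rv_esv_ml")
  miss <- setdiff(need, names(coh))
  if (length(miss)) {
    stop("cohort table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(coh)
  res <- data.frame(
    iso_elbeery_j_min = numeric(n), iso_adjusted_j_min = numeric(n),
    stroke_j_min = numeric(n), useful_stroke_j_min = numeric(n),
    pulsatile_stroke_j_min = numeric(n),
    tpo_elbeery_j_min = numeric(n), tpo_adjusted_j_min = numeric(n),
    efficiency_elbeery = numeric(n), efficiency_adjusted = numeric(n)
  )
  for (i in seq_len(n)) {
    h <- hemo_state(hr = coh$hr_bpm[i], mpap = coh$mpap_mmHg[i],
                    pp = coh$pp_mmHg[i], sv = coh$sv_ml[i],
                    co = coh$co_ml_min[i], mrv_ep = coh$mrv_ep_mmHg[i],
                    rv_edp = coh$rv_edp_mmHg[i], rv_edv = coh$rv_edv_ml[i],
                    rv_esv = coh$rv_esv_ml[i])
    be <- total_power_output(h, "elbeery", "closed_form", constants = constants)
    ba <- total_power_output(h, "adjusted", "closed_form", constants = constants)
    res$iso_elbeery_j_min[i] <- be$isovolumic
    res$iso_adjusted_j_min[i] <- ba$isovolumic
    res$stroke_j_min[i] <- ba$stroke
    res$useful_stroke_j_min[i] <- ba$useful_stroke
    res$pulsatile_stroke_j_min[i] <- ba$pulsatile_stroke
    res$tpo_elbeery_j_min[i] <- be$total
    res$tpo_adjusted_j_min[i] <- ba$total
    res$efficiency_elbeery[i] <- rv_efficiency(be, h, constants)
    res$efficiency_adjusted[i] <- rv_efficiency(ba, h, constants)
  }
  if ("q_rca_ml_min" %in% names(coh) && "oef_frac" %in% names(coh) &&
      "sa_frac" %in% names(coh) && "chb_g_ml" %in% names(coh)) {
    res$o2_delivery_ml_min <- constants$k_hb * coh$oef_frac *
      coh$q_rca_ml_min * coh$sa_frac * coh$chb_g_ml
  }
  res$mvo2_pred_elbeery_ml_min <- res$tpo_elbeery_j_min / constants$k_o2
  res$mvo2_pred_adjusted_ml_min <- res$tpo_adjusted_j_min / constants$k_o2
  cbind(coh[setdiff(names(coh), names(res))], res)
}

#' Generate one subject's beat waveforms
#'
#' Builds smooth periodic RV-pressure, PA-pressure and PA-flow traces whose
#' summary statistics reproduce a scalar hemodynamic state exactly: the PA
#' trace's time mean equals mPAP and its range equals PP; the RV trace's
#' mean over the ejection window equals mRV_EP and its diastolic floor is
#' RV_EDP; the flow trace is either the cardiac-output-calibrated parametric
#' profile (`flow_shape = "invented"`, the clinical route) or a half-sine
#' systolic pulse whose per-beat integral is SV (`"pulse"`, emulating a
#' measured flow probe).  Both pressures use a raised-cosine systole, so
#' ejection onset and end-systole sit at the quarter points of the systolic
#' interval; these ground-truth landmarks are returned for oracle tests.
#'
#' @param h a [hemo_state()].
#' @param rate sampling rate (Hz), >= 50.
#' @param n_beats number of full beats to emit (default 8).
#' @param systolic_frac systolic fraction of the cycle (default 0.45); the
#'   ejection period is half the systolic interval.
#' @param flow_shape `"invented"` or `"pulse"`.
#' @param constants a [rv_constants()] set.
#' @return A list with `rv_pressure`, `pa_pressure`, `pa_flow`
#'   ([pressure_trace()]s), and `truth`, a data frame of per-beat
#'   `t_start`, `t_es`, `t_ed` (s).
#' @export
generate_beat_waveforms <- function(h, rate = 1000, n_beats = 8L,
                                    systolic_frac = 0.45,
                                    flow_shape = c("invented", "pulse"),
                                    constants = rv_constants()) {
  stopifnot(inherits(h, "hemo_state"))
  flow_shape <- match.arg(flow_shape)
  if (rate < 50) {
    stop("sampling rate below 50 Hz cannot resolve systole", call. = FALSE)
  }
  period <- 60 / h$hr
  t_sys <- systolic_frac * period
  # half a period of flat diastole is appended so the last beat's full
  # cycle is resolvable without starting a further systole
  dur <- (n_beats + 0.5) * period
  tt <- seq(0, dur, by = 1 / rate)
  phase <- tt %% period
  in_pad <- tt > n_beats * period + 1e-12
  # raised cosine on [0, t_sys], zero elsewhere in the cycle
  rc <- ifelse(phase <= t_sys & !in_pad,
               (1 - cos(2 * pi * phase / t_sys)) / 2, 0)
  # ejection spans the quarter points [t_sys/4, 3 t_sys/4]; the mean of the
  # raised cosine over that window is (1 + 2/pi)/2
  rc_mean_ej <- (1 + 2 / pi) / 2
  amp_rv <- (h$mrv_ep - h$rv_edp) / rc_mean_ej
  rv <- h$rv_edp + amp_rv * rc
  pa_dias <- h$mpap - h$pp * t_sys / (2 * period)
  if (pa_dias <= 0) {
    stop("state implies non-positive PA diastolic pressure", call. = FALSE)
  }
  pa <- pa_dias + h$pp * rc
  t_start_off <- t_sys / 4
  t_es_off <- 3 * t_sys / 4
  T_ej <- t_es_off - t_start_off
  ej_phase <- phase - t_start_off
  if (flow_shape == "invented") {
    fp <- flow_params(sv = h$sv, t_es = T_ej, t_ed = period,
                      t_reg = constants$t_reg)
    fp <- calibrate_amplitude(fp, co = h$co, rate = max(rate, 1000))
    q <- numeric(length(tt))
    inside <- ej_phase >= 0 & !in_pad
    q[inside] <- invented_flow(ej_phase[inside], fp)
    # the pre-onset sliver of each cycle is the previous beat's late
    # diastole: zero flow
  } else {
    q_pk <- h$sv * 60 * pi / (2 * T_ej)
    q <- ifelse(ej_phase >= 0 & ej_phase <= T_ej & !in_pad,
                q_pk * sin(pi * ej_phase / T_ej), 0)
  }
  k <- seq_len(n_beats) - 1L
  truth <- data.frame(t_start = k * period + t_start_off,
                      t_es = k * period + t_es_off,
                      t_ed = (k + 1L) * period + t_start_off)
  list(rv_pressure = pressure_trace(rv, rate, "RV_pressure"),
       pa_pressure = pressure_trace(pa, rate, "PA_pressure"),
       pa_flow = pressure_trace(q, rate, "PA_flow"),
       truth = truth)
}

#' Specification of one animal banding/hypoxia protocol condition
#'
#' The acute protocol crosses two afterload levels (pulmonary arterial
#' banding raising the zeroth-harmonic input impedance by `delta_z0`) with
#' two oxygenation levels.  Condition codes: first letter afterload
#' (`N` normal, `H` high banding), second letter oxygenation (`N` normoxia,
#' `H` hypoxia).  The mapping is fixed: high afterload sets
#' `delta_z0 = 4 mmHg/(L/min)`; hypoxia sets the arterial saturation target
#' to 0.75 and the assumed extraction fraction to 0.60 (0.50 in normoxia).
#'
#' @param condition one of `"N-N"`, `"H-N"`, `"N-H"`, `"H-H"`.
#' @param baseline named list of baseline scalars: `hr_bpm`, `co_l_min`,
#'   `mpap_mmHg`, `pp_mmHg`, `ef_frac`, `rv_edp_mmHg`, `ep_grad_mmHg`,
#'   `q_rca_ml_min`, `chb_g_ml`.
#' @param sampling_rate waveform sampling rate (Hz), default 250.
#' @param interval_min minutes between data sets (default 40).
#' @param duration_min length of the maintained condition (default 240).
#' @param noise_cv within-animal measurement noise CV (default 0.03).
#' @param mvo2_noise_cv CV of the noise on generated MVO2 (default 0.05).
#' @return A list of class `"animal_spec"`.
#' @export
animal_protocol_spec <- function(condition = c("N-N", "H-N", "N-H", "H-H"),
                                 baseline = list(
                                   hr_bpm = 95, co_l_min = 5.0,
                                   mpap_mmHg = 18, pp_mmHg = 14,
                                   ef_frac = 0.45, rv_edp_mmHg = 5,
                                   ep_grad_mmHg = 5, q_rca_ml_min = 40,
                                   chb_g_ml = 0.10),
                                 sampling_rate = 250, interval_min = 40,
                                 duration_min = 240, noise_cv = 0.03,
                                 mvo2_noise_cv = 0.05) {
  condition <- match.arg(condition)
  high_afterload <- substr(condition, 1, 1) == "H"
  hypoxic <- substr(condition, 3, 3) == "H"
  structure(list(
    condition = condition,
    delta_z0 = if (high_afterload) 4 else 0,   # mmHg per L/min
    sa_target = if (hypoxic) 0.75 else 1.00,
    oef = if (hypoxic) 0.60 else 0.50,
    baseline = baseline, sampling_rate = sampling_rate,
    interval_min = interval_min, duration_min = duration_min,
    noise_cv = noise_cv, mvo2_noise_cv = mvo2_noise_cv
  ), class = "animal_spec")
}

#' Generate an animal protocol time series
#'
#' Emits a baseline row (pre-banding, normoxic) followed by one row per
#' sampling interval of the maintained condition.  Banding raises mean PA
#' pressure and mean ejection pressure by `delta_z0 * CO` (impedance
#' increment times flow, unit-consistent with CO in L/min); hypoxia sets the
#' saturation to its target and selects the hypoxic extraction fraction.
#' MVO2 is generated from the adjusted model's total power output through
#' the coupling constant with multiplicative noise.  Optionally attaches
#' 250 Hz waveforms (measured-flow shape) per row for the integrated
#' stroke-power route.
#'
#' @param spec an [animal_protocol_spec()].
#' @param seed integer RNG seed.
#' @param animal_id label for the subject column.
#' @param waveforms if `TRUE`, attach a `waveforms` attribute: a list (one
#'   per row) of [generate_beat_waveforms()] outputs at the protocol rate.
#' @param constants a [rv_constants()] set.
#' @return A data frame with one row per time point (cohort-table columns
#'   plus `time_min`, `condition`, `delta_z0_mmhg_l_min`).
#' @export
generate_animal_timeseries <- function(spec, seed = 1L, animal_id = "sheep_01",
                                       waveforms = FALSE,
                                       constants = rv_constants()) {
  stopifnot(inherits(spec, "animal_spec"))
  set.seed(as.integer(seed))
  times <- c(0, seq(spec$interval_min, spec$duration_min,
                    by = spec$interval_min))
  b <- spec$baseline
  rows <- vector("list", length(times))
  wfs <- if (waveforms) vector("list", length(times)) else NULL
  for (i in seq_along(times)) {
    at_baseline <- times[i] == 0
    jit <- function(x) x * (1 + stats::rnorm(1, 0, spec$noise_cv))
    hr <- jit(b$hr_bpm)
    co_l <- jit(b$co_l_min)
    dz <- if (at_baseline) 0 else spec$delta_z0
    mpap <- jit(b$mpap_mmHg) + dz * co_l
    pp <- jit(b$pp_mmHg) * (mpap / b$mpap_mmHg)
    mrv_ep <- mpap + jit(b$ep_grad_mmHg)
    rv_edp <- jit(b$rv_edp_mmHg)
    ef <- jit(b$ef_frac)
    sa <- if (at_baseline) 1.00 else spec$sa_target
    oef <- if (at_baseline || sa >= 1) 0.50 else spec$oef
    co <- co_l * 1000
    sv <- co / hr
    rv_edv <- sv / ef
    row <- data.frame(
      subject_id = animal_id, group = spec$condition,
      time_min = times[i], condition = spec$condition,
      delta_z0_mmhg_l_min = dz,
      hr_bpm = hr, mpap_mmHg = mpap, pp_mmHg = pp, sv_ml = sv,
      co_ml_min = co, mrv_ep_mmHg = mrv_ep, rv_edp_mmHg = rv_edp,
      rv_edv_ml = rv_edv, rv_esv_ml = rv_edv - sv, ef_frac = ef,
      sa_frac = sa, oef_frac = oef,
      q_rca_ml_min = jit(b$q_rca_ml_min), chb_g_ml = jit(b$chb_g_ml),
      stringsAsFactors = FALSE
    )
    rows[[i]] <- row
    if (waveforms) {
      h <- hemo_state(hr = hr, mpap = mpap, pp = pp, sv = sv, co = co,
                      mrv_ep = mrv_ep, rv_edp = rv_edp, rv_edv = rv_edv)
      wfs[[i]] <- generate_beat_waveforms(h, rate = spec$sampling_rate,
                                          flow_shape = "pulse",
                                          constants = constants)
    }
  }
  ts <- do.call(rbind, rows)
  rownames(ts) <- NULL
  ts <- compute_cohort_energetics(ts, constants = constants)
  eps <- stats::rnorm(nrow(ts), 0, spec$mvo2_noise_cv)
  ts$mvo2_ml_min <- ts$tpo_adjusted_j_min / constants$k_o2 * (1 + eps)
  if (waveforms) attr(ts, "waveforms") <- wfs
  ts
}
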