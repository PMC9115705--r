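#' Scalar hemodynamic state of one subject
#'
#' Bundles the per-subject scalar hemodynamics the closed-form energetic
#' model needs.  Dependent quantities must be mutually consistent: cardiac
#' output equals heart rate times stroke volume, ejection fraction equals
#' stroke volume over end-diastolic volume, and end-systolic volume equals
#' end-diastolic volume minus stroke volume (each within `tol` relative,
#' to absorb rounding in tabulated data).
#'
#' @param hr heart rate (beats/min).
#' @param mpap mean pulmonary arterial pressure (mmHg).
#' @param pp pulmonary arterial pulse pressure (mmHg, systolic - diastolic).
#' @param sv stroke volume (ml).
#' @param co cardiac output (ml/min).
#' @param mrv_ep mean RV pressure over the ejection period (mmHg).
#' @param rv_edp RV end-diastolic pressure (mmHg).
#' @param rv_edv RV end-diastolic volume (ml).
#' @param rv_esv RV end-systolic volume (ml); default `rv_edv - sv`.
#' @param ef ejection fraction (fraction); default `sv / rv_edv`.
#' @param v0 dead volume from the end-systolic pressure-volume relation (ml);
#'   treated as negligible by default (0).
#' @param tol relative tolerance for the consistency checks.
#' @return A list of class `"hemo_state"`.
#' @examples
#' h <- hemo_state(hr = 75, mpap = 47.4, pp = 30, sv = 74.7,
#'                 co = 75 * 74.7, mrv_ep = 52, rv_edp = 8, rv_edv = 160)
#' h$ef
#' @export
hemo_state <- function(hr, mpap, pp, sv, co = hr * sv, mrv_ep, rv_edp,
                       rv_edv, rv_esv = rv_edv - sv, ef = sv / rv_edv,
                       v0 = 0, tol = 1e-3) {
  .chk_pos(hr, "hr"); .chk_pos(mpap, "mpap"); .chk_pos(pp, "pp", zero_ok = TRUE)
  .chk_pos(sv, "sv"); .chk_pos(co, "co"); .chk_pos(mrv_ep, "mrv_ep")
  .chk_pos(rv_edp, "rv_edp", zero_ok = TRUE); .chk_pos(rv_edv, "rv_edv")
  .chk_pos(rv_esv, "rv_esv"); .chk_pos(ef, "ef"); .chk_pos(v0, "v0", zero_ok = TRUE)
  if (mrv_ep <= rv_edp) {
    stop("mean ejection pressure must exceed end-diastolic pressure",
         call. = FALSE)
  }
  rel <- function(a, b) abs(a - b) / max(abs(b), .Machine$double.eps)
  if (rel(co, hr * sv) > tol) {
    stop("inconsistent state: co != hr * sv (relative error ",
         format(rel(co, hr * sv), digits = 3), ")", call. = FALSE)
  }
  if (rel(ef, sv / rv_edv) > tol) {
    stop("inconsistent state: ef != sv / rv_edv", call. = FALSE)
  }
  if (rel(rv_esv, rv_edv - sv) > tol) {
    stop("inconsistent state: rv_esv != rv_edv - sv", call. = FALSE)
  }
  if (ef >= 1) stop("ejection fraction must be < 1", call. = FALSE)
  structure(list(hr = hr, mpap = mpap, pp = pp, sv = sv, co = co,
                 mrv_ep = mrv_ep, rv_edp = rv_edp, rv_edv = rv_edv,
                 rv_esv = rv_esv, ef = ef, v0 = v0),
            class = "hemo_state")
}

#' Oxygen supply state of the right ventricular free wall
#'
#' @param sa arterial oxygen saturation (fraction in (0, 1]).
#' @param oef RV oxygen extraction fraction (fraction in (0, 1]).
#' @param q_rca right coronary artery blood flow (ml/min).
#' @param chb hemoglobin concentration (g/ml; e.g. 0.15 for 15 g/dl).
#' @return A list of class `"oxy_state"`.
#' @examples
#' oxy_state(sa = 0.95, oef = 0.6, q_rca = 47.5, chb = 0.15)
#' @export
oxy_state <- function(sa, oef, q_rca, chb) {
  .chk_pos(sa, "sa"); .chk_pos(oef, "oef")
  .chk_pos(q_rca, "q_rca"); .chk_pos(chb, "chb")
  if (sa > 1) stop("'sa' is a fraction and must be <= 1", call. = FALSE)
  if (oef > 1) stop("'oef' is a fraction and must be <= 1", call. = FALSE)
  structure(list(sa = sa, oef = oef, q_rca = q_rca, chb = chb),
            class = "oxy_state")
}

#' @export
print.hemo_state <- function(x, ...) {
  cat("Hemodynamic state:\n")
  cat(sprintf("  HR %.4g bpm, mPAP %.4g mmHg, PP %.4g mmHg\n", x$hr, x$mpap, x$pp))
  cat(sprintf("  SV %.4g ml, CO %.4g ml/min, EF %.3g\n", x$sv, x$co, x$ef))
  cat(sprintf("  mRV_EP %.4g, RV_EDP %.4g mmHg; RV_EDV %.4g, RV_ESV %.4g, V0 %.4g ml\n",
              x$mrv_ep, x$rv_edp, x$rv_edv, x$rv_esv, x$v0))
  invisible(x)
}

#' @export
print.oxy_state <- function(x, ...) {
  cat(sprintf("Oxygen state: Sa %.3g, OEF %.3g, Q_RCA %.4g ml/min, Chb %.3g g/ml\n",
              x$sa, x$oef, x$q_rca, x$chb))
  invisible(x)
}
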