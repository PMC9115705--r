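#' Physical and model constants
#'
#' Returns the constant set used throughout the energetic model, with the
#' option to override individual values (e.g. for sensitivity analyses on the
#' oscillatory-power coefficient).
#'
#' @details
#' * `k_o2` (J per ml O2): energy yield of oxidative phosphorylation with
#'   mixed substrates, 20.2 J per ml of oxygen consumed.  This couples
#'   mechanical energy to oxygen consumption.
#' * `k_hb` (ml O2 per g Hb): hemoglobin oxygen carrying capacity, 1.34.
#' * `k_mmhgml` (J per mmHg*ml): conversion from pressure-volume work in
#'   mmHg*ml to joules, 1.33e-4.
#' * `k_osc` (J/min per mmHg): coefficient of the oscillatory stroke-power
#'   estimate, 0.156 times pulmonary arterial pulse pressure.
#' * `t_reg` (s): assumed duration of pulmonary valve regurgitation, 0.04 s.
#'
#' @param ... named overrides for any of the constants.
#' @return A named list of class `"rv_constants"`.
#' @examples
#' c0 <- rv_constants()
#' c0$k_o2
#' rv_constants(k_osc = 0.10)$k_osc
#' @export
rv_constants <- function(...) {
  const <- list(
    k_o2     = 20.2,
    k_hb     = 1.34,
    k_mmhgml = 1.33e-4,
    k_osc    = 0.156,
    t_reg    = 0.04
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(const))
    if (length(bad)) {
      stop("unknown constant(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    const[names(over)] <- over
  }
  for (nm in names(const)) {
    v <- const[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("constant '", nm, "' must be a single positive finite number",
           call. = FALSE)
    }
  }
  structure(const, class = "rv_constants")
}

#' @export
print.rv_constants <- function(x, ...) {
  cat("RV energetic model constants:\n")
  cat(sprintf("  k_o2     = %g J/ml O2   (oxidative phosphorylation yield)\n", x$k_o2))
  cat(sprintf("  k_hb     = %g ml O2/g   (hemoglobin carrying capacity)\n", x$k_hb))
  cat(sprintf("  k_mmhgml = %g J/(mmHg*ml)\n", x$k_mmhgml))
  cat(sprintf("  k_osc    = %g J/min per mmHg PP (oscillatory power)\n", x$k_osc))
  cat(sprintf("  t_reg    = %g s (pulmonary valve regurgitation)\n", x$t_reg))
  invisible(x)
}

# single positive finite scalar check used by constructors
.chk_pos <- function(x, name, zero_ok = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("'", name, "' must be a single finite number", call. = FALSE)
  }
  if (zero_ok) {
    if (x < 0) stop("'", name, "' must be >= 0", call. = FALSE)
  } else {
    if (x <= 0) stop("'", name, "' must be > 0", call. = FALSE)
  }
  x
}
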