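.variant_col <- function(variant = c("adjusted", "elbeery")) {
  match.arg(variant)
}

.new_regression_result <- function(fit, n, response, predictor) {
  s <- summary(fit)
  ci <- stats::confint(fit, level = 0.95)
  co <- s$coefficients
  structure(list(
    slope = unname(co[2, 1]), intercept = unname(co[1, 1]),
    r_squared = s$r.squared,
    slope_p = unname(co[2, 4]), intercept_p = unname(co[1, 4]),
    slope_ci95 = unname(ci[2, ]), intercept_ci95 = unname(ci[1, ]),
    n = n, response = response, predictor = predictor
  ), class = "rv_regression")
}

#' @export
print.rv_regression <- function(x, ...) {
  cat(sprintf("OLS: %s = %.4g x %s + %.4g  (n = %d)\n",
              x$response, x$slope, x$predictor, x$intercept, x$n))
  cat(sprintf("  R^2 = %.4f; slope p = %.3g, 95%% CI [%.4g, %.4g]\n",
              x$r_squared, x$slope_p, x$slope_ci95[1], x$slope_ci95[2]))
  cat(sprintf("  intercept p = %.3g, 95%% CI [%.4g, %.4g]\n",
              x$intercept_p, x$intercept_ci95[1], x$intercept_ci95[2]))
  invisible(x)
}

#' Regression of total power output on oxygen consumption
#'
#' Ordinary least squares of a model variant's total RV power output
#' (response, J/min) on measured/simulated myocardial oxygen consumption
#' rate (predictor, ml/min), with two-sided t-tests and 95% confidence
#' intervals for slope and intercept.  Under the coupling hypothesis the
#' slope estimates the oxidative-phosphorylation yield (20.2 J/ml O2) and
#' the intercept the anaerobic power contribution (expected nil).
#'
#' @param coh cohort data frame with `mvo2_ml_min` and the variant's
#'   `tpo_*_j_min` column.
#' @param variant `"adjusted"` (default) or `"elbeery"`.
#' @return An `"rv_regression"` result.
#' @export
fit_power_oxygen_regression <- function(coh, variant = c("adjusted", "elbeery")) {
  variant <- .variant_col(variant)
  y <- coh[[paste0("tpo_", variant, "_j_min")]]
  x <- coh$mvo2_ml_min
  if (is.null(y) || is.null(x)) {
    stop("cohort needs 'mvo2_ml_min' and 'tpo_", variant, "_j_min' columns",
         call. = FALSE)
  }
  if (length(x) < 3) stop("need at least 3 records", call. = FALSE)
  if (stats::var(x) == 0) {
    stop("degenerate design: zero variance in oxygen consumption",
         call. = FALSE)
  }
  .new_regression_result(stats::lm(y ~ x), length(x),
                         response = paste0("TPO_", variant),
                         predictor = "MVO2")
}

#' Correlation of RV efficiency with oxygen consumption
#'
#' OLS of a model variant's RV efficiency (response, fraction) on oxygen
#' consumption rate (predictor, ml/min).  Efficiency is hypothesised to
#' fall as consumption rises (negative slope): an inefficient ventricle
#' needs more oxygen to sustain the same useful output.
#'
#' @inheritParams fit_power_oxygen_regression
#' @return An `"rv_regression"` result.
#' @export
efficiency_oxygen_correlation <- function(coh, variant = c("adjusted", "elbeery")) {
  variant <- .variant_col(variant)
  y <- coh[[paste0("efficiency_", variant)]]
  x <- coh$mvo2_ml_min
  if (is.null(y) || is.null(x)) {
    stop("cohort needs 'mvo2_ml_min' and 'efficiency_", variant, "' columns",
         call. = FALSE)
  }
  if (length(x) < 3) stop("need at least 3 records", call. = FALSE)
  if (stats::var(x) == 0) {
    stop("degenerate design: zero variance in oxygen consumption",
         call. = FALSE)
  }
  .new_regression_result(stats::lm(y ~ x), length(x),
                         response = paste0("efficiency_", variant),
                         predictor = "MVO2")
}

# pool NYHA III and IV into one severity stratum; other labels pass through
.pool_severity <- function(group) {
  ifelse(group %in% c("NYHA_III", "NYHA_IV"), "NYHA_III_IV", group)
}

#' Group-wise power-fraction summary
#'
#' For each record, expresses isovolumic, useful-stroke and pulsatile-stroke
#' power as fractions of the variant's total power output, then reports the
#' group-wise mean and standard error of the mean (sd/sqrt(n); `NA` for
#' single-record groups).  NYHA III and IV are pooled into one stratum.
#'
#' @inheritParams fit_power_oxygen_regression
#' @return A data frame with columns `group`, `component`, `n`,
#'   `mean_percent`, `sem_percent`.
#' @export
power_fraction_summary <- function(coh, variant = c("adjusted", "elbeery")) {
  variant <- .variant_col(variant)
  iso <- coh[[paste0("iso_", variant, "_j_min")]]
  tot <- coh[[paste0("tpo_", variant, "_j_min")]]
  useful <- coh$useful_stroke_j_min
  if (is.null(iso) || is.null(tot) || is.null(useful)) {
    stop("cohort lacks the power-component columns for variant '", variant,
         "'", call. = FALSE)
  }
  pulsatile <- tot - iso - useful
  grp <- .pool_severity(coh$group)
  comp <- list(isovolumic = iso / tot, useful_stroke = useful / tot,
               pulsatile_stroke = pulsatile / tot)
  res <- list()
  for (g in unique(grp)) {
    idx <- grp == g
    n <- sum(idx)
    if (n == 0) next
    for (cn in names(comp)) {
      v <- comp[[cn]][idx] * 100
      res[[length(res) + 1L]] <- data.frame(
        group = g, component = cn, n = n, mean_percent = mean(v),
        sem_percent = if (n > 1) stats::sd(v) / sqrt(n) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Severity-class comparison by MANOVA
#'
#' One-way MANOVA comparing NYHA II against pooled NYHA III/IV on three
#' dependent variables — RV efficiency under each model variant and the
#' oxygen consumption rate — followed by per-variable Welch t-tests with
#' Bonferroni correction (factor 3).
#'
#' @param coh cohort data frame with `group`, `efficiency_elbeery`,
#'   `efficiency_adjusted` and `mvo2_ml_min`.
#' @param statistic multivariate test statistic, `"Pillai"` (default) or
#'   `"Wilks"`.
#' @return A list of class `"rv_manova"`: `statistic`, `value` (the
#'   multivariate statistic), `approx_f`, `df`, `p_value`, and `post_hoc`,
#'   a data frame of per-variable Welch tests with Bonferroni-adjusted
#'   p-values.
#' @export
class_comparison_manova <- function(coh, statistic = c("Pillai", "Wilks")) {
  statistic <- match.arg(statistic)
  need <- c("group", "efficiency_elbeery", "efficiency_adjusted",
            "mvo2_ml_min")
  miss <- setdiff(need, names(coh))
  if (length(miss)) {
    stop("cohort lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  grp <- factor(.pool_severity(coh$group))
  if (nlevels(grp) != 2) {
    stop("expected exactly two severity strata, got: ",
         paste(levels(grp), collapse = ", "), call. = FALSE)
  }
  if (any(table(grp) < 2)) {
    stop("each stratum needs at least 2 records", call. = FALSE)
  }
  Y <- as.matrix(coh[, c("efficiency_elbeery", "efficiency_adjusted",
                         "mvo2_ml_min")])
  fit <- stats::manova(Y ~ grp)
  sm <- tryCatch(summary(fit, test = statistic),
                 error = function(e) {
                   stop("rank deficiency in the within-group covariance; ",
                        "drop a dependent variable (", conditionMessage(e),
                        ")", call. = FALSE)
                 })
  st <- sm$stats
  post <- do.call(rbind, lapply(colnames(Y), function(v) {
    tt <- stats::t.test(Y[, v] ~ grp)
    data.frame(variable = v,
               mean_1 = unname(tt$estimate[1]), mean_2 = unname(tt$estimate[2]),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value,
               p_bonferroni = min(1, tt$p.value * ncol(Y)),
               stringsAsFactors = FALSE)
  }))
  structure(list(statistic = statistic, value = unname(st[1, 2]),
                 approx_f = unname(st[1, 3]),
                 df = unname(st[1, 4:5]), p_value = unname(st[1, 6]),
                 groups = levels(grp), n = as.vector(table(grp)),
                 post_hoc = post),
            class = "rv_manova")
}

#' @export
print.rv_manova <- function(x, ...) {
  cat(sprintf("MANOVA (%s) %s vs %s (n = %d, %d): statistic %.4f, F(%g, %g) = %.3f, p = %.4g\n",
              x$statistic, x$groups[1], x$groups[2], x$n[1], x$n[2],
              x$value, x$df[1], x$df[2], x$approx_f, x$p_value))
  cat("Post hoc Welch t-tests (Bonferroni x 3):\n")
  print(x$post_hoc, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Full cohort validation report
#'
#' Runs the whole validation battery on a cohort: power-on-oxygen
#' regressions and efficiency correlations for both model variants, the
#' power-fraction summary, and (when two severity strata are present) the
#' MANOVA class comparison.
#'
#' @param coh cohort data frame with energetic columns and `mvo2_ml_min`.
#' @return A list of class `"rv_validation"`.
#' @export
validate_cohort <- function(coh) {
  out <- list(
    regression = list(
      elbeery = fit_power_oxygen_regression(coh, "elbeery"),
      adjusted = fit_power_oxygen_regression(coh, "adjusted")),
    efficiency = list(
      elbeery = efficiency_oxygen_correlation(coh, "elbeery"),
      adjusted = efficiency_oxygen_correlation(coh, "adjusted")),
    power_fractions = list(
      elbeery = power_fraction_summary(coh, "elbeery"),
      adjusted = power_fraction_summary(coh, "adjusted"))
  )
  strata <- unique(.pool_severity(coh$group))
  if (length(strata) == 2 && all(table(.pool_severity(coh$group)) >= 2)) {
    out$manova <- class_comparison_manova(coh)
  }
  structure(out, class = "rv_validation")
}

#' @export
print.rv_validation <- function(x, ...) {
  cat("== Power output vs oxygen consumption ==\n")
  for (v in names(x$regression)) { cat("[", v, "] ", sep = ""); print(x$regression[[v]]) }
  cat("== Efficiency vs oxygen consumption ==\n")
  for (v in names(x$efficiency)) { cat("[", v, "] ", sep = ""); print(x$efficiency[[v]]) }
  cat("== Power fractions (% of total, mean +/- SEM) ==\n")
  for (v in names(x$power_fractions)) {
    cat("[", v, "]\n", sep = ""); print(x$power_fractions[[v]], row.names = FALSE, digits = 4)
  }
  if (!is.null(x$manova)) { cat("== Severity-class comparison ==\n"); print(x$manova) }
  invisible(x)
}
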