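#' Read a cohort table
#'
#' Reads a comma-separated cohort table (UTF-8, header required, units
#' encoded in column names, e.g. `mpap_mmHg`, `co_ml_min`) and validates
#' the per-row consistency invariants: `co = hr * sv`, `ef = sv / rv_edv`
#' and `rv_esv = rv_edv - sv`, each within `tol` relative.
#'
#' @param path file path.
#' @param tol relative tolerance of the consistency checks (default 1e-3,
#'   absorbing tabulation rounding).
#' @return A validated data frame.
#' @export
read_cohort_table <- function(path, tol = 1e-3) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  coh <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  need <- c("subject_id", "group", "hr_bpm", "mpap_mmHg", "pp_mmHg", "sv_ml",
            "co_ml_min", "mrv_ep_mmHg", "rv_edp_mmHg", "rv_edv_ml",
            "rv_esv_ml", "ef_frac")
  miss <- setdiff(need, names(coh))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  rel <- function(a, b) abs(a - b) / pmax(abs(b), .Machine$double.eps)
  checks <- list(
    "co_ml_min != hr_bpm * sv_ml" = rel(coh$co_ml_min, coh$hr_bpm * coh$sv_ml),
    "ef_frac != sv_ml / rv_edv_ml" = rel(coh$ef_frac, coh$sv_ml / coh$rv_edv_ml),
    "rv_esv_ml != rv_edv_ml - sv_ml" = rel(coh$rv_esv_ml,
                                           coh$rv_edv_ml - coh$sv_ml)
  )
  for (msg in names(checks)) {
    bad <- which(checks[[msg]] > tol)
    if (length(bad)) {
      stop("row ", bad[1], ": inconsistent fields (", msg,
           ", relative error ", format(checks[[msg]][bad[1]], digits = 3),
           ")", call. = FALSE)
    }
  }
  coh
}

#' Write a cohort table
#'
#' Writes the cohort as CSV atomically (temporary file in the same
#' directory, then rename).
#'
#' @param coh cohort data frame.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(coh, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv")
  utils::write.csv(coh, tmp, row.names = FALSE, quote = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a waveform file
#'
#' Delimited text with header row and columns `time_s`, `rv_pressure_mmHg`,
#' `pa_pressure_mmHg` and optionally `pa_flow_ml_min`.  The time column
#' must be a uniform grid; the sampling rate is inferred from it.
#'
#' @param path file path.
#' @param tol relative tolerance on time-step uniformity.
#' @return A named list of [pressure_trace()]s (`rv_pressure`,
#'   `pa_pressure`, and `pa_flow` when present).
#' @export
read_waveform_file <- function(path, tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "rv_pressure_mmHg", "pa_pressure_mmHg")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dt <- diff(df$time_s)
  if (any(dt <= 0) || (max(dt) - min(dt)) / stats::median(dt) > tol) {
    bad <- which.max(abs(dt - stats::median(dt)))
    stop("non-uniform time grid at row ", bad + 1,
         " (time_s step deviates from the median)", call. = FALSE)
  }
  rate <- 1 / stats::median(dt)
  out <- list(
    rv_pressure = pressure_trace(df$rv_pressure_mmHg, rate, "RV_pressure",
                                 t0 = df$time_s[1]),
    pa_pressure = pressure_trace(df$pa_pressure_mmHg, rate, "PA_pressure",
                                 t0 = df$time_s[1])
  )
  if ("pa_flow_ml_min" %in% names(df)) {
    out$pa_flow <- pressure_trace(df$pa_flow_ml_min, rate, "PA_flow",
                                  t0 = df$time_s[1])
  }
  out
}

#' Write a waveform file
#'
#' @param traces named list with `rv_pressure`, `pa_pressure` and optionally
#'   `pa_flow` [pressure_trace()]s on a common time base.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_waveform_file <- function(traces, path) {
  rv <- traces$rv_pressure
  df <- data.frame(time_s = trace_times(rv),
                   rv_pressure_mmHg = rv$samples,
                   pa_pressure_mmHg = traces$pa_pressure$samples)
  if (!is.null(traces$pa_flow)) df$pa_flow_ml_min <- traces$pa_flow$samples
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv")
  utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Write analysis results as JSON
#'
#' Serialises per-subject results or a validation report to JSON
#' atomically, embedding the seed and a hash of the configuration for
#' provenance.
#'
#' @param results a list or data frame.
#' @param path destination path.
#' @param seed the RNG seed used (recorded in the output).
#' @param config optional configuration list (recorded and hashed).
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, seed = NULL, config = NULL) {
  payload <- list(results = results)
  if (!is.null(seed)) payload$seed <- seed
  if (!is.null(config)) {
    payload$config <- config
    payload$config_hash <- sum(utf8ToInt(
      paste(utils::capture.output(utils::str(config)), collapse = "")))
  }
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json")
  jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  file.rename(tmp, path)
  invisible(path)
}
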