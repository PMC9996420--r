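#' Run the full analysis pipeline on an event stream and survey table
#'
#' Events -> sessions/segments -> hourly and daily measures -> 14-day window
#' alignment with data-sufficiency QC -> `log(1+x)` transforms ->
#' within/between-person disaggregation -> one two-level random-slope model
#' per outcome. The model predictors are, in order: window-mean hourly app
#' count, window-mean normalized app entropy, log nighttime minutes, log
#' median session duration, log median typing interval.
#'
#' @param events `sensor_events` table (see [read_events()]).
#' @param surveys survey table (see [align_windows()]).
#' @param window_days,min_days,min_hours window and QC parameters
#'   (defaults 14, 3, 3).
#' @param outcomes outcome columns to model.
#' @param center_bp grand-mean center the between-person predictors.
#' @param method `"REML"` or `"ML"`.
#' @param starts optimizer starts passed to [fit_lmm()].
#' @return list of class `study_analysis`: `windows` (window-level table),
#'   `design` (disaggregated modeling table), `fits` (named list of
#'   [fit_lmm()] results), `correlations` (raw/within/between), `qc_table`.
#' @export
analyze_study <- function(events, surveys, window_days = 14, min_days = 3,
                          min_hours = 3,
                          outcomes = c("loss_of_interest", "depressed_mood"),
                          center_bp = TRUE, method = "REML", starts = 3) {
  feats <- compute_features(events)
  win <- window_features(surveys, feats$hourly, feats$nighttime,
                         window_days = window_days, min_days = min_days,
                         min_hours = min_hours)
  model_tab <- win[qc_pass == TRUE,
                   c("person_id", "symptom_date", outcomes,
                     "app_count_mean", "app_entropy_mean", "nighttime_log",
                     "session_duration_log", "typing_interval_log"),
                   with = FALSE]
  setnames(model_tab,
           c("app_count_mean", "app_entropy_mean", "nighttime_log",
             "session_duration_log", "typing_interval_log"),
           MEASURES)
  design <- split_within_between(model_tab, MEASURES, center_bp = center_bp)
  fits <- lapply(outcomes, function(o) {
    fit_lmm(design, mlm_spec(o, method = method), starts = starts)
  })
  names(fits) <- outcomes
  corr <- correlation_table(design, MEASURES, outcomes)
  structure(list(windows = win, design = design, fits = fits,
                 correlations = corr,
                 qc_table = attr(win, "qc_table", exact = TRUE)),
            class = "study_analysis")
}

#' @export
print.study_analysis <- function(x, ...) {
  npass <- sum(x$windows$qc_pass)
  cat("Study analysis:", nrow(x$windows), "windows (", npass,
      "passing QC ),", length(unique(x$design$person_id)), "persons\n")
  for (o in names(x$fits)) {
    cat("\n--- outcome:", o, "---\n")
    print(x$fits[[o]])
  }
  invisible(x)
}
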