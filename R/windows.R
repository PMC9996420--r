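#' Align feature tables with 14-day recall windows
#'
#' The depression items are recalled over the past two weeks, so each survey
#' is paired with the half-open date window `[symptom_date - 14,
#' symptom_date)` — the 14 days strictly before the survey day. Overlapping
#' windows (surveys closer than 14 days) are allowed; feature rows then enter
#' more than one window.
#'
#' @param surveys data.frame with `person_id`, `symptom_date` (Date),
#'   `loss_of_interest`, `depressed_mood` (integers 0-4, at most one record
#'   per person-date).
#' @param hourly hourly feature table from [compute_features()].
#' @param nighttime daily nighttime table from [compute_features()].
#' @param window_days window length in days (default 14).
#' @return list of class `aligned_windows`: `surveys`, `hourly` (hourly rows
#'   keyed by `person_id` + `symptom_date`), `nighttime` (daily rows
#'   zero-filled over all `window_days` days of every window), `window_days`.
#' @export
align_windows <- function(surveys, hourly, nighttime, window_days = 14) {
  sv <- as.data.table(surveys)
  stopifnot(all(c("person_id", "symptom_date") %in% names(sv)))
  sv[, person_id := as.character(person_id)]
  sv[, symptom_date := as.Date(symptom_date)]
  for (it in intersect(c("loss_of_interest", "depressed_mood"), names(sv))) {
    v <- sv[[it]]
    if (any(!is.na(v) & (v < 0 | v > 4 | v != round(v)))) {
      stop("survey item ", it, " outside the 0-4 integer scale")
    }
  }
  if (anyDuplicated(sv, by = c("person_id", "symptom_date"))) {
    stop("more than one survey record per (person, date)")
  }
  sv[, window_start := symptom_date - window_days]

  hf <- as.data.table(hourly)
  hj <- hf[sv[, .(person_id, symptom_date, window_start)],
           on = .(person_id, date >= window_start, date < symptom_date),
           allow.cartesian = TRUE, nomatch = NULL,
           .(person_id, symptom_date = i.symptom_date, date = x.date, hour,
             app_count, app_entropy, session_duration_min, typing_interval_s)]

  nt <- as.data.table(nighttime)
  # zero-fill: every window contributes exactly window_days daily values
  grid <- sv[, .(date = seq(window_start, symptom_date - 1, by = "day")),
             by = .(person_id, symptom_date)]
  nj <- nt[grid, on = c("person_id", "date")]
  nj[is.na(nighttime_min), nighttime_min := 0]

  structure(list(surveys = sv[, window_start := NULL][],
                 hourly = hj, nighttime = nj, window_days = window_days),
            class = "aligned_windows")
}

#' Data-sufficiency filter for recall windows
#'
#' Passive interaction sensing produces data only while the phone is in use,
#' so a sparse window may reflect a sensing gap rather than true inactivity.
#' A day *qualifies* when it has at least `min_hours` unique clock hours with
#' any hourly measure observed; a window passes when it has at least
#' `min_days` qualifying days.
#'
#' @param aligned output of [align_windows()].
#' @param min_days,min_hours thresholds (defaults 3 and 3).
#' @return data.table per window: `person_id`, `symptom_date`,
#'   `n_active_days`, `n_qualifying_days`, `n_active_hours`, `qc_pass`,
#'   `fail_reason` (`NA` when passing).
#' @export
qc_filter <- function(aligned, min_days = 3, min_hours = 3) {
  stopifnot(inherits(aligned, "aligned_windows"))
  key <- c("person_id", "symptom_date")
  dh <- aligned$hourly[, .(n_hours = uniqueN(hour)),
                       by = c(key, "date")]
  per_win <- dh[, .(n_active_days = .N,
                    n_qualifying_days = sum(n_hours >= min_hours),
                    n_active_hours = sum(n_hours)), by = key]
  out <- per_win[as.data.table(aligned$surveys)[, ..key], on = key]
  for (cc in c("n_active_days", "n_qualifying_days", "n_active_hours")) {
    set(out, which(is.na(out[[cc]])), cc, 0L)
  }
  out[, qc_pass := n_qualifying_days >= min_days]
  out[, fail_reason := fifelse(
    qc_pass, NA_character_,
    fifelse(n_active_hours == 0L, "no feature rows in window",
            paste0("only ", n_qualifying_days, " day(s) with >= ", min_hours,
                   " active hours (need ", min_days, ")")))]
  out[order(person_id, symptom_date)]
}

#' Aggregate windows to model-ready predictors
#'
#' For each QC-passing window: `app_count` and `app_entropy` are averaged
#' over the window's non-missing hourly values; hourly median session
#' duration and typing interval are averaged the same way and then
#' transformed by `log(1 + x)`; nighttime use is averaged over *all* window
#' days (true zeros included) and transformed by `log(1 + x)`. `log(1 + x)`
#' rather than `log(x)` keeps the true zeros of nighttime use finite, and is
#' applied after window averaging so each window value is transformed once.
#' Failing windows are emitted with missing features and `qc_pass = FALSE`.
#'
#' @param aligned output of [align_windows()].
#' @param qc output of [qc_filter()] (recomputed with defaults when `NULL`).
#' @return data.table per window: keys, outcomes, `app_count_mean`,
#'   `app_entropy_mean`, `nighttime_log`, `session_duration_log`,
#'   `typing_interval_log`, `n_qualifying_days`, `n_active_hours`, `qc_pass`.
#' @export
aggregate_windows <- function(aligned, qc = NULL) {
  stopifnot(inherits(aligned, "aligned_windows"))
  if (is.null(qc)) qc <- qc_filter(aligned)
  key <- c("person_id", "symptom_date")
  mn <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  hagg <- aligned$hourly[, .(
    app_count_mean = mn(as.numeric(app_count)),
    app_entropy_mean = mn(app_entropy),
    session_duration_raw = mn(session_duration_min),
    typing_interval_raw = mn(typing_interval_s)
  ), by = key]
  nagg <- aligned$nighttime[, .(nighttime_raw = mean(nighttime_min)), by = key]
  out <- Reduce(function(a, b) merge(a, b, by = key, all.x = TRUE),
                list(qc[, c(key, "n_qualifying_days", "n_active_hours",
                            "qc_pass"), with = FALSE],
                     hagg, nagg, as.data.table(aligned$surveys)))
  out[, nighttime_log := log1p(nighttime_raw)]
  out[, session_duration_log := log1p(session_duration_raw)]
  out[, typing_interval_log := log1p(typing_interval_raw)]
  feat <- c("app_count_mean", "app_entropy_mean", "nighttime_raw",
            "session_duration_raw", "typing_interval_raw", "nighttime_log",
            "session_duration_log", "typing_interval_log")
  for (cc in feat) set(out, which(!out$qc_pass), cc, NA_real_)
  setcolorder(out, c(key, "loss_of_interest", "depressed_mood",
                     "app_count_mean", "app_entropy_mean", "nighttime_log",
                     "session_duration_log", "typing_interval_log"))
  out[order(person_id, symptom_date)]
}

#' End-to-end window construction
#'
#' [align_windows()] + [qc_filter()] + [aggregate_windows()] in one call.
#'
#' @inheritParams align_windows
#' @inheritParams qc_filter
#' @return see [aggregate_windows()]; the QC table is attached as attribute
#'   `"qc_table"`.
#' @export
window_features <- function(surveys, hourly, nighttime, window_days = 14,
                            min_days = 3, min_hours = 3) {
  aligned <- align_windows(surveys, hourly, nighttime, window_days)
  qc <- qc_filter(aligned, min_days = min_days, min_hours = min_hours)
  out <- aggregate_windows(aligned, qc)
  setattr(out, "qc_table", qc)
  out
}

#' Moment coefficient of skewness
#'
#' `g1 = m3 / m2^(3/2)` with population (divide-by-n) central moments.
#' Returns `NA` for fewer than 2 values or zero variance.
#'
#' @param x numeric vector; `NA`s dropped.
#' @return scalar skewness.
#' @export
skewness_g1 <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}

#' Summary statistics of the window-level measures
#'
#' Mean, SD, min, max and skewness per behavioral measure across QC-passing
#' windows, on the raw window-mean scale and (for the three time measures)
#' after the `log(1 + x)` transform.
#'
#' @param windows output of [aggregate_windows()] / [window_features()].
#' @return data.table with columns `measure`, `scale` (`raw` / `log1p`),
#'   `mean`, `sd`, `min`, `max`, `skewness`.
#' @export
summarize_measures <- function(windows) {
  w <- as.data.table(windows)[qc_pass == TRUE]
  if (nrow(w) < 2L) stop("need at least 2 QC-passing windows to summarize")
  cols <- list(
    list("app_count", "raw", "app_count_mean"),
    list("app_entropy", "raw", "app_entropy_mean"),
    list("nighttime", "raw", "nighttime_raw"),
    list("nighttime", "log1p", "nighttime_log"),
    list("session_duration", "raw", "session_duration_raw"),
    list("session_duration", "log1p", "session_duration_log"),
    list("typing_interval", "raw", "typing_interval_raw"),
    list("typing_interval", "log1p", "typing_interval_log"))
  rbindlist(lapply(cols, function(cc) {
    x <- w[[cc[[3]]]]
    x <- x[!is.na(x)]
    data.table(measure = cc[[1]], scale = cc[[2]],
               mean = mean(x), sd = sd(x), min = min(x), max = max(x),
               skewness = skewness_g1(x))
  }))
}
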