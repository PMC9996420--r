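#' Normalized Shannon entropy of an app-time allocation
#'
#' For within-hour app time shares `p` (positive, summing to 1) over `N`
#' unique apps, returns `-sum(p * log(p)) / log(N)`, the Shannon entropy
#' normalized by its maximum so the value lies in \[0, 1\] regardless of how
#' many apps were used. `N = 1` returns 0 by convention (the normalizer
#' `log(1) = 0` makes the ratio 0/0; a single app is zero diversity). An
#' empty allocation returns `NA` — an hour with no app use has no entropy,
#' rather than zero entropy.
#'
#' @param p numeric vector of time shares; each in (0, 1], summing to 1
#'   (tolerance 1e-8).
#' @return scalar in \[0, 1\], or `NA_real_` for an empty allocation.
#' @export
#' @examples
#' app_entropy(c(0.5, 0.5))   # 1: uniform use of two apps
#' app_entropy(c(0.75, 0.25)) # 0.811...
#' app_entropy(1)             # 0: single app
app_entropy <- function(p) {
  if (length(p) == 0L) return(NA_real_)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("shares must lie in (0, 1]")
  }
  if (abs(sum(p) - 1) > 1e-8) stop("shares must sum to 1")
  if (length(p) == 1L) return(0)
  val <- -sum(p * log(p)) / log(length(p))
  min(max(val, 0), 1)
}

# clip [start, end) intervals (local milliseconds) to clock hours; returns one
# row per (interval x hour touched) with the overlap in ms
.clip_to_hours <- function(dt) {
  x <- dt[end > start]
  if (nrow(x) == 0L) {
    return(data.table(x, habs = integer(), overlap_s = numeric()))
  }
  x <- copy(x)
  x[, row_id := .I]
  x[, h0 := as.integer(floor(start / 3600000))]
  x[, h1 := as.integer(floor((end - 1e-6) / 3600000))]
  out <- x[, .(habs = seq.int(h0, h1)), by = row_id][x, on = "row_id"]
  out[, overlap_s := pmin(end, (habs + 1) * 3600000) -
        pmax(start, habs * 3600000)]
  out[overlap_s > 0]
}

.hour_key <- function(dt) {
  dt[, date := as.Date(habs %/% 24, origin = "1970-01-01")]
  dt[, hour := as.integer(habs %% 24)]
  dt
}

#' Hourly app count
#'
#' Number of distinct foreground apps whose usage segments intersect each
#' clock hour `[h:00, h+1:00)`. A segment spanning an hour boundary counts in
#' every hour it touches. Hours with no segments do not appear (downstream
#' they are an observed 0 only if the hour shows other activity).
#'
#' @param segments output of [segment_apps()].
#' @return data.table `person_id`, `date`, `hour`, `app_count`.
#' @export
hourly_app_count <- function(segments) {
  seg <- as.data.table(segments)
  if (nrow(seg) == 0L) {
    return(data.table(person_id = character(), date = as.Date(character()),
                      hour = integer(), app_count = integer()))
  }
  clipped <- .clip_to_hours(seg[, .(person_id, app_id, start, end)])
  out <- clipped[, .(app_count = uniqueN(app_id)), by = .(person_id, habs)]
  .hour_key(out)[, .(person_id, date, hour, app_count)][order(person_id, date, hour)]
}

#' Hourly normalized app entropy
#'
#' Builds the within-hour allocation of app time (segment durations clipped
#' to the hour, shared across the apps active in that hour) and applies
#' [app_entropy()]. Hours where a single app was active get entropy 0; hours
#' with no app segments are absent (entropy missing, not zero).
#'
#' @param segments output of [segment_apps()].
#' @return data.table `person_id`, `date`, `hour`, `app_entropy`, `N_apps`.
#' @export
hourly_app_entropy <- function(segments) {
  seg <- as.data.table(segments)
  if (nrow(seg) == 0L) {
    return(data.table(person_id = character(), date = as.Date(character()),
                      hour = integer(), app_entropy = numeric(),
                      N_apps = integer()))
  }
  clipped <- .clip_to_hours(seg[, .(person_id, app_id, start, end)])
  alloc <- clipped[, .(app_time = sum(overlap_s)),
                   by = .(person_id, habs, app_id)]
  alloc[, tot := sum(app_time), by = .(person_id, habs)]
  alloc[, p_share := app_time / tot]
  out <- alloc[, .(
    app_entropy = {
      if (.N == 1L) 0
      else min(max(-sum(p_share * log(p_share)) / log(.N), 0), 1)
    },
    N_apps = .N
  ), by = .(person_id, habs)]
  .hour_key(out)[, .(person_id, date, hour, app_entropy, N_apps)][
    order(person_id, date, hour)]
}

#' Hourly median session duration
#'
#' Median duration (minutes) of the sessions *starting* in each clock hour.
#' A session spanning several hours is attributed to its start hour only.
#' Hours with no session starts are absent (missing downstream).
#'
#' @param sessions output of [sessionize()].
#' @return data.table `person_id`, `date`, `hour`, `session_duration_min`.
#' @export
hourly_session_median <- function(sessions) {
  ses <- as.data.table(sessions)
  if (nrow(ses) == 0L) {
    return(data.table(person_id = character(), date = as.Date(character()),
                      hour = integer(), session_duration_min = numeric()))
  }
  ses <- copy(ses)
  ses[, habs := as.integer(floor(start / 3600000))]
  out <- ses[, .(session_duration_min = median(duration_min)),
             by = .(person_id, habs)]
  .hour_key(out)[, .(person_id, date, hour, session_duration_min)][
    order(person_id, date, hour)]
}

#' Per-keystroke typing intervals
#'
#' For every keystroke followed by another interaction event (keystroke,
#' click, scroll, view change or app change) *within the same session*, the
#' interval is the time from the keystroke to that next event, in seconds,
#' capped at 5 (values above 5 are set to 5, not dropped; extreme gaps
#' reflect distraction or sensor glitches rather than typing speed). A
#' keystroke that is the last interaction event of its session contributes no
#' interval.
#'
#' @param events `sensor_events` table.
#' @param sessions output of [sessionize()] on the same stream.
#' @param cap_s cap in seconds (default 5).
#' @return data.table `person_id`, `date`, `hour` (of the keystroke),
#'   `interval_s`.
#' @export
typing_intervals <- function(events, sessions, cap_s = 5) {
  ev <- as.data.table(events)[kind %chin% INTERACTION_KINDS,
                              .(person_id, t_local, kind)]
  ses <- as.data.table(sessions)
  empty <- data.table(person_id = character(), date = as.Date(character()),
                      hour = integer(), interval_s = numeric())
  if (nrow(ev) == 0L || nrow(ses) == 0L) return(empty)
  sesj <- ses[, .(person_id, session_id, s_start = start, s_end = end)]
  ev <- sesj[ev, on = .(person_id, s_start <= t_local, s_end > t_local)]
  setnames(ev, "s_start", "t_ev")
  ev[, s_end := NULL]
  ev <- ev[!is.na(session_id)]
  if (nrow(ev) == 0L) return(empty)
  setorder(ev, person_id, t_ev)
  ev[, nxt_t := shift(t_ev, -1), by = person_id]
  ev[, nxt_sid := shift(session_id, -1), by = person_id]
  keys <- ev[kind == "keystroke" & !is.na(nxt_t) & nxt_sid == session_id]
  if (nrow(keys) == 0L) return(empty)
  keys[, interval_s := pmin(pmax((nxt_t - t_ev) / 1000, 0), cap_s)]
  keys[, habs := as.integer(floor(t_ev / 3600000))]
  .hour_key(keys)[, .(person_id, date, hour, interval_s)][
    order(person_id, date, hour)]
}

#' Hourly median typing interval
#'
#' @param intervals output of [typing_intervals()].
#' @return data.table `person_id`, `date`, `hour`, `typing_interval_s`
#'   (median of the hour's capped intervals).
#' @export
hourly_typing_median <- function(intervals) {
  iv <- as.data.table(intervals)
  if (nrow(iv) == 0L) {
    return(data.table(person_id = character(), date = as.Date(character()),
                      hour = integer(), typing_interval_s = numeric()))
  }
  iv[, .(typing_interval_s = median(interval_s)),
     by = .(person_id, date, hour)][order(person_id, date, hour)]
}

#' Daily nighttime smartphone use
#'
#' Total active screen time intersected with the presumed sleep window
#' midnight to 6 AM local time, per day, in minutes. A session spanning
#' midnight contributes its post-midnight portion to the new date. Days in
#' the observation range with no overlap are a true 0 (no use during the
#' night), not missing: the sensing stream records only active use, so
#' silence at night is evidence of no use.
#'
#' @param sessions output of [sessionize()].
#' @param date_range optional list mapping person_id to a `Date` vector
#'   `c(first, last)`; defaults to each person's observed session span.
#' @return data.table `person_id`, `date`, `nighttime_min` (in \[0, 360\]).
#' @export
daily_nighttime_use <- function(sessions, date_range = NULL) {
  ses <- as.data.table(sessions)
  if (nrow(ses) == 0L) {
    return(data.table(person_id = character(), date = as.Date(character()),
                      nighttime_min = numeric()))
  }
  ses <- copy(ses)
  ses[, row_id := .I]
  ses[, d0 := as.integer(floor(start / 86400000))]
  ses[, d1 := as.integer(floor(end / 86400000))]
  days <- ses[, .(day = seq.int(d0, d1)), by = row_id][ses, on = "row_id"]
  days[, overlap_s := pmin(end, day * 86400000 + 21600000) -
         pmax(start, day * 86400000)]
  night <- days[overlap_s > 0,
                .(nighttime_min = sum(overlap_s) / 60000),
                by = .(person_id, day)]
  # zero-fill the full per-person day grid
  if (is.null(date_range)) {
    grid <- ses[, .(day = seq.int(min(d0), max(d1))), by = person_id]
  } else {
    grid <- rbindlist(lapply(names(date_range), function(p) {
      r <- as.integer(as.Date(date_range[[p]]))
      data.table(person_id = p, day = seq.int(r[1], r[2]))
    }))
  }
  out <- night[grid, on = c("person_id", "day")]
  out[is.na(nighttime_min), nighttime_min := 0]
  out[, nighttime_min := pmin(nighttime_min, 360)]
  out[, date := as.Date(day, origin = "1970-01-01")]
  out[, .(person_id, date, nighttime_min)][order(person_id, date)]
}

#' All behavioral features from an event stream
#'
#' Runs sessionization, app segmentation and the five measures, assembling
#' the four hourly measures into one table (outer join over active hours) and
#' the daily nighttime measure into another. An hour appears if any measure
#' observed activity there; within such an hour, `app_count` is 0 when no app
#' segment touched it, while `app_entropy` stays missing (entropy of nothing
#' is undefined). Hours with no interaction at all are absent — non-observed,
#' not zero.
#'
#' @param events `sensor_events` table.
#' @param date_range see [daily_nighttime_use()].
#' @return list with elements `hourly` (columns `person_id`, `date`, `hour`,
#'   `app_count`, `app_entropy`, `session_duration_min`, `typing_interval_s`),
#'   `nighttime` (`person_id`, `date`, `nighttime_min`), `sessions`,
#'   `segments`, and `qc` (combined counters).
#' @export
compute_features <- function(events, date_range = NULL) {
  sessions <- sessionize(events)
  segments <- segment_apps(events, sessions)
  ac <- hourly_app_count(segments)
  en <- hourly_app_entropy(segments)[, .(person_id, date, hour, app_entropy)]
  sm <- hourly_session_median(sessions)
  tm <- hourly_typing_median(typing_intervals(events, sessions))
  key <- c("person_id", "date", "hour")
  hourly <- Reduce(function(a, b) merge(a, b, by = key, all = TRUE),
                   list(ac, en, sm, tm))
  if (nrow(hourly)) hourly[is.na(app_count), app_count := 0L]
  nighttime <- daily_nighttime_use(sessions, date_range)
  list(hourly = hourly[order(person_id, date, hour)],
       nighttime = nighttime,
       sessions = sessions, segments = segments,
       qc = c(qc_counters(events), qc_counters(sessions),
              qc_counters(segments)))
}

#' Write / read hourly and daily feature tables
#'
#' Headered CSV with `NA` as the explicit missing-value token and the fixed
#' measure column names `app_count`, `app_entropy`, `session_duration_min`,
#' `typing_interval_s` (hourly) and `nighttime_min` (daily).
#'
#' @param features table as produced by [compute_features()].
#' @param path CSV path.
#' @return `path` invisibly (writers); data.table (readers).
#' @export
write_feature_table <- function(features, path) {
  fwrite(as.data.table(features), path, na = "NA")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- fread(path, na.strings = "NA")
  if ("date" %in% names(out)) out[, date := as.Date(date)]
  out[]
}
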