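#' Construct a canonical sensed-event table
#'
#' Validates and normalises a raw table of passively sensed smartphone
#' interaction events into the canonical in-memory representation used by the
#' rest of the pipeline. Timestamps are stored both as epoch milliseconds and
#' as a continuous local-clock axis (seconds since 1970-01-01 00:00 *local*
#' time), because all downstream features — clock-hour bins, the midnight to
#' 6 AM night window — are local-time concepts.
#'
#' @param x data.frame with columns `person_id`, `timestamp_ms` (epoch
#'   milliseconds), `kind` (one of `screen_on`, `screen_off`,
#'   `app_foreground`, `keystroke`, `click`, `scroll`, `view_change`),
#'   `app_id` (required iff `kind == "app_foreground"`), and optionally `tz`
#'   (IANA zone name per row; default `"UTC"`).
#' @param dedup drop exact duplicate rows (with a warning giving the count).
#' @return A `sensor_events` data.table sorted by (`person_id`, `t_local`)
#'   with derived columns `t_local` (local-clock *milliseconds*, kept integral
#'   so time differences are exact), `date` (local calendar date) and `hour`
#'   (local clock hour 0-23). Attribute `qc` holds the named counter
#'   `duplicates`.
#' @export
as_sensor_events <- function(x, dedup = TRUE) {
  req <- c("person_id", "timestamp_ms", "kind")
  miss <- setdiff(req, names(x))
  if (length(miss)) {
    stop("missing required event columns: ", paste(miss, collapse = ", "))
  }
  ev <- as.data.table(x)
  if (!"tz" %in% names(ev)) ev[, tz := "UTC"]
  if (!"app_id" %in% names(ev)) ev[, app_id := NA_character_]
  ev <- ev[, .(person_id = as.character(person_id),
               timestamp_ms = as.numeric(timestamp_ms),
               tz = as.character(tz),
               kind = as.character(kind),
               app_id = as.character(app_id))]

  bad_ts <- which(!is.finite(ev$timestamp_ms))
  if (length(bad_ts)) {
    stop("unparseable timestamp in row(s) ", paste(head(bad_ts, 5), collapse = ", "))
  }
  bad_kind <- which(!ev$kind %in% EVENT_KINDS)
  if (length(bad_kind)) {
    stop("unknown event kind '", ev$kind[bad_kind[1]], "' in row ", bad_kind[1],
         " (allowed: ", paste(EVENT_KINDS, collapse = ", "), ")")
  }
  bad_app <- which(ev$kind == "app_foreground" &
                     (is.na(ev$app_id) | ev$app_id == ""))
  if (length(bad_app)) {
    stop("app_foreground event without app_id in row ", bad_app[1])
  }

  n_dup <- 0L
  if (dedup) {
    before <- nrow(ev)
    ev <- unique(ev, by = c("person_id", "timestamp_ms", "kind", "app_id"))
    n_dup <- before - nrow(ev)
    if (n_dup > 0L) {
      warning(n_dup, " exact duplicate event row(s) dropped")
    }
  }

  ev[, t_local := local_millis(timestamp_ms, tz)]
  ev[, date := as.Date(floor(t_local / 86400000), origin = "1970-01-01")]
  ev[, hour := as.integer(floor((t_local %% 86400000) / 3600000))]
  setorder(ev, person_id, t_local, kind)
  setattr(ev, "qc", c(duplicates = n_dup))
  setattr(ev, "class", c("sensor_events", class(ev)))
  ev[]
}

# epoch ms + IANA zone -> continuous local-clock milliseconds. Integral ms
# stay exactly representable as doubles, so durations and intervals are exact.
# Vectorised per unique zone; the local axis is what hour-of-day and calendar
# date are computed from, so DST shifts appear as jumps on this axis.
local_millis <- function(timestamp_ms, tz) {
  sec_utc <- floor(timestamp_ms / 1000)
  frac_ms <- timestamp_ms - sec_utc * 1000
  out <- numeric(length(sec_utc))
  for (zone in unique(tz)) {
    idx <- which(tz == zone)
    if (!identical(zone, "UTC")) {
      tt <- as.POSIXct(sec_utc[idx], origin = "1970-01-01", tz = "UTC")
      lt <- as.POSIXlt(tt, tz = zone)
      base <- as.numeric(as.Date(format(lt, "%Y-%m-%d"))) * 86400 +
        lt$hour * 3600 + lt$min * 60 + lt$sec
    } else {
      base <- sec_utc[idx]
    }
    out[idx] <- base * 1000 + frac_ms[idx]
  }
  out
}

#' Read a canonical event log
#'
#' Reads a headered CSV with columns `person_id`, `timestamp_ms`, `tz`,
#' `kind`, `app_id` (the canonical on-disk format) and returns validated
#' [as_sensor_events()] output. Exact duplicate rows are dropped with a
#' warning; an unparseable timestamp or unknown event kind is a hard error
#' naming the offending row.
#'
#' @param path file path.
#' @return `sensor_events` data.table.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("event file not found: ", path)
  raw <- fread(path, colClasses = list(character = "app_id"), na.strings = "NA")
  if ("timestamp_ms" %in% names(raw) && is.character(raw$timestamp_ms)) {
    conv <- suppressWarnings(as.numeric(raw$timestamp_ms))
    bad <- which(is.na(conv) & !is.na(raw$timestamp_ms))
    if (length(bad)) {
      stop("unparseable timestamp '", raw$timestamp_ms[bad[1]], "' in row ", bad[1])
    }
    raw[, timestamp_ms := conv]
  }
  as_sensor_events(raw)
}

#' Write a canonical event log
#'
#' @param events `sensor_events` table (or anything [as_sensor_events()]
#'   accepts).
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  ev <- as.data.table(events)[, .(person_id, timestamp_ms, tz, kind, app_id)]
  fwrite(ev, path, na = "NA")
  invisible(path)
}

#' Reconstruct screen sessions from an event stream
#'
#' A session is the interval from a `screen_on` event to the next
#' `screen_off` event of the same person. A `screen_on` while a session is
#' already open is ignored (the original start is kept); a `screen_off` with
#' no open session is ignored; a session still open at end of stream is
#' dropped; sessions longer than 24 hours are dropped as sensor artifacts.
#' All drops are tallied in the `qc` attribute (named counters
#' `duplicate_on`, `orphan_off`, `dropped_open`, `dropped_over_24h`,
#' `dropped_nonpositive`).
#'
#' @param events `sensor_events` table.
#' @return data.table with columns `person_id`, `session_id`, `start`, `end`
#'   (local-clock milliseconds), `duration_min`, sorted and non-overlapping
#'   within person; attribute `qc` carries the counters.
#' @export
sessionize <- function(events) {
  ev <- as.data.table(events)
  sc <- ev[kind %chin% c("screen_on", "screen_off"),
           .(person_id, t_local, kind)]
  setorder(sc, person_id, t_local, -kind)  # screen_on sorts before screen_off on ties
  qc <- c(duplicate_on = 0L, orphan_off = 0L, dropped_open = 0L,
          dropped_over_24h = 0L, dropped_nonpositive = 0L)
  if (nrow(sc) == 0L) {
    out <- data.table(person_id = character(), session_id = integer(),
                      start = numeric(), end = numeric(),
                      duration_min = numeric())
    setattr(out, "qc", qc)
    return(out)
  }
  sc[, on := kind == "screen_on"]
  # keep only state transitions: first 'on' of a run opens, first 'off' closes
  sc[, keep := on != shift(on, fill = FALSE), by = person_id]
  qc["duplicate_on"] <- sc[on == TRUE & keep == FALSE, .N]
  qc["orphan_off"] <- sc[on == FALSE & keep == FALSE, .N]
  kept <- sc[keep == TRUE]
  kept[, pair_id := ceiling(seq_len(.N) / 2), by = person_id]
  ons  <- kept[on == TRUE,  .(person_id, pair_id, start = t_local)]
  offs <- kept[on == FALSE, .(person_id, pair_id, end = t_local)]
  ses <- offs[ons, on = c("person_id", "pair_id")]
  qc["dropped_open"] <- ses[is.na(end), .N]
  ses <- ses[!is.na(end)]
  qc["dropped_nonpositive"] <- ses[end <= start, .N]
  ses <- ses[end > start]
  qc["dropped_over_24h"] <- ses[end - start > 86400000, .N]
  ses <- ses[end - start <= 86400000]
  setorder(ses, person_id, start)
  ses[, session_id := seq_len(.N), by = person_id]
  ses[, duration_min := (end - start) / 60000]
  out <- ses[, .(person_id, session_id, start, end, duration_min)]
  setattr(out, "qc", qc)
  out[]
}

#' Slice sessions into per-app foreground usage segments
#'
#' Within each session, consecutive `app_foreground` events delimit segments:
#' each segment runs from its `app_foreground` event to the next
#' `app_foreground` event in the same session, or to session end. Time before
#' the first `app_foreground` event of a session is unattributed (no
#' segment). `app_foreground` events outside any session are ignored and
#' counted in the `qc` attribute (`fg_outside_session`).
#'
#' @param events `sensor_events` table.
#' @param sessions output of [sessionize()] on the same stream.
#' @return data.table `person_id`, `session_id`, `app_id`, `start`, `end`
#'   (local-clock milliseconds); attribute `qc`.
#' @export
segment_apps <- function(events, sessions) {
  ev <- as.data.table(events)
  ses <- as.data.table(sessions)
  fg <- ev[kind == "app_foreground", .(person_id, t_local, app_id)]
  qc <- c(fg_outside_session = 0L)
  empty <- data.table(person_id = character(), session_id = integer(),
                      app_id = character(), start = numeric(), end = numeric())
  if (nrow(fg) == 0L || nrow(ses) == 0L) {
    qc["fg_outside_session"] <- nrow(fg)
    setattr(empty, "qc", qc)
    return(empty)
  }
  sesj <- ses[, .(person_id, session_id, s_start = start, s_end = end)]
  fg <- sesj[fg, on = .(person_id, s_start <= t_local, s_end > t_local)]
  # non-equi join overwrites the join columns; s_start now holds t_local
  setnames(fg, c("s_start", "s_end"), c("t_fg", "t_fg2"))
  fg[, t_fg2 := NULL]
  qc["fg_outside_session"] <- fg[is.na(session_id), .N]
  fg <- fg[!is.na(session_id)]
  if (nrow(fg) == 0L) {
    setattr(empty, "qc", qc)
    return(empty)
  }
  setorder(fg, person_id, session_id, t_fg)
  fg <- ses[, .(person_id, session_id, s_end = end)][fg,
            on = c("person_id", "session_id")]
  fg[, seg_start := t_fg]
  fg[, seg_end := shift(t_fg, -1, fill = NA), by = .(person_id, session_id)]
  fg[is.na(seg_end), seg_end := s_end]
  out <- fg[seg_end > seg_start,
            .(person_id, session_id, app_id, start = seg_start, end = seg_end)]
  setattr(out, "qc", qc)
  out[]
}

#' QC counters attached to a pipeline table
#'
#' @param x object returned by [as_sensor_events()], [sessionize()] or
#'   [segment_apps()].
#' @return named integer vector of counters.
#' @export
qc_counters <- function(x) attr(x, "qc", exact = TRUE)
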