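#' Configuration for the raw event-stream generator
#'
#' Emulates the microstructure of passively sensed smartphone interaction:
#' per day a Poisson number of screen sessions (a separate, smaller rate for
#' the midnight-6 AM window), lognormal session durations, a Dirichlet
#' allocation of each session's time across a random subset of the app
#' catalog, keystroke bursts with lognormal inter-key gaps, and sprinkled
#' click/scroll/view-change events. Defaults approximate the usage regime of
#' the motivating study's summary table: a handful of apps per active hour,
#' session medians of a few minutes, a few minutes of nighttime use per day,
#' and sub-second typing intervals.
#'
#' @param n_persons,n_days panel dimensions.
#' @param start_date first calendar day (Date).
#' @param K app catalog size.
#' @param alpha Dirichlet concentration for within-session app time shares.
#' @param apps_per_session_rate Poisson rate; apps used in a session is
#'   `1 + Poisson(rate)`, capped at `K`.
#' @param lambda_day,lambda_night expected sessions per day starting in the
#'   6 AM-midnight and midnight-6 AM windows.
#' @param session_lnorm_mu,session_lnorm_sigma lognormal parameters of
#'   session duration in log-minutes.
#' @param burst_prob probability a session contains a keystroke burst.
#' @param burst_len_rate Poisson rate; keystrokes per burst is `1 + Poisson`.
#' @param interkey_lnorm_mu,interkey_lnorm_sigma lognormal parameters of the
#'   inter-key gap in log-seconds.
#' @param extra_events_rate Poisson rate of additional click/scroll/
#'   view-change events per session.
#' @param link symptom-linkage coefficients used by
#'   [generate_linked_scenario()]: named vector with elements `app_count`
#'   (log-multiplier of `apps_per_session_rate` per unit latent state),
#'   `typing` (additive shift of `interkey_lnorm_mu`), `session_duration`
#'   (additive shift of `session_lnorm_mu`), `nighttime` (log-multiplier of
#'   `lambda_night`).
#' @param state_sd_between,state_sd_within SDs of the latent symptom state's
#'   person-level and window-level parts.
#' @param trait_sd named vector of SDs of stable person-level usage traits:
#'   `app_count` (log-multiplier of `apps_per_session_rate`), `typing`
#'   (additive shift of `interkey_lnorm_mu`), `session_duration` (additive
#'   shift of `session_lnorm_mu`), `nighttime` (log-multiplier of
#'   `lambda_night`). These create the between-person differences that real
#'   usage data show (and that the between-person model terms estimate).
#' @param seed optional integer seed.
#' @return object of class `event_sim_config`.
#' @export
event_sim_config <- function(n_persons = 10, n_days = 10,
                             start_date = as.Date("2021-03-01"),
                             K = 30, alpha = 1, apps_per_session_rate = 2.5,
                             lambda_day = 12, lambda_night = 0.8,
                             session_lnorm_mu = log(2.5),
                             session_lnorm_sigma = 1,
                             burst_prob = 0.5, burst_len_rate = 4,
                             interkey_lnorm_mu = log(0.45),
                             interkey_lnorm_sigma = 0.7,
                             extra_events_rate = 2,
                             link = c(app_count = 0, typing = 0,
                                      session_duration = 0, nighttime = 0),
                             state_sd_between = 0.8, state_sd_within = 0.6,
                             trait_sd = c(app_count = 0.25, typing = 0.15,
                                          session_duration = 0.4,
                                          nighttime = 0.6),
                             seed = NULL) {
  stopifnot(n_persons >= 1, n_days >= 1, K >= 1, alpha > 0,
            lambda_day >= 0, lambda_night >= 0, burst_prob >= 0,
            burst_prob <= 1, apps_per_session_rate >= 0,
            extra_events_rate >= 0)
  structure(list(n_persons = as.integer(n_persons),
                 n_days = as.integer(n_days),
                 start_date = as.Date(start_date), K = as.integer(K),
                 alpha = alpha, apps_per_session_rate = apps_per_session_rate,
                 lambda_day = lambda_day, lambda_night = lambda_night,
                 session_lnorm_mu = session_lnorm_mu,
                 session_lnorm_sigma = session_lnorm_sigma,
                 burst_prob = burst_prob, burst_len_rate = burst_len_rate,
                 interkey_lnorm_mu = interkey_lnorm_mu,
                 interkey_lnorm_sigma = interkey_lnorm_sigma,
                 extra_events_rate = extra_events_rate, link = link,
                 state_sd_between = state_sd_between,
                 state_sd_within = state_sd_within,
                 trait_sd = trait_sd, seed = seed),
            class = "event_sim_config")
}

# seconds -> integral local-clock milliseconds (the authoritative time unit)
.to_ms <- function(x) round(x * 1000)

# stable person-level usage traits (draws one shift per person)
.person_traits <- function(pid, cfg) {
  ts <- cfg$trait_sd
  data.table(person_id = pid,
             trait_app = rnorm(length(pid), 0, ts[["app_count"]]),
             trait_typing = rnorm(length(pid), 0, ts[["typing"]]),
             trait_session = rnorm(length(pid), 0, ts[["session_duration"]]),
             trait_night = rnorm(length(pid), 0, ts[["nighttime"]]))
}

# apply person traits to a per-(person, day) rate table
.apply_traits <- function(rates, traits) {
  r <- traits[rates, on = "person_id"]
  r[, `:=`(lambda_night = lambda_night * exp(trait_night),
           apps_rate = apps_rate * exp(trait_app),
           interkey_mu = interkey_mu + trait_typing,
           session_lnorm_mu = session_lnorm_mu + trait_session)]
  r[, c("trait_app", "trait_typing", "trait_session", "trait_night") := NULL]
  r[]
}

# core generator: one row of `rates` per (person, day) with possibly
# day-varying rates; returns the event table plus the generating session,
# app-segment and interaction-event structure. All times are integral local
# milliseconds and authoritative for the ground truth.
.generate_events_core <- function(rates, cfg) {
  r <- as.data.table(rates)
  # --- sessions ------------------------------------------------------------
  r[, `:=`(nd = rpois(.N, lambda_day), nn = rpois(.N, lambda_night))]
  mk <- function(counts, lo, hi) {
    idx <- rep(seq_len(nrow(r)), counts)
    s <- r[idx]
    s[, start := .to_ms(day * 86400 + lo + runif(.N) * (hi - lo))]
    s
  }
  ses <- rbind(mk(r$nd, 21600, 86400), mk(r$nn, 0, 21600))
  if (nrow(ses) == 0L) {
    return(list(events = as_sensor_events(
      data.table(person_id = character(), timestamp_ms = numeric(),
                 tz = character(), kind = character(),
                 app_id = character())),
      sessions = data.table(), segments = data.table(),
      interactions = data.table()))
  }
  ses[, dur_ms := .to_ms(pmin(rlnorm(.N, session_lnorm_mu,
                                     session_lnorm_sigma), 300) * 60)]
  setorder(ses, person_id, start)
  ses[, end := start + dur_ms]
  ses[, end := pmin(end, shift(start, -1, fill = Inf) - 1000),
      by = person_id]
  ses <- ses[end - start >= 500]
  ses[, dur_ms := end - start]
  ses[, sid := .I]

  # --- app foreground boundaries ------------------------------------------
  ses[, n_apps := pmin(cfg$K, 1L + rpois(.N, apps_rate))]
  app_idx <- unlist(lapply(ses$n_apps, function(k) sample.int(cfg$K, k)))
  fg <- ses[rep(sid, n_apps),
            .(person_id, sid, start, end, dur_ms)]
  fg[, app_id := sprintf("app%03d", app_idx)]
  fg[, share := rgamma(.N, cfg$alpha, 1)]
  fg[, share := share / sum(share), by = sid]
  fg[, t_fg := start + round((cumsum(share) - share) * dur_ms), by = sid]
  fg[, ok := t_fg > shift(t_fg, fill = -Inf) & t_fg < end - 1, by = sid]
  fg <- fg[ok == TRUE]
  fg[, seg_end := shift(t_fg, -1, fill = NA_real_), by = sid]
  fg[is.na(seg_end), seg_end := end]
  segments <- fg[, .(person_id, sid, app_id, start = t_fg, end = seg_end)]

  # --- keystroke bursts ----------------------------------------------------
  ses[, burst := runif(.N) < cfg$burst_prob & dur_ms > 2000]
  bs <- ses[burst == TRUE]
  keys <- data.table(person_id = character(), sid = integer(), t = numeric())
  if (nrow(bs)) {
    bs[, t0 := start + runif(.N) * pmax(dur_ms - 6000, 500)]
    bs[, nk := 1L + rpois(.N, cfg$burst_len_rate)]
    kk <- bs[rep(seq_len(.N), nk),
             .(person_id, sid, t0, end, interkey_mu)]
    kk[, gap := rlnorm(.N, interkey_mu, cfg$interkey_lnorm_sigma) * 1000]
    kk[, t := round(t0 + cumsum(gap) - gap), by = sid]
    kk <- kk[t < end - 10]
    keys <- kk[, .(person_id, sid, t)]
    # terminate most bursts with a click so the final keystroke has a next event
    term <- kk[, .(t_last = max(t), end = end[1L],
                   interkey_mu = interkey_mu[1L]), by = .(person_id, sid)]
    term[, t := round(t_last + rlnorm(.N, interkey_mu,
                                      cfg$interkey_lnorm_sigma) * 1000)]
    term <- term[t < end - 1]
  } else {
    term <- data.table(person_id = character(), sid = integer(),
                       t = numeric())
  }

  # --- extra interaction events -------------------------------------------
  ses[, nx := rpois(.N, cfg$extra_events_rate)]
  ex <- ses[rep(sid, nx), .(person_id, sid, start, end)]
  if (nrow(ex)) {
    ex[, t := round(start + 10 + runif(.N) * (end - start - 20))]
    ex[, kind := sample(c("click", "scroll", "view_change"), .N,
                        replace = TRUE)]
    ex <- ex[t > start & t < end]
  }

  # --- assemble ------------------------------------------------------------
  evt <- rbind(
    ses[, .(person_id, t = start, kind = "screen_on", app_id = NA_character_)],
    ses[, .(person_id, t = end, kind = "screen_off", app_id = NA_character_)],
    segments[, .(person_id, t = start, kind = "app_foreground", app_id)],
    keys[, .(person_id, t, kind = "keystroke", app_id = NA_character_)],
    if (nrow(term)) term[, .(person_id, t, kind = "click",
                             app_id = NA_character_)],
    if (nrow(ex)) ex[, .(person_id, t, kind, app_id = NA_character_)])
  evt[, timestamp_ms := t]
  evt <- unique(evt, by = c("person_id", "timestamp_ms", "kind", "app_id"))
  evt[, tz := "UTC"]
  events <- as_sensor_events(evt[, .(person_id, timestamp_ms, tz, kind,
                                     app_id)])

  inter <- evt[kind %chin% INTERACTION_KINDS, .(person_id, t, kind)]
  list(events = events,
       sessions = ses[, .(person_id, sid, start, end,
                          duration_min = dur_ms / 60000)],
       segments = segments, interactions = inter)
}

# independent ground-truth accumulation: plain loops over the generating
# structure, using the same clock-hour clipping / start-hour attribution /
# 5 s cap / night-window conventions as the definitions, but none of the
# pipeline code.
.accumulate_truth <- function(sessions, segments, interactions) {
  hour_rows <- list()
  night_rows <- list()
  for (p in sort(unique(sessions$person_id))) {
    ses <- sessions[sessions$person_id == p, ]
    seg <- segments[segments$person_id == p, ]
    ints <- interactions[interactions$person_id == p, ]
    ints <- ints[order(ints$t), ]

    app_time <- list()   # key "habs" -> named numeric vector of app ms
    for (i in seq_len(nrow(seg))) {
      a <- seg$start[i]; b <- seg$end[i]; app <- seg$app_id[i]
      for (h in seq.int(floor(a / 3600000), floor((b - 1e-6) / 3600000))) {
        ov <- min(b, (h + 1) * 3600000) - max(a, h * 3600000)
        if (ov <= 0) next
        kh <- as.character(h)
        cur <- app_time[[kh]]
        if (is.null(cur)) cur <- numeric(0)
        prev <- if (app %in% names(cur)) cur[[app]] else 0
        cur[app] <- prev + ov
        app_time[[kh]] <- cur
      }
    }

    ses_dur <- list()    # key habs of start hour -> durations (min)
    night <- list()      # key day -> ms
    for (i in seq_len(nrow(ses))) {
      a <- ses$start[i]; b <- ses$end[i]
      kh <- as.character(floor(a / 3600000))
      ses_dur[[kh]] <- c(ses_dur[[kh]], (b - a) / 60000)
      for (d in seq.int(floor(a / 86400000), floor(b / 86400000))) {
        ov <- min(b, d * 86400000 + 21600000) - max(a, d * 86400000)
        if (ov > 0) {
          kd <- as.character(d)
          night[[kd]] <- (if (is.null(night[[kd]])) 0 else night[[kd]]) + ov
        }
      }
    }

    typing <- list()     # key habs of keystroke hour -> capped intervals (s)
    sid_of <- function(tt) {
      j <- which(ses$start <= tt & ses$end > tt)
      if (length(j)) j[1] else NA_integer_
    }
    if (nrow(ints) > 1L) {
      for (i in seq_len(nrow(ints) - 1L)) {
        if (ints$kind[i] != "keystroke") next
        s1 <- sid_of(ints$t[i]); s2 <- sid_of(ints$t[i + 1L])
        if (is.na(s1) || is.na(s2) || s1 != s2) next
        iv <- min(max((ints$t[i + 1L] - ints$t[i]) / 1000, 0), 5)
        kh <- as.character(floor(ints$t[i] / 3600000))
        typing[[kh]] <- c(typing[[kh]], iv)
      }
    }

    hours <- sort(unique(as.integer(c(names(app_time), names(ses_dur),
                                      names(typing)))))
    for (h in hours) {
      kh <- as.character(h)
      at <- app_time[[kh]]
      ent <- NA_real_
      nap <- 0L
      if (!is.null(at) && length(at)) {
        nap <- length(at)
        pr <- at / sum(at)
        ent <- if (nap == 1L) 0 else
          min(max(-sum(pr * log(pr)) / log(nap), 0), 1)
      }
      hour_rows[[length(hour_rows) + 1L]] <- data.table(
        person_id = p,
        date = as.Date(h %/% 24, origin = "1970-01-01"),
        hour = as.integer(h %% 24),
        app_count = nap,
        app_entropy = ent,
        session_duration_min = if (is.null(ses_dur[[kh]])) NA_real_ else
          median(ses_dur[[kh]]),
        typing_interval_s = if (is.null(typing[[kh]])) NA_real_ else
          median(typing[[kh]]))
    }

    d0 <- floor(min(ses$start) / 86400000)
    d1 <- floor(max(ses$end) / 86400000)
    for (d in seq.int(d0, d1)) {
      kd <- as.character(d)
      night_rows[[length(night_rows) + 1L]] <- data.table(
        person_id = p, date = as.Date(d, origin = "1970-01-01"),
        nighttime_min = min((if (is.null(night[[kd]])) 0
                             else night[[kd]]) / 60000, 360))
    }
  }
  list(hourly = rbindlist(hour_rows)[order(person_id, date, hour)],
       nighttime = rbindlist(night_rows)[order(person_id, date)])
}

#' Generate raw event streams with known ground-truth features
#'
#' Produces a well-formed event stream (paired screen on/off, non-overlapping
#' sessions, every `app_foreground` inside a session) together with the exact
#' hourly and daily feature values implied by the generated structure. The
#' ground truth is computed by an independent plain-loop accumulation inside
#' the generator — not by calling the pipeline — so round-trip tests compare
#' two independent code paths.
#'
#' @param config an [event_sim_config()].
#' @param compute_truth also compute the ground-truth feature tables
#'   (default `TRUE`; skip for speed when only the stream is needed).
#' @return list: `events` (`sensor_events`), `truth_hourly`,
#'   `truth_nighttime` (or `NULL`), `sessions`, `segments`, `config`.
#' @export
generate_event_streams <- function(config, compute_truth = TRUE) {
  stopifnot(inherits(config, "event_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  day0 <- as.integer(config$start_date)
  pid <- sprintf("p%03d", seq_len(config$n_persons))
  rates <- CJ(person_id = pid,
              day = seq.int(day0, day0 + config$n_days - 1L))
  rates[, `:=`(lambda_day = config$lambda_day,
               lambda_night = config$lambda_night,
               apps_rate = config$apps_per_session_rate,
               interkey_mu = config$interkey_lnorm_mu,
               session_lnorm_mu = config$session_lnorm_mu,
               session_lnorm_sigma = config$session_lnorm_sigma)]
  rates <- .apply_traits(rates, .person_traits(pid, config))
  core <- .generate_events_core(rates, config)
  truth <- if (compute_truth && nrow(core$sessions)) {
    .accumulate_truth(core$sessions, core$segments, core$interactions)
  } else NULL
  list(events = core$events,
       truth_hourly = truth$hourly, truth_nighttime = truth$nighttime,
       sessions = core$sessions, segments = core$segments, config = config)
}

#' Generate a full linked study bundle (events + surveys)
#'
#' A latent symptom state per (person, 14-day window) — a person-level part
#' plus a window-level part — drives both the two survey items and the
#' behavior rates through the `link` coefficients of the config: e.g. a
#' negative `link["app_count"]` makes high-symptom windows use fewer distinct
#' apps, and a positive `link["typing"]` slows typing. Surveys fall on the
#' day after each window, so the recall window `[symptom_date - 14,
#' symptom_date)` matches the generating window exactly.
#'
#' @param config an [event_sim_config()]; `n_days` is ignored in favor of
#'   `windows_per_person * 14`.
#' @param windows_per_person surveys (and 14-day windows) per person.
#' @param outcome_intercept,outcome_loading,outcome_noise_sd latent-state to
#'   survey-item mapping: item = round(intercept + loading * state + noise),
#'   clipped to 0-4.
#' @return list: `events`, `surveys` (person_id, symptom_date,
#'   loss_of_interest, depressed_mood), `states` (latent states per window),
#'   `config`.
#' @export
generate_linked_scenario <- function(config, windows_per_person = 4,
                                     outcome_intercept = 2,
                                     outcome_loading = 1,
                                     outcome_noise_sd = 0.5) {
  stopifnot(inherits(config, "event_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  wdays <- 14L
  n <- config$n_persons
  W <- as.integer(windows_per_person)
  day0 <- as.integer(config$start_date)
  pid <- sprintf("p%03d", seq_len(n))

  states <- CJ(person_id = pid, window = seq_len(W))
  b <- rnorm(n, 0, config$state_sd_between)
  states[, state := b[match(person_id, pid)] +
           rnorm(.N, 0, config$state_sd_within)]

  lk <- config$link
  rates <- states[rep(seq_len(.N), each = wdays)]
  rates[, day := day0 + (window - 1L) * wdays + seq_len(wdays) - 1L,
        by = .(person_id, window)]
  rates[, `:=`(
    lambda_day = config$lambda_day,
    lambda_night = config$lambda_night * exp(lk["nighttime"] * state),
    apps_rate = pmax(config$apps_per_session_rate *
                       exp(lk["app_count"] * state), 0.05),
    interkey_mu = config$interkey_lnorm_mu + lk["typing"] * state,
    session_lnorm_mu = config$session_lnorm_mu +
      lk["session_duration"] * state,
    session_lnorm_sigma = config$session_lnorm_sigma)]
  rates <- .apply_traits(rates, .person_traits(pid, config))
  core <- .generate_events_core(rates, config)

  item <- function(s) {
    pmin(pmax(round(outcome_intercept + outcome_loading * s +
                      rnorm(length(s), 0, outcome_noise_sd)), 0), 4)
  }
  surveys <- states[, .(person_id, window,
                        symptom_date = as.Date(day0 + window * wdays,
                                               origin = "1970-01-01"),
                        loss_of_interest = item(state),
                        depressed_mood = item(state))]
  list(events = core$events,
       surveys = surveys[, .(person_id, symptom_date, loss_of_interest,
                             depressed_mood)],
       states = states, config = config)
}
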