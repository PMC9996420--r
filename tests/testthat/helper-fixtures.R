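# fixture builders shared across test files; everything is generated in code

DAY0 <- as.numeric(as.Date("2021-03-01")) * 86400  # local seconds at midnight

# milliseconds at hh:mm:ss.mmm on day `d` (0-based) after DAY0
ms_at <- function(h, m = 0, s = 0, d = 0) {
  (DAY0 + d * 86400 + h * 3600 + m * 60 + s) * 1000
}

# quick event table: df-like list of (kind, t_ms, app, person)
make_events <- function(kind, t_ms, app = NA_character_,
                        person = "p1", dedup = TRUE) {
  as_sensor_events(data.frame(person_id = person, timestamp_ms = t_ms,
                              tz = "UTC", kind = kind,
                              app_id = app, stringsAsFactors = FALSE),
                   dedup = dedup)
}

# hourly feature stub: one row per (person, date, hour) with a constant
# app_count so the row counts as an active hour
hourly_stub <- function(person, date, hours, app_count = 2L,
                        app_entropy = NA_real_,
                        session_duration_min = NA_real_,
                        typing_interval_s = NA_real_) {
  data.table::data.table(person_id = person, date = as.Date(date),
                         hour = as.integer(hours), app_count = app_count,
                         app_entropy = app_entropy,
                         session_duration_min = session_duration_min,
                         typing_interval_s = typing_interval_s)
}

empty_hourly <- function() hourly_stub("p1", as.Date("2021-03-01"), integer(0))

empty_nighttime <- function() {
  data.table::data.table(person_id = character(),
                         date = as.Date(character()),
                         nighttime_min = numeric())
}

survey_row <- function(person, date, loss = 2L, mood = 2L) {
  data.frame(person_id = person, symptom_date = as.Date(date),
             loss_of_interest = loss, depressed_mood = mood)
}

# dense restricted log-likelihood oracle for the random-intercept model,
# built directly from the marginal covariance (independent of the C++ path)
reml_deviance_oracle <- function(s2u0, s2e, y, X, person) {
  n <- length(y)
  Z <- outer(person, unique(person), "==") * 1
  V <- s2e * diag(n) + s2u0 * (Z %*% t(Z))
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(determinant(V)$modulus + determinant(XtViX)$modulus +
               t(r) %*% Vi %*% r + (n - ncol(X)) * log(2 * pi))
}
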