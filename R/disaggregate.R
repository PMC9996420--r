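#' Within/between-person disaggregation of time-varying predictors
#'
#' Longitudinal processes are rarely ergodic: how a person differs from
#' others (between-person) and how a person differs from their own average
#' over time (within-person) are distinct sources of association, and a
#' pooled coefficient conflates them. Each predictor `X` is therefore split
#' as
#' \deqn{X_{it} = \bar{X}_{..} + bp_i + wp_{it}}
#' where `bp_i` is person `i`'s mean of `X` minus the grand mean of the
#' person means, and `wp_it` is the deviation of `X_it` from person `i`'s
#' mean. Person means are computed over that person's observed (QC-passing)
#' windows; a missing `X_it` yields a missing `wp_it` while `bp_i` uses the
#' observed values. Grand-mean centering of `bp` (the default) only shifts
#' the model intercept, which then estimates the outcome of a prototypical
#' person; set `center_bp = FALSE` to keep raw person means.
#'
#' @param data data.frame with one row per (person, occasion).
#' @param vars character vector of predictor column names to split.
#' @param person_col name of the person identifier column.
#' @param center_bp center person means at the grand mean (default `TRUE`).
#' @return data.table with the original columns plus `wp_<var>` and
#'   `bp_<var>` for each predictor; attribute `grand_means` holds the
#'   (unweighted) grand mean of person means per predictor.
#' @export
split_within_between <- function(data, vars, person_col = "person_id",
                                 center_bp = TRUE) {
  dt <- as.data.table(data)
  stopifnot(person_col %in% names(dt), all(vars %in% names(dt)))
  gm <- numeric(0)
  for (v in vars) {
    pm <- dt[, .(person_mean = mean(.SD[[1]], na.rm = TRUE)),
             by = c(person_col), .SDcols = v]
    pm[is.nan(person_mean), person_mean := NA_real_]
    g <- mean(pm$person_mean, na.rm = TRUE)
    gm[v] <- g
    dt <- pm[dt, on = person_col]
    dt[, (paste0("wp_", v)) := .SD[[1]] - person_mean, .SDcols = v]
    dt[, (paste0("bp_", v)) := person_mean - (if (center_bp) g else 0)]
    dt[, person_mean := NULL]
  }
  setattr(dt, "grand_means", gm)
  setattr(dt, "center_bp", center_bp)
  dt[]
}

#' Raw / within / between correlations with the outcomes
#'
#' For each predictor and outcome, the Pearson correlation of the outcome
#' with (a) the raw predictor, (b) its within-person portion and (c) its
#' between-person portion, each across all observations (pairwise complete).
#' The three correlations generally differ — the motivation for
#' disaggregating in the first place. Zero-variance columns give `NA`.
#'
#' @param design output of [split_within_between()].
#' @param vars predictor names passed to [split_within_between()].
#' @param outcomes outcome column names.
#' @return data.table `predictor`, `outcome`, `raw`, `within`, `between`.
#' @export
correlation_table <- function(design, vars,
                              outcomes = c("loss_of_interest",
                                           "depressed_mood")) {
  dt <- as.data.table(design)
  if (nrow(dt) < 3L) stop("need at least 3 observations")
  safe_cor <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
    cor(x[ok], y[ok])
  }
  rbindlist(lapply(vars, function(v) {
    rbindlist(lapply(outcomes, function(o) {
      data.table(predictor = v, outcome = o,
                 raw = safe_cor(dt[[v]], dt[[o]]),
                 within = safe_cor(dt[[paste0("wp_", v)]], dt[[o]]),
                 between = safe_cor(dt[[paste0("bp_", v)]], dt[[o]]))
    }))
  }))
}
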