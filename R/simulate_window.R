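#' Generating parameter set for the two-level model
#'
#' Bundles every fixed effect and variance component used by the window-level
#' generator, so simulation studies can compare estimates against the exact
#' generating values. Defaults are the plug-in values of the motivating
#' analysis: intercept 2.24, within-person app-count effect -0.14,
#' within-person typing-interval effect 0.88, between-person session-duration
#' effect -0.37, all other coefficients 0; intercept variance 0.86, app-count
#' slope variance 0.06, other slope variances 0.01, residual variance 0.54.
#'
#' @param gamma00 intercept.
#' @param gamma_wp,gamma_bp named length-5 vectors of within- and
#'   between-person coefficients, in the order app_count, app_entropy,
#'   nighttime, session_duration, typing_interval.
#' @param sigma2_u named length-6 vector: random-intercept variance followed
#'   by the five random-slope variances.
#' @param sigma2_e residual variance.
#' @return object of class `sim_truth`.
#' @export
sim_truth <- function(gamma00 = 2.24,
                      gamma_wp = c(app_count = -0.14, app_entropy = 0,
                                   nighttime = 0, session_duration = 0,
                                   typing_interval = 0.88),
                      gamma_bp = c(app_count = 0, app_entropy = 0,
                                   nighttime = 0, session_duration = -0.37,
                                   typing_interval = 0),
                      sigma2_u = c(intercept = 0.86, app_count = 0.06,
                                   app_entropy = 0.01, nighttime = 0.01,
                                   session_duration = 0.01,
                                   typing_interval = 0.01),
                      sigma2_e = 0.54) {
  stopifnot(length(gamma_wp) == 5L, length(gamma_bp) == 5L,
            length(sigma2_u) == 6L, all(sigma2_u >= 0), sigma2_e >= 0)
  structure(list(gamma00 = gamma00, gamma_wp = gamma_wp, gamma_bp = gamma_bp,
                 sigma2_u = sigma2_u, sigma2_e = sigma2_e),
            class = "sim_truth")
}

#' Configuration for the window-level generator
#'
#' Predictors are generated on a standardized scale by default (between-person
#' means 0 with SD `tau`, within-person deviations with SD `omega`, both 1):
#' this generator exists to exercise the estimator, and unit scales keep every
#' coefficient comparably well identified. Set `mu`/`tau`/`omega` per
#' predictor to emulate other regimes.
#'
#' @param n_persons,windows_per_person panel dimensions.
#' @param mu,tau,omega scalars or named length-5 vectors (same predictor
#'   order as [sim_truth()]): between-person predictor mean and SD, and
#'   within-person SD.
#' @param truth a [sim_truth()].
#' @param likert_discretize round and clip the outcome to the 0-4 item scale
#'   (off by default: discretization attenuates variance-component recovery).
#' @param seed optional integer seed.
#' @return object of class `window_sim_config`.
#' @export
window_sim_config <- function(n_persons = 150, windows_per_person = 7,
                              mu = 0, tau = 1, omega = 1,
                              truth = sim_truth(),
                              likert_discretize = FALSE, seed = NULL) {
  expand <- function(x) {
    if (length(x) == 1L) x <- rep(x, 5L)
    stopifnot(length(x) == 5L)
    setNames(as.numeric(x), MEASURES)
  }
  stopifnot(n_persons >= 1, windows_per_person >= 1,
            inherits(truth, "sim_truth"))
  cfg <- list(n_persons = as.integer(n_persons),
              windows_per_person = as.integer(windows_per_person),
              mu = expand(mu), tau = expand(tau), omega = expand(omega),
              truth = truth, likert_discretize = isTRUE(likert_discretize),
              seed = seed)
  stopifnot(all(cfg$tau >= 0), all(cfg$omega >= 0))
  structure(cfg, class = "window_sim_config")
}

#' Generate window-level data directly from the two-level model
#'
#' Draws person-level predictor means `bp_i ~ N(mu, tau^2)`, occasion
#' deviations `wp_it ~ N(0, omega^2)`, independent random effects
#' `u_ki ~ N(0, sigma2_u[k])`, and builds the outcome from the linear
#' predictor plus `N(0, sigma2_e)` noise. The between-person predictors enter
#' the outcome centered at their generating means, matching a model fitted
#' with grand-mean-centered `bp` columns, so the generating intercept is
#' recovered directly. The returned table carries ready-to-fit `wp_` and
#' `bp_` columns plus the raw (`raw_`) values.
#'
#' @param config a [window_sim_config()].
#' @return list: `data` (data.table, one row per person-window), `truth`
#'   (the generating [sim_truth()]), `config`.
#' @export
generate_window_level <- function(config) {
  stopifnot(inherits(config, "window_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  tr <- config$truth
  n <- config$n_persons
  w <- config$windows_per_person
  N <- n * w
  pid <- rep(sprintf("p%03d", seq_len(n)), each = w)
  out <- data.table(person_id = pid, window = rep(seq_len(w), n))
  gid <- rep(seq_len(n), each = w)

  u <- matrix(rnorm(n * 6L), n, 6L) * rep(sqrt(tr$sigma2_u), each = n)
  eta <- tr$gamma00 + u[gid, 1L]
  for (k in seq_along(MEASURES)) {
    ms <- MEASURES[k]
    bp_dev <- rnorm(n, 0, config$tau[ms])   # person deviation from mu
    wp <- rnorm(N, 0, config$omega[ms])
    out[, (paste0("wp_", ms)) := wp]
    out[, (paste0("bp_", ms)) := bp_dev[gid]]
    out[, (paste0("raw_", ms)) := config$mu[ms] + bp_dev[gid] + wp]
    eta <- eta + (tr$gamma_wp[k] + u[gid, k + 1L]) * wp +
      tr$gamma_bp[k] * bp_dev[gid]
  }
  y <- eta + rnorm(N, 0, sqrt(tr$sigma2_e))
  if (config$likert_discretize) y <- pmin(pmax(round(y), 0), 4)
  out[, outcome := y]
  list(data = out[], truth = tr, config = config)
}
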