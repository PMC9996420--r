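#' Specify a two-level model with independent random slopes
#'
#' The outcome is regressed on the within-person (`wp_`) and between-person
#' (`bp_`) portions of each predictor, with a random intercept and a random
#' slope for each within-person predictor. The random effects are assumed
#' mutually independent (diagonal covariance): only their variances are
#' estimated, keeping the model parsimonious while still allowing
#' person-specific within-person associations.
#'
#' @param outcome outcome column name.
#' @param predictors base predictor names; the design must contain
#'   `wp_<name>` and `bp_<name>` columns (see [split_within_between()]).
#' @param random_slopes subset of `predictors` whose `wp_` portion gets a
#'   random slope (default: all of them).
#' @param method `"REML"` (default) or `"ML"`.
#' @return object of class `mlm_spec`.
#' @export
mlm_spec <- function(outcome, predictors = MEASURES,
                     random_slopes = predictors, method = c("REML", "ML")) {
  method <- match.arg(method)
  stopifnot(all(random_slopes %in% predictors))
  structure(list(outcome = outcome, predictors = predictors,
                 random_slopes = random_slopes, method = method),
            class = "mlm_spec")
}

# core optimizer over log-variances, shared with the bootstrap.
# starts: list of variance vectors (length q+1) on the natural scale.
.fit_theta <- function(y, X, W, grp, reml, starts,
                       lower = log(1e-10), upper = log(1e6)) {
  obj <- function(lt) {
    lmm_deviance_cpp(exp(lt), y, X, W, grp, reml, FALSE)$deviance
  }
  best <- NULL
  for (th0 in starts) {
    lt0 <- pmin(pmax(log(th0), lower + 1), upper - 1)
    op <- tryCatch(
      nlminb(lt0, obj, lower = lower, upper = upper,
             control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL)
    if (is.null(op)) next
    if (is.null(best) || op$objective < best$objective) best <- op
  }
  if (is.null(best)) stop("variance optimization failed from every start")
  # a variance pinned at the zero boundary makes nlminb report singular/false
  # convergence; with the boundary active that is the expected optimum shape
  boundary <- any(best$par <= lower + 2) || any(best$par >= upper - 2)
  best$converged <- best$convergence == 0 ||
    (boundary && grepl("singular convergence|false convergence", best$message))
  best
}

# method-of-moments style starting values for the variances
.mom_start <- function(y, X, W, grp) {
  q <- ncol(W) - 1L
  ols <- stats::lm.fit(X, y)
  r <- ols$residuals
  m <- length(grp) - 1L
  gsizes <- diff(grp)
  gid <- rep.int(seq_len(m), gsizes)
  pm <- tapply(r, gid, mean)
  s2_tot <- max(var(r), 1e-4)
  wv <- tapply(r, gid, var)
  s2e0 <- max(mean(wv, na.rm = TRUE), 0.1 * s2_tot, 1e-4)
  if (!is.finite(s2e0)) s2e0 <- s2_tot
  s2u0 <- max(var(pm) - s2e0 / mean(gsizes), 0.05 * s2_tot, 1e-4)
  th <- c(s2u0, rep(NA_real_, q), s2e0)
  if (q > 0) {
    for (k in seq_len(q)) {
      vw <- var(W[, k + 1L])
      th[k + 1L] <- 0.1 * s2e0 / max(vw, 1e-8)
    }
  }
  th
}

#' Fit the two-level model by restricted maximum likelihood
#'
#' Maximizes the restricted (or full, `method = "ML"`) likelihood of
#' \deqn{y_i = X_i \gamma + W_i u_i + e_i,\quad
#'   u_i \sim N(0, \mathrm{diag}(\sigma^2_{u0},\ldots)),\quad
#'   e_i \sim N(0, \sigma^2_e I)}
#' over the log-variances with `nlminb`, from several scaled
#' method-of-moments starts (ties broken by the best restricted likelihood);
#' variances may hit the zero boundary. Rows with any missing predictor or
#' outcome are listwise-deleted (missing-at-random handling). Fixed effects
#' are the GLS solution at the estimated variances; their covariance is
#' `(X' V^{-1} X)^{-1}`.
#'
#' @param design data.frame with the outcome, `wp_`/`bp_` predictor columns
#'   and a person identifier.
#' @param spec an [mlm_spec()].
#' @param person_col person identifier column.
#' @param starts number of optimizer starts (scaled 0.1x, 1x, 10x of the
#'   method-of-moments values; default 3).
#' @return object of class `mlm_fit`: `fixed` (term/estimate/se/statistic/
#'   p_value), `varcomp` (component/variance), `sigma2_e`, `logLik`
#'   (restricted when REML), `converged`, `n_obs`, `n_persons`, `n_dropped`,
#'   plus the internal design (for the parametric bootstrap).
#' @export
fit_lmm <- function(design, spec, person_col = "person_id", starts = 3) {
  stopifnot(inherits(spec, "mlm_spec"))
  dt <- as.data.table(design)
  wp_cols <- paste0("wp_", spec$predictors)
  bp_cols <- paste0("bp_", spec$predictors)
  slope_cols <- if (length(spec$random_slopes)) {
    paste0("wp_", spec$random_slopes)
  } else character(0)
  need <- c(spec$outcome, wp_cols, bp_cols, person_col)
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("design lacks column(s): ", paste(miss, collapse = ", "))
  for (cc in setdiff(need, person_col)) {
    if (all(is.na(dt[[cc]]))) stop("column '", cc, "' is entirely missing")
  }
  keep <- complete.cases(dt[, ..need])
  n_dropped <- sum(!keep)
  dd <- dt[keep]
  if (nrow(dd) == 0L) stop("no complete rows after listwise deletion")
  person <- factor(dd[[person_col]])
  if (nlevels(person) < 2L) {
    stop("random effects unidentifiable: need at least 2 persons")
  }
  o <- order(person)
  dd <- dd[o]
  person <- person[o]
  grp <- c(0L, cumsum(tabulate(person)))

  y <- as.numeric(dd[[spec$outcome]])
  X <- cbind("(Intercept)" = 1,
             as.matrix(dd[, c(wp_cols, bp_cols), with = FALSE]))
  W <- if (length(slope_cols)) {
    cbind("(Intercept)" = 1, as.matrix(dd[, slope_cols, with = FALSE]))
  } else {
    matrix(1, nrow(dd), 1, dimnames = list(NULL, "(Intercept)"))
  }
  reml <- spec$method == "REML"

  th0 <- .mom_start(y, X, W, grp)
  scales <- c(1, 0.1, 10)[seq_len(max(1L, min(starts, 3L)))]
  op <- .fit_theta(y, X, W, grp, reml, lapply(scales, function(s) th0 * s))
  theta <- exp(op$par)
  det <- lmm_deviance_cpp(theta, y, X, W, grp, reml, TRUE)
  converged <- isTRUE(det$ok) && isTRUE(op$converged)
  if (!converged) warning("mixed-model fit did not converge cleanly")

  beta <- drop(det$beta)
  se <- sqrt(diag(det$vcov_beta))
  names(beta) <- colnames(X)
  fixed <- data.table(term = colnames(X), estimate = beta, se = se,
                      statistic = beta / se,
                      p_value = 2 * pnorm(-abs(beta / se)))
  q <- ncol(W)
  varcomp <- data.table(
    component = c("(Intercept)", slope_cols, "residual"),
    variance = c(theta[seq_len(q)], theta[q + 1L]))

  structure(list(spec = spec, fixed = fixed, varcomp = varcomp,
                 sigma2_e = theta[q + 1L], theta = theta,
                 logLik = -0.5 * det$deviance, converged = converged,
                 n_obs = length(y), n_persons = nlevels(person),
                 n_dropped = n_dropped,
                 design = list(y = y, X = X, W = W, grp = grp,
                               person = person)),
            class = "mlm_fit")
}

#' @export
print.mlm_fit <- function(x, ...) {
  cat("Two-level linear mixed model (", x$spec$method,
      ", diagonal random effects)\n", sep = "")
  cat("outcome:", x$spec$outcome, "  n_obs:", x$n_obs,
      "  persons:", x$n_persons,
      if (x$n_dropped) paste0("  (", x$n_dropped, " rows listwise-deleted)"),
      "\n")
  if (!x$converged) cat("** fit did not converge cleanly **\n")
  cat(sprintf("log-%slikelihood: %.3f\n",
              if (x$spec$method == "REML") "restricted-" else "", x$logLik))
  cat("\nFixed effects:\n")
  print(as.data.frame(x$fixed), digits = 3, row.names = FALSE)
  cat("\nVariance components:\n")
  print(as.data.frame(x$varcomp), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Wald inference for fixed effects
#'
#' Statistic = estimate / SE, with two-sided p-values and confidence limits
#' from the standard normal reference. The normal reference (rather than a
#' degrees-of-freedom-adjusted t) is a documented approximation; it is
#' accurate at this design's cluster counts (about 150 persons).
#'
#' @param fit an [fit_lmm()] result.
#' @param level confidence level (default 0.95).
#' @return data.table `term`, `estimate`, `se`, `statistic`, `p_value`,
#'   `ci_lower`, `ci_upper`.
#' @export
wald_inference <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "mlm_fit"))
  z <- qnorm(1 - (1 - level) / 2)
  out <- copy(fit$fixed)
  out[, `:=`(ci_lower = estimate - z * se, ci_upper = estimate + z * se)]
  out[]
}

#' Parametric-bootstrap confidence intervals for variance components
#'
#' Simulates `B` datasets from the fitted model (same design matrices; new
#' random effects and residuals drawn from the estimated variances), refits
#' each, and takes percentile intervals of the variance estimates. Estimates
#' at the zero boundary pile up at 0, so lower limits of near-zero components
#' are 0 — the expected boundary behavior for variance parameters.
#'
#' @param fit converged [fit_lmm()] result.
#' @param B replicates (at least 50; default 500).
#' @param seed optional integer seed for reproducibility.
#' @param level confidence level (default 0.95).
#' @return data.table `component`, `estimate`, `ci_lower`, `ci_upper`;
#'   attribute `B`.
#' @export
bootstrap_varcomp_ci <- function(fit, B = 500, seed = NULL, level = 0.95) {
  stopifnot(inherits(fit, "mlm_fit"))
  if (B < 50) stop("B must be at least 50: smaller bootstraps give unstable CIs")
  if (!is.null(seed)) set.seed(seed)
  d <- fit$design
  q <- ncol(d$W)
  m <- length(d$grp) - 1L
  gid <- rep.int(seq_len(m), diff(d$grp))
  mu <- drop(d$X %*% fit$fixed$estimate)
  sd_u <- sqrt(fit$theta[seq_len(q)])
  sd_e <- sqrt(fit$sigma2_e)
  reml <- fit$spec$method == "REML"
  draws <- matrix(NA_real_, nrow = B, ncol = q + 1L)
  for (b in seq_len(B)) {
    u <- matrix(rnorm(m * q), m, q) * rep(sd_u, each = m)
    ystar <- mu + rowSums(d$W * u[gid, , drop = FALSE]) +
      rnorm(length(mu), 0, sd_e)
    op <- tryCatch(
      .fit_theta(ystar, d$X, d$W, d$grp, reml,
                 list(pmax(fit$theta, 1e-6))),
      error = function(e) NULL)
    if (!is.null(op)) draws[b, ] <- exp(op$par)
  }
  a <- (1 - level) / 2
  ql <- apply(draws, 2, quantile, probs = a, na.rm = TRUE)
  qu <- apply(draws, 2, quantile, probs = 1 - a, na.rm = TRUE)
  out <- data.table(component = fit$varcomp$component,
                    estimate = fit$varcomp$variance,
                    ci_lower = pmax(ql, 0), ci_upper = qu)
  setattr(out, "B", B)
  out[]
}

#' Side-by-side report tables for the two outcome models
#'
#' Fixed-effect table ordered intercept, then the five within-person terms,
#' then the five between-person terms; variance-component table ordered
#' intercept variance, slope variances, residual variance. Estimates are
#' formatted to two decimals and p-values in journal style (`<.001` floor).
#' An unconverged fit is flagged in a footnote rather than suppressed.
#'
#' @param fit_loss,fit_mood [fit_lmm()] results for the two outcomes.
#' @return list of class `mlm_report` with `fixed`, `random` (character
#'   tables) and `footnotes`.
#' @export
report_tables <- function(fit_loss, fit_mood) {
  stopifnot(inherits(fit_loss, "mlm_fit"), inherits(fit_mood, "mlm_fit"))
  fmt <- function(x) sprintf("%.2f", x)
  fmt_p <- function(p) ifelse(p < 0.001, "<.001", sub("^0\\.", ".", sprintf("%.3f", p)))
  fixed <- data.table(
    parameter = fit_loss$fixed$term,
    est_model1 = fmt(fit_loss$fixed$estimate),
    se_model1 = fmt(fit_loss$fixed$se),
    p_model1 = fmt_p(fit_loss$fixed$p_value),
    est_model2 = fmt(fit_mood$fixed$estimate),
    se_model2 = fmt(fit_mood$fixed$se),
    p_model2 = fmt_p(fit_mood$fixed$p_value))
  random <- data.table(
    component = c(paste0("var(", fit_loss$varcomp$component[-nrow(fit_loss$varcomp)], ")"),
                  "var(residual)"),
    est_model1 = fmt(fit_loss$varcomp$variance),
    est_model2 = fmt(fit_mood$varcomp$variance))
  notes <- character(0)
  if (!fit_loss$converged) notes <- c(notes, "model 1 did not converge cleanly")
  if (!fit_mood$converged) notes <- c(notes, "model 2 did not converge cleanly")
  structure(list(fixed = fixed, random = random, footnotes = notes),
            class = "mlm_report")
}

#' @export
print.mlm_report <- function(x, ...) {
  cat("Fixed effects (model 1 / model 2):\n")
  print(as.data.frame(x$fixed), row.names = FALSE)
  cat("\nVariance components:\n")
  print(as.data.frame(x$random), row.names = FALSE)
  for (nn in x$footnotes) cat("note:", nn, "\n")
  invisible(x)
}
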