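test_that("REML deviance agrees with a dense-matrix restricted likelihood", {
  set.seed(19)
  person <- rep(sprintf("p%02d", 1:10), each = 4)
  x <- rnorm(40)
  b0 <- rnorm(10, 0, 0.7)
  y <- 1 + 0.5 * x + b0[as.integer(factor(person))] + rnorm(40, 0, 0.6)
  X <- cbind(1, x)
  W <- matrix(1, 40, 1)
  grp <- c(0L, cumsum(tabulate(factor(person))))
  for (th in list(c(0.5, 0.4), c(0.1, 1), c(2, 0.2))) {
    dev_cpp <- passivesense:::lmm_deviance_cpp(th, y, X, W, grp, TRUE,
                                               FALSE)$deviance
    dev_oracle <- reml_deviance_oracle(th[1], th[2], y, X, person)
    expect_equal(dev_cpp, dev_oracle, tolerance = 1e-8)
  }
})

test_that("with zero variance components the fit reduces to OLS", {
  set.seed(23)
  truth0 <- sim_truth(gamma00 = 1.5,
                      gamma_wp = c(app_count = -0.2, app_entropy = 0.4,
                                   nighttime = 0, session_duration = 0.1,
                                   typing_interval = -0.3),
                      gamma_bp = c(app_count = 0.3, app_entropy = 0,
                                   nighttime = -0.1, session_duration = 0,
                                   typing_interval = 0.2),
                      sigma2_u = rep(0, 6), sigma2_e = 0)
  for (i in 1:5) {
    cfg <- window_sim_config(n_persons = sample(8:15, 1),
                             windows_per_person = sample(3:6, 1),
                             truth = truth0, seed = 1000 + i)
    g <- generate_window_level(cfg)
    fit <- fit_lmm(g$data, mlm_spec("outcome"))
    X <- cbind(1, as.matrix(g$data[, c(paste0("wp_", passivesense:::MEASURES),
                                       paste0("bp_", passivesense:::MEASURES)),
                                   with = FALSE]))
    beta_ols <- solve(crossprod(X), crossprod(X, g$data$outcome))
    expect_lt(max(abs(fit$fixed$estimate - drop(beta_ols))), 1e-3)
  }
})

test_that("the optimum dominates a brute-force variance grid", {
  set.seed(71)
  d <- data.frame(person_id = rep(sprintf("p%02d", 1:10), each = 4),
                  x = rnorm(40))
  b0 <- rnorm(10, 0, 0.8)
  d$y <- 2 + 0.6 * d$x + b0[as.integer(factor(d$person_id))] +
    rnorm(40, 0, 0.7)
  dsg <- split_within_between(d, "x")
  fit <- fit_lmm(dsg, mlm_spec("y", predictors = "x",
                               random_slopes = character(0)))
  X <- cbind(1, dsg$wp_x, dsg$bp_x)
  grid <- expand.grid(s2u0 = exp(seq(log(0.01), log(5), length.out = 21)),
                      s2e = exp(seq(log(0.01), log(5), length.out = 21)))
  dev_grid <- mapply(function(a, b) {
    reml_deviance_oracle(a, b, dsg$y, X, dsg$person_id)
  }, grid$s2u0, grid$s2e)
  expect_gte(fit$logLik, max(-0.5 * dev_grid) - 1e-6)
})

test_that("estimates are invariant to row order and flag bad input", {
  set.seed(8)
  g <- generate_window_level(window_sim_config(n_persons = 25,
                                               windows_per_person = 5,
                                               seed = 88))
  fit <- fit_lmm(g$data, mlm_spec("outcome"))
  perm <- g$data[sample(nrow(g$data)), ]
  fit2 <- fit_lmm(perm, mlm_spec("outcome"))
  expect_lt(max(abs(fit$fixed$estimate - fit2$fixed$estimate)), 1e-6)
  expect_lt(max(abs(fit$varcomp$variance - fit2$varcomp$variance)), 1e-6)

  one <- g$data[g$data$person_id == "p001", ]
  expect_error(fit_lmm(one, mlm_spec("outcome")), "unidentifiable")

  bad <- data.table::copy(g$data)
  bad$wp_nighttime <- NA_real_
  expect_error(fit_lmm(bad, mlm_spec("outcome")), "wp_nighttime")
})

test_that("fit matches lme4 on the same diagonal random-slope model", {
  skip_if_not_installed("lme4")
  g <- generate_window_level(window_sim_config(n_persons = 40,
                                               windows_per_person = 5,
                                               seed = 4242))
  fit <- fit_lmm(g$data, mlm_spec("outcome"))
  fml <- outcome ~ wp_app_count + wp_app_entropy + wp_nighttime +
    wp_session_duration + wp_typing_interval + bp_app_count +
    bp_app_entropy + bp_nighttime + bp_session_duration +
    bp_typing_interval + (1 | person_id) +
    (0 + wp_app_count | person_id) + (0 + wp_app_entropy | person_id) +
    (0 + wp_nighttime | person_id) + (0 + wp_session_duration | person_id) +
    (0 + wp_typing_interval | person_id)
  lf <- suppressMessages(lme4::lmer(fml, data = as.data.frame(g$data),
                                    REML = TRUE))
  expect_lt(max(abs(lme4::fixef(lf) - fit$fixed$estimate)), 1e-4)
  vc <- as.data.frame(lme4::VarCorr(lf))$vcov
  expect_lt(max(abs(sort(vc) - sort(fit$varcomp$variance))), 1e-3)
  expect_equal(fit$logLik, as.numeric(stats::logLik(lf)), tolerance = 1e-6)
})

test_that("Wald inference is the normal-reference estimate/SE test", {
  g <- generate_window_level(window_sim_config(n_persons = 20,
                                               windows_per_person = 4,
                                               seed = 55))
  fit <- fit_lmm(g$data, mlm_spec("outcome"))
  tab <- wald_inference(fit)
  expect_equal(tab$statistic, tab$estimate / tab$se)
  expect_equal(tab$p_value, 2 * pnorm(-abs(tab$statistic)))
  expect_equal(tab$ci_upper - tab$estimate,
               qnorm(0.975) * tab$se, tolerance = 1e-12)
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
})

test_that("parametric bootstrap is seeded, bounded and boundary-aware", {
  tr <- sim_truth(gamma00 = 1, gamma_wp = c(0.5, 0, 0, 0, 0),
                  gamma_bp = rep(0, 5),
                  sigma2_u = c(0.5, 0, 0, 0, 0, 0), sigma2_e = 0.4)
  g <- generate_window_level(window_sim_config(n_persons = 30,
                                               windows_per_person = 4,
                                               truth = tr, seed = 77))
  sp <- mlm_spec("outcome", predictors = "app_count")
  fit <- fit_lmm(g$data, sp)
  expect_error(bootstrap_varcomp_ci(fit, B = 20), "at least 50")
  ci1 <- bootstrap_varcomp_ci(fit, B = 60, seed = 5)
  ci2 <- bootstrap_varcomp_ci(fit, B = 60, seed = 5)
  expect_equal(ci1, ci2)
  expect_true(all(ci1$ci_lower <= ci1$ci_upper))
  expect_true(all(ci1$ci_lower >= 0))
  # the true slope variance is 0: its bootstrap lower bound piles at 0
  slope_row <- ci1[ci1$component == "wp_app_count", ]
  expect_lt(slope_row$ci_lower, 1e-6)
})

test_that("bootstrap residual-variance CI attains roughly nominal coverage", {
  tr <- sim_truth(gamma00 = 1, gamma_wp = c(0.4, 0, 0, 0, 0),
                  gamma_bp = rep(0, 5),
                  sigma2_u = c(0.4, 0.05, 0, 0, 0, 0), sigma2_e = 0.54)
  sp <- mlm_spec("outcome", predictors = "app_count")
  set.seed(303)
  hits <- 0L
  n_sets <- 25L
  for (i in seq_len(n_sets)) {
    g <- generate_window_level(window_sim_config(n_persons = 30,
                                                 windows_per_person = 4,
                                                 truth = tr,
                                                 seed = 9000 + i))
    fit <- fit_lmm(g$data, sp, starts = 1)
    ci <- bootstrap_varcomp_ci(fit, B = 50, seed = i)
    rr <- ci[ci$component == "residual", ]
    if (rr$ci_lower <= 0.54 && 0.54 <= rr$ci_upper) hits <- hits + 1L
  }
  # nominal 95%; the acceptance band below is the 3-sigma binomial range
  expect_gte(hits, 20L)
})

test_that("report tables follow the two-model journal layout", {
  g <- generate_window_level(window_sim_config(n_persons = 25,
                                               windows_per_person = 5,
                                               seed = 13))
  fit1 <- fit_lmm(g$data, mlm_spec("outcome"))
  fit2 <- fit_lmm(g$data, mlm_spec("outcome"))
  rep_ok <- report_tables(fit1, fit2)
  expect_equal(nrow(rep_ok$fixed), 11L)  # intercept + 5 wp + 5 bp
  expect_equal(rep_ok$fixed$parameter[1], "(Intercept)")
  expect_true(all(grepl("^wp_", rep_ok$fixed$parameter[2:6])))
  expect_true(all(grepl("^bp_", rep_ok$fixed$parameter[7:11])))
  expect_equal(nrow(rep_ok$random), 7L)  # intercept + 5 slopes + residual
  expect_true(all(grepl("^-?[0-9]+\\.[0-9]{2}$", rep_ok$fixed$est_model1)))
  expect_length(rep_ok$footnotes, 0L)

  fit_bad <- fit1
  fit_bad$converged <- FALSE
  rep_bad <- report_tables(fit_bad, fit2)
  expect_match(rep_bad$footnotes, "model 1")
  expect_equal(nrow(rep_bad$fixed), 11L)
})
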