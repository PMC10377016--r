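test_that("Kaplan-Meier curves match hand-worked product-limit tables", {
  # no events: survival stays at 1
  none <- km_curve(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(none$surv == 1))

  # three subjects, all events: 2/3, 1/3, 0
  all_ev <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(all_ev$surv, c(2 / 3, 1 / 3, 0))

  # five subjects, mixed censoring, worked by hand:
  # t=1 (death, risk 5):       S = 4/5
  # t=2 (censored, no step)
  # t=3 (death, risk 3):       S = 4/5 * 2/3 = 8/15
  # t=4 (censored, no step)
  # t=5 (death, risk 1):       S = 0
  mixed <- km_curve(c(1, 2, 3, 4, 5), c(1, 0, 1, 0, 1))
  ev <- mixed[mixed$n_event > 0, ]
  expect_equal(ev$time, c(1, 3, 5))
  expect_equal(ev$surv, c(4 / 5, 8 / 15, 0), tolerance = 1e-12)
  expect_true(all(diff(mixed$surv) <= 0))

  # with no censoring the curve is 1 - ECDF
  set.seed(41)
  t0 <- rexp(40)
  km <- km_curve(t0, rep(1, 40))
  expect_equal(km$surv, 1 - ecdf(t0)(km$time), tolerance = 1e-12)

  expect_error(km_curve(numeric(0), numeric(0)), "at least one")
})

test_that("log-rank test matches the hand-computed hypergeometric form", {
  # identical groups: statistic 0, p = 1
  t0 <- c(1, 2, 3, 4); e0 <- c(1, 0, 1, 1)
  lr0 <- logrank_test(t0, e0, t0, e0)
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-12)

  # toy case worked by hand: A dies at t=1 (risk 1+1, E_A = 1/2,
  # Var = 1/4), B dies alone at t=2 (no variance contribution).
  # Chi-square = (1 - 1/2)^2 / (1/4) = 1, p = 0.3173
  lr <- logrank_test(1, 1, 2, 1)
  expect_equal(lr$statistic, 1, tolerance = 1e-12)
  expect_equal(lr$p, pchisq(1, 1, lower.tail = FALSE), tolerance = 1e-12)

  # zero events: undefined, reported missing
  expect_message(lrna <- logrank_test(c(1, 2), c(0, 0), c(3), c(0)),
                 "no events")
  expect_true(is.na(lrna$statistic) && is.na(lrna$p))
  expect_error(logrank_test(numeric(0), numeric(0), 1, 1), "non-empty")
})

test_that("quartile comparison selects the extreme quarters correctly", {
  set.seed(42)
  n <- 40
  expr <- setNames(rnorm(n), sprintf("pt%02d", 1:n))
  surv <- survival_table(names(expr), rexp(n, 0.3), rbinom(n, 1, 0.8))
  qk <- quartile_km_compare(expr, surv, horizon_years = 5)

  # membership equals a sort-based oracle
  qs <- quantile(expr, c(0.25, 0.75), names = FALSE)
  expect_equal(qk$n_low, sum(expr <= qs[1]))
  expect_equal(qk$n_high, sum(expr >= qs[2]))
  expect_true(qk$n_low + qk$n_high <= n)
  expect_true(all(qk$curves$low$surv >= 0))

  # degenerate expression has no quartile separation
  flat <- setNames(rep(1, n), names(expr))
  expect_error(quartile_km_compare(flat, surv), "no quartile separation")

  # horizon before the first event: no events, missing p
  late <- survival_table(names(expr), rep(10, n), rep(1, n))
  expect_message(qk0 <- quartile_km_compare(expr, late, horizon_years = 5),
                 "no events")
  expect_true(is.na(qk0$p))

  expect_error(quartile_km_compare(expr[1:5], surv), "at least 8")
})

test_that("quartile split separates simulated risk groups", {
  cfg <- synthetic_config(seed = 43, beta_true = 1.2)
  em <- simulate_expression_matrix(cfg, n_units = 3)
  sc <- suppressWarnings(simulate_survival_cohort(cfg, em, "unit_02"))
  qk <- quartile_km_compare(setNames(em["unit_02", ], colnames(em)),
                            sc$surv)
  expect_lt(qk$p, 1e-4)

  null_cfg <- synthetic_config(seed = 44, beta_true = 0)
  sc0 <- simulate_survival_cohort(null_cfg, em, "unit_02")
  qk0 <- quartile_km_compare(setNames(em["unit_02", ], colnames(em)),
                             sc0$surv)
  expect_gt(qk0$p, 0.001)
})

test_that("cox_fit recovers scale-invariant hazard ratios", {
  cfg <- synthetic_config(seed = 45)
  em <- simulate_expression_matrix(cfg, n_units = 2)
  sc <- simulate_survival_cohort(cfg, em, "unit_01")
  x <- setNames(em["unit_01", ], colnames(em))

  fit <- cox_fit(x, sc$surv, horizon_years = 5)
  expect_gt(fit$HR, 1)
  expect_true(fit$ci_lower < fit$HR & fit$HR < fit$ci_upper)
  expect_equal(fit$beta, cfg$beta_true, tolerance = 0.25)

  # standardized fits are invariant under linear rescaling ...
  fit_scaled <- cox_fit(10 * x + 3, sc$surv, horizon_years = 5)
  expect_equal(fit_scaled$beta, fit$beta, tolerance = 1e-8)
  # ... and raw-scale coefficients scale inversely
  raw <- cox_fit(x, sc$surv, standardize = FALSE, horizon_years = 5)
  raw10 <- cox_fit(10 * x, sc$surv, standardize = FALSE, horizon_years = 5)
  expect_equal(raw10$beta, raw$beta / 10, tolerance = 1e-6)

  expect_error(cox_fit(setNames(rep(1, nrow(sc$surv)), sc$surv$patient_id),
                       sc$surv), "does not vary")
  allcens <- survival_table(sc$surv$patient_id, sc$surv$time,
                            rep(0, nrow(sc$surv)))
  expect_error(cox_fit(x, allcens), "at least one event")
})

test_that("two-group exponential data recover the rate ratio", {
  set.seed(46)
  n <- 1500
  grp <- rep(c(0, 1), each = n / 2)
  rate <- ifelse(grp == 1, 0.6, 0.2)  # hazard ratio 3
  surv <- survival_table(sprintf("p%04d", 1:n), rexp(n, rate), rep(1, n))
  fit <- cox_fit(setNames(grp, surv$patient_id), surv, standardize = FALSE)
  expect_equal(fit$HR, 3, tolerance = 0.15)

  # log-rank p and Cox score test agree asymptotically on two-group data
  lr <- logrank_test(surv$time[grp == 0], surv$event[grp == 0],
                     surv$time[grp == 1], surv$event[grp == 1])
  sctest <- survival::coxph(
    survival::Surv(surv$time, surv$event) ~ grp)$score
  expect_equal(lr$statistic, sctest, tolerance = 0.02)
})

test_that("the hazard screen ranks the causal unit at the extreme", {
  cfg <- synthetic_config(seed = 47)
  em <- simulate_expression_matrix(cfg, n_units = 15)
  sc <- simulate_survival_cohort(cfg, em, "unit_07")
  scr <- survival_screen(em, sc$surv, horizon_years = 5)
  expect_equal(nrow(scr), 15L)
  expect_equal(scr$unit[1], "unit_07")  # top of the HR ordering
  expect_true(scr$significant[scr$unit == "unit_07"])
  expect_true(all(diff(scr$HR) <= 0))
  expect_equal(scr$q, p.adjust(scr$p, "BH"), tolerance = 1e-12)

  # empty unit list gives an empty screen
  empty <- survival_screen(em[0, , drop = FALSE], sc$surv)
  expect_equal(nrow(empty), 0L)

  # a broken unit is recorded and the screen continues
  em2 <- em; em2["unit_01", ] <- 1
  scr2 <- survival_screen(em2, sc$surv)
  expect_equal(nrow(scr2), 15L)
  expect_match(scr2$reason[scr2$unit == "unit_01"], "vary")
})

test_that("administrative censoring truncates follow-up at the horizon", {
  surv <- survival_table(c("a", "b", "c"), c(2, 6, 8), c(1, 1, 0))
  cens <- administrative_censor(surv, 5)
  expect_equal(cens$time, c(2, 5, 5))
  expect_equal(cens$event, c(1L, 0L, 0L))

  months <- survival_table(c("a", "b"), c(50, 70), c(1, 1),
                           time_unit = "months")
  cm <- administrative_censor(months, 5)  # horizon 60 months
  expect_equal(cm$time, c(50, 60))
  expect_equal(cm$event, c(1L, 0L))
})
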