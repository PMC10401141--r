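tto_fixture <- function(event_dt, start_dt) {
  n <- length(event_dt)
  demo <- tibble::tibble(primaryid = as.character(seq_len(n)), event_dt = event_dt)
  drugs <- tibble::tibble(
    primaryid = as.character(seq_len(n)), drug_seq = "1",
    drugname = "QUETIAPINE", prod_ai = "QUETIAPINE", role_cod = "PS",
    start_dt = start_dt, indi_pt = NA_character_
  )
  make_reports(demo, drugs = drugs)
}

test_that("TTO is whole-day date arithmetic with counted exclusions", {
  rep <- tto_fixture(
    event_dt = c("20200131", "20200101", "20200301", "202003", "20200105", ""),
    start_dt = c("20200101", "20200110", "202002", "20200301", "20200105", "20200101")
  )
  spec <- cohort_spec("QUETIAPINE")
  tto <- compute_tto(rep, spec)
  # report 1: 30 days; report 5: same-day onset adjusted to 0.5
  expect_equal(sort(tto$durations), c(0.5, 30))
  expect_equal(sort(tto$durations_raw), c(0, 30))
  expect_equal(tto$n_excluded_negative, 1L) # event before start
  expect_equal(tto$n_excluded_missing, 3L) # partial start, partial event, no event
  expect_equal(tto$n_zero_adjusted, 1L)

  # the epsilon is configurable
  tto2 <- compute_tto(rep, spec, zero_epsilon = 0.25)
  expect_true(0.25 %in% tto2$durations)
})

test_that("earliest day-precision start date is used for multi-therapy reports", {
  demo <- tibble::tibble(primaryid = "1", event_dt = "20200210")
  drugs <- tibble::tibble(
    primaryid = "1", drug_seq = c("1", "2", "3"),
    drugname = "QUETIAPINE", prod_ai = "QUETIAPINE", role_cod = "PS",
    start_dt = c("202001", "20200201", "20200115"), indi_pt = NA_character_
  )
  tto <- compute_tto(make_reports(demo, drugs = drugs), cohort_spec("QUETIAPINE"))
  expect_equal(tto$durations_raw, 26) # from 2020-01-15, not the partial January row
})

test_that("Weibull MLE recovers planted parameters and rejects degenerate input", {
  set.seed(42)
  x <- rweibull(2000, shape = 0.5, scale = 5)
  fit <- weibull_mle(x)
  expect_gt(fit$beta, 0.45)
  expect_lt(fit$beta, 0.55)
  expect_gt(fit$alpha, 4.4)
  expect_lt(fit$alpha, 5.6)
  expect_true(fit$beta_ci[1] < fit$beta && fit$beta < fit$beta_ci[2])

  set.seed(43)
  xe <- stats::rexp(2000, rate = 1 / 3) # exponential = Weibull with beta 1
  fe <- weibull_mle(xe)
  expect_true(fe$beta_ci[1] < 1 && 1 < fe$beta_ci[2])
  expect_equal(fe$failure_type, "random")

  expect_error(weibull_mle(c(1, 1, 1, 1)), "degenerate")
  expect_error(weibull_mle(c(1, 2)), "at least 3")
  expect_error(weibull_mle(c(0, 1, 2)), "positive")
})

test_that("scale equivariance: durations in weeks rescale alpha, not beta", {
  set.seed(44)
  x <- rweibull(400, shape = 0.7, scale = 12)
  f1 <- weibull_mle(x)
  f2 <- weibull_mle(x * 7)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-5)
  expect_equal(f2$alpha, f1$alpha * 7, tolerance = 1e-4)
  expect_equal(f2$beta_ci, f1$beta_ci, tolerance = 1e-4)
})

test_that("failure classification partitions the CI space", {
  expect_equal(classify_failure(c(0.13, 0.17)), "early")
  expect_equal(classify_failure(c(0.9, 1.2)), "random")
  expect_equal(classify_failure(c(1.05, 1.4)), "wear_out")
  # boundary: CI touching 1 is random, not early/wear-out
  expect_equal(classify_failure(c(0.8, 1.0)), "random")
  expect_equal(classify_failure(c(1.0, 1.3)), "random")
})

test_that("shape CIs cover the truth at close to nominal rate", {
  set.seed(45)
  n_sim <- 200L
  covered <- 0L
  for (i in seq_len(n_sim)) {
    fit <- weibull_mle(rweibull(200, shape = 0.5, scale = 5))
    if (fit$beta_ci[1] < 0.5 && 0.5 < fit$beta_ci[2]) covered <- covered + 1L
  }
  expect_gte(covered / n_sim, 0.91)
  expect_lte(covered / n_sim, 0.99)
})

test_that("log-scale Wald intervals match an independent survreg route", {
  set.seed(46)
  x <- rweibull(500, shape = 0.6, scale = 8)
  fit <- weibull_mle(x)
  sr <- survival::survreg(survival::Surv(x) ~ 1, dist = "weibull")
  # survreg parametrization: scale = exp(intercept), shape = 1/sr$scale
  expect_equal(fit$alpha, exp(unname(stats::coef(sr))), tolerance = 1e-3)
  expect_equal(fit$beta, 1 / sr$scale, tolerance = 1e-3)
})

test_that("per-level pooling fits each priority level separately", {
  set.seed(47)
  n <- 120
  event <- format(as.Date("2020-01-01") + round(rweibull(n, 0.3, 5)), "%Y%m%d")
  rep <- tto_fixture(event_dt = event, start_dt = rep("20200101", n))
  rep$reacs <- tibble::tibble(
    primaryid = as.character(1:n),
    pt = rep(c("Tachycardia", "Extrasystoles"), length.out = n)
  )
  scored <- tibble::tibble(
    pt = c("Tachycardia", "Extrasystoles"),
    level = c("moderate", "weak")
  )
  tab <- tto_by_priority(rep, scored, cohort_spec("QUETIAPINE"))
  expect_setequal(tab$level, c("weak", "moderate"))
  expect_equal(sum(tab$n), n)
  mod <- tab[tab$level == "moderate", ]
  expect_equal(mod$failure_type, "early")
  expect_lt(mod$beta_high, 1)

  # degenerate level: all durations equal -> summary without a fit
  rep2 <- tto_fixture(rep("20200105", 4), rep("20200101", 4))
  rep2$reacs <- tibble::tibble(primaryid = as.character(1:4), pt = "Tachycardia")
  tab2 <- tto_by_priority(rep2, scored[1, ], cohort_spec("QUETIAPINE"))
  expect_equal(tab2$median, 4)
  expect_equal(tab2$q1, 4)
  expect_true(is.na(tab2$beta))
})
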