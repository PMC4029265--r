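test_that("product-limit estimate matches hand-computed values", {
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  # S(1) = 1 * (1 - 1/3) = 2/3; at t = 3 the risk set is one subject,
  # S(3) = 2/3 * (1 - 1/1) = 0
  expect_equal(km$time, c(1, 3))
  expect_equal(km$survival, c(2 / 3, 0))
  expect_equal(km$n_risk, c(3L, 1L))
})

test_that("degenerate product-limit cases behave as defined", {
  # all censored: no event times, curve stays at 1
  expect_equal(nrow(km_estimate(c(2, 5, 9), c(0, 0, 0))), 0L)
  # no censoring: S equals 1 - empirical CDF at event times
  withr::with_seed(2, t <- sort(round(rexp(30, 0.1), 2) + 0.01))
  km <- km_estimate(t, rep(1, 30))
  expect_equal(km$survival, 1 - ecdf(t)(km$time))
  # negative time errors
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
  # ordering invariance
  withr::with_seed(3, {
    tt <- round(rexp(25, 0.1), 1) + 0.1
    ev <- rbinom(25, 1, 0.6)
    perm <- sample(25)
  })
  expect_equal(km_estimate(tt, ev), km_estimate(tt[perm], ev[perm]))
})

test_that("product-limit estimate matches survival::survfit", {
  skip_if_not_installed("survival")
  d <- random_surv_data(60, seed = 44)
  km <- km_estimate(d$times, d$events)
  sf <- survival::survfit(survival::Surv(d$times, d$events) ~ 1)
  ref <- summary(sf, times = km$time)
  expect_equal(km$survival, ref$surv, tolerance = 1e-12)
  expect_equal(km$n_risk, ref$n.risk)
})

test_that("log-rank statistic matches the brute-force hypergeometric oracle", {
  # identical data duplicated into two groups: exactly no separation
  t0 <- c(1, 3, 4, 7)
  e0 <- c(1, 0, 1, 1)
  lr0 <- logrank_test(c(t0, t0), c(e0, e0), rep(c("A", "B"), each = 4))
  expect_equal(lr0$chi_square, 0)
  expect_equal(lr0$p_value, 1)
  # early-vs-late event groups against a step-by-step evaluation
  tt <- c(1:10 / 2, 5 + 1:10 / 2)
  ev <- rep(1, 20)
  gg <- rep(c(0, 1), each = 10)
  lr <- logrank_test(tt, ev, gg)
  expect_equal(lr$chi_square, logrank_oracle(tt, ev, gg), tolerance = 1e-12)
  # p is the upper-tail chi-square(1) probability by definition
  expect_equal(lr$p_value, pchisq(lr$chi_square, 1, lower.tail = FALSE))
  # random datasets with ties and censoring
  for (i in 1:8) {
    d <- random_surv_data(30, seed = 200 + i)
    x <- as.integer(d$groups == "B")
    if (length(unique(d$groups)) < 2 || sum(d$events) == 0) next
    lr <- logrank_test(d$times, d$events, d$groups)
    expect_equal(lr$chi_square, logrank_oracle(d$times, d$events, x),
                 tolerance = 1e-10)
  }
})

test_that("log-rank agrees with survival::survdiff and is label-symmetric", {
  skip_if_not_installed("survival")
  d <- random_surv_data(80, seed = 321)
  lr <- logrank_test(d$times, d$events, d$groups)
  ref <- survival::survdiff(survival::Surv(d$times, d$events) ~ d$groups)
  expect_equal(lr$chi_square, ref$chisq, tolerance = 1e-10)
  swapped <- logrank_test(d$times, d$events,
                          ifelse(d$groups == "A", "B", "A"))
  expect_equal(lr$chi_square, swapped$chi_square, tolerance = 1e-12)
  expect_error(logrank_test(d$times, d$events, rep("A", 80)), "two groups")
})

test_that("Cox fit matches survival::coxph with Breslow ties", {
  skip_if_not_installed("survival")
  for (i in 1:5) {
    d <- random_surv_data(60, seed = 400 + i)
    x <- as.integer(d$groups == "B")
    fit <- cox_univariate(d$times, d$events, d$groups)
    ref <- survival::coxph(survival::Surv(d$times, d$events) ~ x,
                           ties = "breslow")
    expect_equal(fit$coef, unname(ref$coefficients), tolerance = 1e-7)
    expect_equal(fit$log_hr_se, unname(sqrt(ref$var[1, 1])), tolerance = 1e-7)
  }
})

test_that("identical event-time distributions give a hazard ratio near 1", {
  t0 <- c(2, 5, 8, 11, 14, 17)
  e0 <- c(1, 1, 0, 1, 1, 0)
  fit <- cox_univariate(c(t0, t0), c(e0, e0), rep(c("A", "B"), each = 6))
  expect_equal(fit$hazard_ratio, 1, tolerance = 1e-8)
  expect_equal(fit$coef, 0, tolerance = 1e-8)
})

test_that("the score test at zero equals the log-rank statistic on tie-free data", {
  for (i in 1:6) {
    withr::with_seed(600 + i, {
      n <- 40
      tt <- rexp(n, 0.05) # continuous: ties almost surely absent
      ev <- rbinom(n, 1, 0.8)
      gg <- rep(c(0, 1), n / 2)
    })
    lr <- logrank_test(tt, ev, gg)
    cx <- cox_univariate(tt, ev, gg)
    expect_equal(cx$score_chi_square, lr$chi_square, tolerance = 1e-10)
  }
})

test_that("complete separation is flagged as an unbounded hazard ratio", {
  tt <- c(1, 2, 3, 4, 10, 11, 12, 13)
  ev <- rep(1, 8)
  gg <- rep(c("late", "early"), each = 4) # "early" sorts second -> all early events
  fit <- cox_univariate(tt, ev, rev(gg))
  expect_true(fit$infinite_hr)
  expect_true(is.infinite(fit$hazard_ratio) || fit$hazard_ratio == 0)
})

test_that("a true hazard ratio of 2 is recovered at n = 400 per group", {
  withr::with_seed(4242, {
    n <- 400
    t1 <- rexp(n, 1 / 60)       # baseline group
    t2 <- rexp(n, 2 / 60)       # doubled hazard
    tt <- c(t1, t2)
    cens <- runif(2 * n, 0, 270) # ~20% censoring under these scales
    time <- pmin(tt, cens)
    ev <- as.integer(tt <= cens)
    gg <- rep(c("ref", "x"), each = n)
  })
  expect_lt(abs(mean(ev == 0) - 0.2), 0.07)
  fit <- cox_univariate(time, ev, gg)
  expect_gt(fit$hazard_ratio, 1.7)
  expect_lt(fit$hazard_ratio, 2.35)
})
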