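test_that("Spearman correlation matches the rank formula and is invariant
           under monotone transforms", {
  expect_equal(spearman_corr(1:10, (1:10)^3)$rho, 1.0)
  expect_equal(spearman_corr(1:10, rev(1:10))$rho, -1.0)
  # rank-formula oracle: rho = 1 - 6 sum(d^2) / (n(n^2-1)) without ties
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  d <- rank(x) - rank(y)
  expect_equal(1 - 6 * sum(d^2) / (4 * 15), 0.8)
  expect_equal(spearman_corr(x, y)$rho, 0.8)
  set.seed(3)
  a <- stats::rnorm(30); b <- stats::rnorm(30)
  expect_equal(spearman_corr(a, b)$rho, spearman_corr(exp(a), b)$rho)
  expect_equal(spearman_corr(a, b)$rho, spearman_corr(a, b^3)$rho)
  expect_warning(r <- spearman_corr(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r$rho))
})

test_that("Kaplan-Meier median and curve behave as the estimator dictates", {
  # all events at t = 5 -> median 5
  r <- km_estimate(data.frame(time_months = rep(5, 8), event = 1))
  expect_equal(r$median_months, 5)
  # all censored -> median not reached
  r2 <- km_estimate(data.frame(time_months = c(10, 20, 30), event = 0))
  expect_true(is.na(r2$median_months))
  # nonincreasing curve starting at/below 1; no censoring -> empirical survival
  set.seed(8)
  t <- stats::rexp(50, 0.1)
  r3 <- km_estimate(data.frame(time_months = t, event = 1))
  expect_true(all(diff(r3$surv) <= 1e-12))
  expect_true(all(r3$surv <= 1))
  emp <- vapply(r3$time, function(u) mean(t > u), numeric(1))
  expect_equal(r3$surv, emp, tolerance = 1e-12)
})

test_that("inverse Kaplan-Meier follow-up matches hand computation", {
  # all censored at 110 -> follow-up 110
  r <- median_followup_inverse_km(
    data.frame(time_months = rep(110, 6), event = 0))
  expect_equal(r$median_months, 110)
  # all events -> flagged, not estimable
  expect_warning(
    r2 <- median_followup_inverse_km(
      data.frame(time_months = c(3, 6, 9), event = 1)),
    "not estimable")
  expect_true(is.na(r2$median_months))
  # mixed 6-record set, reverse product-limit by hand:
  # censorings (reverse events) at 4, 8, 10 ->
  # S(4) = 4/5, S(8) = 4/5 * 2/3 = 0.533, S(10) = 0.267 -> median 10
  rec <- data.frame(time_months = c(2, 4, 6, 8, 10, 12),
                    event = c(1, 0, 1, 0, 0, 1))
  r3 <- median_followup_inverse_km(rec)
  expect_equal(r3$median_months, 10)
})

test_that("log-rank test: identical groups give chi2 0, toy table matches
           the observed-minus-expected oracle", {
  rec <- data.frame(time_months = rep(c(2, 4, 6, 8), 2),
                    event = rep(c(1, 1, 0, 1), 2))
  g <- rep(c("a", "b"), each = 4)
  r <- log_rank_test(rec, g)
  expect_equal(r$chi2, 0, tolerance = 1e-12)
  expect_equal(r$p, 1, tolerance = 1e-12)
  expect_error(log_rank_test(rec, rep("a", 8)), "two nonempty groups")

  # toy two-group set; oracle: sum over event times of O - E and
  # hypergeometric variance for group 1
  rec2 <- data.frame(time_months = c(1, 2, 3, 4, 5, 6, 7, 8),
                     event = c(1, 1, 1, 0, 1, 1, 0, 1))
  g2 <- c(1, 1, 1, 1, 2, 2, 2, 2)
  times <- sort(unique(rec2$time_months[rec2$event == 1]))
  OmE <- 0; V <- 0
  for (tt in times) {
    at1 <- sum(rec2$time_months >= tt & g2 == 1)
    at2 <- sum(rec2$time_months >= tt & g2 == 2)
    d1 <- sum(rec2$time_months == tt & rec2$event == 1 & g2 == 1)
    d <- sum(rec2$time_months == tt & rec2$event == 1)
    n <- at1 + at2
    OmE <- OmE + d1 - d * at1 / n
    if (n > 1) V <- V + d * (at1 / n) * (at2 / n) * (n - d) / (n - 1)
  }
  chi2_oracle <- OmE^2 / V
  r2 <- log_rank_test(rec2, g2)
  expect_equal(r2$chi2, chi2_oracle, tolerance = 1e-9)
})

test_that("median dichotomization sends ties low", {
  expect_identical(dichotomize_at_median(c(1, 2, 3, 4)),
                   c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(dichotomize_at_median(c(1, 2, 2, 3)),
                   c(FALSE, FALSE, FALSE, TRUE))
  expect_warning(r <- dichotomize_at_median(rep(2, 4)), "empty")
  expect_true(all(!r))
})

test_that("Cox fit recovers a two-group rate ratio and covers the null", {
  set.seed(40)
  # two-group exponential with rate ratio 2, n = 2000 -> HR in [1.8, 2.2]
  g <- rep(0:1, each = 1000)
  t <- stats::rexp(2000, rate = 0.05 * ifelse(g == 1, 2, 1))
  rec <- data.frame(time_months = t, event = 1, grp = g)
  fit <- cox_fit(rec, "grp")
  expect_gt(fit$table$hr, 1.8)
  expect_lt(fit$table$hr, 2.2)
  expect_true(fit$table$hr_lower < fit$table$hr)
  # covariate independent of the hazard, n = 1000 -> CI covers HR = 1
  x <- stats::rnorm(1000)
  rec2 <- data.frame(time_months = stats::rexp(1000, 0.05), event = 1, x = x)
  fit2 <- cox_fit(rec2, "x")
  expect_true(fit2$table$hr_lower <= 1 && 1 <= fit2$table$hr_upper)
  # guards
  expect_error(cox_fit(transform(rec2, x = 1), "x"), "constant")
  expect_error(cox_fit(data.frame(time_months = c(1, 2), event = c(1, 0),
                                  x = c(1, 2)), "x"), "2 events")
  expect_error(cox_fit(rec2, "absent"), "missing covariate")
})

test_that("binary outcome at horizon classifies and excludes correctly", {
  rec <- data.frame(time_months = c(10, 12, 30, 24, 25),
                    event = c(1, 0, 0, 1, 0))
  bo <- binary_outcome_at_horizon(rec, 24)
  expect_identical(bo$label, c(TRUE, NA, FALSE, TRUE, FALSE))
  expect_identical(bo$evaluable, c(TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_error(binary_outcome_at_horizon(
    data.frame(time_months = c(5, 6), event = c(0, 0)), 24), "evaluable")
})

test_that("ROC/Youden matches the exhaustive-threshold oracle", {
  # worked 4-point set: separable -> AUC 1, cut between 2 and 3
  r <- roc_youden(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$auc, 1.0)
  expect_equal(r$sensitivity, 1.0)
  expect_equal(r$specificity, 1.0)
  expect_gt(r$cut, 2); expect_lt(r$cut, 3)
  # random small marker sets against the oracle
  set.seed(66)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    marker <- round(stats::runif(n, 0, 4), 1)
    label <- stats::runif(n) < 0.5
    if (!any(label) || all(label)) next
    mine <- roc_youden(marker, label)
    orc <- oracle_roc(marker, label)
    expect_equal(mine$auc, orc$auc, tolerance = 1e-12)
    expect_equal(mine$sensitivity + mine$specificity,
                 orc$sensitivity + orc$specificity, tolerance = 1e-12)
    expect_equal(mine$cut, orc$cut, tolerance = 1e-9)
  }
  # AUC invariant under strictly increasing marker transforms
  set.seed(67)
  m <- stats::rnorm(60); l <- stats::runif(60) < 0.4
  expect_equal(roc_youden(m, l)$auc, roc_youden(exp(m), l)$auc)
  expect_error(roc_youden(1:5, rep(TRUE, 5)), "both outcome classes")
})

test_that("IPCW horizon ROC agrees with binary mode when nothing is
           censored before the horizon", {
  set.seed(68)
  n <- 300
  x <- stats::rnorm(n)
  t <- stats::rexp(n, 0.04 * exp(0.8 * x))
  rec <- data.frame(time_months = t, event = 1, x = x)
  a <- roc_at_horizon(rec, "x", 24, mode = "binary")
  b <- roc_at_horizon(rec, "x", 24, mode = "ipcw")
  expect_equal(b$auc, a$auc, tolerance = 1e-9)
})

test_that("ISS and R-ISS reproduce the staging rules over the full grid", {
  expect_identical(iss_stage(3.0, 4.0), 1L)
  expect_identical(iss_stage(6.0, 4.0), 3L)
  expect_identical(iss_stage(3.0, 3.0), 2L)
  expect_identical(iss_stage(4.0, 4.0), 2L)
  expect_identical(r_iss_stage(1L, FALSE, FALSE), 1L)
  expect_identical(r_iss_stage(3L, FALSE, TRUE), 3L)
  expect_identical(r_iss_stage(3L, TRUE, FALSE), 3L)
  expect_identical(r_iss_stage(2L, TRUE, TRUE), 2L)
  # exhaustive truth table over ISS x high-risk x LDH
  grid <- expand.grid(iss = 1:3, hr = c(FALSE, TRUE), ldh = c(FALSE, TRUE))
  got <- r_iss_stage(grid$iss, grid$hr, grid$ldh)
  want <- ifelse(grid$iss == 1 & !grid$hr & !grid$ldh, 1L,
                 ifelse(grid$iss == 3 & (grid$hr | grid$ldh), 3L, 2L))
  expect_identical(got, want)
  expect_error(iss_stage(-1, 4), "nonnegative")
  expect_error(r_iss_stage(4L, FALSE, FALSE), "must be 1, 2 or 3")
})
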