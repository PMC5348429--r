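test_that("product-limit estimate matches the hand computation", {
  # censored at 1, events at 2 and 3: S(2) = 1 * (1 - 1/2) = 0.5, S(3) = 0
  km <- km_estimate(c(1, 2, 3), c(FALSE, TRUE, TRUE))
  expect_equal(km_survival_at(km, 2), 0.5)
  expect_equal(km_survival_at(km, 3), 0)
  expect_equal(km$median_survival, 2)

  # no events: survival identically 1, median undefined
  km0 <- km_estimate(c(4, 9, 17), rep(FALSE, 3))
  expect_true(all(km0$curve$surv == 1))
  expect_true(is.na(km0$median_survival))
  expect_error(km_estimate(numeric(0), logical(0)), "empty")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(71)
  for (i in 1:5) {
    tm <- round(rexp(60, 0.05), 1) + 0.1
    km <- km_estimate(tm, rep(TRUE, 60))
    at <- sort(unique(tm))
    expect_equal(km_survival_at(km, at), vapply(at, function(t)
      mean(tm > t), numeric(1)))
  }
})

test_that("log-rank statistic matches first-principles hypergeometric sums", {
  # interleaved groups, all events: e.g. at t=2 five remain (3 A, 2 B), the
  # event is in A, so O-E contributes 1 - 3/5 and V (3/5)(2/5)
  tm <- c(2, 4, 6, 1, 3, 5)
  grp <- rep(c("A", "B"), each = 3)
  ev <- rep(TRUE, 6)
  E <- 3 / 6 + 3 / 5 + 2 / 4 + 2 / 3 + 1 / 2 + 1
  V <- (3 / 6) * (3 / 6) + (3 / 5) * (2 / 5) + (2 / 4) * (2 / 4) +
       (2 / 3) * (1 / 3) + (1 / 2) * (1 / 2) + 0
  chisq_hand <- (3 - E)^2 / V

  lr <- logrank_test(tm, ev, grp)
  expect_equal(lr$chi_square, chisq_hand, tolerance = 1e-12)
  expect_equal(lr$df, 1L)

  mine <- logrank_chisq2(tm, ev, grp == "A")
  expect_equal(mine$chi_square, chisq_hand, tolerance = 1e-12)
  expect_equal(mine$observed - mine$expected, 3 - E, tolerance = 1e-12)
  expect_equal(mine$variance, V, tolerance = 1e-12)
})

test_that("log-rank test is invariant to group relabeling and null on identical groups", {
  set.seed(12)
  tm <- rep(round(rexp(25, 0.04), 1), 2)
  ev <- rep(runif(25) < 0.7, 2)
  grp <- rep(c("x", "y"), each = 25)   # two copies of the same sample
  lr <- logrank_test(tm, ev, grp)
  expect_equal(lr$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1, tolerance = 1e-9)

  tm2 <- round(rexp(50, 0.04), 1); ev2 <- runif(50) < 0.6
  g <- rep(c("a", "b"), 25)
  expect_equal(logrank_test(tm2, ev2, g)$chi_square,
               logrank_test(tm2, ev2, ifelse(g == "a", "b", "a"))$chi_square,
               tolerance = 1e-12)

  expect_error(logrank_test(tm2, ev2, rep("a", 50)), "two groups")
  expect_error(logrank_test(tm2, rep(FALSE, 50), g), "one event")
})

test_that("Cox fits recover simulated hazard ratios", {
  d <- simulate_binary_cox(2000, true_hr = 2.0, seed = 17)
  expect_gt(mean(!d$event), 0.1)   # meaningful censoring present
  fit <- cox_fit(d, "x")
  expect_true(fit$converged)
  expect_gt(fit$terms$hr, 1.8)
  expect_lt(fit$terms$hr, 2.2)
  expect_lt(fit$terms$p, 0.001)

  null <- cox_fit(simulate_binary_cox(2000, true_hr = 1.0, seed = 18), "x")
  expect_gt(null$terms$hr, 0.9)
  expect_lt(null$terms$hr, 1.1)

  expect_error(cox_fit(within(d, x <- 1), "x"), "constant covariate: x")
  expect_error(cox_fit(within(d, event <- FALSE), "x"), "at least one event")
})

test_that("Cox score test at zero equals the log-rank chi-square (tie-free)", {
  set.seed(29)
  for (i in 1:5) {
    n <- 120
    x <- rbinom(n, 1, 0.5)
    tm <- rexp(n) / (0.05 * 1.8^x)   # continuous: no ties
    ev <- runif(n) < 0.8
    if (!any(ev)) next
    fit <- cox_fit(data.frame(x = x, time_months = tm, event = ev), "x")
    lr <- logrank_chisq2(tm, ev, x == 1)
    expect_equal(fit$score_test, lr$chi_square, tolerance = 1e-6)
  }
})

test_that("mean estimated log-HR tracks the truth across a hazard grid", {
  for (hr in c(0.5, 1, 2)) {
    est <- vapply(1:4, function(s) {
      d <- simulate_binary_cox(1250, true_hr = hr, seed = 300 + 10 * hr + s)
      log(cox_fit(d, "x")$terms$hr)
    }, numeric(1))
    expect_lt(abs(mean(est) - log(hr)), 0.1)
  }
})

test_that("prognostic tables use the reported reference levels", {
  coh <- generate_cohort(cohort_config(196, seed = 41))
  cuts <- build_cutoff_table(coh)
  sc <- classify_cohort(coh, cuts)
  rep <- prognostic_report(coh, sc)

  uni <- rep$univariate
  expect_true(all(c("agege65", "pTT4", "pNN1_2",
                    "metastasis_timingsynchronous", "IS_Mlow") %in% uni$term))
  expect_true(all(uni$ci_lo <= uni$hr & uni$hr <= uni$ci_hi))

  mv <- rep$multivariate
  expect_setequal(unique(mv$model_id),
                  c("multivariate_IS", "multivariate_IS_M",
                    "multivariate_IS_MA"))
  # each multivariate fit adjusts the score for the six clinical factors
  expect_equal(sum(mv$model_id == "multivariate_IS_M"), 7L)

  # continuous age parameterization supported
  rep2 <- prognostic_report(coh, sc, age_term = "continuous")
  expect_true("age" %in% rep2$univariate$term)

  # subgroup fits stratify on mutation status
  rep3 <- prognostic_report(coh, sc, subgroup_by = "kras")
  expect_setequal(unique(rep3$multivariate$subgroup),
                  c("kras:wild", "kras:mutant"))

  allcens <- cohort(coh$clinical,
                    within(coh$survival, event <- FALSE), coh$densities)
  expect_error(prognostic_report(allcens, sc), "no events")
})

test_that("KM curve tables carry one curve per model class", {
  coh <- generate_cohort(cohort_config(150, seed = 43))
  cuts <- build_cutoff_table(coh)
  sc <- classify_cohort(coh, cuts)
  km <- km_curves_table(coh, sc)
  expect_setequal(unique(km$group),
                  c(t(outer(c("IS", "IS_M", "IS_MA"), c("low", "high"),
                            paste, sep = "_"))))
  expect_true(all(km$survival > 0 | km$survival == 0))
  for (g in unique(km$group)) {
    s <- km$survival[km$group == g]
    expect_true(all(diff(s) <= 0))           # non-increasing
    expect_true(all(km$at_risk[km$group == g] >= 1))
  }
  expect_true(all(unlist(attr(km, "logrank")) >= 0))
})
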