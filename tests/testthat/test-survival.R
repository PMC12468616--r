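test_that("Kaplan-Meier matches closed-form values without censoring", {
  cur <- km_estimate(data.frame(time_years = 1:3, event = 1))$curve
  expect_equal(cur$survival, c(2 / 3, 1 / 3, 0))
  # no censoring: KM equals the empirical survival function
  set.seed(79)
  t <- round(rexp(40, 1), 3)
  cur2 <- km_estimate(data.frame(time_years = t, event = 1))$curve
  emp <- vapply(cur2$time, function(u) mean(t > u), numeric(1))
  expect_equal(cur2$survival, emp)
})

test_that("an all-censored cohort has flat survival one", {
  cur <- km_estimate(data.frame(time_years = 1:3, event = 0))$curve
  expect_true(all(cur$survival == 1))
  expect_true(is.na(median_survival(km_estimate(
    data.frame(time_years = 1:3, event = 0)))))
})

test_that("a mixed six-record set reproduces hand-computed product-limit values", {
  rec <- data.frame(time_years = c(1, 2, 3, 4, 4, 5),
                    event = c(1, 0, 1, 1, 1, 0))
  km <- km_estimate(rec)
  # hand calculation: S(1) = 5/6, S(3) = 5/6 * 3/4, S(4) = 5/8 * 1/3
  expect_equal(km$curve$survival,
               c(5 / 6, 5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 1 / 3,
                 5 / 6 * 3 / 4 * 1 / 3))
  expect_true(all(diff(km$curve$survival) <= 0))
  expect_true(all(km$curve$ci_lower <= km$curve$survival &
                    km$curve$survival <= km$curve$ci_upper))
  expect_equal(median_survival(km), 4)
  # step to 0.4 at t = 5 -> median 5
  toy <- km_estimate(data.frame(time_years = c(5, 5, 5, 5, 5),
                                event = c(1, 1, 1, 0, 0)))
  expect_equal(median_survival(toy), 5)
})

test_that("log-rank matches the hand-computed two-group chi-square", {
  rec <- data.frame(time_years = c(1, 2, 3, 4), event = 1,
                    group = c("A", "A", "B", "B"))
  lr <- logrank(rec)
  # hand: O_A = 2, E_A = 1/2 + 1/3 = 5/6, V = 1/4 + 2/9 = 17/36
  expect_equal(lr$statistic, (2 - 5 / 6)^2 / (17 / 36), tolerance = 1e-6)
  expect_identical(lr$df, 1)
})

test_that("log-rank separates disjoint groups and not identical ones", {
  set.seed(83)
  early <- data.frame(time_years = runif(40, 0.1, 1), event = 1, group = "E")
  late <- data.frame(time_years = runif(40, 5, 10), event = 1, group = "L")
  expect_lt(logrank(rbind(early, late))$p_value, 0.01)
  same <- rbind(transform(early, group = "A"), transform(early, group = "B"))
  expect_lt(logrank(same)$statistic, 1e-8)
  expect_error(logrank(early), "two non-empty groups")
})

test_that("c-index hits its closed-form extremes", {
  d <- data.frame(time_years = c(5, 3, 1), event = 1)
  expect_equal(harrell_c_index(c(1, 2, 3), d), 1)
  expect_equal(harrell_c_index(c(3, 2, 1), d), 0)
  expect_equal(harrell_c_index(c(2, 2, 2), d), 0.5)
  expect_error(harrell_c_index(1, data.frame(time_years = 1, event = 0)),
               "admissible")
})

test_that("c-index equals the O(n^2) brute force and complements reversed risk", {
  set.seed(89)
  n <- 200
  grade <- sample(1:3, n, TRUE, prob = c(0.6, 0.3, 0.1))
  t <- rexp(n, rate = c(1 / 8, 1 / 5, 1 / 1.5)[grade])
  e <- rbinom(n, 1, 0.7)
  risk <- grade + rnorm(n, 0, 0.01)  # tie-free ordinal risk
  rec <- data.frame(time_years = t, event = e)
  ci <- harrell_c_index(risk, rec)
  # brute force, plain double loop
  conc <- 0; adm <- 0
  for (i in 1:n) for (j in 1:n) {
    if (i != j && t[i] < t[j] && e[i] == 1) {
      adm <- adm + 1
      if (risk[i] > risk[j]) conc <- conc + 1
      else if (risk[i] == risk[j]) conc <- conc + 0.5
    }
  }
  expect_equal(ci, conc / adm)
  expect_equal(harrell_c_index(-risk, rec), 1 - ci)
  # independent route: survival's concordance with the predictor reversed
  cc <- survival::concordance(survival::Surv(t, e) ~ risk)
  expect_equal(ci, 1 - cc$concordance, tolerance = 1e-10)
})

test_that("graded cohorts yield a full metrics bundle", {
  ch <- gen_cohort(cohort_spec(n_patients = 120, seed = 31))$cohort
  m <- survival_metrics(ch, "grade")
  expect_gt(m$c_index, 0.5)
  expect_identical(nrow(m$medians), 3L)
  expect_true(all(c("statistic", "p_value") %in% names(m$logrank)))
})
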