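test_that("KM estimate matches hand product-limit and ECDF identities", {
  # all censored: constant curve at 1
  km <- km_estimate(c(3, 5, 8), c(0, 0, 0))
  expect_length(km$event_times, 0)
  expect_equal(km_survival_at(km, c(1, 10)), c(1, 1))

  # hand product-limit on {1 event, 2 censored, 3 event}
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$event_times, c(1, 3))
  expect_equal(km$survival, c(2 / 3, 0))
  expect_equal(km$at_risk, c(3, 1))

  # no censoring: survival equals 1 - ECDF at every event time
  set.seed(11)
  t <- stats::rexp(40, 0.1)
  km <- km_estimate(t, rep(1, 40))
  ec <- stats::ecdf(t)
  expect_equal(km$survival, 1 - ec(km$event_times), tolerance = 1e-12)
  expect_true(all(diff(km$survival) <= 0))
  expect_true(all(km$survival >= 0 & km$survival <= 1))
  expect_error(km_estimate(c(-1, 2), c(1, 1)),
               class = "tsr_validation_error")
})

test_that("k-sample log-rank reduces to z^2 for two groups", {
  set.seed(21)
  d <- sim_surv(80)
  lt <- logrank_test(d$time, d$event, d$group)
  expect_equal(lt$df, 1)
  expect_equal(lt$chi_square, logrank_z(d$time, d$event, d$group == 1)^2,
               tolerance = 1e-9)

  # identical groups: statistic 0, p 1
  t2 <- rep(c(2, 4, 6), 2); e2 <- rep(c(1, 1, 0), 2)
  g2 <- rep(c("a", "b"), each = 3)
  lt0 <- logrank_test(t2, e2, g2)
  expect_equal(lt0$chi_square, 0, tolerance = 1e-12)
  expect_equal(lt0$p, 1)

  # three-group test has 2 df
  g3 <- rep(c("a", "b", "c"), length.out = 80)
  expect_equal(logrank_test(d$time, d$event, g3)$df, 2)
  expect_error(logrank_test(d$time, rep(0, 80), d$group),
               class = "tsr_validation_error")
})

test_that("log-rank power at the planted categorical effect is high", {
  reject <- vapply(1:60, function(i) {
    co <- simulate_cohort(cohort_spec(seed = 3000 + i))
    g <- dichotomize(co$tsr, 33.5)
    logrank_test(co$time_months, co$event, g)$p < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.95)
})

test_that("Cox fit matches a dense grid search of the partial likelihood", {
  # 4 subjects, all events, no ties: closed-form partial likelihood.
  # Alternating group membership keeps the likelihood bounded (the
  # earliest-failures-in-one-group configuration is monotone and is
  # covered by the separation test below).
  time <- c(1, 2, 3, 4); event <- rep(1L, 4); x <- c(1, 0, 1, 0)
  d <- data.frame(x = x)
  fit <- cox_fit(d, time = time, event = event, covariates = "x")
  plik <- function(b) {
    risk <- exp(b * x); ll <- 0
    for (i in order(time)) {
      at <- time >= time[i]
      ll <- ll + b * x[i] - log(sum(risk[at]))
    }
    ll
  }
  grid <- seq(-5, 5, by = 0.001)
  b_grid <- grid[which.max(vapply(grid, plik, numeric(1)))]
  expect_equal(unname(fit$coefficients), b_grid, tolerance = 0.001)
  expect_gte(fit$loglik, fit$loglik_null)
  expect_true(fit$converged)
  expect_true(fit$ci_lower < fit$hr && fit$hr < fit$ci_upper)
})

test_that("Cox fit flags separation and rejects constant covariates", {
  d <- data.frame(x = c(1, 1, 0, 0))
  expect_error(cox_fit(data.frame(x = rep(1, 4)), time = 1:4,
                       event = rep(1, 4), covariates = "x"),
               class = "tsr_validation_error")
  # monotone likelihood: group 1 always fails first
  sep <- cox_fit(d, time = c(1, 2, 10, 20), event = rep(1, 4),
                 covariates = "x")
  expect_false(sep$converged)
  expect_true(any(grepl("separation|converge", sep$flags,
                        ignore.case = TRUE)))
})

test_that("continuous TSR covariate counts stroma per 10 points", {
  expect_equal(continuous_tsr_covariate(100), 0)
  expect_equal(continuous_tsr_covariate(33.5), 6.65)
  expect_equal(continuous_tsr_covariate(40, orientation = "tumor"), 4)
  expect_error(continuous_tsr_covariate(120),
               class = "tsr_validation_error")
})

test_that("continuous per-10-point stroma hazard is recovered", {
  # hazard doubles per 10 percentage points of stroma
  hrs <- vapply(1:30, function(i) {
    co <- simulate_cohort(cohort_spec(
      n_patients = 400,
      planted_log_hazards = c(stroma_per10 = log(2)),
      baseline_hazard = 1e-4, seed = 6000 + i))
    co$stroma10 <- continuous_tsr_covariate(co$tsr)
    unname(cox_fit(co, covariates = "stroma10")$hr)
  }, numeric(1))
  expect_equal(mean(hrs), 2, tolerance = 0.05)
})

test_that("administrative censoring truncates at the horizon", {
  out <- censor_at_horizon(c(72, 59, 60), c(1, 1, 1), horizon = 60)
  expect_equal(out$time, c(60, 59, 60))
  expect_equal(out$event, c(0L, 1L, 1L))
  # cohort fully beyond the horizon: zero events, tests error cleanly
  far <- censor_at_horizon(c(70, 80), c(1, 1), horizon = 60)
  expect_error(logrank_test(far$time, far$event, c("a", "b")),
               class = "tsr_validation_error")
  expect_error(censor_at_horizon(1, 1, horizon = 0),
               class = "tsr_validation_error")
})

test_that("log-rank chi-square equals the Cox score test with Breslow ties", {
  set.seed(31)
  worst <- 0
  for (i in 1:50) {
    d <- sim_surv(30 + (i %% 3))
    if (sum(d$event) == 0 || length(unique(d$group)) < 2) next
    eq <- score_test_equivalence(d$time, d$event, d$group)
    worst <- max(worst, eq$rel_diff)
  }
  expect_lt(worst, 1e-8)

  # identical groups: both statistics vanish
  eq0 <- score_test_equivalence(rep(c(1, 2, 3), 2), rep(c(1, 1, 0), 2),
                                rep(c(0, 1), each = 3))
  expect_equal(eq0$logrank_chisq, 0, tolerance = 1e-12)
  expect_equal(eq0$cox_score_chisq, 0, tolerance = 1e-12)
})
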