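test_that("candidate cutpoints honour the minimum-group constraint", {
  tsr <- seq(10, 100, by = 10)
  cand <- candidate_cutpoints(tsr, 0.1)
  expect_length(cand, 9)
  expect_equal(cand, seq(15, 95, by = 10))

  expect_error(candidate_cutpoints(rep(50, 10)),
               class = "tsr_validation_error")

  cand5 <- candidate_cutpoints(tsr, 0.5)
  expect_length(cand5, 1)
  expect_equal(cand5, 55)
})

test_that("log-rank z matches the hand life-table computation", {
  time <- 1:6; event <- rep(1L, 6)
  g1 <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  z <- logrank_z(time, event, g1)
  expect_equal(z, 0.6963305683, tolerance = 1e-9)
  expect_equal(z, logrank_hand(time, event, g1), tolerance = 1e-12)

  # duplicated groups are exactly balanced
  t2 <- c(2, 5, 7, 2, 5, 7); e2 <- c(1, 0, 1, 1, 0, 1)
  expect_equal(logrank_z(t2, e2, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)),
               0)

  expect_error(logrank_z(1:4, rep(0, 4), c(TRUE, TRUE, FALSE, FALSE)),
               class = "tsr_validation_error")
  expect_error(logrank_z(1:4, rep(1, 4), rep(TRUE, 4)),
               class = "tsr_validation_error")

  # random datasets: life-table loop oracle
  set.seed(41)
  for (i in 1:25) {
    d <- sim_surv(40)
    if (sum(d$event) == 0 || length(unique(d$group)) < 2) next
    expect_equal(logrank_z(d$time, d$event, d$group == 1),
                 logrank_hand(d$time, d$event, d$group == 1),
                 tolerance = 1e-10)
  }
})

test_that("null permutation distribution of z^2 is chi-square(1)", {
  set.seed(53)
  d <- sim_surv(60, hr = 1, censor_rate = 0.02)
  z2 <- vapply(1:2000, function(i) {
    logrank_z(d$time, d$event, sample(d$group) == 1)^2
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(z2, stats::pchisq, df = 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("maximal selection scans candidates exhaustively and reproducibly", {
  co <- simulate_cohort(cohort_spec(n_patients = 120, seed = 71))
  res <- max_selected_rank(co$tsr, co$time_months, co$event)
  expect_s3_class(res, "tsr_cutpoint")
  expect_true(res$selected_cutoff %in% res$candidates)
  expect_equal(abs(res$statistics[match(res$selected_cutoff,
                                        res$candidates)]),
               res$max_abs_statistic)
  expect_equal(res$max_abs_statistic, max(abs(res$statistics)))

  # definitional equivalence: statistics equal per-candidate recomputation
  z_brute <- vapply(res$candidates, function(cc)
    logrank_z(co$time_months, co$event, co$tsr <= cc), numeric(1))
  expect_equal(res$statistics, z_brute)

  # both groups satisfy the minimum-size constraint
  k <- ceiling(0.1 * nrow(co))
  nlow <- sum(co$tsr <= res$selected_cutoff)
  expect_gte(nlow, k); expect_gte(nrow(co) - nlow, k)

  # permutation equivariance: patient order is irrelevant
  idx <- sample(nrow(co))
  res2 <- max_selected_rank(co$tsr[idx], co$time_months[idx],
                            co$event[idx])
  expect_equal(res2$selected_cutoff, res$selected_cutoff)

  # rank invariance: a monotone transform maps the selected split
  tr <- function(x) 100 * (x / 100)^2
  res3 <- max_selected_rank(tr(co$tsr), co$time_months, co$event)
  expect_identical(co$tsr <= res$selected_cutoff,
                   tr(co$tsr) <= res3$selected_cutoff)
})

test_that("ties in |z| break toward the smaller cutoff", {
  # symmetric toy data engineered to tie: two identical-shape candidates
  tsr <- c(10, 20, 30, 40)
  time <- c(1, 2, 3, 4); event <- rep(1L, 4)
  res <- max_selected_rank(tsr, time, event, min_group_fraction = 0.25)
  dup <- abs(abs(res$statistics) - res$max_abs_statistic) < 1e-12
  expect_equal(res$selected_cutoff, min(res$candidates[dup]))
})

test_that("dichotomization sends the boundary to stroma-high", {
  g <- dichotomize(c(33.5, 33.6, 10, 90), 33.5)
  expect_identical(as.character(g),
                   c("stroma-high", "stroma-low", "stroma-high",
                     "stroma-low"))
  expect_identical(levels(g), c("stroma-low", "stroma-high"))
  expect_true(all(dichotomize(c(20, 50, 80), 0.5) == "stroma-low"))
  expect_error(dichotomize(50, 0), class = "tsr_validation_error")
})

test_that("planted cutoffs are recovered by the maximal selection", {
  sel <- vapply(1:20, function(i) {
    co <- simulate_cohort(cohort_spec(
      n_patients = 500, planted_cutoff = 40,
      planted_log_hazards = c(stroma_high = log(2.5)),
      seed = 5000 + i))
    max_selected_rank(co$tsr, co$time_months, co$event)$selected_cutoff
  }, numeric(1))
  expect_lte(abs(stats::median(sel) - 40), 5)
})

test_that("permutation p-value is available behind a flag", {
  co <- simulate_cohort(cohort_spec(n_patients = 60, seed = 81))
  pp <- maxstat_permutation_p(co$tsr, co$time_months, co$event,
                              B = 50, seed = 1)
  expect_true(pp$p > 0 && pp$p <= 1)
  expect_length(pp$null_max, 50)
})
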