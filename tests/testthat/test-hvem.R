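test_that("start-day rules generate the prescribed distributions", {
  set.seed(601)
  sync <- draw_start_day(start_rule("synchronized"), 50000)
  expect_equal(mean(sync), 180, tolerance = 0.01)
  # integer rounding slightly inflates the unit SD: sd(round(Z)) ~= 1.041
  expect_equal(stats::sd(sync), 1.0408, tolerance = 0.01)
  rnd <- draw_start_day(start_rule("random"), 60000)
  expect_equal(range(rnd), c(151L, 210L))
  expect_gt(suppressWarnings(
    stats::chisq.test(table(factor(rnd, levels = 151:210)))
  )$p.value, 0.001)
  set.seed(602)
  s1 <- draw_start_day(start_rule("random"), 5)
  set.seed(602)
  expect_identical(draw_start_day(start_rule("random"), 5), s1)
})

test_that("durations count days elapsed from the setup day", {
  # goal met by a seizure on the setup day itself: zero further days needed
  tc <- toy_course(c(50, 60))
  expect_identical(monitor_until_goal(tc, 50, 1), 0L)
  # distinct-day counting: two seizures on one day are a single seizure day
  tc2 <- toy_course(c(101, 109, 119), counts = c(2L, 1L, 1L))
  expect_identical(monitor_until_goal(tc2, 100, 3), 19L)
  # goals may be vectorized and are monotone
  expect_identical(monitor_until_goal(tc2, 100, c(1, 2, 3)), c(1L, 9L, 19L))
  expect_error(monitor_until_goal(tc2, 0, 1), "first year")
  expect_error(monitor_until_goal(tc2, 100, 0), "goal")
})

test_that("monitoring agrees with the exhaustive enumeration oracle", {
  # toy courses with seizures confined to a 10-day window: check every
  # start day and every reachable goal against a day-by-day scan
  set.seed(603)
  for (rep in 1:20) {
    days <- sort(sample(1:10, sample(1:6, 1)))
    tc <- toy_course(days)
    for (s in 1:10) {
      reachable <- sum(days >= s)
      for (k in seq_len(max(reachable, 1))) {
        got <- monitor_until_goal(tc, s, k, extend = FALSE)
        expect_identical(got, oracle_duration(tc$daily_counts, s, k))
      }
    }
  }
})

test_that("censoring and unreachable goals are handled explicitly", {
  tc <- toy_course(c(100, 200))
  expect_identical(monitor_until_goal(tc, 150, c(1, 3), extend = FALSE),
                   c(50L, NA_integer_))
  empty <- toy_course(integer(0))
  expect_error(monitor_until_goal(empty, 1, 1, extend = TRUE), "unreachable")
  expect_identical(monitor_until_goal(empty, 1, 1, extend = FALSE),
                   NA_integer_)
})

test_that("monitoring extends the course in-phase when the year runs out", {
  set.seed(604)
  tc <- generate_noncycling_timecourse(12)
  d <- monitor_until_goal(tc, 360, 5)
  expect_true(is.finite(d) && d >= 4)
  # duration matches a scan of the extended course itself
  tmpl <- build_cycle_template(30, 365)
  tcc <- generate_cycling_timecourse(24, tmpl, f = 0.5)
  set.seed(605)
  d2 <- monitor_until_goal(tcc, 300, 5)
  expect_true(is.finite(d2))
})

test_that("duration to first seizure matches the geometric waiting time", {
  # high-rate non-cycling patients: P(day has a seizure) is
  # p = 1 - (364/365)^N and days-beyond-setup to the first seizure day is
  # approximately geometric with mean (1 - p) / p
  n_annual <- 240
  p <- 1 - (364 / 365)^n_annual
  set.seed(606)
  d <- replicate(50000, {
    tc <- generate_noncycling_timecourse(n_annual)
    monitor_until_goal(tc, 180, 1)
  })
  expect_equal(mean(d), (1 - p) / p, tolerance = 0.02)
})

test_that("per-patient durations are monotone in the goal", {
  set.seed(607)
  grid <- frequency_grid(rep(1, 14))
  tab <- build_interval_table(grid)
  counts <- sample_annual_counts(tab, 200)
  tmpl <- build_cycle_template(20, 365)
  for (i in 1:200) {
    tc <- if (i %% 2) generate_noncycling_timecourse(counts[i])
          else generate_cycling_timecourse(counts[i], tmpl)
    s <- draw_start_day(start_rule("random"), 1)
    d <- monitor_until_goal(tc, s, c(1, 3, 5))
    expect_true(all(diff(d) >= 0))
  }
})

test_that("start rules are interchangeable for non-cycling courses", {
  # no cycling: the process is day-exchangeable, so synchronized vs random
  # starts must give statistically indistinguishable durations
  set.seed(608)
  d_sync <- numeric(3000)
  d_rand <- numeric(3000)
  for (i in 1:3000) {
    tc <- generate_noncycling_timecourse(60)
    d_sync[i] <- monitor_until_goal(tc, draw_start_day(start_rule("synchronized"), 1), 3)
    tc2 <- generate_noncycling_timecourse(60)
    d_rand[i] <- monitor_until_goal(tc2, draw_start_day(start_rule("random"), 1), 3)
  }
  expect_gt(compare_groups(d_sync, d_rand)$p_value, 0.01)
})

test_that("cohort simulation is reproducible and correctly structured", {
  g_c <- frequency_grid(rep(1, 14), age_group = "children")
  g_a <- frequency_grid(rep(1, 14), age_group = "adults")
  res <- simulate_cohort(g_c, g_a, n_children = 10, n_adults = 10,
                         seed = 99)
  # six (age group, goal) duration vectors of length 10 under random start
  for (age in c("children", "adults")) {
    for (k in c(1, 3, 5)) {
      d <- res$duration_days[res$age_group == age & res$goal == k &
                               res$start_rule == "random"]
      expect_length(d, 10)
      expect_true(all(d >= 0))
    }
  }
  expect_true(all(!res$cycling[res$age_group == "children"]))
  expect_setequal(unique(res$start_rule[res$age_group == "adults"]),
                  c("random", "synchronized"))
  expect_setequal(unique(res$start_rule[res$age_group == "children"]),
                  "random")
  # bit-identical replay under the same seed
  res2 <- simulate_cohort(g_c, g_a, n_children = 10, n_adults = 10,
                          seed = 99)
  expect_identical(res, res2)
  # a different seed moves the draws
  res3 <- simulate_cohort(g_c, g_a, n_children = 10, n_adults = 10,
                          seed = 100)
  expect_false(identical(res$duration_days, res3$duration_days))
  # child streams: enlarging the children's cohort leaves adults untouched
  res4 <- simulate_cohort(g_c, g_a, n_children = 25, n_adults = 10,
                          seed = 99)
  a1 <- as.data.frame(res[res$age_group == "adults", ])
  a4 <- as.data.frame(res4[res4$age_group == "adults", ])
  rownames(a1) <- rownames(a4) <- NULL
  expect_identical(a4, a1)
})

test_that("weekly capture respects the monitored-day boundary", {
  expect_equal(unname(weekly_capture_fraction(rep(0, 5), weeks = 1)), 100)
  # 7 days beyond setup = 8 monitored days: counted at week 2, not week 1
  expect_equal(unname(weekly_capture_fraction(7, weeks = 1:2)), c(0, 100))
  expect_equal(unname(weekly_capture_fraction(6, weeks = 1)), 100)
  x <- c(0, 3, 7, 20, 80, NA)
  pct <- weekly_capture_fraction(x)
  expect_true(all(diff(pct) >= 0))
  expect_true(all(pct >= 0 & pct <= 100))
  expect_error(weekly_capture_fraction(numeric(0)), "empty")
})
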