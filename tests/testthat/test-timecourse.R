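test_that("cycle templates split the period as specified", {
  t7 <- build_cycle_template(7, 14)
  expect_equal(t7$pattern, c(1L, 1L, 1L, 1L, 0L, 0L, 0L))
  expect_equal(t7$active_days, c(1:4, 8:11))
  t20 <- build_cycle_template(20, 20)
  expect_equal(t20$pattern, c(rep(1L, 10), rep(0L, 10)))
  t15 <- build_cycle_template(15, 365)
  expect_equal(t15$pattern, c(rep(1L, 7), rep(0L, 8)))
  # direct tiling oracle: 24 full cycles x 7 ones + 5 leading ones
  tiled <- rep(t15$pattern, length.out = 365)
  expect_equal(t15$active_days, which(tiled == 1L))
  expect_length(t15$active_days, 173)
  expect_error(build_cycle_template(9, 365), "unsupported odd cycle")
  expect_error(build_cycle_template(30, 20), "horizon")
})

test_that("phase offset continues a cycle where it left off", {
  full <- build_cycle_template(30, 730)
  head_block <- build_cycle_template(30, 365)
  tail_block <- build_cycle_template(30, 365, phase_offset = 365 %% 30)
  expect_equal(c(head_block$active_days, 365 + tail_block$active_days),
               full$active_days)
})

test_that("every generated course conserves its annual seizure total", {
  set.seed(501)
  model <- cycling_model()
  for (i in 1:30) {
    n <- sample(0:400, 1)
    tc <- generate_noncycling_timecourse(n)
    expect_identical(sum(tc$daily_counts[1:365]), as.integer(n))
    len <- sample(c(7, 15, 20, 30), 1)
    tmpl <- build_cycle_template(len, 365)
    tcc <- generate_cycling_timecourse(n, tmpl, model)
    expect_identical(sum(tcc$daily_counts[1:365]), as.integer(n))
    expect_true(tcc$allocated_fraction >= 0 && tcc$allocated_fraction <= 1)
  }
  expect_error(generate_noncycling_timecourse(-1), "non-negative")
})

test_that("non-cycling placement is uniform over the year", {
  tc0 <- generate_noncycling_timecourse(0)
  expect_true(all(tc0$daily_counts == 0L))
  set.seed(502)
  pooled <- integer(365)
  for (i in 1:20) {
    pooled <- pooled + generate_noncycling_timecourse(10000)$daily_counts
  }
  p <- suppressWarnings(stats::chisq.test(pooled))$p.value
  expect_gt(p, 0.001)
})

test_that("phase-locked allocation boundaries behave as specified", {
  tmpl <- build_cycle_template(30, 365)
  inactive <- setdiff(1:365, tmpl$active_days)
  set.seed(503)
  # f = 1: everything on active days
  tc1 <- generate_cycling_timecourse(300, tmpl, f = 1)
  expect_true(all(tc1$daily_counts[inactive] == 0L))
  expect_equal(sum(tc1$daily_counts[tmpl$active_days]), 300)
  # f = 0: indistinguishable from uniform placement; active-day share equals
  # the active time fraction
  tot_active <- 0
  for (i in 1:50) {
    tc0 <- generate_cycling_timecourse(1000, tmpl, f = 0)
    tot_active <- tot_active + sum(tc0$daily_counts[tmpl$active_days])
  }
  expect_equal(tot_active / 50000, length(tmpl$active_days) / 365,
               tolerance = 0.02)
})

test_that("active-day seizure share matches the closed-form expectation", {
  # f fixed at 0.34 on a 30-day template: expected active share is
  # f + (1 - f) * (185 / 365)
  tmpl <- build_cycle_template(30, 365)
  expect_length(tmpl$active_days, 185)
  expected <- 0.34 + 0.66 * (185 / 365)
  set.seed(504)
  share <- replicate(200, {
    tc <- generate_cycling_timecourse(360, tmpl, f = 0.34)
    sum(tc$daily_counts[tmpl$active_days]) / 360
  })
  expect_equal(mean(share), expected, tolerance = 0.01)
})

test_that("extreme phase-locking draws are clipped into [0, 1]", {
  wild <- cycling_model(plv_mean = 0.5, plv_sd = 1)
  tmpl <- build_cycle_template(20, 365)
  set.seed(505)
  fs <- replicate(200, generate_cycling_timecourse(50, tmpl,
                                                   wild)$allocated_fraction)
  expect_true(all(fs >= 0 & fs <= 1))
  expect_true(any(fs == 0) || any(fs == 1))  # clipping actually engaged
})

test_that("cohort structure follows the age-specific cycling prevalence", {
  expect_true(all(is.na(assign_cohort_structure(1000, "children"))))
  set.seed(506)
  a <- assign_cohort_structure(10000, "adults")
  expect_equal(sum(is.na(a)), 4000)
  expect_equal(unname(table(a)[c("7", "15", "20", "30")]),
               c(1200, 1020, 1800, 1980), ignore_attr = TRUE)
  # deterministic under a fixed seed
  set.seed(507)
  one <- assign_cohort_structure(1, "adults")
  set.seed(507)
  expect_identical(assign_cohort_structure(1, "adults"), one)
  expect_error(assign_cohort_structure(10, "elderly"), "arg")
})

test_that("extension preserves rate, cycling status, and phase", {
  set.seed(508)
  # rate preservation: a year-long extension carries ~ annual_total seizures
  tot_ext <- 0
  for (i in 1:50) {
    tc <- generate_noncycling_timecourse(200)
    ext <- extend_timecourse(tc, 365)
    expect_identical(ext$annual_total, tc$annual_total)
    expect_true(is.na(ext$cycle_length))
    tot_ext <- tot_ext + sum(ext$daily_counts[366:730])
  }
  expect_equal(tot_ext / 50, 200, tolerance = 0.05)
  # a 30-day-cycle course extended with f = 1 keeps all extension seizures
  # in the active phase continued from day 366
  tmpl <- build_cycle_template(30, 365)
  tcc <- generate_cycling_timecourse(300, tmpl, f = 1)
  extc <- extend_timecourse(tcc, 400)
  expect_length(extc$daily_counts, 765)
  seiz_ext <- which(extc$daily_counts[366:765] > 0) + 365
  phase <- ((seiz_ext - 1) %% 30) + 1
  expect_true(all(phase <= 15))
  expect_equal(extc$allocated_fraction, 1)
})

test_that("cycling model validates its parameters", {
  expect_error(cycling_model(prevalence = 1.2), "prevalence")
  expect_error(cycling_model(cycle_mixture = c("7" = 0.5, "15" = 0.4)),
               "sum to 1")
  expect_error(cycling_model(plv_sd = -0.1), "plv_sd")
  m <- cycling_model()
  expect_equal(sum(m$cycle_mixture), 1)
})
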