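#' Monitoring start-day rule
#'
#' Two ways of randomizing the first monitored day, both centred mid-year so
#' that the expected number of remaining seizures is comparable:
#'
#' * `"synchronized"`: day `180 + round(z)`, `z` a standard normal draw — a
#'   Gaussian start concentrated within ~1 day of the beginning of the
#'   15/20/30-day cycles (all of which restart around day 181). Used to ask
#'   whether timing monitoring to the cycle onset helps.
#' * `"random"`: a uniform integer on days 151-210, unrelated to cycle phase.
#'
#' @param mode `"random"` or `"synchronized"`.
#' @return object of class `start_rule`.
#' @export
start_rule <- function(mode = c("random", "synchronized")) {
  mode <- match.arg(mode)
  structure(
    list(mode = mode,
         anchor_day = if (mode == "synchronized") 180L else 150L,
         jitter = if (mode == "synchronized") "gaussian_sd1" else "uniform_60"),
    class = "start_rule"
  )
}

#' Draw monitoring start days
#'
#' @param rule a [start_rule()].
#' @param n number of draws.
#' @return integer vector of start days.
#' @export
draw_start_day <- function(rule, n = 1) {
  stopifnot(inherits(rule, "start_rule"))
  if (rule$mode == "synchronized") {
    as.integer(180L + round(stats::rnorm(n)))
  } else {
    150L + sample.int(60L, n, replace = TRUE)  # uniform on 151..210
  }
}

#' Days of monitoring needed to observe k distinct seizure days
#'
#' Monitoring is set up on `start_day`, which is observed in full: seizures
#' on it count toward the goal. Recording stops on the day the `goal`-th
#' distinct calendar day with at least one seizure is observed, and the
#' duration is the number of days elapsed from setup to that day:
#' `duration = (day of the goal-th seizure day) - start_day`. A goal met by
#' a seizure on the start day itself therefore has duration 0 — durations
#' count days beyond setup, the convention that reproduces the published
#' duration summaries (see the methods vignette). Multiple seizures on one
#' day count as a single seizure day. If the simulated year ends before the
#' goal is met the course is extended in 365-day blocks by the same
#' generative process ([extend_timecourse()]); with `extend = FALSE` an
#' unmet goal yields `NA` (censored).
#'
#' @param tc a `timecourse`.
#' @param start_day setup day (within the course's first year); observed in
#'   full.
#' @param goal target number of distinct seizure days; may be a vector (e.g.
#'   `c(1, 3, 5)`), in which case one duration per goal is returned.
#' @param extend extend the course past its horizon when needed (default) or
#'   censor.
#' @param max_years safety cap on extensions before an unreachable-goal
#'   error.
#' @return integer vector of durations in days (>= 0), one per goal.
#' @export
monitor_until_goal <- function(tc, start_day, goal, extend = TRUE,
                               max_years = 60L) {
  stopifnot(inherits(tc, "timecourse"))
  start_day <- as.integer(start_day)
  goal <- as.integer(goal)
  if (any(goal < 1)) stop("goal must be >= 1")
  if (start_day < 1 || start_day > 365L) {
    stop("start_day must lie within the course's first year")
  }
  kmax <- max(goal)
  if (extend && tc$annual_total == 0L) {
    stop("unreachable goal: time-course has no seizures at any horizon")
  }
  years <- 0L
  repeat {
    seiz_days <- which(tc$daily_counts > 0L)
    eligible <- seiz_days[seiz_days >= start_day]
    if (length(eligible) >= kmax) {
      return(as.integer(eligible[goal] - start_day))
    }
    if (!extend) {
      out <- rep(NA_integer_, length(goal))
      met <- goal <= length(eligible)
      out[met] <- eligible[goal[met]] - start_day
      return(out)
    }
    if (years >= max_years) {
      stop("unreachable goal: ", kmax, " distinct seizure days not reached ",
           "within ", max_years, " extension years")
    }
    tc <- extend_timecourse(tc, 365L)
    years <- years + 1L
  }
}

#' Simulate monitoring durations for full cohorts
#'
#' Runs the complete pipeline for one children's and one adults' cohort:
#' annual seizure totals are drawn from each group's frequency grid, daily
#' time-courses are generated (children never cycle; adults follow the
#' cycling model), and each patient is monitored from a random start day
#' until every goal is met. Adult courses are additionally monitored under
#' the cycle-synchronized start rule (same time-courses, independent start
#' draw) when `synchronized_adults = TRUE`, supporting the cycling vs
#' non-cycling comparison at cycle onset.
#'
#' Each pipeline stage consumes its own child stream of the master seed, so
#' results are reproducible and stages are insulated from one another.
#'
#' @param grid_children,grid_adults [frequency_grid()] objects per age group.
#' @param n_children,n_adults cohort sizes.
#' @param goals distinct-seizure-day targets (default `c(1, 3, 5)`).
#' @param model a [cycling_model()] for the adult cohort.
#' @param seed master seed (integer).
#' @param synchronized_adults also monitor adults from a cycle-synchronized
#'   start.
#' @param extend extension policy: `TRUE` to continue monitoring past day
#'   365 in-phase, `FALSE` to censor (`NA` durations).
#' @return object of class `hvem_cohort`: a long data frame with one row per
#'   patient x goal x start rule and columns `age_group`, `patient_id`,
#'   `annual_seizures`, `cycling`, `cycle_length`, `plv_fraction`,
#'   `start_rule`, `start_day`, `goal`, `duration_days`, plus attributes
#'   `seed` and `goals`.
#' @export
simulate_cohort <- function(grid_children, grid_adults,
                            n_children = 50000, n_adults = 50000,
                            goals = c(1, 3, 5), model = cycling_model(),
                            seed = 1, synchronized_adults = TRUE,
                            extend = TRUE) {
  stopifnot(inherits(grid_children, "frequency_grid"),
            inherits(grid_adults, "frequency_grid"),
            n_children >= 1, n_adults >= 1)
  goals <- sort(as.integer(goals))
  seeds <- derive_seeds(seed, 2L)
  res_c <- simulate_group(grid_children, as.integer(n_children), "children",
                          goals, model, seeds[1], FALSE, extend)
  res_a <- simulate_group(grid_adults, as.integer(n_adults), "adults",
                          goals, model, seeds[2], synchronized_adults, extend)
  out <- rbind(res_c, res_a)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  attr(out, "goals") <- goals
  class(out) <- c("hvem_cohort", "data.frame")
  out
}

# one age group: counts -> time-courses -> monitoring (random start, and
# optionally synchronized start on the same courses)
simulate_group <- function(grid, n, age_group, goals, model, seed,
                           synchronized, extend) {
  set.seed(seed)
  table <- build_interval_table(grid)
  counts <- sample_annual_counts(table, n)
  structure_vec <- assign_cohort_structure(n, age_group, model)
  templates <- list()
  for (len in unique(structure_vec[!is.na(structure_vec)])) {
    templates[[as.character(len)]] <- build_cycle_template(len, 365L)
  }
  rules <- c("random", if (synchronized) "synchronized")
  nk <- length(goals)
  nr <- length(rules)
  total <- n * nk * nr
  durations <- integer(total)
  start_days <- integer(total)
  rule_col <- character(total)
  goal_col <- integer(total)
  pid <- integer(total)
  plv <- rep(NA_real_, n)
  rule_objs <- lapply(rules, start_rule)
  names(rule_objs) <- rules
  row <- 0L
  for (i in seq_len(n)) {
    len <- structure_vec[i]
    tc <- if (is.na(len)) {
      generate_noncycling_timecourse(counts[i])
    } else {
      generate_cycling_timecourse(counts[i], templates[[as.character(len)]],
                                  model)
    }
    plv[i] <- tc$allocated_fraction
    for (r in rules) {
      s <- draw_start_day(rule_objs[[r]], 1)
      d <- monitor_until_goal(tc, s, goals, extend = extend)
      idx <- row + seq_len(nk)
      durations[idx] <- d
      start_days[idx] <- s
      rule_col[idx] <- r
      goal_col[idx] <- goals
      pid[idx] <- i
      row <- row + nk
    }
  }
  data.frame(
    age_group = age_group,
    patient_id = pid,
    annual_seizures = as.integer(counts)[pid],
    cycling = !is.na(structure_vec[pid]),
    cycle_length = structure_vec[pid],
    plv_fraction = plv[pid],
    start_rule = rule_col,
    start_day = start_days,
    goal = goal_col,
    duration_days = durations
  )
}

#' Weekly capture percentages
#'
#' Percentage of patients for whom the goal was met within each monitoring
#' week: a duration of `d` days beyond setup (the [monitor_until_goal()]
#' convention) occupies `d + 1` monitored calendar days, so capture by the
#' end of week `w` means `d + 1 <= 7 * w`. A patient needing 8 recording
#' days counts at week 2, not week 1.
#'
#' @param durations numeric vector of durations in days beyond setup (`NA`
#'   = censored, counted as not captured).
#' @param weeks week indices (default 1-10).
#' @return numeric vector of percentages in `[0, 100]`, named by week;
#'   non-decreasing in week.
#' @export
weekly_capture_fraction <- function(durations, weeks = 1:10) {
  durations <- as.numeric(durations)
  if (length(durations) == 0) stop("empty duration vector")
  out <- vapply(weeks, function(w) {
    100 * sum(!is.na(durations) & durations + 1 <= 7 * w) / length(durations)
  }, numeric(1))
  names(out) <- paste0("week", weeks)
  out
}
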