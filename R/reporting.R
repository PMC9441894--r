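#' Summary statistics of a duration distribution
#'
#' Mean, sample SD (n-1 denominator), median, interquartile range, and
#' skewness of a vector of monitoring durations. Quantiles use linear
#' interpolation at positions `(i - 0.5) / n` (R type 5), the convention of
#' MATLAB's `prctile`; skewness is the biased moment coefficient
#' `g1 = m3 / m2^(3/2)` (MATLAB `skewness` default), appropriate at the
#' cohort sizes used here.
#'
#' @param durations numeric vector (NAs dropped with a warning).
#' @return one-row data frame: `n`, `mean`, `sd`, `median`, `iqr`,
#'   `skewness`.
#' @examples
#' describe(c(1, 1, 1, 10))
#' @export
describe <- function(durations) {
  x <- as.numeric(durations)
  if (anyNA(x)) {
    warning("dropping ", sum(is.na(x)), " censored (NA) durations")
    x <- x[!is.na(x)]
  }
  if (length(x) == 0) stop("empty duration vector")
  q <- stats::quantile(x, c(0.25, 0.75), type = 5, names = FALSE)
  data.frame(
    n = length(x),
    mean = mean(x),
    sd = stats::sd(x),
    median = stats::median(x),
    iqr = q[2] - q[1],
    skewness = skewness_g1(x)
  )
}

#' Biased moment skewness g1
#'
#' `g1 = m3 / m2^(3/2)` with central moments computed with denominator `n`
#' (no small-sample correction).
#'
#' @param x numeric vector of length >= 2.
#' @return scalar skewness.
#' @export
skewness_g1 <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2) stop("need at least two observations")
  d <- x - mean(x)
  m2 <- mean(d^2)
  if (m2 == 0) return(NaN)
  mean(d^3) / m2^1.5
}

#' Two-sample comparison of monitoring durations
#'
#' Two-tailed two-sample Student's t-test, pooled equal-variance by default
#' (MATLAB `ttest2` convention); Welch's unequal-variance variant is
#' available behind a flag. Group medians are reported alongside because the
#' duration distributions are strongly right-skewed.
#'
#' @param a,b numeric duration vectors.
#' @param welch use the Welch (unequal variance) variant.
#' @return one-row data frame: `t_statistic`, `df`, `p_value`, `mean_a`,
#'   `mean_b`, `median_a`, `median_b`.
#' @export
compare_groups <- function(a, b, welch = FALSE) {
  a <- as.numeric(a[!is.na(a)])
  b <- as.numeric(b[!is.na(b)])
  if (length(a) < 2 || length(b) < 2) stop("both groups need >= 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("degenerate comparison: zero variance in both groups")
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  data.frame(
    t_statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    mean_a = mean(a), mean_b = mean(b),
    median_a = stats::median(a), median_b = stats::median(b)
  )
}

#' Cohort comparison table of monitoring durations
#'
#' Builds the study's headline comparison table: for each goal (1, 3, 5
#' distinct seizure days), children vs adults under the random start rule,
#' and adults with vs without seizure cycling under both the random and the
#' cycle-synchronized start rules. Each row carries both groups' descriptive
#' statistics and the pooled two-sample t-test.
#'
#' @param cohort an [simulate_cohort()] result that includes adult
#'   synchronized-start durations.
#' @return data frame with one row per comparison x goal; columns
#'   `comparison`, `goal`, `group_a`, `group_b`, then `describe()` fields
#'   suffixed `_a` / `_b`, and `t_statistic`, `p_value`.
#' @export
build_table1 <- function(cohort) {
  stopifnot(inherits(cohort, "hvem_cohort"))
  goals <- sort(unique(cohort$goal))
  has_sync <- any(cohort$start_rule == "synchronized")
  if (!has_sync) {
    stop("cohort lacks synchronized-start adult durations; ",
         "run simulate_cohort(synchronized_adults = TRUE)")
  }
  pick <- function(age, rule, cyc = NULL) {
    sel <- cohort$age_group == age & cohort$start_rule == rule
    if (!is.null(cyc)) sel <- sel & cohort$cycling == cyc
    cohort[sel, ]
  }
  specs <- list(
    list(label = "adults vs children (random start)",
         a = function(g) pick("adults", "random"),
         b = function(g) pick("children", "random"),
         names = c("adults", "children")),
    list(label = "adults cycling vs non-cycling (random start)",
         a = function(g) pick("adults", "random", TRUE),
         b = function(g) pick("adults", "random", FALSE),
         names = c("cycling", "non-cycling")),
    list(label = "adults cycling vs non-cycling (cycle-start)",
         a = function(g) pick("adults", "synchronized", TRUE),
         b = function(g) pick("adults", "synchronized", FALSE),
         names = c("cycling", "non-cycling"))
  )
  rows <- list()
  for (sp in specs) {
    da <- sp$a(); db <- sp$b()
    if (nrow(da) == 0 || nrow(db) == 0) {
      stop("missing subgroup for comparison: ", sp$label)
    }
    for (g in goals) {
      xa <- da$duration_days[da$goal == g]
      xb <- db$duration_days[db$goal == g]
      sa <- describe(xa); sb <- describe(xb)
      cmp <- compare_groups(xa, xb)
      names(sa) <- paste0(names(sa), "_a")
      names(sb) <- paste0(names(sb), "_b")
      rows[[length(rows) + 1]] <- cbind(
        data.frame(comparison = sp$label, goal = g,
                   group_a = sp$names[1], group_b = sp$names[2]),
        sa, sb,
        data.frame(t_statistic = cmp$t_statistic, p_value = cmp$p_value)
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Weekly capture-percentage grid
#'
#' Cumulative percentage of patients who met each goal by the end of each
#' monitoring week, per age group, under the random start rule (the rule
#' applied to both age groups).
#'
#' @param cohort an [simulate_cohort()] result.
#' @param weeks week indices (default 1-10).
#' @return data frame with columns `age_group`, `goal`, `week`,
#'   `percent_captured`; percentages are non-decreasing along weeks within
#'   each group x goal.
#' @export
build_fig1_tables <- function(cohort, weeks = 1:10) {
  stopifnot(inherits(cohort, "hvem_cohort"))
  rows <- list()
  for (age in unique(cohort$age_group)) {
    for (g in sort(unique(cohort$goal))) {
      d <- cohort$duration_days[cohort$age_group == age &
                                  cohort$start_rule == "random" &
                                  cohort$goal == g]
      pct <- weekly_capture_fraction(d, weeks)
      rows[[length(rows) + 1]] <- data.frame(
        age_group = age, goal = g, week = weeks,
        percent_captured = unname(pct)
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot weekly capture curves
#'
#' Base-graphics rendering of the weekly capture grid: one panel per age
#' group, one line per goal.
#'
#' @param fig1 a [build_fig1_tables()] result.
#' @return `fig1`, invisibly.
#' @export
plot_weekly_capture <- function(fig1) {
  ages <- unique(fig1$age_group)
  goals <- sort(unique(fig1$goal))
  cols <- c("blue", "darkgreen", "red")[seq_along(goals)]
  old <- graphics::par(mfrow = c(1, length(ages)))
  on.exit(graphics::par(old))
  for (age in ages) {
    sub <- fig1[fig1$age_group == age, ]
    plot(NULL, xlim = range(sub$week), ylim = c(0, 100),
         xlab = "week of monitoring", ylab = "% of patients with goal met",
         main = age)
    for (i in seq_along(goals)) {
      s <- sub[sub$goal == goals[i], ]
      graphics::lines(s$week, s$percent_captured, col = cols[i], type = "b",
                      pch = 16)
    }
    graphics::legend("bottomright", legend = paste(goals, "seizure days"),
                     col = cols, lty = 1, pch = 16, bty = "n")
  }
  invisible(fig1)
}
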