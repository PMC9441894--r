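#' Construct a monthly seizure-frequency density grid
#'
#' A frequency grid holds point probability densities of monthly seizure
#' frequency at a set of breakpoints within the study's inclusion window of
#' 1-30 seizures/month. The default breakpoints step by 1 from 1 to 10
#' seizures/month and by 5 from 10 to 30. Densities need not be normalized:
#' all downstream probabilities are renormalized over the covered intervals.
#'
#' @param densities non-negative point probability densities, one per
#'   breakpoint.
#' @param breakpoints strictly increasing monthly seizure frequencies; the
#'   first must be >= 1 and the last <= 30.
#' @param age_group `"children"` or `"adults"`.
#' @return object of class `frequency_grid`: a list with elements
#'   `breakpoints`, `densities`, `age_group`.
#' @seealso [build_interval_table()], [read_density_grid()],
#'   [calibrate_surrogate_grid()]
#' @examples
#' g <- frequency_grid(densities = rep(1, 14), age_group = "children")
#' @export
frequency_grid <- function(densities,
                           breakpoints = c(1:10, 15, 20, 25, 30),
                           age_group = c("children", "adults")) {
  age_group <- match.arg(age_group)
  breakpoints <- as.numeric(breakpoints)
  densities <- as.numeric(densities)
  if (length(breakpoints) < 2) {
    stop("a frequency grid needs at least two breakpoints")
  }
  if (length(densities) != length(breakpoints)) {
    stop("need one density per breakpoint (", length(breakpoints), ")")
  }
  if (any(diff(breakpoints) <= 0)) {
    stop("breakpoints must be strictly increasing")
  }
  if (breakpoints[1] < 1 || breakpoints[length(breakpoints)] > 30) {
    stop("breakpoints must lie in the inclusion window [1, 30] seizures/month")
  }
  if (any(!is.finite(densities)) || any(densities < 0)) {
    stop("densities must be finite and non-negative")
  }
  structure(
    list(breakpoints = breakpoints, densities = densities,
         age_group = age_group),
    class = "frequency_grid"
  )
}

#' @export
print.frequency_grid <- function(x, ...) {
  cat("<frequency_grid> ", x$age_group, ", ",
      length(x$breakpoints), " breakpoints on [",
      x$breakpoints[1], ", ", x$breakpoints[length(x$breakpoints)],
      "] seizures/month\n", sep = "")
  invisible(x)
}

#' Read a density grid from a two-column CSV
#'
#' Expects a header and columns `monthly_frequency`, `density`.
#'
#' @param path CSV file path.
#' @inheritParams frequency_grid
#' @return a [frequency_grid()].
#' @export
read_density_grid <- function(path, age_group = c("children", "adults")) {
  df <- utils::read.csv(path)
  need <- c("monthly_frequency", "density")
  if (!all(need %in% names(df))) {
    stop("density CSV must have columns: ", paste(need, collapse = ", "))
  }
  frequency_grid(densities = df$density, breakpoints = df$monthly_frequency,
                 age_group = match.arg(age_group))
}

#' Write a density grid to CSV
#'
#' @param grid a [frequency_grid()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_density_grid <- function(grid, path) {
  stopifnot(inherits(grid, "frequency_grid"))
  utils::write.csv(
    data.frame(monthly_frequency = grid$breakpoints, density = grid$densities),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Surrogate mean density of a frequency interval
#'
#' The density curve is treated as close to linear within each short
#' interval, so the interval's mean density is approximated by the arithmetic
#' mean of the densities at its two endpoints (a trapezoid-rule weight).
#'
#' @param pd_start,pd_end non-negative point densities at the interval start
#'   and end.
#' @return the surrogate mean density, `(pd_start + pd_end) / 2`.
#' @examples
#' surrogate_mean_density(0.2, 0.1)
#' @export
surrogate_mean_density <- function(pd_start, pd_end) {
  if (any(!is.finite(pd_start)) || any(!is.finite(pd_end)) ||
      any(pd_start < 0) || any(pd_end < 0)) {
    stop("densities must be finite and non-negative")
  }
  (pd_start + pd_end) / 2
}

#' Build the interval probability table of a frequency grid
#'
#' Consecutive breakpoints define frequency intervals. Each interval `i`
#' receives the raw probability `P_i = mPD*_i * L_i` (surrogate mean density
#' times interval length, i.e. its approximate area under the density curve),
#' then probabilities are normalized to sum to one over the covered window:
#' `nP_i = P_i / sum(P)`.
#'
#' @param grid a [frequency_grid()].
#' @return object of class `interval_table`: a data frame with columns
#'   `start`, `end`, `length`, `mean_density`, `prob`, `norm_prob`, with the
#'   grid's age group attached as attribute `age_group`.
#' @examples
#' g <- frequency_grid(densities = c(3, 1, 1), breakpoints = c(1, 2, 4))
#' build_interval_table(g)
#' @export
build_interval_table <- function(grid) {
  stopifnot(inherits(grid, "frequency_grid"))
  bp <- grid$breakpoints
  de <- grid$densities
  n <- length(bp) - 1L
  start <- bp[-length(bp)]
  end <- bp[-1]
  len <- end - start
  mpd <- surrogate_mean_density(de[-length(de)], de[-1])
  P <- mpd * len
  tot <- sum(P)
  if (tot <= 0) {
    stop("degenerate distribution: all interval probabilities are zero")
  }
  out <- data.frame(
    start = start, end = end, length = len,
    mean_density = mpd, prob = P, norm_prob = P / tot
  )
  attr(out, "age_group") <- grid$age_group
  class(out) <- c("interval_table", "data.frame")
  out
}

#' Write an interval table to CSV
#'
#' @param table an [build_interval_table()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_interval_table <- function(table, path) {
  stopifnot(inherits(table, "interval_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Sample per-patient annual seizure counts from an interval table
#'
#' Each patient is assigned a frequency interval with probability `nP_i`,
#' then an integer annual count uniformly on `[12*start_i, 12*end_i]`
#' (inclusive on both ends: a patient in the 2-3 seizures/month interval
#' draws uniformly between 24 and 36 seizures/year). Interval assignment is
#' realized as one multinomial draw of per-interval patient counts followed
#' by a random permutation of the assembled cohort, which is distributionally
#' identical to independent per-patient interval draws.
#'
#' @param table an [build_interval_table()] result.
#' @param n_patients number of patients to sample (>= 1).
#' @return integer vector of annual seizure counts with attribute
#'   `age_group`, class `annual_counts`.
#' @examples
#' g <- frequency_grid(densities = rep(1, 14))
#' set.seed(1)
#' counts <- sample_annual_counts(build_interval_table(g), 100)
#' @export
sample_annual_counts <- function(table, n_patients) {
  stopifnot(inherits(table, "interval_table"),
            length(n_patients) == 1, n_patients >= 1)
  n_patients <- as.integer(n_patients)
  per_interval <- as.vector(stats::rmultinom(1, n_patients, table$norm_prob))
  lo <- as.integer(round(12 * table$start))
  hi <- as.integer(round(12 * table$end))
  counts <- integer(0)
  for (i in seq_len(nrow(table))) {
    if (per_interval[i] == 0) next
    span <- hi[i] - lo[i] + 1L
    counts <- c(counts,
                lo[i] - 1L + sample.int(span, per_interval[i], replace = TRUE))
  }
  counts <- counts[sample.int(length(counts))]  # mix patients across intervals
  structure(counts, age_group = attr(table, "age_group"),
            class = "annual_counts")
}

#' Monthly summary statistics of an annual-count sample
#'
#' Statistics are computed on annual counts divided by 12, for comparison
#' with published monthly seizure-frequency summaries.
#'
#' @param sample an [sample_annual_counts()] result (or a bare integer vector
#'   of annual counts).
#' @return data frame with one row: `mean`, `median`, `sd` of monthly
#'   frequency.
#' @export
summarize_monthly <- function(sample) {
  x <- as.numeric(sample)
  if (length(x) == 0) stop("empty sample")
  m <- x / 12
  data.frame(mean = mean(m), median = stats::median(m), sd = stats::sd(m))
}
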