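#' Multidien cycling model parameters
#'
#' Describes the prevalence and structure of multidien (week-to-month scale)
#' seizure cycles in adult time-courses, as measured from chronic intracranial
#' EEG cohorts: 60% of adult time-courses cycle; cycle periods of 7, 15, 20,
#' and 30 days occur in proportions 20/17/30/33; the fraction of a patient's
#' seizures locked to the active half-cycle is drawn per patient from a
#' Normal(0.34, 0.18) clipped to `[0, 1]` (the phase-locking value, PLV).
#'
#' @param prevalence fraction of adult time-courses with cycling.
#' @param cycle_mixture named numeric vector mapping cycle length in days to
#'   its probability among cycling time-courses; must sum to 1.
#' @param plv_mean,plv_sd mean and SD of the phase-locked seizure fraction.
#' @return object of class `cycling_model`.
#' @export
cycling_model <- function(prevalence = 0.60,
                          cycle_mixture = c("7" = 0.20, "15" = 0.17,
                                            "20" = 0.30, "30" = 0.33),
                          plv_mean = 0.34, plv_sd = 0.18) {
  if (is.null(names(cycle_mixture)) || any(names(cycle_mixture) == "")) {
    stop("cycle_mixture must be named by cycle length in days")
  }
  if (abs(sum(cycle_mixture) - 1) > 1e-9) {
    stop("cycle_mixture probabilities must sum to 1")
  }
  if (prevalence < 0 || prevalence > 1) stop("prevalence must be in [0, 1]")
  if (plv_mean < 0 || plv_mean > 1) stop("plv_mean must be in [0, 1]")
  if (plv_sd < 0) stop("plv_sd must be >= 0")
  structure(
    list(prevalence = prevalence, cycle_mixture = cycle_mixture,
         plv_mean = plv_mean, plv_sd = plv_sd),
    class = "cycling_model"
  )
}

#' Build a binary cycle template
#'
#' A cycle template is a binary vector over one cycle period — ones for the
#' active half-cycle, zeros for the inactive half — tiled across the
#' simulation horizon starting on day 1 with the active half. Because the
#' time resolution is one day, odd periods split unevenly: the 7-day cycle
#' has 4 ones then 3 zeros and the 15-day cycle 7 ones then 8 zeros; even
#' periods split half/half, ones first.
#'
#' @param cycle_length cycle period in days. Any even length is accepted,
#'   plus the specifically defined odd lengths 7 and 15.
#' @param horizon number of days to tile (>= `cycle_length`).
#' @param phase_offset days of the cycle already elapsed before the first
#'   tiled day (0 starts at the beginning of the active half). Used to
#'   continue a cycle in phase when extending a time-course.
#' @return object of class `cycle_template`: list with `cycle_length`,
#'   `pattern` (binary vector of one period), `active_days` (day indices of
#'   ones over the horizon), `horizon`, `phase_offset`.
#' @examples
#' build_cycle_template(7, 14)$active_days
#' @export
build_cycle_template <- function(cycle_length, horizon, phase_offset = 0) {
  cycle_length <- as.integer(cycle_length)
  horizon <- as.integer(horizon)
  if (horizon < cycle_length) stop("horizon must be >= cycle_length")
  n_ones <- if (cycle_length %% 2 == 0) {
    cycle_length %/% 2
  } else if (cycle_length == 7) {
    4L
  } else if (cycle_length == 15) {
    7L
  } else {
    stop("unsupported odd cycle length: ", cycle_length,
         " (defined lengths: 7, 15, and any even period)")
  }
  pattern <- c(rep(1L, n_ones), rep(0L, cycle_length - n_ones))
  idx <- ((phase_offset + seq_len(horizon) - 1L) %% cycle_length) + 1L
  tiled <- pattern[idx]
  structure(
    list(cycle_length = cycle_length, pattern = pattern,
         active_days = which(tiled == 1L), horizon = horizon,
         phase_offset = as.integer(phase_offset)),
    class = "cycle_template"
  )
}

# internal constructor; daily_counts over >= 365 days
new_timecourse <- function(daily_counts, cycle_length = NA_integer_,
                           allocated_fraction = NA_real_) {
  structure(
    list(daily_counts = as.integer(daily_counts),
         annual_total = sum(daily_counts[1:365]),
         cycle_length = cycle_length,
         allocated_fraction = allocated_fraction),
    class = "timecourse"
  )
}

#' @export
print.timecourse <- function(x, ...) {
  cat("<timecourse> ", x$annual_total, " seizures/year over ",
      length(x$daily_counts), " days",
      if (!is.na(x$cycle_length)) {
        paste0("; ", x$cycle_length, "-day cycle, phase-locked fraction ",
               signif(x$allocated_fraction, 3))
      } else {
        "; no cycling"
      }, "\n", sep = "")
  invisible(x)
}

#' Generate a non-cycling daily seizure time-course
#'
#' Each of the patient's `annual_total` seizures is assigned independently to
#' a uniformly random day of the 365-day year. More than one seizure per day
#' is allowed; the daily counts always sum exactly to the annual total.
#'
#' @param annual_total seizures in the year (>= 0).
#' @return object of class `timecourse` with a 365-day `daily_counts` vector.
#' @export
generate_noncycling_timecourse <- function(annual_total) {
  annual_total <- as.integer(annual_total)
  if (is.na(annual_total) || annual_total < 0) {
    stop("annual_total must be a non-negative count")
  }
  days <- sample.int(365L, annual_total, replace = TRUE)
  new_timecourse(tabulate(days, nbins = 365L))
}

#' Generate a cycling daily seizure time-course
#'
#' A phase-locked fraction `f` of the year's seizures — drawn per patient
#' from Normal(`plv_mean`, `plv_sd`) and clipped to `[0, 1]` — is placed
#' uniformly on the template's active days only (`round(f * annual_total)`
#' seizures, ties rounded half away from zero). The remaining seizures are
#' placed uniformly over all 365 days, so active days carry both shares.
#'
#' @param annual_total seizures in the year (>= 0).
#' @param template a [build_cycle_template()] with horizon 365.
#' @param model a [cycling_model()] supplying the PLV distribution.
#' @param f optional fixed phase-locked fraction in `[0, 1]`, overriding the
#'   random draw (used in tests and sensitivity analyses).
#' @return object of class `timecourse`; the realized fraction is recorded
#'   in `$allocated_fraction`.
#' @export
generate_cycling_timecourse <- function(annual_total, template,
                                        model = cycling_model(), f = NULL) {
  annual_total <- as.integer(annual_total)
  if (is.na(annual_total) || annual_total < 0) {
    stop("annual_total must be a non-negative count")
  }
  stopifnot(inherits(template, "cycle_template"))
  if (template$horizon < 365L) stop("template horizon must cover 365 days")
  if (is.null(f)) {
    f <- clip(stats::rnorm(1, model$plv_mean, model$plv_sd), 0, 1)
  } else {
    stopifnot(f >= 0, f <= 1)
  }
  n_locked <- as.integer(round_half_away(f * annual_total))
  act <- template$active_days[template$active_days <= 365L]
  locked_days <- act[sample.int(length(act), n_locked, replace = TRUE)]
  free_days <- sample.int(365L, annual_total - n_locked, replace = TRUE)
  new_timecourse(tabulate(c(locked_days, free_days), nbins = 365L),
                 cycle_length = template$cycle_length,
                 allocated_fraction = f)
}

#' Assign cycling structure across a cohort
#'
#' Children's time-courses never cycle. Adults are split into non-cycling
#' (40%) and cycling (60%) groups, the cycling group allocated across the
#' 7/15/20/30-day periods at 20/17/30/33%. Allocation is exact-proportional:
#' each category receives the integer part of its expected count and any
#' remaining patients are assigned by a weighted random draw; the final
#' label vector is randomly permuted.
#'
#' @param n_patients cohort size (>= 1).
#' @param age_group `"children"` or `"adults"`.
#' @param model a [cycling_model()].
#' @return integer vector of length `n_patients`: `NA` for no cycling,
#'   otherwise the cycle length in days.
#' @export
assign_cohort_structure <- function(n_patients,
                                    age_group = c("children", "adults"),
                                    model = cycling_model()) {
  age_group <- match.arg(age_group)
  n_patients <- as.integer(n_patients)
  stopifnot(n_patients >= 1)
  if (age_group == "children") {
    return(rep(NA_integer_, n_patients))
  }
  lens <- as.integer(names(model$cycle_mixture))
  probs <- c(1 - model$prevalence, model$prevalence * model$cycle_mixture)
  labels <- c(NA_integer_, lens)
  target <- n_patients * probs
  base <- floor(target)
  short <- n_patients - sum(base)
  counts <- base
  if (short > 0) {
    frac <- target - base
    if (sum(frac) <= 0) frac <- probs
    extra <- sample.int(length(labels), short, replace = FALSE,
                        prob = frac / sum(frac))
    counts[extra] <- counts[extra] + 1
  }
  assignment <- rep(labels, times = counts)
  assignment[sample.int(n_patients)]
}

#' Extend a time-course beyond its current horizon
#'
#' Appends days generated by the same process as the original course: same
#' annual seizure rate, same realized phase-locked fraction, and — for
#' cycling courses — the cycle continued in phase from the day after the
#' current end. Internally a full 365-day block is generated and truncated
#' to `extra_days`, which preserves the per-day rate. Monitoring sessions
#' that run past the end of the simulated year use this to continue
#' observation rather than censoring.
#'
#' @param tc a `timecourse`.
#' @param extra_days days to append (>= 1).
#' @param model a [cycling_model()] (only consulted for its class; the
#'   realized fraction is reused).
#' @return extended `timecourse`; `annual_total` still refers to days 1-365.
#' @export
extend_timecourse <- function(tc, extra_days, model = cycling_model()) {
  stopifnot(inherits(tc, "timecourse"), extra_days >= 1)
  extra_days <- as.integer(extra_days)
  # extensions longer than a year proceed in yearly blocks
  while (extra_days > 365L) {
    tc <- extend_timecourse(tc, 365L, model)
    extra_days <- extra_days - 365L
  }
  cur <- length(tc$daily_counts)
  if (is.na(tc$cycle_length)) {
    days <- sample.int(365L, tc$annual_total, replace = TRUE)
  } else {
    tmpl <- build_cycle_template(tc$cycle_length, 365L,
                                 phase_offset = cur %% tc$cycle_length)
    f <- tc$allocated_fraction
    n_locked <- as.integer(round_half_away(f * tc$annual_total))
    act <- tmpl$active_days
    locked <- act[sample.int(length(act), n_locked, replace = TRUE)]
    days <- c(locked, sample.int(365L, tc$annual_total - n_locked,
                                 replace = TRUE))
  }
  block <- tabulate(days[days <= extra_days], nbins = extra_days)
  out <- tc
  out$daily_counts <- c(tc$daily_counts, as.integer(block))
  out
}
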