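# Independent oracles used by the test suite. Each deliberately takes a
# different computational path from the implementation it checks.

# Interval probabilities by numerical integration of the linearly
# interpolated density (quadrature route, vs the closed-form trapezoid
# weights in build_interval_table).
oracle_interval_probs <- function(breakpoints, densities) {
  f <- stats::approxfun(breakpoints, densities)
  n <- length(breakpoints) - 1L
  raw <- vapply(seq_len(n), function(i) {
    stats::integrate(f, breakpoints[i], breakpoints[i + 1],
                     rel.tol = 1e-10)$value
  }, numeric(1))
  raw / sum(raw)
}

# Exhaustive day-by-day scan: walk forward from the setup day, counting
# calendar days with >= 1 seizure; report days elapsed from setup when the
# k-th such day is found, NA if the counts vector runs out.
oracle_duration <- function(daily_counts, start_day, k) {
  seen <- 0L
  for (d in start_day:length(daily_counts)) {
    if (daily_counts[d] > 0) {
      seen <- seen + 1L
      if (seen == k) return(d - start_day)
    }
  }
  NA_integer_
}

# direct evaluation of the biased moment skewness, written independently
oracle_g1 <- function(x) {
  n <- length(x)
  xc <- x - sum(x) / n
  (sum(xc^3) / n) / (sum(xc^2) / n)^(3 / 2)
}

# MATLAB-prctile-convention quantile via explicit order statistics:
# plotting positions (i - 0.5) / n with linear interpolation, clamped.
oracle_prctile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  pos <- (seq_len(n) - 0.5) / n
  vapply(p, function(pp) {
    if (pp <= pos[1]) return(xs[1])
    if (pp >= pos[n]) return(xs[n])
    stats::approx(pos, xs, xout = pp)$y
  }, numeric(1))
}

# fixed-seizure-day toy course on a 365-day year
toy_course <- function(seizure_days, counts = NULL) {
  dc <- integer(365)
  if (is.null(counts)) counts <- rep(1L, length(seizure_days))
  dc[seizure_days] <- counts
  hvemsim:::new_timecourse(dc)
}
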