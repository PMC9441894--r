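#' Round half away from zero
#'
#' Rounding convention of MATLAB's `round`: ties go away from zero rather
#' than to the even digit (base R `round`). Used when converting the
#' phase-locked seizure fraction into a whole seizure count so that the
#' allocation matches the original simulation convention.
#'
#' @param x numeric vector.
#' @return numeric vector of rounded values.
#' @examples
#' round_half_away(c(0.5, 1.5, 2.5, -0.5))
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# clamp to [lo, hi]
clip <- function(x, lo = 0, hi = 1) pmin(hi, pmax(lo, x))

#' Derive independent stage seeds from a master seed
#'
#' Spawns reproducible child seeds so that each pipeline stage (annual-count
#' sampling, time-course generation, monitoring) consumes its own random
#' stream: enlarging one stage does not perturb the draws of another.
#'
#' @param seed master seed (single integer).
#' @param n number of child seeds.
#' @return integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(length(seed) == 1, is.finite(seed), length(n) == 1, n >= 1)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

# 32-bit FNV-1a hash of a character scalar, as 8 hex digits; used to stamp
# output files with a config fingerprint without external dependencies.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # h * 16777619 mod 2^32 in exact double arithmetic (split at 16 bits)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  # h < 2^32 may exceed integer range; format the two 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
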