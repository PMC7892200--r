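#' Derive a child RNG seed from a parent seed and labels
#'
#' Deterministically folds integer and character labels into a parent seed so
#' that every participant, session and pipeline stage draws from its own
#' reproducible stream. The result is always a positive integer below 2^31,
#' and is a pure function of its arguments.
#'
#' @param seed Parent integer seed.
#' @param ... Integer or character labels identifying the sub-stream.
#' @return A single integer seed.
#' @examples
#' derive_seed(1, "P01", 3)
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483629 # prime below 2^31; keeps products exact in doubles
  s <- as.numeric(seed) %% m
  for (part in list(...)) {
    codes <- if (is.character(part)) {
      unlist(lapply(part, function(p) as.numeric(utf8ToInt(p))))
    } else {
      as.numeric(part)
    }
    for (k in codes) {
      s <- (s * 69069 + (k %% m) * 7919 + 1) %% m
    }
  }
  as.integer(s %% (m - 1) + 1)
}

# Evaluate `expr` under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards.
with_rng <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Standard error of the mean.
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  sd(x) / sqrt(length(x))
}

# Sign multiplier making compensatory responses positive: -1 for positive
# perturbations, +1 for negative ones.
comp_mult <- function(pert_hz) {
  ifelse(pert_hz > 0, -1, 1)
}

#' Convert a windowed response in Hz to percent compensation
#'
#' Applies `response / |perturbation| * 100 * compMult`, where compMult is -1
#' for positive and +1 for negative perturbations, so that responses opposing
#' the perturbation are positive regardless of its direction.
#'
#' @param response_hz Mean normalized F1 response in Hz.
#' @param pert_hz Signed perturbation magnitude in Hz (non-zero).
#' @return Percent compensation (positive = opposing).
#' @examples
#' percent_compensation(-10, 200) # +5
#' @export
percent_compensation <- function(response_hz, pert_hz) {
  stopifnot(all(pert_hz != 0))
  response_hz / abs(pert_hz) * 100 * comp_mult(pert_hz)
}

# Cheap structural hash for provenance blocks (sum over serialized bytes).
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  v <- as.integer(raw)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
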