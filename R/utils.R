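# Internal helpers shared across modules.

#' @importFrom withr with_seed
NULL

# Evaluate `code` under a fixed RNG state without disturbing the caller's.
local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Stage offsets keep substreams distinct while remaining a pure function of
# the single cohort seed. Offsets are small so seed + offset stays < 2^31.
stage_seed <- function(seed, stage) {
  offset <- c(viability = 11L, expression = 23L, methylome = 37L,
              bootstrap = 53L, pipeline = 71L)[[stage]]
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}

# Welch two-sample t-test by the closed form, with explicit degenerate
# handling: zero pooled standard error gives t = 0, p = 1 for equal means
# and |t| = Inf, p = 0 otherwise (stats::t.test refuses constant data).
welch_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  dm <- mean(x) - mean(y)
  if (se2 == 0) {
    if (dm == 0) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = Inf * sign(dm), df = NA_real_, p = 0))
  }
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  t <- dm / sqrt(se2)
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

stopifnot_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a single finite number in [%s, %s]",
                 name, format(lo), format(hi)), call. = FALSE)
  invisible(x)
}

stopifnot_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}
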