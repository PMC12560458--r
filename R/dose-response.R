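#' DSS computation parameters
#'
#' @param activity_threshold Inhibition floor `t` in percent (default 10):
#'   only the response area above this level counts as drug activity.
#' @param ceiling Inhibition ceiling (100); responses are clipped here before
#'   integration.
#' @param variant `"dss1"` (default) normalizes the activity area by the full
#'   activity window `(100 - t) * (x2 - x1)`; `"dss2"` additionally divides
#'   by `log10(top)` (guarded to `top > 10`), kept for compatibility with the
#'   alternative score family.
#' @return A `dss_params` list.
#' @export
dss_params <- function(activity_threshold = 10, ceiling = 100,
                       variant = c("dss1", "dss2")) {
  stopifnot_scalar_number(activity_threshold, "activity_threshold", 0, 99.999)
  structure(list(t = activity_threshold, ceiling = ceiling,
                 variant = match.arg(variant)),
            class = "dss_params")
}

#' Normalize raw viability signals to percent inhibition
#'
#' Converts raw luminescence to inhibition relative to the plate controls:
#' `inhibition = 100 * (neg_mean - signal) / (neg_mean - pos_mean)`, where
#' the negative control (DMSO, full viability) defines 0% and the positive
#' control (full kill) defines 100%. Values are clipped to `[-25, 100]`:
#' mild growth stimulation is retained without letting it dominate fits.
#'
#' @param screen Well-level data frame as produced by
#'   [gen_viability_screen()] (columns `sample`, `drug`, `dose_index`,
#'   `concentration`, `signal`, `well_type`).
#' @return Data frame `sample`, `drug`, `dose_index`, `concentration`,
#'   `inhibition`, one row per drug well, plus per-sample control means as
#'   attribute `controls`.
#' @export
normalize_viability <- function(screen) {
  stopifnot(is.data.frame(screen),
            all(c("sample", "signal", "well_type") %in% names(screen)))
  ctrl <- do.call(rbind, lapply(split(screen, screen$sample), function(df) {
    neg <- mean(df$signal[df$well_type == "neg_ctrl"])
    pos <- mean(df$signal[df$well_type == "pos_ctrl"])
    if (!is.finite(neg) || !is.finite(pos))
      stop("sample '", df$sample[1], "': missing control wells",
           call. = FALSE)
    if (neg <= pos)
      stop("sample '", df$sample[1], "': degenerate controls ",
           "(negative-control mean <= positive-control mean)", call. = FALSE)
    data.frame(sample = df$sample[1], neg_mean = neg, pos_mean = pos,
               stringsAsFactors = FALSE)
  }))
  rownames(ctrl) <- ctrl$sample
  wells <- screen[screen$well_type == "drug", , drop = FALSE]
  neg <- ctrl[wells$sample, "neg_mean"]
  pos <- ctrl[wells$sample, "pos_mean"]
  out <- data.frame(
    sample = wells$sample, drug = wells$drug,
    dose_index = wells$dose_index, concentration = wells$concentration,
    inhibition = clamp(100 * (neg - wells$signal) / (neg - pos), -25, 100),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "controls") <- ctrl
  out
}

# Parameter box used by the 4PL fitter; m bounds depend on the tested range.
.fit_bounds <- function(x1, x2) {
  list(lower = c(bottom = -25, top = -25, m = x1 - 2, s = 1e-3),
       upper = c(bottom = 25, top = 120, m = x2 + 2, s = 10))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `y(x) = bottom + (top - bottom) / (1 + 10^(s * (m - x)))` with
#' `x = log10(concentration)` to percent-inhibition data. Parameters are
#' box-constrained (`bottom` in `[-25, 25]`, `top` in `[-25, 120]`, slope
#' `s` in `(0, 10]`, midpoint `m` within 2 log10 units of the tested range)
#' and the optimizer (Levenberg-Marquardt with bounds) is started from four
#' deterministic initializations; the best residual sum of squares wins.
#' Short series cannot support the full model: with only 3 distinct doses
#' the lower asymptote is pinned at 0, and with 2 the slope is additionally
#' pinned at 1.
#'
#' @param concentration Concentrations (same arbitrary unit across doses).
#' @param inhibition Percent inhibition at each concentration. Replicate
#'   measurements at the same concentration are averaged before fitting.
#' @return A `dose_response_fit` list: `bottom`, `top`, `m` (log10 EC50),
#'   `s`, `x1`, `x2` (log10 of the tested range), `rss`, `converged`.
#' @examples
#' x <- 10^(0:4)
#' y <- 80 / (1 + 10^(1 * (2 - log10(x))))
#' fit_4pl(x, y)
#' @export
fit_4pl <- function(concentration, inhibition) {
  stopifnot(length(concentration) == length(inhibition))
  ok <- is.finite(concentration) & is.finite(inhibition) & concentration > 0
  x <- log10(concentration[ok]); y <- inhibition[ok]
  if (length(unique(x)) < 2)
    stop("cannot fit a dose-response curve with fewer than 2 distinct doses",
         call. = FALSE)
  ## average replicates per dose
  if (anyDuplicated(x)) {
    y <- tapply(y, x, mean)
    x <- as.numeric(names(y)); y <- as.numeric(y)
  }
  o <- order(x); x <- x[o]; y <- y[o]
  x1 <- x[1]; x2 <- x[length(x)]
  b <- .fit_bounds(x1, x2)

  rng <- range(y)
  top0 <- clamp(rng[2], 0, 120)
  bot0 <- clamp(rng[1], -25, 25)
  ## m starts: where the response crosses half of its observed span, plus the
  ## grid midpoint; s starts shallow and steep
  half <- (rng[1] + rng[2]) / 2
  m_half <- if (any(y >= half) && any(y <= half))
    x[which.min(abs(y - half))] else (x1 + x2) / 2
  starts <- list(
    c(bottom = bot0, top = top0, m = m_half, s = 1),
    c(bottom = bot0, top = top0, m = (x1 + x2) / 2, s = 1),
    c(bottom = 0, top = top0, m = m_half, s = 3),
    c(bottom = 0, top = max(top0, 50), m = x1 + 0.75 * (x2 - x1), s = 0.5)
  )

  ## short series cannot support all 4 parameters: pin the lower asymptote
  ## at 0 for 3-point series, and additionally the slope at 1 for 2 points
  free <- switch(min(length(x), 4L) - 1L,
                 c(FALSE, TRUE, TRUE, FALSE),      # 2 points: top, m
                 c(FALSE, TRUE, TRUE, TRUE),       # 3 points: top, m, s
                 c(TRUE, TRUE, TRUE, TRUE),
                 c(TRUE, TRUE, TRUE, TRUE))
  fixed <- c(bottom = 0, top = NA, m = NA, s = 1)
  resid_fn <- function(pf) {
    p <- fixed; p[free] <- pf
    four_pl(x, p[1], p[2], p[3], p[4]) - y
  }
  best <- NULL
  for (p0 in starts) {
    p0 <- clamp(p0, b$lower, b$upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0[free], lower = b$lower[free],
                         upper = b$upper[free], fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 1000, maxfev = 10000,
                           ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (!is.finite(rss)) next
    if (is.null(best) || rss < best$rss) {
      p <- fixed; p[free] <- fit$par
      best <- list(par = p, rss = rss, info = fit$info)
    }
  }
  if (is.null(best)) {
    return(structure(list(bottom = NA_real_, top = NA_real_, m = NA_real_,
                          s = NA_real_, x1 = x1, x2 = x2, rss = NA_real_,
                          converged = FALSE),
                     class = "dose_response_fit"))
  }
  p <- best$par
  structure(list(bottom = unname(p[1]), top = unname(p[2]),
                 m = unname(p[3]), s = unname(p[4]),
                 x1 = x1, x2 = x2, rss = best$rss,
                 ## info 1-3: ftol/ptol criteria; 4: gradient criterion
                 converged = best$info %in% 1:4),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "4PL fit: bottom %.3g, top %.3g, log10 EC50 %.3g, slope %.3g (RSS %.3g%s)\n",
    x$bottom, x$top, x$m, x$s, x$rss,
    if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Drug Sensitivity Score of a fitted dose-response curve
#'
#' Integrates the clipped response `y_hat(x) = min(max(y(x), 0), 100)` above
#' the activity threshold `t` across the tested log10-concentration range and
#' normalizes by the full activity window:
#' `DSS = 100 * A / ((100 - t) * (x2 - x1))` with
#' `A = integral of max(0, y_hat(x) - t) dx` over `[x1, x2]`. The integral is
#' evaluated piecewise with the closed-form logistic antiderivative: the
#' curve is monotone in `x`, so the crossings with `t` and with the 0/100
#' clip levels are solved analytically and each sub-interval is either
#' constant or an exact logistic segment. Results are clamped to `[0, 100]`.
#' Non-converged fits score 0 (with a warning) so responder counts stay
#' conservative.
#'
#' @param fit A `dose_response_fit` (or a list with fields `bottom`, `top`,
#'   `m`, `s`, `x1`, `x2`, and optionally `converged`).
#' @param params A [dss_params()].
#' @return A single DSS value in `[0, 100]`.
#' @examples
#' fit <- list(bottom = 0, top = 80, m = 2, s = 1, x1 = 0, x2 = 4,
#'             converged = TRUE)
#' compute_dss(fit, dss_params())
#' @export
compute_dss <- function(fit, params = dss_params()) {
  stopifnot(inherits(params, "dss_params"))
  if (!is.null(fit$converged) && !isTRUE(fit$converged)) {
    warning("non-converged dose-response fit: DSS reported as 0")
    return(0)
  }
  if (!is.finite(fit$x1) || !is.finite(fit$x2) || fit$x1 >= fit$x2)
    stop("invalid integration range: x1 must be below x2", call. = FALSE)
  a <- dss_area(fit$bottom, fit$top, fit$m, fit$s, fit$x1, fit$x2,
                params$t, params$ceiling)
  dss <- 100 * a / ((100 - params$t) * (fit$x2 - fit$x1))
  if (identical(params$variant, "dss2")) {
    if (is.finite(fit$top) && fit$top > 10) dss <- dss / log10(fit$top)
    else dss <- 0
  }
  clamp(dss, 0, 100)
}

# Area of max(0, min(max(y, 0), ceiling) - t) over [x1, x2] for a monotone
# 4PL segment, via analytic breakpoints and the logistic antiderivative
# F(x) = bottom * x + (top - bottom)/(s * ln 10) * ln(1 + 10^(s (x - m))).
dss_area <- function(bottom, top, m, s, x1, x2, t, ceiling = 100) {
  if (!all(is.finite(c(bottom, top, m, s, x1, x2, t)))) return(0)
  if (abs(top - bottom) < 1e-12) {         # constant response
    y <- clamp(bottom, 0, ceiling)
    return(max(0, y - t) * (x2 - x1))
  }
  ## x where y(x) = level (unique, curve is strictly monotone for s > 0)
  crossing <- function(level) {
    f <- (top - bottom) / (level - bottom) - 1
    if (!is.finite(f) || f <= 0) return(NA_real_)
    m - log10(f) / s
  }
  br <- c(crossing(t), crossing(0), crossing(ceiling))
  br <- br[is.finite(br) & br > x1 & br < x2]
  pts <- sort(unique(c(x1, br, x2)))
  anti <- function(x) {
    ## log1p(10^u) computed stably for large |u|
    u <- s * log(10) * (x - m)
    l <- ifelse(u > 30, u, log1p(exp(u)))
    bottom * x + (top - bottom) / (s * log(10)) * l
  }
  total <- 0
  for (i in seq_len(length(pts) - 1)) {
    a <- pts[i]; b <- pts[i + 1]
    ymid <- four_pl((a + b) / 2, bottom, top, m, s)
    yclip <- clamp(ymid, 0, ceiling)
    if (yclip <= t) next
    if (ymid >= ceiling) total <- total + (ceiling - t) * (b - a)
    else if (ymid <= 0) next
    else total <- total + (anti(b) - anti(a)) - t * (b - a)
  }
  total
}

#' Assemble a drugs-by-samples DSS matrix
#'
#' @param values Data frame with columns `drug`, `sample`, `dss` (one row per
#'   screened drug/sample pair). Duplicate pairs must agree within `1e-9` or
#'   an error is raised; pairs never screened become `NA`.
#' @return Numeric matrix, rows = drugs, columns = samples.
#' @export
build_dss_matrix <- function(values) {
  stopifnot(is.data.frame(values),
            all(c("drug", "sample", "dss") %in% names(values)))
  if (nrow(values) == 0)
    return(matrix(numeric(0), 0, 0))
  key <- paste(values$drug, values$sample, sep = "\r")
  if (anyDuplicated(key)) {
    rng <- tapply(values$dss, key, function(v) diff(range(v)))
    if (any(rng > 1e-9, na.rm = TRUE))
      stop("conflicting DSS values for duplicate (drug, sample) pairs: ",
           paste(utils::head(sub("\r", " / ", names(rng)[which(rng > 1e-9)]), 3),
                 collapse = ", "), call. = FALSE)
    keep <- !duplicated(key)
    values <- values[keep, , drop = FALSE]
  }
  drugs <- sort(unique(values$drug))
  samples <- sort(unique(values$sample))
  mat <- matrix(NA_real_, length(drugs), length(samples),
                dimnames = list(drugs, samples))
  mat[cbind(match(values$drug, drugs), match(values$sample, samples))] <-
    values$dss
  mat
}

#' Compute the full DSS matrix from a raw viability screen
#'
#' Runs the whole scoring chain: control normalization, per-(sample, drug)
#' 4PL fit, DSS integration, matrix assembly.
#'
#' @param screen Well-level screen data frame (see [normalize_viability()]).
#' @param params A [dss_params()].
#' @return List with `dss` (drugs x samples matrix) and `fits` (data frame of
#'   fitted parameters per drug/sample, including the convergence flag).
#' @export
dss_matrix_from_screen <- function(screen, params = dss_params()) {
  inh <- normalize_viability(screen)
  grp <- split(inh, list(inh$sample, inh$drug), drop = TRUE)
  fits <- do.call(rbind, lapply(grp, function(df) {
    fit <- fit_4pl(df$concentration, df$inhibition)
    dss <- withCallingHandlers(
      compute_dss(fit, params),
      warning = function(w) invokeRestart("muffleWarning"))
    data.frame(sample = df$sample[1], drug = df$drug[1],
               bottom = fit$bottom, top = fit$top, m = fit$m, s = fit$s,
               x1 = fit$x1, x2 = fit$x2, rss = fit$rss,
               converged = fit$converged, dss = dss,
               stringsAsFactors = FALSE)
  }))
  rownames(fits) <- NULL
  n_bad <- sum(!fits$converged)
  if (n_bad > 0)
    warning(n_bad, " dose-response fits did not converge; their DSS is 0")
  list(dss = build_dss_matrix(fits), fits = fits)
}

#' DSS matrix from planted true curve parameters
#'
#' Evaluates the DSS integral directly on the true 4PL parameters of a
#' synthetic cohort (no fitting), which is both the noiseless reference for
#' end-to-end checks and a fast route to a cohort-scale DSS matrix.
#'
#' @param truth Truth data frame from [gen_viability_screen()].
#' @param params A [dss_params()].
#' @return Drugs x samples DSS matrix.
#' @export
dss_from_truth <- function(truth, params = dss_params()) {
  dss <- vapply(seq_len(nrow(truth)), function(i) {
    100 * dss_area(truth$bottom[i], truth$top[i], truth$m[i], truth$s[i],
                   truth$x1[i], truth$x2[i], params$t, params$ceiling) /
      ((100 - params$t) * (truth$x2[i] - truth$x1[i]))
  }, 0)
  build_dss_matrix(data.frame(drug = truth$drug, sample = truth$sample,
                              dss = clamp(dss, 0, 100),
                              stringsAsFactors = FALSE))
}
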