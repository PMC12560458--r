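#' Simulate a multi-dose viability screen with planted group structure
#'
#' Generates raw luminescence wells for every culture in the cohort: for each
#' drug a 5-point (by default) ten-fold dose escalation series plus shared
#' negative (DMSO-like, full viability) and positive (full-kill) control
#' wells. Each drug is either "active" in a group — its true dose response is
#' a four-parameter logistic (4PL) curve with a high top asymptote — or
#' inactive (top = 0, wells sit at the negative-control level). Resistant
#' cultures receive a smaller fraction of active drugs than sensitive ones,
#' which is the planted signal every downstream classification stage must
#' recover.
#'
#' Raw well signal is
#' `neg_mean - (neg_mean - pos_mean) * y_true(x) / 100` multiplied by
#' lognormal noise with coefficient of variation `viability_cv` (mean 1), so
#' `viability_cv = 0` reproduces the true curve exactly.
#'
#' @param config A [cohort_config()].
#' @return A list with components:
#'   \describe{
#'     \item{screen}{data frame of wells with columns `sample`, `drug`,
#'       `dose_index`, `concentration`, `signal`, `well_type`
#'       (`drug` / `neg_ctrl` / `pos_ctrl`); control wells carry `NA` drug
#'       and dose fields.}
#'     \item{truth}{data frame of true per-drug-per-sample 4PL parameters
#'       (`bottom`, `top`, `m` = log10 EC50, `s` slope, `x1`, `x2` = log10 of
#'       the tested range, `active`, `group`).}
#'     \item{groups}{named character vector sample -> group.}
#'   }
#' @examples
#' sim <- gen_viability_screen(cohort_config(n_drugs = 10, seed = 7))
#' head(sim$screen)
#' @export
gen_viability_screen <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  samples <- cohort_samples(cfg)
  groups <- cohort_groups(cfg)
  drugs <- sprintf("D%04d", seq_len(cfg$n_drugs))

  local_seed(stage_seed(cfg$seed, "viability"), {
    ## per-drug dose grid: anchor log10 concentration randomized, 10-fold steps
    x1 <- stats::runif(cfg$n_drugs, -3, 0)
    x2 <- x1 + (cfg$doses_per_drug - 1)          # log10 units
    ## drug-level base curve shape
    base_m <- x1 + stats::runif(cfg$n_drugs, 1, cfg$doses_per_drug - 2)
    base_s <- stats::runif(cfg$n_drugs, 0.6, 2)
    base_top <- stats::runif(cfg$n_drugs, 60, 100)
    ## per-group activity
    active_sens <- stats::runif(cfg$n_drugs) < cfg$frac_active_drugs_sensitive
    active_res <- stats::runif(cfg$n_drugs) < cfg$frac_active_drugs_resistant

    truth <- do.call(rbind, lapply(seq_along(samples), function(si) {
      grp <- groups[[si]]
      active <- if (grp == "sensitive") active_sens else active_res
      ## mild per-sample jitter of the curve; part of the planted truth
      m <- base_m + stats::rnorm(cfg$n_drugs, 0, 0.15)
      top <- ifelse(active,
                    clamp(base_top + stats::rnorm(cfg$n_drugs, 0, 5), 50, 100),
                    0)
      data.frame(sample = samples[si], drug = drugs, group = grp,
                 bottom = 0, top = top, m = m, s = base_s,
                 x1 = x1, x2 = x2, active = active,
                 stringsAsFactors = FALSE)
    }))

    ## optional missing-data injection: drop whole drug x sample series
    if (cfg$missing_fraction > 0) {
      drop <- stats::runif(nrow(truth)) < cfg$missing_fraction
      truth <- truth[!drop, , drop = FALSE]
    }

    ## drug wells
    x <- truth$x1[rep(seq_len(nrow(truth)), each = cfg$doses_per_drug)] +
      rep(seq_len(cfg$doses_per_drug) - 1, nrow(truth))
    idx <- rep(seq_len(nrow(truth)), each = cfg$doses_per_drug)
    y_true <- four_pl(x, truth$bottom[idx], truth$top[idx],
                      truth$m[idx], truth$s[idx])
    mean_signal <- cfg$neg_mean - (cfg$neg_mean - cfg$pos_mean) * y_true / 100
    wells <- data.frame(
      sample = truth$sample[idx],
      drug = truth$drug[idx],
      dose_index = rep(seq_len(cfg$doses_per_drug), nrow(truth)),
      concentration = 10^x,
      signal = mean_signal * lognormal_noise(length(x), cfg$viability_cv),
      well_type = "drug",
      stringsAsFactors = FALSE
    )

    ## shared control wells per sample plate
    ctrl <- do.call(rbind, lapply(samples, function(s) {
      n <- cfg$n_ctrl_wells
      data.frame(
        sample = s, drug = NA_character_, dose_index = NA_integer_,
        concentration = NA_real_,
        signal = c(cfg$neg_mean * lognormal_noise(n, cfg$viability_cv),
                   cfg$pos_mean * lognormal_noise(n, cfg$viability_cv)),
        well_type = rep(c("neg_ctrl", "pos_ctrl"), each = n),
        stringsAsFactors = FALSE
      )
    }))

    list(screen = rbind(wells, ctrl),
         truth = truth,
         groups = groups)
  })
}

# 4PL on the log10-concentration axis; increasing in x for s > 0, top > bottom.
four_pl <- function(x, bottom, top, m, s) {
  bottom + (top - bottom) / (1 + 10^(s * (m - x)))
}

# Multiplicative lognormal noise with mean 1 and coefficient of variation cv.
lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Write a viability screen to CSV
#'
#' Columns: `sample, drug, dose_index, concentration, signal, well_type`.
#' @param screen The `screen` data frame from [gen_viability_screen()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_viability_csv <- function(screen, path) {
  utils::write.csv(screen, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a viability screen CSV
#' @param path CSV written by [write_viability_csv()].
#' @return The screen data frame.
#' @export
read_viability_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(sample = "character",
                                       drug = "character",
                                       well_type = "character"))
  need <- c("sample", "drug", "dose_index", "concentration", "signal",
            "well_type")
  if (!all(need %in% names(df)))
    stop("viability CSV is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  df$drug[df$drug == ""] <- NA_character_
  df
}
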