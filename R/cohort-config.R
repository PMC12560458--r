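#' Configuration of a synthetic GSC screening cohort
#'
#' Defines the study conditions emulated by the synthetic-data generators:
#' cohort composition (drug-sensitive and drug-resistant culture counts),
#' screen geometry (drug panel size, 5-point ten-fold dose escalation,
#' control wells), planted effect sizes for each molecular modality, and the
#' noise model parameters. The defaults mirror the screening design the
#' package targets: 4 sensitive and 5 resistant cultures screened against a
#' panel of 329 drugs shared across all cultures, with luminescence read-out
#' normalized between DMSO (negative) and benzethonium chloride (positive)
#' control wells.
#'
#' @param n_sensitive,n_resistant Number of drug-sensitive / drug-resistant
#'   cultures (samples). Defaults 4 and 5.
#' @param n_drugs Size of the drug panel screened in every sample (default
#'   329, the panel shared across the full cohort).
#' @param doses_per_drug Doses per drug in the escalation series (default 5,
#'   ten-fold spacing).
#' @param n_genes Genes in the synthetic expression matrix.
#' @param n_islands CpG islands on the synthetic chromosome.
#' @param seed Integer seed; identical configuration and seed give
#'   byte-identical outputs.
#' @param frac_active_drugs_sensitive,frac_active_drugs_resistant Proportion
#'   of panel drugs that elicit a true dose response in each group. The
#'   resistant fraction must not exceed the sensitive fraction for the
#'   planted structure to point the documented way.
#' @param stemness_log2fc Planted log2 fold change of stemness-panel genes in
#'   resistant cultures (default 1).
#' @param subtype_log2fc Planted log2 fold change separating the proneural
#'   (up in sensitive) and mesenchymal (up in resistant) panels.
#' @param dm_island_fraction Fraction of islands with a planted group
#'   methylation difference.
#' @param dm_delta Planted between-group difference in island mean
#'   methylation, percentage points in `[0, 100]`.
#' @param viability_cv Coefficient of variation of the multiplicative
#'   lognormal well noise (0 = noiseless).
#' @param nb_dispersion Negative-binomial dispersion of the count generator
#'   (variance = mu + dispersion * mu^2; 0 gives the Poisson limit).
#' @param meth_beta_precision Precision (a + b) of the per-site Beta draws
#'   around an island's mean methylation; `Inf` makes every site equal the
#'   island mean.
#' @param n_ctrl_wells Negative and positive control wells per plate
#'   (default 16 each).
#' @param neg_mean,pos_mean Expected raw luminescence of the negative
#'   (DMSO, full viability) and positive (full kill) controls; must satisfy
#'   `neg_mean > pos_mean`.
#' @param missing_fraction Fraction of drug-by-sample series dropped at
#'   random to emulate incomplete screening (default 0).
#' @param coverage_mean,coverage_floor Mean and floor of per-site nanopore
#'   read coverage (coverage = floor + negative-binomial draw).
#'
#' @return An object of class `cohort_config` (a validated named list).
#' @examples
#' cfg <- cohort_config(seed = 1)
#' cfg$n_drugs
#' @export
cohort_config <- function(n_sensitive = 4L,
                          n_resistant = 5L,
                          n_drugs = 329L,
                          doses_per_drug = 5L,
                          n_genes = 2000L,
                          n_islands = 500L,
                          seed = 1L,
                          frac_active_drugs_sensitive = 0.25,
                          frac_active_drugs_resistant = 0.08,
                          stemness_log2fc = 1,
                          subtype_log2fc = 1,
                          dm_island_fraction = 0.05,
                          dm_delta = 30,
                          viability_cv = 0.1,
                          nb_dispersion = 0.1,
                          meth_beta_precision = 50,
                          n_ctrl_wells = 16L,
                          neg_mean = 1e5,
                          pos_mean = 2e3,
                          missing_fraction = 0,
                          coverage_mean = 15,
                          coverage_floor = 1L) {
  cfg <- list(
    n_sensitive = stopifnot_count(n_sensitive, "n_sensitive"),
    n_resistant = stopifnot_count(n_resistant, "n_resistant"),
    n_drugs = stopifnot_count(n_drugs, "n_drugs"),
    doses_per_drug = stopifnot_count(doses_per_drug, "doses_per_drug", min = 2L),
    n_genes = stopifnot_count(n_genes, "n_genes"),
    n_islands = stopifnot_count(n_islands, "n_islands"),
    seed = stopifnot_count(seed, "seed", min = 0L),
    frac_active_drugs_sensitive =
      stopifnot_scalar_number(frac_active_drugs_sensitive,
                              "frac_active_drugs_sensitive", 0, 1),
    frac_active_drugs_resistant =
      stopifnot_scalar_number(frac_active_drugs_resistant,
                              "frac_active_drugs_resistant", 0, 1),
    stemness_log2fc = stopifnot_scalar_number(stemness_log2fc,
                                              "stemness_log2fc"),
    subtype_log2fc = stopifnot_scalar_number(subtype_log2fc, "subtype_log2fc"),
    dm_island_fraction = stopifnot_scalar_number(dm_island_fraction,
                                                 "dm_island_fraction", 0, 1),
    dm_delta = stopifnot_scalar_number(dm_delta, "dm_delta", 0, 100),
    viability_cv = stopifnot_scalar_number(viability_cv, "viability_cv", 0),
    nb_dispersion = stopifnot_scalar_number(nb_dispersion, "nb_dispersion", 0),
    meth_beta_precision = if (identical(meth_beta_precision, Inf)) Inf else
      stopifnot_scalar_number(meth_beta_precision, "meth_beta_precision", 1e-6),
    n_ctrl_wells = stopifnot_count(n_ctrl_wells, "n_ctrl_wells", min = 2L),
    neg_mean = stopifnot_scalar_number(neg_mean, "neg_mean", 0),
    pos_mean = stopifnot_scalar_number(pos_mean, "pos_mean", 0),
    missing_fraction = stopifnot_scalar_number(missing_fraction,
                                               "missing_fraction", 0, 1),
    coverage_mean = stopifnot_scalar_number(coverage_mean, "coverage_mean", 0),
    coverage_floor = stopifnot_count(coverage_floor, "coverage_floor", min = 1L)
  )
  if (cfg$pos_mean >= cfg$neg_mean)
    stop("invalid cohort_config: positive-control mean must be below the ",
         "negative-control mean (pos_mean < neg_mean)", call. = FALSE)
  if (cfg$frac_active_drugs_resistant > cfg$frac_active_drugs_sensitive)
    stop("invalid cohort_config: frac_active_drugs_resistant must not ",
         "exceed frac_active_drugs_sensitive", call. = FALSE)
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  samples: %d sensitive + %d resistant\n",
              x$n_sensitive, x$n_resistant))
  cat(sprintf("  screen:  %d drugs x %d doses (10-fold), CV = %g\n",
              x$n_drugs, x$doses_per_drug, x$viability_cv))
  cat(sprintf("  expression: %d genes, stemness log2FC = %g\n",
              x$n_genes, x$stemness_log2fc))
  cat(sprintf("  methylome: %d islands, DM fraction = %g, delta = %g%%\n",
              x$n_islands, x$dm_island_fraction, x$dm_delta))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Sample identifiers: sensitive cultures sort before resistant ones so the
# documented lexicographic tie-break in rankings is exercised predictably.
cohort_samples <- function(cfg) {
  c(sprintf("GSC_S%02d", seq_len(cfg$n_sensitive)),
    sprintf("GSC_R%02d", seq_len(cfg$n_resistant)))
}

cohort_groups <- function(cfg) {
  stats::setNames(rep(c("sensitive", "resistant"),
                      c(cfg$n_sensitive, cfg$n_resistant)),
                  cohort_samples(cfg))
}
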