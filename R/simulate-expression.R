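#' Simulate an RNA-seq count matrix with planted stemness and subtype shifts
#'
#' Draws negative-binomial counts (variance `mu + dispersion * mu^2`) for
#' `n_genes` genes over the cohort. Three gene panels carry planted
#' between-group structure:
#' \itemize{
#'   \item a 34-gene stemness panel whose mean is multiplied by
#'     `2^stemness_log2fc` in resistant cultures;
#'   \item a proneural (PN) panel shifted up in sensitive cultures and a
#'     mesenchymal (MES) panel shifted up in resistant cultures, each by
#'     `2^subtype_log2fc`.
#' }
#' The panels are returned as named gene sets ready for [write_gmt()].
#'
#' @param config A [cohort_config()].
#' @return A list with `counts` (genes x samples integer matrix), `genesets`
#'   (named list of gene symbol vectors: `stemness`, `PN`, `MES`), `truth`
#'   (per-gene planted log2 fold change, resistant vs sensitive) and
#'   `groups`.
#' @examples
#' sim <- gen_expression_matrix(cohort_config(n_genes = 200, seed = 3))
#' dim(sim$counts)
#' @export
gen_expression_matrix <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  n_stem <- 34L; n_pn <- 28L; n_mes <- 27L
  if (cfg$n_genes < n_stem + n_pn + n_mes)
    stop("n_genes too small to host the stemness and subtype panels (need >= ",
         n_stem + n_pn + n_mes, ")", call. = FALSE)
  samples <- cohort_samples(cfg)
  groups <- cohort_groups(cfg)
  genes <- sprintf("GENE%05d", seq_len(cfg$n_genes))

  local_seed(stage_seed(cfg$seed, "expression"), {
    panel_idx <- sample.int(cfg$n_genes, n_stem + n_pn + n_mes)
    stem_idx <- panel_idx[seq_len(n_stem)]
    pn_idx <- panel_idx[n_stem + seq_len(n_pn)]
    mes_idx <- panel_idx[n_stem + n_pn + seq_len(n_mes)]

    base_mu <- 2^stats::runif(cfg$n_genes, 2, 10)
    ## baseline-match the two subtype panels: the planted opposite shifts,
    ## not panel composition, must drive the PN/MES enrichment contrast
    panel_mu <- 2^stats::runif(max(n_pn, n_mes), 4, 9)
    base_mu[pn_idx] <- panel_mu[seq_len(n_pn)]
    base_mu[mes_idx] <- panel_mu[seq_len(n_mes)]
    ## planted shifts: stemness up in resistant; PN panel up in sensitive,
    ## MES panel up in resistant (each relative to its own baseline)
    lfc_res <- numeric(cfg$n_genes)   # applied to resistant samples
    lfc_sens <- numeric(cfg$n_genes)  # applied to sensitive samples
    lfc_res[stem_idx] <- cfg$stemness_log2fc
    lfc_sens[pn_idx] <- cfg$subtype_log2fc
    lfc_res[mes_idx] <- cfg$subtype_log2fc
    lfc <- lfc_res - lfc_sens         # net resistant-vs-sensitive log2 FC

    mu <- base_mu %o% rep(1, length(samples))
    res <- groups == "resistant"
    mu[, res] <- mu[, res] * 2^lfc_res
    mu[, !res] <- mu[, !res] * 2^lfc_sens

    counts <- matrix(
      if (cfg$nb_dispersion > 0)
        stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
      else
        stats::rpois(length(mu), lambda = mu),
      nrow = cfg$n_genes, dimnames = list(genes, samples)
    )

    list(counts = counts,
         genesets = list(stemness = genes[sort(stem_idx)],
                         PN = genes[sort(pn_idx)],
                         MES = genes[sort(mes_idx)]),
         truth = data.frame(gene = genes, log2fc = lfc,
                            stringsAsFactors = FALSE),
         groups = groups)
  })
}
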