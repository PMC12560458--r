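#' Normalize an RNA-seq count matrix
#'
#' Library-size normalization to log2 counts-per-million:
#' `log2(count / library_size * 1e6 + 1)`. The downstream scores (rank
#' z-scores, ssGSEA) are rank-based and depend only weakly on the variance
#' stabilizer, so this light-weight transform is the default; the mode used
#' is recorded in the `normalization` attribute.
#'
#' @param counts Non-negative genes x samples matrix.
#' @return Normalized matrix with attribute `normalization = "log2cpm"`.
#' @export
normalize_expression <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0, na.rm = TRUE))
  libsize <- colSums(counts)
  if (any(libsize == 0))
    stop("sample(s) with zero library size: ",
         paste(colnames(counts)[libsize == 0], collapse = ", "),
         call. = FALSE)
  out <- log2(sweep(counts, 2, libsize, "/") * 1e6 + 1)
  attr(out, "normalization") <- "log2cpm"
  out
}

#' Rank-normalized per-gene z-scores across samples
#'
#' For each gene, values are replaced by their ranks across samples (average
#' ranks for ties) and the ranks are standardized to mean 0, standard
#' deviation 1. Constant genes cannot be ranked informatively and become an
#' all-zero row (with a warning). Because only ranks enter, any monotone
#' per-gene transform of the input leaves the result unchanged.
#'
#' @param norm_expr Normalized genes x samples matrix (>= 2 samples).
#' @return Matrix of the same shape; non-constant rows have exact mean 0 and
#'   sd 1.
#' @export
gene_zscores <- function(norm_expr) {
  stopifnot(is.matrix(norm_expr), ncol(norm_expr) >= 2)
  z <- t(apply(norm_expr, 1, function(v) {
    r <- rank(v, ties.method = "average")
    s <- stats::sd(r)
    if (s == 0) rep(0, length(v)) else (r - mean(r)) / s
  }))
  dimnames(z) <- dimnames(norm_expr)
  n_const <- sum(apply(norm_expr, 1, function(v) length(unique(v)) == 1))
  if (n_const > 0)
    warning(n_const, " constant genes mapped to all-zero z-rows")
  z
}

#' Gene-set score from rank-normalized z-scores
#'
#' Summarizes a gene panel (e.g. the 34-gene stemness panel) per group: each
#' group's score is the sum over panel genes of the group-mean z-score
#' (`score_fun = "mean"` averages instead). Because every gene's z-row is
#' centered across samples, the two group scores weighted by group size sum
#' to zero gene-by-gene, making the score a signed contrast between groups.
#' A Welch t-test on the per-sample mean z over the panel tests the group
#' difference.
#'
#' @param z Matrix from [gene_zscores()].
#' @param geneset Character vector of gene symbols; members absent from the
#'   matrix are dropped with a warning.
#' @param labels Data frame `sample`, `group` covering the matrix columns.
#' @param score_fun `"sum"` (default) or `"mean"` over panel genes.
#' @return List: `group_scores` (named numeric), `sample_scores` (per-sample
#'   mean z over the panel), `welch` (list `t`, `df`, `p`), `n_genes_used`.
#' @export
set_score <- function(z, geneset, labels, score_fun = c("sum", "mean")) {
  score_fun <- match.arg(score_fun)
  stopifnot(is.matrix(z), is.character(geneset))
  present <- intersect(geneset, rownames(z))
  if (length(present) == 0)
    stop("no gene of the set is present in the matrix", call. = FALSE)
  if (length(present) < length(geneset))
    warning(length(geneset) - length(present),
            " set genes absent from the matrix were dropped")
  zs <- z[present, labels$sample, drop = FALSE]
  groups <- split(labels$sample, labels$group)
  group_scores <- vapply(groups, function(ss) {
    gm <- rowMeans(zs[, ss, drop = FALSE])
    if (score_fun == "sum") sum(gm) else mean(gm)
  }, 0)
  sample_scores <- colMeans(zs)
  welch <- if (length(groups) == 2 && all(lengths(groups) >= 2))
    welch_test(sample_scores[groups[[1]]], sample_scores[groups[[2]]])
  else NULL
  list(group_scores = group_scores, sample_scores = sample_scores,
       welch = welch, n_genes_used = length(present))
}

#' ssGSEA configuration
#'
#' @param alpha Rank weight exponent (default 0.75, the original single-
#'   sample enrichment convention).
#' @return An `ssgsea_config` list.
#' @export
ssgsea_config <- function(alpha = 0.75) {
  stopifnot_scalar_number(alpha, "alpha", 0)
  structure(list(alpha = alpha), class = "ssgsea_config")
}

#' Single-sample gene set enrichment score
#'
#' Per sample, genes are ordered by decreasing normalized expression (ties
#' broken deterministically by gene symbol) and assigned rank values
#' `N, N-1, ..., 1`. Walking down the ordering, the enrichment score is the
#' summed difference between the weighted in-set empirical CDF (weights
#' `rank_value^alpha`) and the unweighted out-of-set ECDF, normalized by the
#' number of out-of-set genes:
#' `ES = sum_i (P_in(i) - P_out(i)) / (N - n_set)`.
#' With `alpha = 0` the score depends on ranks only, so any strictly
#' increasing transform of one sample's values leaves its ES unchanged.
#'
#' @param norm_expr Normalized genes x samples matrix.
#' @param geneset Gene symbols; must intersect the matrix genes and must not
#'   cover the whole universe.
#' @param config An [ssgsea_config()].
#' @return Named per-sample numeric vector of enrichment scores.
#' @export
ssgsea_score <- function(norm_expr, geneset, config = ssgsea_config()) {
  stopifnot(is.matrix(norm_expr))
  genes <- rownames(norm_expr)
  in_set <- genes %in% geneset
  if (!any(in_set))
    stop("gene set does not intersect the expression matrix", call. = FALSE)
  if (all(in_set))
    stop("gene set covers the whole universe; out-of-set ECDF undefined",
         call. = FALSE)
  n <- length(genes); n_out <- sum(!in_set)
  vapply(seq_len(ncol(norm_expr)), function(j) {
    v <- norm_expr[, j]
    ord <- order(-v, genes)                    # descending, symbol tie-break
    rank_value <- n - seq_len(n) + 1           # N at the top of the list
    w <- ifelse(in_set[ord], abs(rank_value)^config$alpha, 0)
    p_in <- cumsum(w) / sum(w)
    p_out <- cumsum(!in_set[ord]) / n_out
    sum(p_in - p_out) / n_out
  }, 0) |> stats::setNames(colnames(norm_expr))
}

#' Call the transcriptional subtype from paired enrichment scores
#'
#' Each sample is labeled by the larger of its proneural and mesenchymal
#' enrichment scores; an exact tie yields `"ambiguous"` with a warning. The
#' signed margin `es_pn - es_mes` is reported alongside.
#'
#' @param es_pn,es_mes Named per-sample enrichment scores for the PN and MES
#'   signatures (same samples).
#' @return Data frame `sample`, `subtype`, `es_pn`, `es_mes`, `margin`.
#' @export
classify_subtype <- function(es_pn, es_mes) {
  stopifnot(length(es_pn) == length(es_mes),
            setequal(names(es_pn), names(es_mes)))
  es_mes <- es_mes[names(es_pn)]
  subtype <- ifelse(es_pn > es_mes, "PN",
                    ifelse(es_mes > es_pn, "MES", "ambiguous"))
  if (any(subtype == "ambiguous"))
    warning("exact enrichment-score tie in: ",
            paste(names(es_pn)[subtype == "ambiguous"], collapse = ", "))
  data.frame(sample = names(es_pn), subtype = unname(subtype),
             es_pn = unname(es_pn), es_mes = unname(es_mes),
             margin = unname(es_pn - es_mes),
             stringsAsFactors = FALSE)
}

#' Hypergeometric over-representation of a gene list
#'
#' For each gene set, tests whether the differentially expressed list
#' overlaps the set more than chance: with universe size `N`, set size `K`
#' (after intersection with the universe), list size `n` and overlap `k`,
#' the upper-tail p-value is `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#' P-values are Benjamini-Hochberg adjusted across sets.
#'
#' @param de_genes Differentially expressed gene symbols (must be a subset of
#'   `universe`; entries outside it raise an error).
#' @param universe All assayed gene symbols.
#' @param genesets Named list of gene-symbol vectors.
#' @return Data frame `set`, `set_size`, `overlap`, `p`, `padj`, ordered by
#'   increasing p.
#' @export
ora_hypergeometric <- function(de_genes, universe, genesets) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  de_genes <- unique(de_genes)
  if (!all(de_genes %in% universe))
    stop("differentially expressed genes outside the universe: ",
         paste(utils::head(setdiff(de_genes, universe), 3), collapse = ", "),
         call. = FALSE)
  n_univ <- length(universe); n_de <- length(de_genes)
  rows <- lapply(names(genesets), function(nm) {
    set <- intersect(unique(genesets[[nm]]), universe)
    k <- length(intersect(set, de_genes))
    p <- stats::phyper(k - 1, length(set), n_univ - length(set), n_de,
                       lower.tail = FALSE)
    data.frame(set = nm, set_size = length(set), overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p, out$set), , drop = FALSE]
}
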