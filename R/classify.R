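#' Configuration for resistance classification
#'
#' @param responder_threshold DSS level at and above which a drug counts as
#'   eliciting a moderate-to-high response (default 10; the comparison is
#'   inclusive, `DSS >= 10`).
#' @param n_clusters Number of groups to cut the dendrogram into (default 2:
#'   resistant vs sensitive).
#' @param bootstrap_b Multiscale bootstrap replicates per scale (default
#'   10000).
#' @param scales Relative resampling sizes `r` (default 0.5 to 1.4 in steps
#'   of 0.1); at scale `r` the bootstrap draws `round(r * n_drugs)` drugs
#'   with replacement.
#' @param seed Seed for the bootstrap resampling.
#' @return A `classification_config` list.
#' @export
classification_config <- function(responder_threshold = 10,
                                  n_clusters = 2L,
                                  bootstrap_b = 10000L,
                                  scales = seq(0.5, 1.4, by = 0.1),
                                  seed = 1L) {
  stopifnot_scalar_number(responder_threshold, "responder_threshold", 1e-9)
  stopifnot(is.numeric(scales), all(scales > 0))
  structure(list(responder_threshold = responder_threshold,
                 n_clusters = stopifnot_count(n_clusters, "n_clusters", 2L),
                 bootstrap_b = stopifnot_count(bootstrap_b, "bootstrap_b"),
                 scales = as.numeric(scales),
                 seed = stopifnot_count(seed, "seed", 0L)),
            class = "classification_config")
}

#' Count responder drugs per culture
#'
#' A drug is a responder in a culture when its DSS is at or above the
#' threshold (inclusive). Cultures are ranked by descending count; ties are
#' broken by lexicographic sample id, so the ranking is deterministic.
#'
#' @param dss Drugs x samples DSS matrix (missing entries allowed; they never
#'   count).
#' @param config A [classification_config()].
#' @return Data frame `sample`, `responders`, `rank`, ordered by rank.
#' @export
count_responders <- function(dss, config = classification_config()) {
  stopifnot(is.matrix(dss), ncol(dss) >= 1)
  counts <- colSums(dss >= config$responder_threshold, na.rm = TRUE)
  ord <- order(-counts, colnames(dss))
  data.frame(sample = colnames(dss)[ord],
             responders = as.integer(counts[ord]),
             rank = seq_along(ord),
             stringsAsFactors = FALSE)
}

#' Center a DSS matrix per drug
#'
#' Subtracts from each entry the mean DSS of that drug across all screened
#' cultures, so each drug contributes its deviation from the cohort-average
#' response. Centering (rather than division by the mean) is used as the
#' pre-clustering normalization; drugs with no observed value are dropped
#' with a warning.
#'
#' @param dss Drugs x samples DSS matrix.
#' @return Matrix of the same shape with exactly zero per-drug mean.
#' @export
normalize_dss <- function(dss) {
  stopifnot(is.matrix(dss))
  all_missing <- rowSums(!is.na(dss)) == 0
  if (any(all_missing)) {
    warning(sum(all_missing), " drugs with no observed DSS dropped")
    dss <- dss[!all_missing, , drop = FALSE]
  }
  dss - rowMeans(dss, na.rm = TRUE)
}

#' Restrict a DSS matrix to drugs screened in every listed culture
#'
#' @param dss Drugs x samples DSS matrix.
#' @param samples Cultures that must all have an observed value (default: all
#'   columns).
#' @return The submatrix (columns reduced to `samples`) containing only
#'   complete drugs; the retained drug count is attached as attribute
#'   `n_common`.
#' @export
restrict_common <- function(dss, samples = colnames(dss)) {
  stopifnot(is.matrix(dss), length(samples) >= 1,
            all(samples %in% colnames(dss)))
  sub <- dss[, samples, drop = FALSE]
  keep <- rowSums(is.na(sub)) == 0
  if (!any(keep))
    stop("no drug was screened in every listed culture", call. = FALSE)
  out <- sub[keep, , drop = FALSE]
  attr(out, "n_common") <- sum(keep)
  out
}

#' Cluster cultures into resistant and sensitive groups
#'
#' Agglomerative hierarchical clustering (Ward.D2 linkage on Euclidean
#' distances between culture columns) of the per-drug centered DSS matrix,
#' cut into `n_clusters` groups. With two groups, the cluster whose cultures
#' respond to fewer drugs on average (lower mean responder count) is labeled
#' `"resistant"`, the other `"sensitive"` — a deterministic restatement of
#' the by-inspection labeling of ranked screens.
#'
#' @param centered Per-drug centered DSS matrix ([normalize_dss()]), complete
#'   (no `NA`; apply [restrict_common()] first).
#' @param responders Responder counts from [count_responders()] computed on
#'   the uncentered matrix.
#' @param config A [classification_config()].
#' @return List with `hclust` (the dendrogram), `labels` (data frame
#'   `sample`, `group`, `responders`, `rank`), and `cluster_members` (list of
#'   sample-id vectors per cluster).
#' @export
cluster_cultures <- function(centered, responders,
                             config = classification_config()) {
  stopifnot(is.matrix(centered), !anyNA(centered))
  if (ncol(centered) < config$n_clusters)
    stop("fewer cultures than requested clusters", call. = FALSE)
  hc <- stats::hclust(stats::dist(t(centered), method = "euclidean"),
                      method = "ward.D2")
  cut <- stats::cutree(hc, k = config$n_clusters)
  counts <- stats::setNames(responders$responders, responders$sample)
  mean_cnt <- tapply(counts[names(cut)], cut, mean)
  if (config$n_clusters == 2L) {
    ## lower mean responder count -> resistant; exact tie broken by cluster id
    by_count <- order(mean_cnt, as.numeric(names(mean_cnt)))
    lab_of <- stats::setNames(c("resistant", "sensitive")[order(by_count)],
                              names(mean_cnt))
  } else {
    lab_of <- stats::setNames(sprintf("cluster%d", sort(unique(cut))),
                              as.character(sort(unique(cut))))
  }
  labels <- data.frame(sample = names(cut),
                       group = unname(lab_of[as.character(cut)]),
                       responders = as.integer(counts[names(cut)]),
                       stringsAsFactors = FALSE)
  ord <- match(responders$sample, labels$sample)
  labels <- labels[ord, , drop = FALSE]
  labels$rank <- responders$rank
  rownames(labels) <- NULL
  list(hclust = hc,
       labels = labels,
       cluster_members = split(names(cut), unname(lab_of[as.character(cut)])))
}

# All clades (member index sets of every internal node) of an hclust tree.
hclust_clades <- function(hc) {
  n <- length(hc$labels)
  members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    pick <- function(j) if (j < 0) hc$labels[-j] else members[[j]]
    members[[i]] <- sort(c(pick(hc$merge[i, 1]), pick(hc$merge[i, 2])))
  }
  members
}

#' Multiscale bootstrap stability of the culture clusters
#'
#' Quantifies how stably each reference cluster reappears when the drug panel
#' is resampled. For each scale `r`, `B` bootstrap replicates draw
#' `round(r * n_drugs)` drugs with replacement, recluster the cultures
#' (Ward.D2 / Euclidean), and record whether the reference cluster occurs as
#' a clade of the replicate dendrogram; the per-scale hit fraction is the
#' bootstrap probability `BP_r`. The scale dependence of
#' `z_r = qnorm(1 - BP_r)` is modeled as `z(r) = v * sqrt(r) + c / sqrt(r)`
#' (weighted least squares across scales) and the approximately unbiased
#' p-value is `AU = 1 - pnorm(v - c)`; `BP` is the naive value at scale 1.
#'
#' @param centered Complete per-drug centered DSS matrix.
#' @param responders Responder counts (for reference cluster labels).
#' @param config A [classification_config()]; `bootstrap_b`, `scales` and
#'   `seed` control the resampling.
#' @return Data frame per reference cluster: `cluster`, `au`, `bp`, and the
#'   per-scale probabilities as a matrix attribute `bp_scales`.
#' @export
multiscale_bootstrap <- function(centered, responders,
                                 config = classification_config()) {
  ref <- cluster_cultures(centered, responders, config)
  ref_sets <- lapply(ref$cluster_members, sort)
  n_drugs <- nrow(centered)
  scales <- config$scales
  B <- config$bootstrap_b
  tc <- t(centered)

  hits <- matrix(0, length(ref_sets), length(scales),
                 dimnames = list(names(ref_sets), paste0("r", scales)))
  local_seed(stage_seed(config$seed, "bootstrap"), {
    for (si in seq_along(scales)) {
      n_r <- max(2L, round(scales[si] * n_drugs))
      for (b in seq_len(B)) {
        rows <- sample.int(n_drugs, n_r, replace = TRUE)
        hcb <- stats::hclust(stats::dist(tc[, rows, drop = FALSE]),
                             method = "ward.D2")
        clades <- hclust_clades(hcb)
        for (k in seq_along(ref_sets)) {
          if (any(vapply(clades, identical, TRUE, y = ref_sets[[k]])))
            hits[k, si] <- hits[k, si] + 1
        }
      }
    }
  })
  bp <- hits / B

  res <- do.call(rbind, lapply(seq_along(ref_sets), function(k) {
    est <- au_from_bp(bp[k, ], scales, B)
    data.frame(cluster = names(ref_sets)[k], au = est$au, bp = est$bp,
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  attr(res, "bp_scales") <- bp
  attr(res, "members") <- ref_sets
  res
}

#' Fit the multiscale model to per-scale bootstrap probabilities
#'
#' Implements the scale-curve fit behind AU estimation:
#' `qnorm(1 - BP_r) = v * sqrt(r) + c / sqrt(r)` by weighted least squares
#' (binomial variance weights), giving `AU = 1 - pnorm(v - c)` and the
#' model's naive probability `1 - pnorm(v + c)` at scale 1. Degenerate
#' profiles are handled explicitly: all-ones give `AU = BP = 1`; all-zeros
#' give `AU = 0` with a warning; a profile constant across scales has no
#' scale dependence, so the curvature term is taken as 0 and `AU` equals the
#' bootstrap probability at scale 1.
#'
#' @param bp Per-scale bootstrap probabilities (same length as `scales`).
#' @param scales The resampling scales `r`.
#' @param b Number of bootstrap replicates per scale (for the weights).
#' @return List `au`, `bp` (value at or nearest to scale 1), `v`, `c`.
#' @export
au_from_bp <- function(bp, scales, b) {
  stopifnot(length(bp) == length(scales))
  at1 <- which.min(abs(scales - 1))
  if (all(bp >= 1)) return(list(au = 1, bp = 1, v = -Inf, c = 0))
  if (all(bp <= 0)) {
    warning("cluster never reproduced at any scale; AU reported as 0")
    return(list(au = 0, bp = 0, v = Inf, c = 0))
  }
  if (diff(range(bp)) < 1e-12) {
    ## constant profile: no measurable scale dependence (c = 0)
    z <- stats::qnorm(1 - bp[at1])
    return(list(au = 1 - stats::pnorm(z), bp = bp[[at1]], v = z, c = 0))
  }
  eps <- 0.5 / b
  bpc <- clamp(bp, eps, 1 - eps)
  z <- stats::qnorm(1 - bpc)
  X <- cbind(sqrt(scales), 1 / sqrt(scales))
  w <- b * stats::dnorm(z)^2 / (bpc * (1 - bpc))
  fit <- stats::lm.wfit(X, z, w)
  v <- fit$coefficients[[1]]; cc <- fit$coefficients[[2]]
  list(au = 1 - stats::pnorm(v - cc),
       bp = bp[[at1]],
       v = v, c = cc)
}

#' Welch two-sample comparison of responder counts between groups
#'
#' Unpaired two-tailed t-test with Welch's correction, the standard contrast
#' for group differences in this pipeline. The degenerate case (both groups
#' constant with equal means) returns `t = 0`, `p = 1` instead of an error.
#'
#' @param counts Named numeric vector (sample -> responder count) or the data
#'   frame from [count_responders()].
#' @param labels Data frame with columns `sample`, `group` (two groups).
#' @return List `t`, `df`, `p`, `means` (named group means).
#' @export
compare_counts <- function(counts, labels) {
  if (is.data.frame(counts))
    counts <- stats::setNames(counts$responders, counts$sample)
  stopifnot(all(labels$sample %in% names(counts)))
  grps <- split(counts[labels$sample], labels$group)
  if (length(grps) != 2)
    stop("exactly two groups are required", call. = FALSE)
  if (any(lengths(grps) < 2))
    stop("each group needs at least 2 cultures", call. = FALSE)
  tt <- welch_test(grps[[1]], grps[[2]])
  c(tt, list(means = vapply(grps, mean, 0)))
}

#' Export a culture dendrogram as Newick
#'
#' @param hc An `hclust` object (from [cluster_cultures()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
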