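# Independent oracles used across test files. These deliberately re-derive
# quantities by brute force / enumeration, never by calling the code paths
# they check.

# Trapezoid-rule oracle for the DSS activity area on a dense grid.
trapezoid_dss <- function(bottom, top, m, s, x1, x2, t = 10, n = 1e5) {
  x <- seq(x1, x2, length.out = n)
  y <- bottom + (top - bottom) / (1 + 10^(s * (m - x)))
  g <- pmax(0, pmin(pmax(y, 0), 100) - t)
  a <- sum((g[-1] + g[-n]) / 2 * diff(x))
  100 * a / ((100 - t) * (x2 - x1))
}

# Step-by-step single-sample enrichment oracle: explicit walk down the
# ordered gene list, running in-set weighted CDF minus out-of-set ECDF.
ssgsea_oracle <- function(values, genes, set, alpha) {
  ord <- order(-values, genes)
  n <- length(genes)
  in_set <- genes[ord] %in% set
  rank_value <- n:1
  w <- ifelse(in_set, abs(rank_value)^alpha, 0)
  p_in <- 0; p_out <- 0; es <- 0
  wsum <- sum(w); n_out <- sum(!in_set)
  for (i in seq_len(n)) {
    if (in_set[i]) p_in <- p_in + w[i] / wsum
    else p_out <- p_out + 1 / n_out
    es <- es + (p_in - p_out)
  }
  es / n_out
}

# Hypergeometric upper tail by direct combinatorial enumeration.
hyper_upper_oracle <- function(N, K, n, k) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Small complete fixture: deterministic site records on two islands.
tiny_islands <- function() {
  data.frame(island = c("isl1", "isl2"), chrom = "chrT",
             start = c(100L, 500L), end = c(200L, 600L),
             stringsAsFactors = FALSE)
}

default_labels <- function(groups) {
  data.frame(sample = names(groups), group = unname(groups),
             stringsAsFactors = FALSE)
}
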