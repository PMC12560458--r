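test_that("log2 CPM normalization has the documented arithmetic", {
  counts <- matrix(c(1, 999999), nrow = 2,
                   dimnames = list(c("g1", "g2"), "s1"))
  norm <- normalize_expression(counts)
  expect_equal(norm["g1", "s1"], log2(2))     # 1 CPM -> log2(1 + 1)
  ## all-zero gene stays 0 everywhere; doubling a sample changes nothing
  m <- matrix(c(0, 5, 10, 0, 50, 100), nrow = 3,
              dimnames = list(c("g0", "g1", "g2"), c("a", "b")))
  norm2 <- normalize_expression(m)
  expect_equal(unname(norm2["g0", ]), c(0, 0))
  doubled <- m; doubled[, "a"] <- m[, "a"] * 2
  expect_equal(normalize_expression(doubled)[, "a"], norm2[, "a"])
  ## zero library size errors
  expect_error(normalize_expression(cbind(m, z = c(0, 0, 0))),
               "zero library size")
})

test_that("rank z-scores standardize exactly and ignore monotone transforms", {
  m <- matrix(c(1, 2, 3), nrow = 1, dimnames = list("g1", c("a", "b", "c")))
  expect_equal(unname(gene_zscores(m)[1, ]), c(-1, 0, 1))
  expect_warning(z0 <- gene_zscores(rbind(m, gc = c(4, 4, 4))),
                 "constant genes")
  expect_equal(unname(z0["gc", ]), c(0, 0, 0))
  set.seed(31)
  m2 <- matrix(rnorm(60), nrow = 10,
               dimnames = list(sprintf("g%02d", 1:10), letters[1:6]))
  z <- gene_zscores(m2)
  expect_lt(max(abs(rowMeans(z))), 1e-12)
  expect_equal(unname(apply(z, 1, stats::sd)), rep(1, 10), tolerance = 1e-12)
  ## strictly monotone per-gene transform leaves z unchanged
  expect_equal(gene_zscores(exp(m2)), z)
})

test_that("set scores contrast groups and conserve z-centering", {
  set.seed(32)
  m <- matrix(rnorm(80), nrow = 10,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:8)))
  z <- gene_zscores(m)
  labels <- data.frame(sample = sprintf("s%d", 1:8),
                       group = rep(c("resistant", "sensitive"), each = 4))
  sc <- set_score(z, c("g01", "g02", "g03"), labels)
  ## per gene, group-size-weighted group means of a centered row sum to 0
  for (g in c("g01", "g02", "g03")) {
    gm <- tapply(z[g, labels$sample], labels$group, mean)
    expect_equal(unname(4 * gm[1] + 4 * gm[2]), 0, tolerance = 1e-12)
  }
  ## hence equal-size groups give opposite scores
  expect_equal(sc$group_scores[["resistant"]],
               -sc$group_scores[["sensitive"]], tolerance = 1e-12)
  ## identical data in both groups: difference vanishes
  m_same <- cbind(m[, 1:4], m[, 1:4])
  colnames(m_same) <- sprintf("s%d", 1:8)
  sc_same <- set_score(gene_zscores(m_same), c("g01", "g02"), labels)
  expect_equal(sc_same$group_scores[["resistant"]],
               sc_same$group_scores[["sensitive"]], tolerance = 1e-12)
  ## absent genes dropped with warning; none present errors
  expect_warning(set_score(z, c("g01", "nope"), labels), "absent")
  expect_error(set_score(z, c("nope"), labels), "no gene")
  ## mean variant scales the sum by the panel size
  sc_mean <- set_score(z, c("g01", "g02", "g03"), labels, score_fun = "mean")
  expect_equal(sc_mean$group_scores, sc$group_scores / 3, tolerance = 1e-12)
})

test_that("ssGSEA equals step-by-step enumeration on a 4-gene universe", {
  expr <- matrix(c(8, 4, 2, 1), nrow = 4,
                 dimnames = list(c("gA", "gB", "gC", "gD"), "s1"))
  ## set = top-1 expressed gene: hand enumeration of the running sum.
  ## Order: gA gB gC gD; rank values 4 3 2 1; alpha = 0.75.
  ## P_in steps: 1, 1, 1, 1 (gA only); P_out steps: 0, 1/3, 2/3, 1.
  ## ES = (1-0) + (1-1/3) + (1-2/3) + (1-1) = 2, normalized by 3.
  es <- ssgsea_score(expr, "gA")
  expect_equal(unname(es), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(es), ssgsea_oracle(expr[, 1], rownames(expr), "gA", 0.75),
               tolerance = 1e-12)
  ## larger random universes against the oracle, several alphas
  set.seed(33)
  m <- matrix(rpois(50 * 3, 40) + runif(150), nrow = 50,
              dimnames = list(sprintf("g%02d", 1:50), c("a", "b", "c")))
  for (alpha in c(0, 0.75, 1)) {
    set <- sample(rownames(m), 8)
    got <- ssgsea_score(m, set, ssgsea_config(alpha = alpha))
    for (s in colnames(m))
      expect_equal(unname(got[s]),
                   ssgsea_oracle(m[, s], rownames(m), set, alpha),
                   tolerance = 1e-12)
  }
})

test_that("ssGSEA invariances: identical profiles, rank-only at alpha 0", {
  set.seed(34)
  m <- matrix(rexp(40), nrow = 20,
              dimnames = list(sprintf("g%02d", 1:20), c("a", "b")))
  m[, "b"] <- m[, "a"]
  set <- c("g03", "g07", "g11")
  es <- ssgsea_score(m, set)
  expect_equal(es[["a"]], es[["b"]])
  ## alpha = 0: strictly increasing transform leaves ES unchanged
  cfg0 <- ssgsea_config(alpha = 0)
  m2 <- m; m2[, "a"] <- log1p(m2[, "a"]) * 3 + 2
  expect_equal(ssgsea_score(m, set, cfg0)[["a"]],
               ssgsea_score(m2, set, cfg0)[["a"]], tolerance = 1e-12)
  ## gene (row) order never matters
  perm <- m[sample(nrow(m)), , drop = FALSE]
  expect_equal(ssgsea_score(perm, set), es)
  ## set = universe is an error
  expect_error(ssgsea_score(m, rownames(m)), "universe")
})

test_that("subtype calls take the larger enrichment score and swap on swap", {
  pn <- c(s1 = 0.5, s2 = -0.1, s3 = 0.2)
  mes <- c(s1 = 0.1, s2 = 0.4, s3 = 0.2)
  expect_warning(calls <- classify_subtype(pn, mes), "tie")
  expect_equal(calls$subtype, c("PN", "MES", "ambiguous"))
  expect_equal(calls$margin, unname(pn - mes))
  swapped <- suppressWarnings(classify_subtype(mes, pn))
  flip <- c(PN = "MES", MES = "PN", ambiguous = "ambiguous")
  expect_equal(swapped$subtype, unname(flip[calls$subtype]))
})

test_that("planted subtype structure is recovered from counts", {
  cfg <- cohort_config(n_genes = 400, seed = 35)
  es <- gen_expression_matrix(cfg)
  ne <- normalize_expression(es$counts)
  calls <- classify_subtype(ssgsea_score(ne, es$genesets$PN),
                            ssgsea_score(ne, es$genesets$MES))
  want <- ifelse(es$groups[calls$sample] == "sensitive", "PN", "MES")
  expect_equal(calls$subtype, unname(want))
})

test_that("hypergeometric ORA matches enumeration and BH arithmetic", {
  ## N = 10, K = 5, n = 4, k = 4 -> C(5,4) C(5,0) / C(10,4) = 5/210
  universe <- sprintf("g%02d", 1:10)
  de <- universe[1:4]
  sets <- list(hit = universe[1:5], miss = universe[6:10])
  tab <- ora_hypergeometric(de, universe, sets)
  expect_equal(tab$p[tab$set == "hit"], 5 / 210, tolerance = 1e-12)
  expect_equal(tab$overlap[tab$set == "miss"], 0L)
  expect_equal(tab$p[tab$set == "miss"], 1)   # P(X >= 0) = 1
  ## exhaustive agreement with the combinatorial oracle for all N <= 12
  set.seed(36)
  for (N in c(6, 9, 12)) {
    u <- sprintf("u%02d", seq_len(N))
    for (rep in 1:10) {
      K <- sample(N - 1, 1); n <- sample(N - 1, 1)
      s <- list(s = sample(u, K))
      d <- sample(u, n)
      got <- ora_hypergeometric(d, u, s)
      k <- length(intersect(s$s, d))
      expect_equal(got$p, hyper_upper_oracle(N, K, n, k), tolerance = 1e-12)
    }
  }
  ## BH on {0.01, 0.02, 0.03} adjusts to {0.03, 0.03, 0.03}
  sets3 <- list(a = "x", b = "y", c = "z")
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  ## error contracts
  expect_error(ora_hypergeometric("zz", universe, sets), "outside")
  expect_error(ora_hypergeometric(character(), character(), sets),
               "empty universe")
})
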