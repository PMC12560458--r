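test_that("bedMethyl parsing: empty file, known fixture, malformed lines", {
  f <- tempfile()
  writeLines(character(), f)
  empty <- read_bedmethyl(f)
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "n_malformed"), 0L)
  ## 3-line fixture with one non-5mC code filtered out
  writeLines(c(
    "chr1\t100\t101\tm\t12\t+\t100\t101\t255,0,0\t12\t75.5\t9\t3\t0\t0\t0\t0\t0",
    "chr1\t150\t151\th\t10\t+\t150\t151\t255,0,0\t10\t20\t2\t8\t0\t0\t0\t0\t0",
    "chr2\t900\t901\tm\t4\t-\t900\t901\t255,0,0\t4\t25\t1\t3\t0\t0\t0\t0\t0"
  ), f)
  rec <- read_bedmethyl(f)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$start, c(100L, 900L))
  expect_equal(rec$percent, c(75.5, 25))
  expect_equal(rec$coverage, c(12L, 4L))
  ## > 10% malformed lines is an error
  writeLines(c(rep("garbage line", 3),
               "chr1\t1\t2\tm\t5\t+\t1\t2\t.\t5\t50\t2\t3\t0\t0\t0\t0\t0"), f)
  expect_error(read_bedmethyl(f), "malformed")
  expect_error(read_bedmethyl(tempfile()), "cannot read")
})

test_that("writer output round-trips through the reader without loss", {
  cfg <- cohort_config(n_islands = 15, seed = 41)
  sim <- gen_methylome(cfg)
  rec <- sim$records[[3]]
  f <- tempfile()
  write_bedmethyl(rec, f)
  back <- read_bedmethyl(f)
  expect_equal(back$chrom, rec$chrom)
  expect_equal(back$start, rec$start)
  expect_equal(back$coverage, rec$coverage)
  expect_equal(back$percent, rec$percent)
})

test_that("depth filtering keeps coverage >= 5 inclusively", {
  rec <- data.frame(chrom = "c", start = 1:6, strand = "+",
                    coverage = c(100, 5, 4, 6, 1, 5), percent = 50,
                    stringsAsFactors = FALSE)
  out <- filter_depth(rec)
  expect_equal(out$coverage, c(100, 5, 6, 5))
  expect_equal(attr(out, "n_dropped"), 2L)
  expect_equal(nrow(filter_depth(rec, methylation_config(0L))), 6L)
  ## random coverages equal a brute-force comparison
  set.seed(42)
  rec2 <- data.frame(chrom = "c", start = 1:200, strand = "+",
                     coverage = rpois(200, 6), percent = 1,
                     stringsAsFactors = FALSE)
  expect_equal(filter_depth(rec2)$start, rec2$start[rec2$coverage >= 5])
})

test_that("island aggregation means sites and matches a per-site scan", {
  isl <- tiny_islands()
  rec <- data.frame(
    chrom = "chrT", start = c(120L, 150L, 199L, 200L, 550L),
    strand = "+", coverage = 10,
    percent = c(0, 100, 60, 99, 40), stringsAsFactors = FALSE)
  m <- island_methylation(list(s1 = rec), isl)
  ## site at 200 is outside [100, 200); singleton island means its site
  expect_equal(m["isl1", "s1"], mean(c(0, 100, 60)))
  expect_equal(m["isl2", "s1"], 40)
  expect_equal(attr(m, "n_sites")["isl1", "s1"], 3L)
  ## random fixture vs brute-force per-site scan
  set.seed(43)
  islands <- data.frame(island = sprintf("i%02d", 1:50), chrom = "chrT",
                        start = seq(0, by = 1000, length.out = 50),
                        end = seq(0, by = 1000, length.out = 50) +
                          sample(100:900, 50, TRUE),
                        stringsAsFactors = FALSE)
  recs <- data.frame(chrom = "chrT",
                     start = sample(0:49999, 1000),
                     strand = "+", coverage = 10,
                     percent = runif(1000, 0, 100),
                     stringsAsFactors = FALSE)
  got <- suppressWarnings(island_methylation(list(a = recs), islands))
  for (i in seq_len(50)) {
    inside <- recs$start >= islands$start[i] & recs$start < islands$end[i]
    want <- if (any(inside)) mean(recs$percent[inside]) else NA_real_
    expect_equal(unname(got[islands$island[i], "a"]), want)
  }
  ## order invariance and split invariance
  shuffled <- recs[sample(nrow(recs)), ]
  expect_equal(suppressWarnings(island_methylation(list(a = shuffled),
                                                   islands)), got)
})

test_that("strand combining merges CpG dinucleotide records by coverage", {
  rec <- data.frame(chrom = "chrT",
                    start = c(120L, 121L, 150L),
                    strand = c("+", "-", "+"),
                    coverage = c(10L, 30L, 8L),
                    percent = c(80, 40, 10), stringsAsFactors = FALSE)
  m <- suppressWarnings(island_methylation(list(s = rec), tiny_islands(),
                                           combine_strands = TRUE))
  merged <- (80 * 10 + 40 * 30) / 40
  expect_equal(m["isl1", "s"], mean(c(merged, 10)))
  expect_equal(attr(m, "n_sites")["isl1", "s"], 2L)
})

test_that("MGMT coordinate conversion addresses both boundary sites", {
  cfg <- methylation_config()
  base <- data.frame(chrom = "chr10", strand = "+", coverage = 10,
                     stringsAsFactors = FALSE)
  ## 1-based [129466685, 129467446] covers 0-based starts 129466684..129467445
  inside_first <- cbind(base, start = 129466684L, percent = 100)
  inside_last <- cbind(base, start = 129467445L, percent = 100)
  outside_lo <- cbind(base, start = 129466683L, percent = 100)
  outside_hi <- cbind(base, start = 129467446L, percent = 100)
  expect_equal(mgmt_status(inside_first, cfg)$n_sites, 1L)
  expect_equal(mgmt_status(inside_last, cfg)$n_sites, 1L)
  expect_identical(mgmt_status(outside_lo, cfg)$status, "undetermined")
  expect_identical(mgmt_status(outside_hi, cfg)$status, "undetermined")
})

test_that("MGMT cutoff is strict: exactly 22% is unmethylated", {
  mk <- function(pct) data.frame(chrom = "chr10",
                                 start = 129466684L + seq(0, 970, by = 10),
                                 strand = "+", coverage = 10, percent = pct,
                                 stringsAsFactors = FALSE)
  expect_identical(mgmt_status(mk(0))$status, "unmethylated")
  expect_identical(mgmt_status(mk(22))$status, "unmethylated")
  expect_identical(mgmt_status(mk(22 + 1e-9))$status, "methylated")
  expect_identical(mgmt_status(mk(30))$status, "methylated")
})

test_that("differential islands: extreme separation, direction, degeneracy", {
  meth <- rbind(
    sep = c(10, 10, 10, 10, 40, 40, 40, 40, 40) +
      c(0.01, -0.01, 0.02, -0.02, 0.01, -0.01, 0.02, -0.02, 0),
    flat = rep(20, 9))
  colnames(meth) <- c(sprintf("S%d", 1:4), sprintf("R%d", 1:5))
  labels <- data.frame(sample = colnames(meth),
                       group = rep(c("sensitive", "resistant"), c(4, 5)))
  dm <- differential_islands(meth, labels)
  sep <- dm[dm$island == "sep", ]
  expect_true(sep$significant)
  expect_identical(sep$direction, "hyper")    # resistant group sits higher
  flat <- dm[dm$island == "flat", ]
  expect_equal(flat$p, 1)
  expect_equal(flat$t, 0)
  ## islands with < 2 group values are skipped with a warning
  meth2 <- rbind(meth, thin = c(1, NA, NA, NA, 2, NA, NA, NA, NA))
  expect_warning(dm2 <- differential_islands(meth2, labels), "skipped")
  expect_false("thin" %in% dm2$island)
  ## Student default equals t.test(var.equal = TRUE)
  ref <- stats::t.test(meth["sep", 5:9], meth["sep", 1:4], var.equal = TRUE)
  expect_equal(sep$p, ref$p.value, tolerance = 1e-12)
  welch <- differential_islands(meth, labels,
                                methylation_config(dm_test = "welch"))
  refw <- stats::t.test(meth["sep", 5:9], meth["sep", 1:4])
  expect_equal(welch[welch$island == "sep", "p"], refw$p.value,
               tolerance = 1e-12)
})

test_that("null methylation calibration flags about alpha of islands", {
  cfg <- cohort_config(n_islands = 600, dm_island_fraction = 0, seed = 44)
  sim <- gen_methylome(cfg)
  m <- island_methylation(sim$records, sim$islands)
  m <- m[rownames(m) != "MGMT", ]
  dm <- differential_islands(m, default_labels(sim$groups))
  frac <- mean(dm$significant)
  se <- sqrt(0.05 * 0.95 / nrow(dm))
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("inverse methylation-expression linkage recovers planted pairs", {
  ## construct methylation and expression with known sign structure
  samples <- c(sprintf("S%d", 1:4), sprintf("R%d", 1:5))
  labels <- data.frame(sample = samples,
                       group = rep(c("sensitive", "resistant"), c(4, 5)))
  meth <- rbind(up = c(rep(10, 4), rep(40, 5)),   # hyper in resistant
                dn = c(rep(50, 4), rep(20, 5)),   # hypo in resistant
                nc = c(rep(30, 4), rep(30, 5)))
  colnames(meth) <- samples
  jitter <- matrix(seq(-0.02, 0.02, length.out = 27), nrow = 3)
  meth <- meth + jitter
  expr <- rbind(gene_up = c(rep(5, 4), rep(2, 5)),   # down in resistant
                gene_dn = c(rep(3, 4), rep(6, 5)),   # up in resistant
                gene_nc = rep(4, 9))
  colnames(expr) <- samples
  dm <- differential_islands(meth, labels)
  map <- data.frame(island = c("up", "dn", "nc"),
                    gene = c("gene_up", "gene_dn", "gene_nc"),
                    stringsAsFactors = FALSE)
  linked <- link_expression(dm, map, meth, expr, labels)
  expect_true(linked$linked[linked$island == "up"])    # inverse pair
  expect_true(linked$linked[linked$island == "dn"])    # inverse, other sign
  expect_false(linked$linked[linked$island == "nc"])   # zero expression delta
  expect_lt(linked$spearman[linked$island == "up"], 0)
  ## same-direction pair is rejected
  map2 <- data.frame(island = "up", gene = "gene_dn")
  linked2 <- link_expression(dm[dm$island == "up", ], map2, meth, expr, labels)
  expect_false(linked2$linked)
  ## unmapped islands are counted, not linked
  map3 <- data.frame(island = "up", gene = "absent_gene")
  linked3 <- link_expression(dm[dm$island == "up", ], map3, meth, expr, labels)
  expect_equal(nrow(linked3), 0L)
  expect_equal(attr(linked3, "n_unmapped"), 1L)
})

test_that("island BED round-trips through write and read", {
  isl <- tiny_islands()
  f <- tempfile()
  write_island_bed(isl, f)
  expect_equal(read_island_bed(f), isl)
})
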