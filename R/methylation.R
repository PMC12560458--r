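#' Methylation analysis configuration
#'
#' @param min_site_coverage Minimum valid read coverage per CpG site
#'   (inclusive; default 5). Interpreted as a per-site filter — the
#'   conservative operational reading of a depth-5 sequencing floor; set to
#'   0 to disable if the floor is taken as mean genome coverage instead.
#' @param dm_alpha Significance level for differential island methylation
#'   (default 0.05; raw p-values, no multiplicity correction — a BH column
#'   is emitted for information only).
#' @param dm_test `"student"` (classical independent two-sample t-test,
#'   default) or `"welch"`.
#' @param mgmt_chrom,mgmt_start,mgmt_end MGMT promoter interval, 1-based
#'   inclusive hg38 coordinates (defaults chr10:129,466,685-129,467,446, the
#'   98-CpG promoter island).
#' @param mgmt_cutoff Mean-methylation percentage above which (strictly) a
#'   sample is called MGMT methylated (default 22).
#' @return A `methylation_config` list.
#' @export
methylation_config <- function(min_site_coverage = 5L,
                               dm_alpha = 0.05,
                               dm_test = c("student", "welch"),
                               mgmt_chrom = MGMT_REGION$chrom,
                               mgmt_start = MGMT_REGION$start,
                               mgmt_end = MGMT_REGION$end,
                               mgmt_cutoff = 22) {
  stopifnot_scalar_number(dm_alpha, "dm_alpha", 1e-12, 1 - 1e-12)
  stopifnot_scalar_number(mgmt_cutoff, "mgmt_cutoff", 1e-9, 100 - 1e-9)
  structure(list(min_site_coverage = stopifnot_count(min_site_coverage,
                                                     "min_site_coverage", 0L),
                 dm_alpha = dm_alpha, dm_test = match.arg(dm_test),
                 mgmt_chrom = mgmt_chrom,
                 mgmt_start = mgmt_start, mgmt_end = mgmt_end,
                 mgmt_cutoff = mgmt_cutoff),
            class = "methylation_config")
}

#' Read per-CpG-site 5mC records from a bedMethyl file
#'
#' Parses the tab-separated bedMethyl dialect emitted by nanopore
#' modified-base pipelines: at least 10 columns, with the modification code
#' in column 4, valid coverage in column 10 and percent modified in column
#' 11. Only 5mC records (code `"m"`) are returned. Malformed lines are
#' counted and reported via the `n_malformed` attribute; more than 10%
#' malformed lines is an error.
#'
#' @param path bedMethyl file (plain text, tab-separated).
#' @return Data frame `chrom`, `start` (0-based), `strand`, `coverage`,
#'   `percent`, with attribute `n_malformed`.
#' @export
read_bedmethyl <- function(path) {
  if (!file.exists(path))
    stop("cannot read bedMethyl file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    out <- data.frame(chrom = character(), start = integer(),
                      strand = character(), coverage = integer(),
                      percent = numeric(), stringsAsFactors = FALSE)
    attr(out, "n_malformed") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  well_formed <- nf >= 11
  rows <- fields[well_formed]
  get <- function(i) vapply(rows, `[[`, "", i)
  start <- suppressWarnings(as.integer(get(2)))
  coverage <- suppressWarnings(as.integer(get(10)))
  percent <- suppressWarnings(as.numeric(get(11)))
  parsed_ok <- !is.na(start) & !is.na(coverage) & !is.na(percent)
  n_malformed <- sum(!well_formed) + sum(!parsed_ok)
  if (n_malformed > 0.10 * length(lines))
    stop(sprintf("%d of %d lines malformed in %s", n_malformed,
                 length(lines), path), call. = FALSE)
  keep <- parsed_ok & get(4) == "m"
  out <- data.frame(chrom = get(1)[keep], start = start[keep],
                    strand = get(6)[keep], coverage = coverage[keep],
                    percent = percent[keep], stringsAsFactors = FALSE)
  attr(out, "n_malformed") <- n_malformed
  out
}

#' Write per-site records as bedMethyl
#'
#' Emits the 18-column tab-separated bedMethyl layout (modification code
#' `"m"`, valid coverage in column 10, percent modified in column 11) so
#' that [read_bedmethyl()] round-trips the records without loss.
#'
#' @param records Data frame `chrom`, `start` (0-based), `strand`,
#'   `coverage`, `percent`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bedmethyl <- function(records, path) {
  n_mod <- round(records$coverage * records$percent / 100)
  lines <- sprintf(
    "%s\t%d\t%d\tm\t%d\t%s\t%d\t%d\t255,0,0\t%d\t%s\t%d\t%d\t0\t0\t0\t0\t0",
    records$chrom, records$start, records$start + 1L, records$coverage,
    records$strand, records$start, records$start + 1L, records$coverage,
    formatC(records$percent, format = "fg", digits = 10), n_mod,
    records$coverage - n_mod)
  writeLines(lines, path)
  invisible(path)
}

#' Filter CpG-site records by minimum coverage
#'
#' Keeps records with `coverage >= min_site_coverage` (inclusive boundary).
#'
#' @param records Site records ([read_bedmethyl()]).
#' @param config A [methylation_config()].
#' @return Filtered records; the number removed is attached as attribute
#'   `n_dropped`.
#' @export
filter_depth <- function(records, config = methylation_config()) {
  keep <- records$coverage >= config$min_site_coverage
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

islands_granges <- function(islands) {
  stopifnot(all(c("island", "chrom", "start", "end") %in% names(islands)),
            all(islands$start < islands$end))
  gr <- GenomicRanges::GRanges(
    islands$chrom,
    IRanges::IRanges(start = islands$start + 1L, end = islands$end))
  names(gr) <- islands$island
  self <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                      drop.redundant = TRUE)
  if (length(self) > 0)
    warning(length(self), " overlapping island pairs in the reference")
  gr
}

#' Aggregate site methylation into a CpG-island matrix
#'
#' The methylation of an island in a sample is the unweighted mean of the
#' percent-modified values of all its CpG sites (both strands pooled;
#' membership is interval overlap of the 0-based site position with the
#' half-open island `[start, end)`). Islands with no covered site in a
#' sample are `NA`.
#'
#' @param records_by_sample Named list (sample -> site-record data frame,
#'   already depth-filtered as desired).
#' @param islands Island reference data frame (`island`, `chrom`, `start`,
#'   `end`, BED 0-based half-open).
#' @param combine_strands If `TRUE`, a minus-strand record at position
#'   `p + 1` is merged with a plus-strand record at `p` (same CpG
#'   dinucleotide) by coverage-weighted average before aggregation.
#' @return Islands x samples matrix of mean methylation percent, with the
#'   per-entry contributing-site counts as attribute `n_sites`.
#' @export
island_methylation <- function(records_by_sample, islands,
                               combine_strands = FALSE) {
  stopifnot(is.list(records_by_sample), !is.null(names(records_by_sample)))
  gr <- islands_granges(islands)
  samples <- names(records_by_sample)
  mat <- matrix(NA_real_, length(gr), length(samples),
                dimnames = list(names(gr), samples))
  nsites <- matrix(0L, length(gr), length(samples),
                   dimnames = dimnames(mat))
  for (s in samples) {
    rec <- records_by_sample[[s]]
    if (combine_strands) rec <- merge_cpg_strands(rec)
    if (nrow(rec) == 0) next
    sites <- GenomicRanges::GRanges(
      rec$chrom, IRanges::IRanges(start = rec$start + 1L, width = 1L))
    hits <- GenomicRanges::findOverlaps(sites, gr)
    if (length(hits) == 0) next
    idx <- S4Vectors::subjectHits(hits)
    val <- rec$percent[S4Vectors::queryHits(hits)]
    agg <- tapply(val, idx, mean)
    mat[as.integer(names(agg)), s] <- as.numeric(agg)
    cnt <- table(idx)
    nsites[as.integer(names(cnt)), s] <- as.integer(cnt)
  }
  empty <- rowSums(!is.na(mat)) == 0
  if (any(empty))
    warning(sum(empty), " islands with no covered site in any sample")
  attr(mat, "n_sites") <- nsites
  mat
}

# Merge +/- records of the same CpG dinucleotide (minus at plus position + 1)
# by coverage-weighted average.
merge_cpg_strands <- function(rec) {
  minus <- rec$strand == "-"
  key_plus <- paste(rec$chrom, rec$start)
  key_minus <- paste(rec$chrom, rec$start - 1L)
  partner <- match(key_minus[minus], key_plus[!minus])
  has_partner <- !is.na(partner)
  if (!any(has_partner)) return(rec)
  plus_idx <- which(!minus)[partner[has_partner]]
  minus_idx <- which(minus)[has_partner]
  cov_p <- rec$coverage[plus_idx]; cov_m <- rec$coverage[minus_idx]
  tot <- cov_p + cov_m
  rec$percent[plus_idx] <- (rec$percent[plus_idx] * cov_p +
                              rec$percent[minus_idx] * cov_m) / tot
  rec$coverage[plus_idx] <- tot
  out <- rec[-minus_idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' MGMT promoter methylation status of one sample
#'
#' Averages the percent-modified values of all CpG sites inside the MGMT
#' promoter interval (stored as 1-based inclusive coordinates and converted
#' to the 0-based site convention internally) and calls the sample
#' methylated when the mean strictly exceeds the cutoff (default 22%). With
#' no site in the region the status is `"undetermined"`.
#'
#' @param records Site records of one sample (depth-filtered as desired).
#' @param config A [methylation_config()].
#' @return List `mean` (percent), `n_sites`, `status`
#'   (`"methylated"` / `"unmethylated"` / `"undetermined"`).
#' @export
mgmt_status <- function(records, config = methylation_config()) {
  ## 1-based inclusive [start, end] covers 0-based positions start-1 .. end-1
  in_region <- records$chrom == config$mgmt_chrom &
    records$start >= config$mgmt_start - 1L &
    records$start <= config$mgmt_end - 1L
  n <- sum(in_region)
  if (n == 0)
    return(list(mean = NA_real_, n_sites = 0L, status = "undetermined"))
  m <- mean(records$percent[in_region])
  list(mean = m, n_sites = n,
       status = if (m > config$mgmt_cutoff) "methylated" else "unmethylated")
}

#' Differential island methylation between groups
#'
#' Per island, an independent two-sample t-test (classical equal-variance
#' Student's test by default; Welch selectable) compares mean methylation
#' between the two groups. Raw p-values are compared to `dm_alpha` with no
#' multiplicity correction (a BH-adjusted column is included for information
#' only). Islands observed in fewer than 2 samples of either group are
#' skipped with a warning; an island with zero variance in both groups and
#' equal means gets `p = 1`.
#'
#' @param meth Islands x samples matrix ([island_methylation()]).
#' @param labels Data frame `sample`, `group` with groups `resistant` and
#'   `sensitive`.
#' @param config A [methylation_config()].
#' @return Data frame `island`, `mean_resistant`, `mean_sensitive`, `delta`
#'   (resistant - sensitive), `t`, `p`, `padj_bh`, `significant`,
#'   `direction` (`"hyper"`/`"hypo"` in resistant).
#' @export
differential_islands <- function(meth, labels,
                                 config = methylation_config()) {
  stopifnot(is.matrix(meth), all(labels$sample %in% colnames(meth)))
  res_s <- labels$sample[labels$group == "resistant"]
  sen_s <- labels$sample[labels$group == "sensitive"]
  if (length(res_s) < 2 || length(sen_s) < 2)
    stop("both groups need at least 2 samples", call. = FALSE)
  welch <- config$dm_test == "welch"
  rows <- lapply(rownames(meth), function(isl) {
    x <- meth[isl, res_s]; y <- meth[isl, sen_s]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) return(NULL)
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      tstat <- if (mean(x) == mean(y)) 0 else Inf * sign(mean(x) - mean(y))
      p <- if (mean(x) == mean(y)) 1 else 0
    } else {
      tt <- stats::t.test(x, y, var.equal = !welch)
      tstat <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(island = isl, mean_resistant = mean(x),
               mean_sensitive = mean(y), delta = mean(x) - mean(y),
               t = tstat, p = p, stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, TRUE))
  if (skipped > 0)
    warning(skipped, " islands skipped (fewer than 2 values in a group)")
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no island is testable in both groups", call. = FALSE)
  out$padj_bh <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < config$dm_alpha
  out$direction <- ifelse(out$delta > 0, "hyper",
                          ifelse(out$delta < 0, "hypo", "none"))
  rownames(out) <- NULL
  out
}

#' Link differentially methylated islands to inverse expression changes
#'
#' An island is linked to its associated gene when the between-group
#' methylation change and the gene's expression change point in opposite
#' directions: `sign(delta_methylation) * sign(delta_expression) < 0`, with
#' deltas computed as resistant-group mean minus sensitive-group mean. A
#' per-island Spearman correlation between methylation and expression across
#' samples is reported alongside. Islands without a mapping, or mapped to
#' genes absent from the expression matrix, are skipped (count reported via
#' attribute `n_unmapped`).
#'
#' @param dm Data frame from [differential_islands()] (typically filtered to
#'   `significant` islands by the caller; all rows supplied are assessed).
#' @param island_gene_map Data frame `island`, `gene`.
#' @param meth Islands x samples methylation matrix.
#' @param norm_expr Normalized genes x samples expression matrix.
#' @param labels Data frame `sample`, `group`.
#' @return Data frame `island`, `gene`, `delta_methylation`,
#'   `delta_expression`, `spearman`, `linked`, with attribute `n_unmapped`.
#' @export
link_expression <- function(dm, island_gene_map, meth, norm_expr, labels) {
  stopifnot(all(c("island", "gene") %in% names(island_gene_map)))
  map <- island_gene_map[match(dm$island, island_gene_map$island), ]
  mapped <- !is.na(map$gene) & map$gene %in% rownames(norm_expr)
  n_unmapped <- sum(!mapped)
  res_s <- labels$sample[labels$group == "resistant"]
  sen_s <- labels$sample[labels$group == "sensitive"]
  all_s <- c(res_s, sen_s)
  rows <- lapply(which(mapped), function(i) {
    isl <- dm$island[i]; gene <- map$gene[i]
    d_expr <- mean(norm_expr[gene, res_s]) - mean(norm_expr[gene, sen_s])
    rho <- suppressWarnings(
      stats::cor(meth[isl, all_s], norm_expr[gene, all_s],
                 method = "spearman", use = "complete.obs"))
    data.frame(island = isl, gene = gene,
               delta_methylation = dm$delta[i], delta_expression = d_expr,
               spearman = rho,
               linked = sign(dm$delta[i]) * sign(d_expr) < 0,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) == 0) {
    data.frame(island = character(), gene = character(),
               delta_methylation = numeric(), delta_expression = numeric(),
               spearman = numeric(), linked = logical(),
               stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Read / write a BED4 CpG-island reference
#'
#' BED convention: 0-based half-open intervals, columns
#' `chrom, start, end, name`.
#' @param path File path.
#' @return `read_island_bed`: data frame `island`, `chrom`, `start`, `end`.
#' @export
read_island_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "island"),
                          colClasses = c("character", "integer", "integer",
                                         "character"))
  df[, c("island", "chrom", "start", "end")]
}

#' @rdname read_island_bed
#' @param islands Island data frame (`island`, `chrom`, `start`, `end`).
#' @export
write_island_bed <- function(islands, path) {
  utils::write.table(islands[, c("chrom", "start", "end", "island")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
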