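#' Read and write feature-by-sample matrices as TSV
#'
#' The exchange format for every matrix in the pipeline: tab-separated,
#' header row of sample ids, first column the feature id, missing entries as
#' empty fields. Values are written at 6 significant digits; a write-read
#' cycle is therefore stable at the string level.
#'
#' @param path File path.
#' @param feature_col Name to give the id column on write (default
#'   `"feature"`).
#' @return `read_matrix`: a numeric matrix with feature row names.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = "")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate feature ids in ", path, ": ",
         paste(utils::head(unique(ids[duplicated(ids)]), 3), collapse = ", "),
         call. = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- ids
  mat
}

#' @rdname read_matrix
#' @param mat Numeric matrix with row and column names.
#' @export
write_matrix <- function(mat, path, feature_col = "feature") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  fmt <- ifelse(is.na(mat), "", formatC(mat, format = "g", digits = 6))
  dim(fmt) <- dim(mat)
  header <- paste(c(feature_col, colnames(mat)), collapse = "\t")
  body <- apply(cbind(rownames(mat), fmt), 1, paste, collapse = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then member symbols,
#' tab-separated.
#' @param path File path.
#' @return `read_gmt`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                  vapply(fields, `[[`, "", 1))
}

#' @rdname read_gmt
#' @param genesets Named list of gene-symbol vectors.
#' @export
write_gmt <- function(genesets, path) {
  lines <- vapply(names(genesets), function(nm) {
    paste(c(nm, "na", genesets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write sample group labels
#'
#' TSV with columns `sample`, `group` and optionally `responders`, `rank`.
#' @param path File path.
#' @return `read_labels`: the labels data frame.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(df)))
    stop("labels file must have columns 'sample' and 'group'", call. = FALSE)
  if (anyDuplicated(df$sample))
    stop("duplicate sample in labels file", call. = FALSE)
  df
}

#' @rdname read_labels
#' @param labels Labels data frame.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes the stages in dependency order on one simulated cohort:
#' simulate (viability screen, expression counts, methylome), score the
#' screen to a DSS matrix, classify cultures into resistant/sensitive groups
#' (with optional multiscale-bootstrap stability), compute stemness and
#' PN/MES subtype scores, and run the methylation analyses (island
#' aggregation, MGMT status, differential methylation, inverse expression
#' linkage). All intermediate artifacts are written under `outdir` and a run
#' manifest summarizing counts and collected warnings is returned and saved
#' as JSON.
#'
#' @param config A [cohort_config()].
#' @param outdir Output directory (created if needed).
#' @param dss_source `"fit"` (default; full 4PL fitting from raw wells) or
#'   `"truth"` (DSS evaluated from the planted curve parameters, exact and
#'   fast).
#' @param bootstrap_b Bootstrap replicates for cluster stability; 0 skips
#'   the stability stage.
#' @param dss A [dss_params()].
#' @param class_cfg A [classification_config()]; its seed defaults to the
#'   cohort seed.
#' @param meth_cfg A [methylation_config()].
#' @return The manifest (list), invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config, outdir,
                         dss_source = c("fit", "truth"),
                         bootstrap_b = 0L,
                         dss = dss_params(),
                         class_cfg = classification_config(seed = config$seed),
                         meth_cfg = methylation_config()) {
  dss_source <- match.arg(dss_source)
  stopifnot(inherits(config, "cohort_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  warnings_seen <- character()
  note <- function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  withCallingHandlers({
    ## --- simulate -------------------------------------------------------
    screen_sim <- gen_viability_screen(config)
    expr_sim <- gen_expression_matrix(config)
    meth_sim <- gen_methylome(config)
    write_viability_csv(screen_sim$screen, file.path(outdir, "screen.csv"))
    write_matrix(expr_sim$counts, file.path(outdir, "counts.tsv"),
                 feature_col = "gene")
    write_gmt(expr_sim$genesets, file.path(outdir, "genesets.gmt"))
    write_island_bed(meth_sim$islands, file.path(outdir, "islands.bed"))
    for (s in names(meth_sim$records))
      write_bedmethyl(meth_sim$records[[s]],
                      file.path(outdir, paste0(s, ".bedmethyl")))

    ## --- DSS ------------------------------------------------------------
    if (dss_source == "fit") {
      scored <- dss_matrix_from_screen(screen_sim$screen, dss)
      dss_mat <- scored$dss
    } else {
      dss_mat <- dss_from_truth(screen_sim$truth, dss)
    }
    write_matrix(dss_mat, file.path(outdir, "dss.tsv"), feature_col = "drug")

    ## --- classification -------------------------------------------------
    common <- restrict_common(dss_mat)
    responders <- count_responders(common, class_cfg)
    centered <- normalize_dss(common)
    clus <- cluster_cultures(centered, responders, class_cfg)
    write_labels(clus$labels, file.path(outdir, "labels.tsv"))
    write_dendrogram_newick(clus$hclust, file.path(outdir, "dendrogram.nwk"))
    welch <- compare_counts(responders, clus$labels)
    stability <- NULL
    if (bootstrap_b > 0) {
      bcfg <- class_cfg; bcfg$bootstrap_b <- as.integer(bootstrap_b)
      stability <- multiscale_bootstrap(centered, responders, bcfg)
      jsonlite::write_json(
        list(clusters = stability,
             bp_scales = as.data.frame(attr(stability, "bp_scales"))),
        file.path(outdir, "stability.json"), auto_unbox = TRUE, digits = NA)
    }

    ## --- expression scores ----------------------------------------------
    norm_expr <- normalize_expression(expr_sim$counts)
    z <- gene_zscores(norm_expr)
    stem <- set_score(z, expr_sim$genesets$stemness, clus$labels)
    es_pn <- ssgsea_score(norm_expr, expr_sim$genesets$PN)
    es_mes <- ssgsea_score(norm_expr, expr_sim$genesets$MES)
    subtype <- classify_subtype(es_pn, es_mes)
    utils::write.table(subtype, file.path(outdir, "subtypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    ## --- methylation ----------------------------------------------------
    filtered <- lapply(meth_sim$records, filter_depth, config = meth_cfg)
    meth_mat <- island_methylation(filtered, meth_sim$islands)
    write_matrix(meth_mat, file.path(outdir, "island_methylation.tsv"),
                 feature_col = "island")
    mgmt <- lapply(filtered, mgmt_status, config = meth_cfg)
    jsonlite::write_json(mgmt, file.path(outdir, "mgmt.json"),
                         auto_unbox = TRUE, digits = NA)
    dm <- differential_islands(meth_mat, clus$labels, meth_cfg)
    utils::write.table(dm, file.path(outdir, "differential_islands.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    ## planted-truth island -> gene map for the linkage stage: pair each DM
    ## island with a planted DM gene where available (synthetic cohorts have
    ## no shared gene/island coordinate system)
    planted_genes <- expr_sim$truth$gene[expr_sim$truth$log2fc != 0]
    dm_isl <- dm$island[dm$significant]
    map <- data.frame(
      island = dm_isl,
      gene = rep_len(planted_genes, length(dm_isl)),
      stringsAsFactors = FALSE)
    linked <- link_expression(dm[dm$significant, , drop = FALSE], map,
                              meth_mat, norm_expr, clus$labels)
    utils::write.table(linked, file.path(outdir, "linked_islands.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    ## --- manifest -------------------------------------------------------
    manifest <- list(
      tool = paste0("gscreen ",
                    as.character(utils::packageVersion("gscreen"))),
      seed = config$seed,
      n_samples = length(screen_sim$groups),
      n_drugs_screened = nrow(dss_mat),
      n_drugs_common = attr(common, "n_common"),
      responders = stats::setNames(responders$responders, responders$sample),
      cluster_sizes = vapply(clus$cluster_members, length, 0L),
      responder_welch_p = welch$p,
      stability = if (is.null(stability)) NULL else
        stats::setNames(stability$au, stability$cluster),
      stemness_scores = stem$group_scores,
      subtype_calls = stats::setNames(subtype$subtype, subtype$sample),
      mgmt_methylated = names(Filter(function(x)
        identical(x$status, "methylated"), mgmt)),
      n_islands_tested = nrow(dm),
      n_islands_significant = sum(dm$significant),
      n_islands_linked = sum(linked$linked),
      warnings = warnings_seen
    )
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(manifest)
  }, warning = note)
}
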