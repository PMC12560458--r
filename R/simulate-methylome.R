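# Promoter region used for MGMT methylation calls: 1-based inclusive hg38
# coordinates spanning the 98 CpG sites of the MGMT CpG island.
MGMT_REGION <- list(chrom = "chr10", start = 129466685, end = 129467446,
                    n_sites = 98L)

#' Simulate per-CpG-site methylomes and a CpG-island reference
#'
#' Places `n_islands` non-overlapping CpG islands on a synthetic chromosome
#' (`chrS`), each with 5-100 CpG sites, and draws per-site 5mC fractions from
#' a Beta distribution around the island's mean (precision
#' `meth_beta_precision`; `Inf` collapses every site onto the island mean). A
#' fraction `dm_island_fraction` of islands receives a planted between-group
#' mean difference of `dm_delta` percentage points with random sign. Per-site
#' read coverage is `coverage_floor` plus a negative-binomial draw so a
#' minimum-depth filter has something to remove.
#'
#' One additional region emulates the MGMT promoter island: 98 CpG sites at
#' the hg38 coordinates used for clinical MGMT calls (chr10:129,466,685-
#' 129,467,446, 1-based inclusive). Each sample is planted as MGMT methylated
#' (mean 30%) or unmethylated (mean 10%).
#'
#' @param config A [cohort_config()].
#' @param site_range Integer range of CpG sites per island (default 5-100).
#' @param chrom_length Length of the synthetic chromosome; an island layout
#'   that does not fit is an invalid-configuration error.
#' @return A list with:
#'   \describe{
#'     \item{islands}{data frame `island`, `chrom`, `start`, `end` (0-based
#'       half-open, BED convention); includes the MGMT island.}
#'     \item{records}{named list (one element per sample) of per-site record
#'       data frames: `chrom`, `start` (0-based), `strand`, `coverage`,
#'       `percent` (5mC, 0-100, rounded to 4 decimals).}
#'     \item{truth}{list with `island_means` (island x group planted means,
#'       percent), `dm_islands` (data frame of planted DM island ids and
#'       signed deltas), `mgmt` (per-sample planted status and mean).}
#'     \item{groups}{named character vector sample -> group.}
#'   }
#' @examples
#' sim <- gen_methylome(cohort_config(n_islands = 20, seed = 5))
#' head(sim$islands)
#' @export
gen_methylome <- function(config, site_range = c(5L, 100L),
                          chrom_length = 250e6) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  samples <- cohort_samples(cfg)
  groups <- cohort_groups(cfg)

  local_seed(stage_seed(cfg$seed, "methylome"), {
    n <- cfg$n_islands
    n_sites <- sample(seq(site_range[1], site_range[2]), n, replace = TRUE)
    ## site positions: CpGs every 2-40 bp inside an island, islands separated
    ## by 1-5 kb gaps on the synthetic chromosome
    gaps <- sample(1000:5000, n, replace = TRUE)
    site_pos <- vector("list", n)
    cursor <- 0L
    for (i in seq_len(n)) {
      cursor <- cursor + gaps[i]
      offs <- cumsum(sample(2:40, n_sites[i], replace = TRUE))
      site_pos[[i]] <- cursor + offs
      cursor <- cursor + offs[n_sites[i]] + 1L
    }
    if (cursor > chrom_length)
      stop("invalid cohort_config: ", n, " islands do not fit on a ",
           "chromosome of length ", format(chrom_length, scientific = FALSE),
           call. = FALSE)
    islands <- data.frame(
      island = sprintf("CGI%05d", seq_len(n)),
      chrom = "chrS",
      start = vapply(site_pos, min, 0) - 1,      # 0-based half-open
      end = vapply(site_pos, max, 0) + 1,
      stringsAsFactors = FALSE
    )

    ## planted island means per group (fractions)
    base_mean <- stats::runif(n, 0.15, 0.55)
    n_dm <- round(cfg$dm_island_fraction * n)
    dm_idx <- if (n_dm > 0) sort(sample.int(n, n_dm)) else integer(0)
    delta_sign <- sample(c(-1, 1), n_dm, replace = TRUE)
    delta <- numeric(n)
    delta[dm_idx] <- delta_sign * cfg$dm_delta / 100
    mean_sens <- base_mean
    mean_res <- clamp(base_mean + delta, 0.02, 0.98)

    ## MGMT-like promoter: 98 evenly spaced sites within the hg38 interval
    mgmt_start0 <- MGMT_REGION$start - 1L       # to 0-based
    mgmt_pos <- round(seq(mgmt_start0, MGMT_REGION$end - 1L,
                          length.out = MGMT_REGION$n_sites))
    mgmt_status <- sample(c(TRUE, FALSE), length(samples), replace = TRUE)
    names(mgmt_status) <- samples
    mgmt_mean <- ifelse(mgmt_status, 0.30, 0.10)

    island_site <- rep(seq_len(n), n_sites)
    all_pos <- unlist(site_pos)
    records <- stats::setNames(lapply(seq_along(samples), function(si) {
      mu <- if (groups[[si]] == "resistant") mean_res else mean_sens
      frac <- rbeta_around(mu[island_site], cfg$meth_beta_precision)
      mfrac <- rbeta_around(rep(mgmt_mean[[si]], MGMT_REGION$n_sites),
                            cfg$meth_beta_precision)
      data.frame(
        chrom = c(rep("chrS", length(all_pos)),
                  rep(MGMT_REGION$chrom, MGMT_REGION$n_sites)),
        start = c(all_pos, mgmt_pos),
        strand = "+",
        coverage = cfg$coverage_floor +
          stats::rnbinom(length(all_pos) + MGMT_REGION$n_sites,
                         mu = cfg$coverage_mean, size = 3),
        percent = round(100 * c(frac, mfrac), 4),
        stringsAsFactors = FALSE
      )
    }), samples)

    islands <- rbind(islands, data.frame(
      island = "MGMT", chrom = MGMT_REGION$chrom,
      start = mgmt_start0, end = MGMT_REGION$end,
      stringsAsFactors = FALSE))

    list(
      islands = islands,
      records = records,
      truth = list(
        island_means = data.frame(island = islands$island[seq_len(n)],
                                  mean_sensitive = 100 * mean_sens,
                                  mean_resistant = 100 * mean_res,
                                  stringsAsFactors = FALSE),
        dm_islands = data.frame(island = islands$island[dm_idx],
                                delta = 100 * (mean_res - mean_sens)[dm_idx],
                                stringsAsFactors = FALSE),
        mgmt = data.frame(sample = samples, methylated = mgmt_status,
                          planted_mean = 100 * mgmt_mean,
                          stringsAsFactors = FALSE)
      ),
      groups = groups
    )
  })
}

# Beta draw with given mean vector and precision (a + b); Inf degenerates to
# the mean itself.
rbeta_around <- function(mean, precision) {
  if (is.infinite(precision)) return(mean)
  stats::rbeta(length(mean), shape1 = mean * precision,
               shape2 = (1 - mean) * precision)
}
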