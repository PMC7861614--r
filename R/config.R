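#' Pipeline configuration
#'
#' Central container for every numeric constant used by the pipeline.
#' Defaults mirror the analysis settings of the study design this package
#' implements: 50-bp single-end reads, 260-bp ChIP fragments, 1-kb bins
#' kept at >50% mappability, a promoter window of 10 kb upstream / 15 kb
#' downstream of an insertion, a 5-kb insertion clustering filter, and a
#' de-repression call at >4-fold change, adjusted p < 0.05 and >1 RPKM.
#'
#' @param kmer_length k-mer (read) length in bp for mappability tracks.
#' @param pair_gap_shift mate-2 shift in bp for paired mappability.
#' @param fragment_length ChIP fragment length in bp for read extension.
#' @param bin_width genomic bin width in bp.
#' @param mappability_min_frac minimum mean bin mappability (exclusive).
#' @param tss_window_up,tss_window_down promoter proximity window in bp
#'   upstream/downstream of an insertion reference point.
#' @param cluster_min_gap minimum insertion spacing in bp; closer pairs are
#'   dropped from proximity analyses.
#' @param proximity_radius bin-to-insertion distance in bp defining "near".
#' @param control_min_distance minimum insertion distance in bp for control
#'   heterochromatin bins.
#' @param lfc_threshold absolute log2 fold-change call threshold.
#' @param padj_threshold BH-adjusted p-value call threshold.
#' @param rpkm_threshold minimum mean RPKM for a feature to be callable.
#' @param matrix_before,matrix_after metaprofile window in bp before/after
#'   the insertion reference point.
#' @param profile_bin,heatmap_bin positional bin size in bp for profiles
#'   and heatmaps.
#' @param n_bootstrap bootstrap resamples for profile confidence intervals.
#' @param ci_level confidence level for bootstrap intervals.
#' @param heatmap_cap_percentile percentile at which heatmap values are
#'   capped.
#' @param mapq_rna,mapq_chip minimum mapping quality for RNA-seq and
#'   ChIP-seq counting.
#' @param upregulated_families TE families de-repressed in the knockdown.
#' @param other_families control TE families.
#' @param het_region heterochromatin control region, a list with elements
#'   `chrom`, `start`, `end` (0-based half-open), or `NULL`.
#' @param seed integer root seed for all randomised stages.
#'
#' @return an object of class `pipeline_config` (a validated list).
#' @export
#' @examples
#' cfg <- pipeline_config(seed = 1)
#' cfg$bin_width
pipeline_config <- function(kmer_length = 50L,
                            pair_gap_shift = 146L,
                            fragment_length = 260L,
                            bin_width = 1000L,
                            mappability_min_frac = 0.5,
                            tss_window_up = 10000L,
                            tss_window_down = 15000L,
                            cluster_min_gap = 5000L,
                            proximity_radius = 1000L,
                            control_min_distance = 10000L,
                            lfc_threshold = 2,
                            padj_threshold = 0.05,
                            rpkm_threshold = 1,
                            matrix_before = 10000L,
                            matrix_after = 15000L,
                            profile_bin = 5L,
                            heatmap_bin = 50L,
                            n_bootstrap = 200L,
                            ci_level = 0.95,
                            heatmap_cap_percentile = 99,
                            mapq_rna = 50L,
                            mapq_chip = 255L,
                            upregulated_families = c("gypsy", "mdg1", "blood",
                                                     "297", "412"),
                            other_families = c("Juan", "Bari1", "1360",
                                               "pogo", "Burdock", "diver"),
                            het_region = NULL,
                            seed = 1L) {
  cfg <- list(
    kmer_length = as.integer(kmer_length),
    pair_gap_shift = as.integer(pair_gap_shift),
    fragment_length = as.integer(fragment_length),
    bin_width = as.integer(bin_width),
    mappability_min_frac = mappability_min_frac,
    tss_window_up = as.integer(tss_window_up),
    tss_window_down = as.integer(tss_window_down),
    cluster_min_gap = as.integer(cluster_min_gap),
    proximity_radius = as.integer(proximity_radius),
    control_min_distance = as.integer(control_min_distance),
    lfc_threshold = lfc_threshold,
    padj_threshold = padj_threshold,
    rpkm_threshold = rpkm_threshold,
    matrix_before = as.integer(matrix_before),
    matrix_after = as.integer(matrix_after),
    profile_bin = as.integer(profile_bin),
    heatmap_bin = as.integer(heatmap_bin),
    n_bootstrap = as.integer(n_bootstrap),
    ci_level = ci_level,
    heatmap_cap_percentile = heatmap_cap_percentile,
    mapq_rna = as.integer(mapq_rna),
    mapq_chip = as.integer(mapq_chip),
    upregulated_families = as.character(upregulated_families),
    other_families = as.character(other_families),
    het_region = het_region,
    seed = as.integer(seed)
  )
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  lens <- c("kmer_length", "fragment_length", "bin_width", "tss_window_up",
            "tss_window_down", "cluster_min_gap", "proximity_radius",
            "control_min_distance", "matrix_before", "matrix_after",
            "profile_bin", "heatmap_bin", "n_bootstrap")
  for (k in lens) {
    if (!is.finite(cfg[[k]]) || cfg[[k]] <= 0L)
      stop("config: '", k, "' must be a positive integer", call. = FALSE)
  }
  if (cfg$pair_gap_shift < 0L)
    stop("config: 'pair_gap_shift' must be >= 0", call. = FALSE)
  if (cfg$mappability_min_frac <= 0 || cfg$mappability_min_frac > 1)
    stop("config: 'mappability_min_frac' must be in (0, 1]", call. = FALSE)
  if (cfg$ci_level <= 0 || cfg$ci_level >= 1)
    stop("config: 'ci_level' must be in (0, 1)", call. = FALSE)
  thr <- c("lfc_threshold", "padj_threshold", "rpkm_threshold")
  for (k in thr) {
    if (cfg[[k]] < 0) stop("config: '", k, "' must be >= 0", call. = FALSE)
  }
  if (length(intersect(cfg$upregulated_families, cfg$other_families)) > 0L)
    stop("config: upregulated and other family lists must be disjoint",
         call. = FALSE)
  if (!is.null(cfg$het_region)) {
    hr <- cfg$het_region
    if (!all(c("chrom", "start", "end") %in% names(hr)) ||
        hr$start < 0 || hr$end <= hr$start)
      stop("config: 'het_region' must have chrom, 0 <= start < end",
           call. = FALSE)
  }
  invisible(cfg)
}

#' Read a pipeline configuration from a JSON file
#'
#' The file holds a flat object whose keys match the arguments of
#' [pipeline_config()], plus an optional `sim` sub-object with arguments
#' for [sim_config()] and an optional logical `simulate` switch used by
#' [run_all()].
#'
#' @param path JSON file path.
#' @return list with elements `config` ([pipeline_config()] object),
#'   `sim` (list or NULL) and `simulate` (logical).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- raw$sim
  simulate <- isTRUE(raw$simulate)
  paths <- raw$paths
  raw$sim <- NULL
  raw$simulate <- NULL
  raw$paths <- NULL
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L)
    stop("config: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$het_region)) raw$het_region <- as.list(raw$het_region)
  cfg <- do.call(pipeline_config, raw)
  list(config = cfg, sim = sim, simulate = simulate, paths = paths)
}
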