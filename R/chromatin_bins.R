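#' Tile the genome into mappability-filtered bins
#'
#' Non-overlapping bins of `bin_width` bp tile each chromosome from 0;
#' the last partial bin of a chromosome is dropped, as is the
#' mitochondrial contig. Bins whose mean mappability does not exceed
#' `mappability_min_frac` are removed (at the default, bins with
#' mappability <= 50% go).
#'
#' @param genome [te_genome()].
#' @param track `mappability_track` covering the genome.
#' @param config [pipeline_config()].
#' @return data.table(chrom, start, end, mean_mappability) of retained
#'   bins.
#' @export
make_filtered_bins <- function(genome, track, config = pipeline_config()) {
  bw <- config$bin_width
  values <- if (inherits(track, "mappability_track")) track$values
            else track
  chroms <- setdiff(names(genome$lengths), genome$mito_name)
  rows <- lapply(chroms, function(nm) {
    L <- genome$lengths[[nm]]
    nb <- L %/% bw
    if (nb == 0L) return(NULL)
    v <- values[[nm]]
    if (is.null(v) || length(v) != L)
      stop("mappability track does not cover chromosome ", nm,
           call. = FALSE)
    cs <- c(0, cumsum(v))
    starts <- (seq_len(nb) - 1L) * bw
    data.table::data.table(chrom = nm, start = starts, end = starts + bw,
                           mean_mappability =
                             (cs[starts + bw + 1L] - cs[starts + 1L]) / bw)
  })
  bins <- data.table::rbindlist(rows)
  bins[mean_mappability > config$mappability_min_frac]
}

# distance from bin [start, end) to the nearest of a set of points:
# 0 when a point lies inside the bin, else the gap to the closest edge
dist_to_nearest_center <- function(bins, centers_by_chrom) {
  d <- rep(Inf, nrow(bins))
  for (nm in names(centers_by_chrom)) {
    ctr <- sort(centers_by_chrom[[nm]])
    if (length(ctr) == 0L) next
    idx <- which(bins$chrom == nm)
    if (length(idx) == 0L) next
    s <- bins$start[idx]
    e <- bins$end[idx]
    # candidate centers flanking each bin edge
    j <- findInterval(e - 1L, ctr)
    lo <- pmax(j, 1L)
    hi <- pmin(j + 1L, length(ctr))
    dd <- pmin(dist_point_bin(ctr[lo], s, e), dist_point_bin(ctr[hi], s, e))
    d[idx] <- dd
  }
  d
}

dist_point_bin <- function(p, s, e) {
  ifelse(p < s, s - p, ifelse(p >= e, p - e, 0L))
}

#' Assign bins to insertion-proximity categories
#'
#' Mutually exclusive categories with fixed precedence:
#' `near_upregulated_te` (bin within `proximity_radius` of an
#' upregulated-family insertion centre), then `near_other_te` (same rule
#' against the other-family list), then `control_het` (bin contained in
#' the heterochromatin control region and further than
#' `control_min_distance` from every insertion of any family), else
#' `unassigned`.
#'
#' @param bins bin table from [make_filtered_bins()].
#' @param insertions insertion table.
#' @param config [pipeline_config()]; `het_region` must be set when
#'   control bins are requested.
#' @param require_het error when `het_region` is missing (default TRUE).
#' @return `bins` with an added `category` column.
#' @export
assign_categories <- function(bins, insertions, config = pipeline_config(),
                              require_het = TRUE) {
  bins <- data.table::copy(data.table::as.data.table(bins))
  ins <- data.table::as.data.table(insertions)
  if (is.null(config$het_region) && require_het)
    stop("config: 'het_region' is required for category assignment",
         call. = FALSE)
  ctr <- insertion_centers(ins)
  by_chrom <- function(sel) split(ctr[sel], ins$chrom[sel])
  d_up <- dist_to_nearest_center(bins,
                                 by_chrom(ins$family %in%
                                            config$upregulated_families))
  d_other <- dist_to_nearest_center(bins,
                                    by_chrom(ins$family %in%
                                               config$other_families))
  d_all <- dist_to_nearest_center(bins, split(ctr, ins$chrom))
  cat <- rep("unassigned", nrow(bins))
  if (!is.null(config$het_region)) {
    hr <- config$het_region
    in_het <- bins$chrom == hr$chrom & bins$start >= hr$start &
      bins$end <= hr$end
    cat[in_het & d_all > config$control_min_distance] <- "control_het"
  }
  cat[d_other <= config$proximity_radius] <- "near_other_te"
  cat[d_up <= config$proximity_radius] <- "near_upregulated_te"
  bins[, category := cat]
  bins
}

#' Count fragments per bin and normalise
#'
#' Records are extended to `fragment_length` and centred
#' ([fragment_transform()]); each fragment is assigned to exactly the
#' bin containing its midpoint (default), which conserves totals, or to
#' every bin it overlaps (`assign = "overlap"`). The normalised signal is
#' `(count / mean_mappability) * 1e6 / library_size`, where the library
#' size of a sample is its total retained fragment count excluding the
#' mitochondrial contig. Callers are expected to have deduplicated and
#' mapping-quality-filtered `records` beforehand.
#'
#' @param records alignment-record table (deduplicated, mapq-filtered).
#' @param bins categorised bin table.
#' @param genome [te_genome()].
#' @param config [pipeline_config()].
#' @param conditions optional named character vector mapping sample ->
#'   condition; adds per-condition replicate-mean columns `mean.<cond>`.
#' @param assign `"midpoint"` or `"overlap"`.
#' @return `bins` with added `count.<sample>`, `norm.<sample>` and
#'   optionally `mean.<condition>` columns.
#' @export
bin_signal <- function(records, bins, genome, config = pipeline_config(),
                       conditions = NULL,
                       assign = c("midpoint", "overlap")) {
  assign <- match.arg(assign)
  bins <- data.table::copy(data.table::as.data.table(bins))
  bw <- config$bin_width
  frag <- fragment_transform(records, config$fragment_length,
                             center = TRUE, genome = genome)
  samples <- sort(unique(records$sample_id))
  nonmito <- frag$chrom != (genome$mito_name %||% "")
  lib <- vapply(samples, function(sm) sum(frag$sample_id == sm & nonmito),
                numeric(1L))
  if (any(lib == 0))
    stop("bin_signal: sample(s) with zero retained fragments: ",
         paste(samples[lib == 0], collapse = ", "), call. = FALSE)
  bins[, bin_idx := .I]
  if (assign == "midpoint") {
    frag[, mid := (start + end) %/% 2L]
    frag[, start := (mid %/% bw) * bw]
    key <- bins[, .(chrom, start, bin_idx)]
    hits <- merge(frag[, .(chrom, start, sample_id)], key,
                  by = c("chrom", "start"))
  } else {
    q <- frag[, .(chrom, qstart = start, qend = end - 1L, sample_id)]
    s <- bins[, .(chrom, bstart = start, bend = end - 1L, bin_idx)]
    data.table::setkey(s, chrom, bstart, bend)
    hits <- data.table::foverlaps(q, s, by.x = c("chrom", "qstart", "qend"),
                                  nomatch = NULL)
  }
  for (sm in samples) {
    cnt <- integer(nrow(bins))
    tb <- hits[sample_id == sm, .N, by = bin_idx]
    cnt[tb$bin_idx] <- tb$N
    bins[, (paste0("count.", sm)) := cnt]
    bins[, (paste0("norm.", sm)) :=
           (cnt / mean_mappability) * 1e6 / lib[[sm]]]
  }
  if (!is.null(conditions)) {
    for (cond in unique(conditions)) {
      sms <- intersect(names(conditions)[conditions == cond], samples)
      cols <- paste0("norm.", sms)
      bins[, (paste0("mean.", cond)) := rowMeans(.SD), .SDcols = cols]
    }
  }
  bins
}

#' Compare knockdown and control signal per bin category
#'
#' For each category: the fold change of medians with a pseudocount,
#' `(median(kd) + c) / (median(ctrl) + c)`, and a two-sided Wilcoxon
#' rank-sum test of knockdown versus control bin values. A category is
#' flagged significant when the median fold change differs more than
#' `fc_threshold`-fold (in either direction) and `p < p_threshold`.
#' Categories with fewer than 2 bins report `NA` statistics.
#'
#' @param bins bin table carrying `mean.<kd>` and `mean.<ctrl>` columns
#'   (see [bin_signal()]).
#' @param kd,ctrl condition names of knockdown and control.
#' @param categories categories to test (default: all but `unassigned`).
#' @param pseudocount pseudocount `c`; default half the smallest nonzero
#'   signal among the tested bins.
#' @param fc_threshold,p_threshold significance flag thresholds
#'   (defaults: 2-fold, 0.001).
#' @return data.table(category, n_bins, median_fc, p, significant).
#' @export
compare_categories <- function(bins, kd, ctrl, categories = NULL,
                               pseudocount = NULL, fc_threshold = 2,
                               p_threshold = 0.001) {
  bins <- data.table::as.data.table(bins)
  kcol <- paste0("mean.", kd)
  ccol <- paste0("mean.", ctrl)
  if (!all(c(kcol, ccol, "category") %in% names(bins)))
    stop("bins must carry 'category' and condition-mean columns",
         call. = FALSE)
  if (is.null(categories))
    categories <- setdiff(unique(bins$category), "unassigned")
  sel <- bins$category %in% categories
  if (is.null(pseudocount)) {
    vals <- c(bins[[kcol]][sel], bins[[ccol]][sel])
    nz <- vals[vals > 0]
    pseudocount <- if (length(nz) > 0L) min(nz) / 2 else 1
  }
  rows <- lapply(categories, function(cg) {
    kv <- bins[[kcol]][bins$category == cg]
    cv <- bins[[ccol]][bins$category == cg]
    n <- length(kv)
    if (n < 2L) {
      return(data.table::data.table(category = cg, n_bins = n,
                                    median_fc = NA_real_, p = NA_real_,
                                    significant = NA))
    }
    fc <- (median(kv) + pseudocount) / (median(cv) + pseudocount)
    p <- suppressWarnings(
      stats::wilcox.test(kv, cv, alternative = "two.sided",
                         exact = FALSE)$p.value)
    if (is.nan(p)) p <- 1  # all values tied
    data.table::data.table(category = cg, n_bins = n, median_fc = fc,
                           p = p,
                           significant = (fc > fc_threshold |
                                            fc < 1 / fc_threshold) &
                             p < p_threshold)
  })
  data.table::rbindlist(rows)
}

#' Per-base CPM coverage track
#'
#' ChIP mode extends reads to the configured fragment length and centres
#' them before accumulating per-base coverage; RNA mode uses the raw
#' read spans. Coverage is scaled by `1e6 / N` where `N` is the number of
#' retained reads of the library excluding the mitochondrial contig
#' (exact scaling: a single read yields covered bases at exactly 1e6).
#' Mapping-quality thresholds follow the mode (`mapq_chip` / `mapq_rna`);
#' ChIP reads are additionally deduplicated.
#'
#' @param records alignment-record table (one or more samples).
#' @param genome [te_genome()].
#' @param config [pipeline_config()].
#' @param mode `"chip"` or `"rna"`.
#' @return named list (per sample) of per-base track lists
#'   (chromosome -> numeric vector).
#' @export
coverage_track <- function(records, genome, config = pipeline_config(),
                           mode = c("chip", "rna")) {
  mode <- match.arg(mode)
  minq <- if (mode == "chip") config$mapq_chip else config$mapq_rna
  rec <- data.table::as.data.table(records)[mapq >= minq]
  if (mode == "chip") {
    rec <- deduplicate(rec)
    rec <- fragment_transform(rec, config$fragment_length, center = TRUE,
                              genome = genome)
  }
  samples <- sort(unique(rec$sample_id))
  out <- lapply(samples, function(sm) {
    sub <- rec[sample_id == sm]
    N <- sum(sub$chrom != (genome$mito_name %||% ""))
    if (N == 0L) N <- 1L
    accumulate_coverage(sub, genome$lengths, scale = 1e6 / N)
  })
  stats::setNames(out, samples)
}

accumulate_coverage <- function(rec, lengths, scale = 1) {
  lapply(stats::setNames(names(lengths), names(lengths)), function(nm) {
    L <- lengths[[nm]]
    sub <- rec[chrom == nm]
    if (nrow(sub) == 0L) return(numeric(L))
    d <- tabulate(sub$start + 1L, nbins = L + 1L) -
      tabulate(sub$end + 1L, nbins = L + 1L)
    cumsum(d)[seq_len(L)] * scale
  })
}

#' Per-consensus CPM coverage
#'
#' Per-base read coverage over each TE consensus sequence (records live
#' in consensus coordinate space, chromosome = family name), optionally
#' restricted to sense-strand reads, scaled per million retained reads.
#'
#' @param records alignment-record table in consensus space.
#' @param consensus_lengths named integer vector of consensus lengths.
#' @param sense_only count only `+`-strand (sense) reads.
#' @param min_mapq minimum mapping quality (default 0: all reads).
#' @return named list (per sample) of per-consensus numeric vectors.
#' @export
consensus_coverage <- function(records, consensus_lengths,
                               sense_only = TRUE, min_mapq = 0L) {
  rec <- data.table::as.data.table(records)[mapq >= min_mapq]
  unknown <- setdiff(unique(rec$chrom), names(consensus_lengths))
  if (length(unknown) > 0L)
    stop("records target unknown consensus: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (sense_only) rec <- rec[strand == "+"]
  samples <- sort(unique(rec$sample_id))
  out <- lapply(samples, function(sm) {
    sub <- rec[sample_id == sm]
    N <- max(nrow(sub), 1L)
    accumulate_coverage(sub, consensus_lengths, scale = 1e6 / N)
  })
  stats::setNames(out, samples)
}
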