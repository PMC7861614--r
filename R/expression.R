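#' Construct a count matrix container
#'
#' Features are genes and/or TE families (each TE consensus behaves as a
#' single-feature "chromosome" of class `te_family`).
#'
#' @param counts integer matrix, features x samples, with dimnames.
#' @param features data.frame(feature_id, class, length) matching rows.
#' @param samples data.frame(sample, condition) matching columns.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, features, samples) {
  features <- data.table::as.data.table(features)
  samples <- data.table::as.data.table(samples)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (nrow(counts) != nrow(features) || ncol(counts) != nrow(samples))
    stop("count_matrix: dimension mismatch", call. = FALSE)
  if (any(counts < 0L)) stop("count_matrix: negative counts", call. = FALSE)
  if (any(features$length <= 0L))
    stop("count_matrix: non-positive feature length", call. = FALSE)
  rownames(counts) <- features$feature_id
  colnames(counts) <- samples$sample
  structure(list(counts = counts, features = features, samples = samples),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts),
      "samples\n")
  cat("  classes:", paste(names(table(x$features$class)),
                          table(x$features$class), collapse = ", "), "\n")
  invisible(x)
}

#' Feature table for a TE consensus set
#'
#' Each consensus sequence becomes one full-length feature on its own
#' "chromosome" (named after the family), sense strand `+`.
#'
#' @param lengths named integer vector of consensus lengths.
#' @return data.table(feature_id, class, chrom, start, end, strand).
#' @export
consensus_features <- function(lengths) {
  data.table::data.table(feature_id = names(lengths), class = "te_family",
                         chrom = names(lengths), start = 0L,
                         end = as.integer(lengths), strand = "+")
}

#' Strand-aware unique-read counting over features
#'
#' A record is counted iff its mapping quality passes `min_mapq`, its
#' orientation matches the feature under the chosen strandedness
#' (`reverse`: read strand opposite the feature strand, as for dUTP
#' stranded RNA-seq; `forward`: equal; `unstranded`: any), and it
#' overlaps at least one feature. A record overlapping several features
#' is assigned to exactly one: the feature with the largest overlap in
#' bp, ties broken by feature order in the annotation. Each record
#' therefore contributes at most one count.
#'
#' @param records alignment-record table.
#' @param features data.table(feature_id, class, chrom, start, end,
#'   strand); `length` is derived as `end - start`.
#' @param strandedness one of `"reverse"`, `"forward"`, `"unstranded"`.
#' @param min_mapq minimum mapping quality (inclusive).
#' @param samples optional data.frame(sample, condition); defaults to the
#'   samples present in `records` with condition `NA`.
#' @return [count_matrix()] object.
#' @export
count_features <- function(records, features,
                           strandedness = c("reverse", "forward",
                                            "unstranded"),
                           min_mapq = 0L, samples = NULL) {
  strandedness <- match.arg(strandedness)
  features <- data.table::as.data.table(features)
  if (nrow(features) == 0L) stop("no features", call. = FALSE)
  feats <- data.table::copy(features)
  feats[, feat_idx := .I]
  if (is.null(samples)) {
    samples <- data.table::data.table(sample = sort(unique(records$sample_id)),
                                      condition = NA_character_)
  } else {
    samples <- data.table::as.data.table(samples)
  }

  rec <- data.table::as.data.table(records)[mapq >= min_mapq]
  counts <- matrix(0L, nrow = nrow(feats), ncol = nrow(samples),
                   dimnames = list(feats$feature_id, samples$sample))
  if (nrow(rec) > 0L) {
    rec[, rec_id := .I]
    # foverlaps works on closed intervals; shift ends to inclusive
    q <- rec[, .(chrom, qstart = start, qend = end - 1L, rec_id)]
    s <- feats[, .(chrom, fstart = start, fend = end - 1L, feat_idx)]
    data.table::setkey(s, chrom, fstart, fend)
    hits <- data.table::foverlaps(q, s, by.x = c("chrom", "qstart", "qend"),
                                  nomatch = NULL)
    if (nrow(hits) > 0L) {
      hits[, ov := pmin(qend, fend) - pmax(qstart, fstart) + 1L]
      hits <- merge(hits, rec[, .(rec_id, rstrand = strand,
                                  sample_id)], by = "rec_id")
      fstr <- feats$strand[hits$feat_idx]
      okstrand <- switch(strandedness,
        unstranded = rep(TRUE, nrow(hits)),
        forward = hits$rstrand == fstr | fstr == ".",
        reverse = hits$rstrand != fstr | fstr == ".")
      hits <- hits[okstrand]
      if (nrow(hits) > 0L) {
        data.table::setorder(hits, rec_id, -ov, feat_idx)
        best <- unique(hits, by = "rec_id")
        tab <- best[, .N, by = .(feat_idx, sample_id)]
        tab <- tab[sample_id %in% samples$sample]
        counts[cbind(tab$feat_idx, match(tab$sample_id, samples$sample))] <-
          tab$N
      }
    }
  }
  count_matrix(counts,
               feats[, .(feature_id, class, length = end - start)],
               samples)
}

#' Read a count matrix written by the pipeline
#'
#' TSV with columns `feature_id`, `class`, `length` followed by one
#' column per sample. Condition labels are taken from sample names
#' (`knockdown` if the name contains "knockdown", else `control`) unless
#' given explicitly.
#'
#' @param path TSV path.
#' @param conditions optional named character vector sample -> condition.
#' @return [count_matrix()].
#' @export
read_counts_tsv <- function(path, conditions = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("feature_id", "class", "length")
  if (!all(need %in% names(dt)))
    stop("counts table must have columns: ", paste(need, collapse = " "),
         call. = FALSE)
  smp <- setdiff(names(dt), need)
  if (is.null(conditions))
    conditions <- stats::setNames(
      ifelse(grepl("knockdown", smp), "knockdown", "control"), smp)
  count_matrix(as.matrix(dt[, smp, with = FALSE]),
               dt[, .(feature_id, class, length)],
               data.table::data.table(sample = smp,
                                      condition = conditions[smp]))
}

#' Median-of-ratios size factors
#'
#' The robust library-size estimate: for sample j,
#' `s_j = median_f counts[f, j] / geomean_k counts[f, k]`, where the
#' median runs over features with no zero count in any sample.
#'
#' @param cm [count_matrix()] object (or plain integer matrix).
#' @param features optional character vector restricting the features used
#'   (e.g. gene features only, as when TE counts borrow gene-derived size
#'   factors).
#' @return named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(cm, features = NULL) {
  m <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  if (!is.null(features)) m <- m[rownames(m) %in% features, , drop = FALSE]
  keep <- rowSums(m == 0L) == 0L
  if (!any(keep))
    stop("size_factors: no feature is nonzero in every sample",
         call. = FALSE)
  m <- m[keep, , drop = FALSE]
  geo <- exp(rowMeans(log(m)))
  s <- apply(m, 2L, function(col) median(col / geo))
  if (any(!is.finite(s)) || any(s <= 0))
    stop("size_factors: non-positive size factor", call. = FALSE)
  s
}

#' RPKM and CPM on robust library sizes
#'
#' Counts are first divided by the per-sample size factor; the robust
#' library size is the column sum of these normalised counts. CPM is
#' normalised counts per million of that library; RPKM additionally
#' divides by feature length in kb.
#'
#' @param cm [count_matrix()].
#' @param s size-factor vector (default: [size_factors()] of `cm`).
#' @return list(norm, cpm, rpkm): numeric matrices shaped like the counts.
#' @export
rpkm_cpm <- function(cm, s = size_factors(cm)) {
  m <- cm$counts
  norm <- sweep(m, 2L, s, "/")
  lib <- colSums(norm)
  if (any(lib <= 0)) stop("rpkm_cpm: zero library size", call. = FALSE)
  cpm <- sweep(norm, 2L, lib, "/") * 1e6
  rpkm <- cpm * 1e3 / cm$features$length
  list(norm = norm, cpm = cpm, rpkm = rpkm)
}

#' Fold change and significance between two conditions
#'
#' Log2 fold changes are computed on size-factor-normalised counts with a
#' pseudocount, as
#' `lfc = log2((mean_KD + c) / (mean_ctrl + c))`. Significance comes from
#' a pluggable per-feature test (default: Welch two-sample t-test on
#' `log2(normalised count + c)`); p-values are Benjamini-Hochberg
#' adjusted across all features. This deliberately replaces a full
#' negative-binomial engine: the downstream biological thresholds, not
#' the test engine, are the contract here.
#'
#' @param cm [count_matrix()].
#' @param s size-factor vector.
#' @param groups character vector (length = samples) of condition labels;
#'   exactly two distinct labels, each with >= 2 samples.
#' @param kd label of the knockdown (numerator) condition; default: the
#'   second label in sorted order.
#' @param test function(kd_log2_values, ctrl_log2_values) -> p-value, or
#'   NULL for the built-in t-test.
#' @param pseudocount pseudocount `c` (default 0.5).
#' @return data.table(feature_id, class, lfc, p, padj, rpkm_mean).
#' @export
fold_change_and_test <- function(cm, s = size_factors(cm), groups,
                                 kd = NULL, test = NULL, pseudocount = 0.5) {
  lv <- sort(unique(groups))
  if (length(lv) != 2L)
    stop("exactly two condition labels required", call. = FALSE)
  if (is.null(kd)) kd <- lv[2L]
  ctrl <- setdiff(lv, kd)
  if (sum(groups == kd) < 2L || sum(groups == ctrl) < 2L)
    stop("each condition needs >= 2 samples", call. = FALSE)
  nm <- rpkm_cpm(cm, s)
  norm <- nm$norm
  lkd <- log2(norm[, groups == kd, drop = FALSE] + pseudocount)
  lct <- log2(norm[, groups == ctrl, drop = FALSE] + pseudocount)
  lfc <- log2(rowMeans(norm[, groups == kd, drop = FALSE]) + pseudocount) -
    log2(rowMeans(norm[, groups == ctrl, drop = FALSE]) + pseudocount)
  if (is.null(test)) test <- builtin_log_t_test
  p <- vapply(seq_len(nrow(norm)),
              function(i) test(lkd[i, ], lct[i, ]), numeric(1L))
  p <- pmin(pmax(p, 0), 1)
  data.table::data.table(feature_id = cm$features$feature_id,
                         class = cm$features$class,
                         lfc = lfc, p = p,
                         padj = stats::p.adjust(p, method = "BH"),
                         rpkm_mean = rowMeans(nm$rpkm))
}

# Welch t-test on log2 values; degenerate (zero-variance) features fall
# back to p = 1 when means agree and p = 0 otherwise.
builtin_log_t_test <- function(x, y) {
  if (stats::var(x) < 1e-12 && stats::var(y) < 1e-12) {
    return(if (abs(mean(x) - mean(y)) < 1e-9) 1 else 0)
  }
  tryCatch(stats::t.test(x, y)$p.value, error = function(e) 1)
}

#' Classify features as de-repressed
#'
#' A feature is `upregulated` iff `lfc > lfc_threshold`,
#' `padj < padj_threshold` and `rpkm_mean > rpkm_threshold`
#' (>4-fold change, adjusted p < 0.05, >1 RPKM at the defaults);
#' `downregulated` is symmetric with `lfc < -lfc_threshold`. Features at
#' or below the RPKM floor are `low_expression` regardless of fold
#' change; everything else is `not_significant`.
#'
#' @param de result of [fold_change_and_test()].
#' @param config [pipeline_config()] supplying the three thresholds.
#' @return `de` with an added `label` column.
#' @export
classify_de <- function(de, config = pipeline_config()) {
  de <- data.table::as.data.table(de)
  lab <- rep("not_significant", nrow(de))
  up <- de$lfc > config$lfc_threshold & de$padj < config$padj_threshold
  dn <- de$lfc < -config$lfc_threshold & de$padj < config$padj_threshold
  lab[up & !is.na(up)] <- "upregulated"
  lab[dn & !is.na(dn)] <- "downregulated"
  lab[de$rpkm_mean <= config$rpkm_threshold] <- "low_expression"
  out <- data.table::copy(de)
  out[, label := lab]
  out
}

#' Delta-delta-CT fold change
#'
#' qPCR relative quantification: `2^-ddCT` with
#' `ddCT = (ct_target - ct_ref) - (ct_target_ctrl - ct_ref_ctrl)`.
#'
#' @param ct_target,ct_ref CT cycles of target and reference gene in the
#'   treated sample.
#' @param ct_target_ctrl,ct_ref_ctrl same in the control sample.
#' @return fold change (numeric).
#' @export
#' @examples
#' ddct_fold_change(20, 15, 23, 15.5)  # 2^2.5
ddct_fold_change <- function(ct_target, ct_ref, ct_target_ctrl,
                             ct_ref_ctrl) {
  stopifnot(is.finite(ct_target), is.finite(ct_ref),
            is.finite(ct_target_ctrl), is.finite(ct_ref_ctrl))
  ddct <- (ct_target - ct_ref) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
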