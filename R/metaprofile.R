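#' Insertion-anchored signal matrix
#'
#' One row per insertion; columns are positional bins of `bin_size` bp
#' spanning `[-before, +after)` around the insertion reference point
#' (interval centre). Each cell is the mean track value over its bin;
#' positions beyond chromosome bounds contribute 0 (missing data as
#' zero).
#'
#' @param track per-base track: named list of numeric vectors (or a
#'   `mappability_track`).
#' @param points insertion table (family, chrom, start, end).
#' @param before,after window extent in bp upstream/downstream of the
#'   reference point.
#' @param bin_size positional bin width in bp; must divide
#'   `before + after`.
#' @return object of class `meta_matrix`: list(values, points, before,
#'   after, bin_size).
#' @export
reference_point_matrix <- function(track, points, before = 10000L,
                                   after = 15000L, bin_size = 50L) {
  values <- if (inherits(track, "mappability_track")) track$values else track
  span <- before + after
  if (span %% bin_size != 0L)
    stop("bin_size must divide before + after", call. = FALSE)
  ncol <- span %/% bin_size
  points <- data.table::as.data.table(points)
  ctr <- insertion_centers(points)
  mat <- matrix(0, nrow = nrow(points), ncol = ncol)
  for (i in seq_len(nrow(points))) {
    v <- values[[points$chrom[i]]]
    if (is.null(v)) stop("unknown chromosome: ", points$chrom[i],
                         call. = FALSE)
    L <- length(v)
    w0 <- ctr[i] - before                    # window start, 0-based
    lo <- max(w0, 0L)
    hi <- min(w0 + span, L)
    win <- numeric(span)
    if (hi > lo) win[(lo - w0 + 1L):(hi - w0)] <- v[(lo + 1L):hi]
    mat[i, ] <- colMeans(matrix(win, nrow = bin_size))
  }
  rn <- if ("family" %in% names(points)) {
    paste0(points$family, "_", points$chrom, ":", points$start)
  } else {
    paste0(points$chrom, ":", points$start)
  }
  rownames(mat) <- make.unique(rn)
  colnames(mat) <- seq(-before, after - bin_size, by = bin_size)
  structure(list(values = mat, points = points, before = before,
                 after = after, bin_size = bin_size),
            class = "meta_matrix")
}

#' @export
print.meta_matrix <- function(x, ...) {
  cat("meta_matrix:", nrow(x$values), "reference points x",
      ncol(x$values), "positional bins of", x$bin_size, "bp\n")
  invisible(x)
}

#' Bootstrap mean profile with confidence intervals
#'
#' The profile is the plain column mean over rows (insertions); the
#' confidence band is a percentile bootstrap over rows (resampled with
#' replacement `n_boot` times). Resampling rows is the statistically
#' coherent choice: insertions are the sampling units, positions are
#' not. The returned band is clipped so that
#' `ci_low <= mean <= ci_high`. Deterministic under `seed`. With fewer
#' than 2 rows the band degenerates to the mean.
#'
#' @param mat `meta_matrix` (or plain numeric matrix).
#' @param n_boot number of bootstrap resamples.
#' @param ci_level confidence level.
#' @param seed integer RNG seed.
#' @return data.table(position, mean, ci_low, ci_high).
#' @export
profile_bootstrap <- function(mat, n_boot = 200L, ci_level = 0.95,
                              seed = 1L) {
  m <- if (inherits(mat, "meta_matrix")) mat$values else as.matrix(mat)
  pos <- if (!is.null(colnames(m))) as.numeric(colnames(m))
         else seq_len(ncol(m))
  mu <- colMeans(m)
  if (nrow(m) < 2L) {
    return(data.table::data.table(position = pos, mean = mu, ci_low = mu,
                                  ci_high = mu))
  }
  set.seed(seed)
  boot <- matrix(NA_real_, nrow = n_boot, ncol = ncol(m))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(m), nrow(m), replace = TRUE)
    boot[b, ] <- colMeans(m[idx, , drop = FALSE])
  }
  alpha <- (1 - ci_level) / 2
  lo <- apply(boot, 2L, stats::quantile, probs = alpha, names = FALSE)
  hi <- apply(boot, 2L, stats::quantile, probs = 1 - alpha, names = FALSE)
  data.table::data.table(position = pos, mean = mu,
                         ci_low = pmin(lo, mu), ci_high = pmax(hi, mu))
}

#' Cap and sort a heatmap matrix
#'
#' Values above the `cap_percentile` percentile (computed over the whole
#' matrix) are set to that percentile; rows are ordered by decreasing
#' row mean of `sort_reference` (e.g. the control sample), preserving row
#' identity. Idempotent.
#'
#' @param mat `meta_matrix` to cap.
#' @param cap_percentile percentile in `(0, 100]`.
#' @param sort_reference row-aligned `meta_matrix` used for ordering;
#'   default: `mat` itself.
#' @return `meta_matrix` with capped, reordered values.
#' @export
heatmap_prepare <- function(mat, cap_percentile = 99,
                            sort_reference = mat) {
  m <- mat$values
  r <- sort_reference$values
  if (nrow(m) != nrow(r) ||
      !identical(mat$points[, .(chrom, start, end)],
                 sort_reference$points[, .(chrom, start, end)]))
    stop("heatmap_prepare: matrices are not row-aligned", call. = FALSE)
  # type-1 (order statistic) quantile so that re-capping is a no-op
  cap <- stats::quantile(m, probs = cap_percentile / 100, names = FALSE,
                         type = 1)
  m <- pmin(m, cap)
  ord <- order(-rowMeans(r))
  out <- mat
  out$values <- m[ord, , drop = FALSE]
  out$points <- mat$points[ord]
  out
}

#' Write a meta matrix as TSV
#'
#' @param mat `meta_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_meta_matrix <- function(mat, path) {
  dt <- data.table::as.data.table(mat$values, keep.rownames = "row")
  write_tsv(dt, path)
}
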