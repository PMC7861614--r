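#' Exact k-mer genome mappability track
#'
#' Constructs all n-mers of the genome and marks an n-mer starting at
#' position p as uniquely mapping iff its sequence occurs at exactly one
#' location across both strands of the whole genome (its own origin).
#' Per-base mappability is the number of uniquely mapping n-mers covering
#' a coordinate, divided by n, so values lie in `[0, 1]` and the track
#' total equals the number of unique n-mers exactly.
#'
#' Uniqueness is exact string matching (no mismatch tolerance). A
#' palindromic n-mer whose two strand hits share one locus counts as
#' unique. Positions within n-1 bases of a chromosome edge are covered by
#' fewer than n n-mers and therefore cannot reach mappability 1 even in
#' unique sequence; this is by construction, not a defect.
#'
#' @param genome [te_genome()] object.
#' @param n k-mer (read) length in bp.
#' @param unique_flags optional externally computed uniqueness, a named
#'   list (per chromosome) of logical vectors of length
#'   `chromosome length - n + 1`; overrides the internal exact-match
#'   classification (hook for mismatch-tolerant aligners).
#' @return object of class `mappability_track`: list with `values` (named
#'   list of per-base numeric vectors) and `n`.
#' @export
#' @examples
#' g <- te_genome(c(c1 = "ACGTTGCA"))
#' kmer_mappability(g, 4)$values$c1
kmer_mappability <- function(genome, n, unique_flags = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  chroms <- names(genome$lengths)
  km <- lapply(chroms, function(nm) {
    L <- genome$lengths[[nm]]
    if (L < n) return(NULL)
    p0 <- 0:(L - n)
    # reverse complement of the k-mer at p is a substring of the
    # reverse-complemented chromosome: one chartr/reverse per chromosome
    # instead of one per k-mer
    rcseq <- revcomp(genome$sequences[[nm]])
    data.table::data.table(chrom = nm, pos = p0,
                           k = substring(genome$sequences[[nm]],
                                         p0 + 1L, p0 + n),
                           rk = substring(rcseq, L - p0 - n + 1L, L - p0))
  })
  km <- data.table::rbindlist(km)
  if (nrow(km) > 0L) {
    if (is.null(unique_flags)) {
      km[, canon := data.table::fifelse(k <= rk, k, rk)]
      km[, uniq := .N == 1L, by = canon]
    } else {
      km[, uniq := unlist(unique_flags[chroms], use.names = FALSE)]
    }
  }
  values <- lapply(chroms, function(nm) {
    L <- genome$lengths[[nm]]
    v <- numeric(L)
    if (L >= n) {
      starts <- km[chrom == nm & uniq == TRUE, pos]
      if (length(starts) > 0L) {
        d <- tabulate(starts + 1L, nbins = L + 1L) -
          tabulate(starts + n + 1L, nbins = L + 1L)
        v <- cumsum(d)[seq_len(L)] / n
      }
    }
    v
  })
  structure(list(values = stats::setNames(values, chroms), n = n),
            class = "mappability_track")
}

#' Paired-fragment mappability approximation
#'
#' For 2 x n-bp paired-end data, mappability is approximated twice and
#' averaged position-wise: (i) as the single-fragment track with k-mer
#' length `2 * n`, and (ii) from all ordered pairs where mate 1 is the
#' n-mer at p and mate 2 is the reverse complement of the n-mer at
#' `p + shift`. A pair is unique iff that ordered pair of sequences with
#' that separation occurs at exactly one locus over both strands. Each
#' mate of a unique pair contributes `1/(2n)` over its own span (total
#' pair mass 1). Pairs whose second mate would run off the chromosome are
#' skipped and contribute no coverage.
#'
#' @inheritParams kmer_mappability
#' @param shift distance in bp between mate start positions.
#' @return `mappability_track` (the mean of the two approaches).
#' @export
paired_mappability <- function(genome, n, shift) {
  n <- as.integer(n)
  shift <- as.integer(shift)
  if (is.na(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  if (is.na(shift) || shift < 0L) stop("shift must be >= 0", call. = FALSE)
  single <- kmer_mappability(genome, 2L * n)

  chroms <- names(genome$lengths)
  span <- shift + n
  pr <- lapply(chroms, function(nm) {
    L <- genome$lengths[[nm]]
    if (L < span) return(NULL)
    p0 <- 0:(L - span)
    sq <- genome$sequences[[nm]]
    rcseq <- revcomp(sq)
    k1 <- substring(sq, p0 + 1L, p0 + n)
    k2 <- substring(sq, p0 + shift + 1L, p0 + shift + n)
    rk1 <- substring(rcseq, L - p0 - n + 1L, L - p0)
    rk2 <- substring(rcseq, L - p0 - shift - n + 1L, L - p0 - shift)
    data.table::data.table(chrom = nm, pos = p0, sig = paste0(k1, "|", k2),
                           rsig = paste0(rk2, "|", rk1))
  })
  pr <- data.table::rbindlist(pr)
  if (nrow(pr) > 0L) {
    pr[, canon := data.table::fifelse(sig <= rsig, sig, rsig)]
    pr[, cnt := .N, by = canon]
  }
  values <- lapply(chroms, function(nm) {
    L <- genome$lengths[[nm]]
    v <- numeric(L)
    if (nrow(pr) > 0L) {
      starts <- pr[chrom == nm & cnt == 1L, pos]
      if (length(starts) > 0L) {
        d <- tabulate(starts + 1L, nbins = L + 1L) -
          tabulate(starts + n + 1L, nbins = L + 1L) +
          tabulate(starts + shift + 1L, nbins = L + 1L) -
          tabulate(starts + shift + n + 1L, nbins = L + 1L)
        v <- cumsum(d)[seq_len(L)] / (2 * n)
      }
    }
    (v + single$values[[nm]]) / 2
  })
  structure(list(values = stats::setNames(values, chroms), n = n,
                 shift = shift, paired = TRUE),
            class = "mappability_track")
}

#' Mean mappability over an interval
#'
#' @param track `mappability_track` (or any per-base track list).
#' @param interval one-row interval table (chrom, start, end).
#' @return numeric scalar in `[0, 1]`.
#' @export
region_mean_mappability <- function(track, interval) {
  values <- if (inherits(track, "mappability_track")) track$values
            else track
  if (nrow(interval) != 1L)
    stop("region_mean_mappability expects a single interval", call. = FALSE)
  if (interval$end <= interval$start)
    stop("zero-width interval", call. = FALSE)
  v <- values[[interval$chrom]]
  if (is.null(v)) stop("unknown chromosome: ", interval$chrom, call. = FALSE)
  if (interval$end > length(v))
    stop("interval beyond chromosome end", call. = FALSE)
  mean(v[(interval$start + 1L):interval$end])
}

#' @export
print.mappability_track <- function(x, ...) {
  cat("mappability_track: n =", x$n,
      if (isTRUE(x$paired)) paste0("(paired, shift = ", x$shift, ")") else "",
      "\n")
  tot <- sum(vapply(x$values, sum, numeric(1)))
  cat("  chromosomes:", length(x$values),
      " total mass:", format(tot), "\n")
  invisible(x)
}
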