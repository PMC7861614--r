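# Shared fixtures and independent brute-force oracles.
# Oracles deliberately use naive per-position string matching / double
# loops so they share no code path with the implementation.

rand_genome <- function(lens, seed = NULL, mito = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1L))
  if (is.null(names(lens)))
    names(seqs) <- paste0("chr", seq_along(lens))
  te_genome(seqs, mito_name = mito)
}

# plant an exact duplication of a random subsequence within the genome:
# source from the first half, copy into the second half (never overlapping)
plant_duplication <- function(genome, dup_len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eligible <- names(genome$lengths)[genome$lengths >= 2L * dup_len + 2L]
  stopifnot(length(eligible) > 0L)
  nm <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
  s <- genome$sequences[[nm]]
  L <- nchar(s)
  half <- L %/% 2L
  src <- sample.int(half - dup_len + 1L, 1L)
  piece <- substring(s, src, src + dup_len - 1L)
  dst <- half + sample.int(L - half - dup_len + 1L, 1L)
  substr(s, dst, dst + dup_len - 1L) <- piece
  seqs <- genome$sequences
  seqs[[nm]] <- s
  te_genome(seqs, mito_name = genome$mito_name)
}

# exhaustive string-match mappability oracle
oracle_kmer_track <- function(genome, n) {
  allk <- lapply(genome$sequences, function(s) {
    L <- nchar(s)
    if (L < n) character(0) else substring(s, 1:(L - n + 1L), n:L)
  })
  flat <- unlist(allk, use.names = FALSE)
  out <- lapply(names(genome$sequences), function(nm) {
    L <- genome$lengths[[nm]]
    v <- numeric(L)
    ks <- allk[[nm]]
    for (p in seq_along(ks)) {
      q <- ks[p]
      rcq <- revcomp(q)
      if (sum(flat == q | flat == rcq) == 1L)
        v[p:(p + n - 1L)] <- v[p:(p + n - 1L)] + 1 / n
    }
    v
  })
  stats::setNames(out, names(genome$sequences))
}

# exhaustive ordered-pair-enumeration oracle, averaged with the 2n-mer
# oracle (mirrors the paired definition, not the implementation)
oracle_paired_track <- function(genome, n, shift) {
  single <- oracle_kmer_track(genome, 2L * n)
  span <- shift + n
  prs <- lapply(genome$sequences, function(s) {
    L <- nchar(s)
    if (L < span) return(list(k1 = character(0), k2 = character(0)))
    p0 <- 0:(L - span)
    list(k1 = substring(s, p0 + 1L, p0 + n),
         k2 = substring(s, p0 + shift + 1L, p0 + shift + n))
  })
  K1 <- unlist(lapply(prs, `[[`, "k1"), use.names = FALSE)
  K2 <- unlist(lapply(prs, `[[`, "k2"), use.names = FALSE)
  out <- lapply(names(genome$sequences), function(nm) {
    L <- genome$lengths[[nm]]
    v <- numeric(L)
    k1 <- prs[[nm]]$k1
    k2 <- prs[[nm]]$k2
    for (p in seq_along(k1)) {
      a <- k1[p]
      b <- k2[p]
      cnt <- sum((K1 == a & K2 == b) | (K1 == revcomp(b) & K2 == revcomp(a)))
      if (cnt == 1L) {
        v[p:(p + n - 1L)] <- v[p:(p + n - 1L)] + 1 / (2 * n)
        v[(p + shift):(p + shift + n - 1L)] <-
          v[(p + shift):(p + shift + n - 1L)] + 1 / (2 * n)
      }
    }
    (v + single[[nm]]) / 2
  })
  stats::setNames(out, names(genome$sequences))
}

rand_records <- function(n, genome, samples = c("s1", "s2"),
                         mapq_pool = c(0L, 30L, 255L), width = c(30L, 60L),
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chrom <- sample(names(genome$lengths), n, replace = TRUE)
  w <- sample(width[1L]:width[2L], n, replace = TRUE)
  start <- vapply(seq_len(n), function(i)
    sample.int(genome$lengths[[chrom[i]]] - w[i], 1L) - 1L, integer(1L))
  alignment_records(chrom, start, start + w,
                    sample(c("+", "-"), n, replace = TRUE),
                    mapq_pool[sample.int(length(mapq_pool), n,
                                         replace = TRUE)],
                    samples[sample.int(length(samples), n,
                                       replace = TRUE)])
}

# brute-force largest-overlap counting oracle (double loop)
oracle_count <- function(records, features, strandedness, min_mapq) {
  feats <- as.data.frame(features)
  rec <- as.data.frame(records)
  samples <- sort(unique(rec$sample_id))
  m <- matrix(0L, nrow = nrow(feats), ncol = length(samples),
              dimnames = list(feats$feature_id, samples))
  for (i in seq_len(nrow(rec))) {
    if (rec$mapq[i] < min_mapq) next
    best <- 0L
    best_f <- NA_integer_
    for (f in seq_len(nrow(feats))) {
      if (feats$chrom[f] != rec$chrom[i]) next
      oks <- switch(strandedness,
                    unstranded = TRUE,
                    forward = feats$strand[f] == "." ||
                      rec$strand[i] == feats$strand[f],
                    reverse = feats$strand[f] == "." ||
                      rec$strand[i] != feats$strand[f])
      if (!oks) next
      ov <- min(rec$end[i], feats$end[f]) - max(rec$start[i], feats$start[f])
      if (ov > best) {
        best <- ov
        best_f <- f
      }
    }
    if (best > 0L)
      m[best_f, match(rec$sample_id[i], samples)] <-
        m[best_f, match(rec$sample_id[i], samples)] + 1L
  }
  m
}

demo_config_path <- function() {
  system.file("extdata", "demo_config.json", package = "teinsite")
}
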