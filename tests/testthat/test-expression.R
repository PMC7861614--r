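make_features <- function() {
  data.table::data.table(
    feature_id = c("geneA", "geneB", "te1"),
    class = c("gene", "gene", "te_family"),
    chrom = c("c1", "c1", "te1"),
    start = c(100L, 160L, 0L),
    end = c(200L, 400L, 500L),
    strand = c("+", "+", "+"))
}

test_that("count_features honours strand mode, mapq and largest overlap", {
  feats <- make_features()
  # read on '-' over a '+' gene: counted in reverse mode, not forward
  r1 <- alignment_records("c1", 110, 160, "-", 60, "s1")
  expect_identical(
    sum(count_features(r1, feats, "reverse", 50)$counts), 1L)
  expect_identical(
    sum(count_features(r1, feats, "forward", 50)$counts), 0L)
  expect_identical(
    sum(count_features(r1, feats, "unstranded", 50)$counts), 1L)
  # mapq below threshold -> not counted
  r2 <- alignment_records("c1", 110, 160, "-", 0, "s1")
  expect_identical(sum(count_features(r2, feats, "reverse", 50)$counts), 0L)
  # 30 bp on geneA vs 100 bp on geneB -> one count, to geneB
  r3 <- alignment_records("c1", 170, 270, "-", 60, "s1")
  cm <- count_features(r3, feats, "reverse", 50)
  expect_identical(as.vector(cm$counts[, "s1"]), c(0L, 1L, 0L))
  # exact overlap tie -> first feature in annotation order wins
  r4 <- alignment_records("c1", 130, 230, "-", 60, "s1")
  cm4 <- count_features(r4, feats, "reverse", 50)
  expect_identical(as.vector(cm4$counts[, "s1"]), c(1L, 0L, 0L))
})

test_that("count_features matches the double-loop oracle in all modes", {
  feats <- data.table::data.table(
    feature_id = sprintf("f%02d", 1:12),
    class = "gene",
    chrom = rep(c("chr1", "chr2"), each = 6L),
    start = rep(seq(0L, 1500L, by = 300L), 2L),
    end = rep(seq(0L, 1500L, by = 300L), 2L) +
      rep(c(250L, 350L), 6L),  # some overlapping neighbours
    strand = rep(c("+", "-", "."), 4L))
  g <- rand_genome(c(chr1 = 2000L, chr2 = 2000L), seed = 71)
  set.seed(72)
  rec <- rand_records(500L, g)
  for (mode in c("reverse", "forward", "unstranded")) {
    got <- count_features(rec, feats, mode, min_mapq = 30L)$counts
    want <- oracle_count(rec, feats, mode, 30L)
    expect_identical(got[, colnames(want)], want)
  }
  # conservation: each record contributes at most one count
  got <- count_features(rec, feats, "unstranded", 0L)$counts
  expect_lte(sum(got), nrow(rec))
})

test_that("size_factors: symmetry, scaling and direct-formula oracle", {
  f <- data.table::data.table(feature_id = paste0("f", 1:3),
                              class = "gene", length = 1000L)
  s2 <- data.table::data.table(sample = c("a", "b"), condition = "x")
  m <- matrix(c(10L, 20L, 30L, 10L, 20L, 30L), ncol = 2)
  expect_equal(unname(size_factors(count_matrix(m, f, s2))), c(1, 1))
  m2 <- matrix(c(10L, 20L, 30L, 20L, 40L, 60L), ncol = 2)
  expect_equal(unname(size_factors(count_matrix(m2, f, s2))),
               c(1 / sqrt(2), sqrt(2)))

  # random 200 x 4 vs brute-force median-of-ratios
  set.seed(81)
  m3 <- matrix(rnbinom(800L, mu = 50, size = 5), ncol = 4)
  f3 <- data.table::data.table(feature_id = paste0("f", 1:200),
                               class = "gene", length = 1000L)
  s4 <- data.table::data.table(sample = paste0("s", 1:4), condition = "x")
  cm <- count_matrix(m3, f3, s4)
  got <- size_factors(cm)
  keep <- apply(m3, 1L, function(r) all(r > 0L))
  geo <- apply(m3[keep, ], 1L, function(r) exp(mean(log(r))))
  want <- apply(m3[keep, ], 2L, function(col) median(col / geo))
  expect_equal(unname(got), unname(want))

  # scale equivariance: scaling one sample rescales its size factor by c
  # (up to the global geometric-mean reference shared by all samples), so
  # normalised counts agree up to one global scalar and CPM is invariant
  m4 <- m3
  m4[, 2L] <- m4[, 2L] * 3L
  s_a <- size_factors(cm)
  s_b <- size_factors(count_matrix(m4, f3, s4))
  expect_equal(unname(s_b / s_a), c(1, 3, 1, 1) * 3^(-1 / 4),
               tolerance = 1e-9)
  norm_a <- sweep(m3, 2L, s_a, "/")
  norm_b <- sweep(m4, 2L, s_b, "/")
  ratio <- norm_b / norm_a
  expect_lt(max(ratio) - min(ratio), 1e-9)
  cpm_a <- rpkm_cpm(cm, s_a)$cpm
  cpm_b <- rpkm_cpm(count_matrix(m4, f3, s4), s_b)$cpm
  expect_equal(cpm_a, cpm_b, tolerance = 1e-9)

  expect_error(size_factors(matrix(c(0L, 1L, 1L, 0L), 2L)), "nonzero")
})

test_that("rpkm_cpm implements the stated formulas", {
  f <- data.table::data.table(feature_id = "f1", class = "gene",
                              length = 2000L)
  sm <- data.table::data.table(sample = c("a", "b"), condition = "x")
  cm <- count_matrix(matrix(c(100L, 100L), ncol = 2), f, sm)
  out <- rpkm_cpm(cm, s = c(1, 1))
  # single feature: library = 100, cpm = 1e6, rpkm = 1e6 * 1e3 / 2000
  expect_equal(unname(out$cpm[1, ]), c(1e6, 1e6))
  expect_equal(unname(out$rpkm[1, ]), c(5e5, 5e5))
  # the stated worked example: count 100, length 2 kb, library 1e6 -> 50
  expect_equal(100 * 1e6 / 1e6 * 1e3 / 2000, 50)

  # random matrix vs element-wise oracle
  set.seed(91)
  m <- matrix(rnbinom(120L, mu = 30, size = 3) + 1L, ncol = 4)
  f2 <- data.table::data.table(feature_id = paste0("f", 1:30),
                               class = "gene",
                               length = sample(500:3000, 30L))
  s4 <- data.table::data.table(sample = paste0("s", 1:4), condition = "x")
  cm2 <- count_matrix(m, f2, s4)
  s <- size_factors(cm2)
  out2 <- rpkm_cpm(cm2, s)
  for (j in 1:4) {
    nj <- m[, j] / s[j]
    expect_equal(unname(out2$cpm[, j]), nj * 1e6 / sum(nj))
    expect_equal(unname(out2$rpkm[, j]),
                 nj * 1e6 / sum(nj) * 1e3 / f2$length)
  }
  # identical samples give identical columns
  expect_equal(out$rpkm[, 1], out$rpkm[, 2])
})

test_that("fold_change_and_test: limits, symmetry and BH adjustment", {
  f <- data.table::data.table(feature_id = paste0("f", 1:20),
                              class = "gene", length = 1000L)
  sm <- data.table::data.table(sample = paste0("s", 1:4),
                               condition = c("ctrl", "ctrl", "kd", "kd"))
  set.seed(101)
  base <- matrix(rnbinom(80L, mu = 200, size = 10) + 1L, ncol = 4)

  # identical groups -> lfc exactly 0
  m_eq <- cbind(base[, 1:2], base[, 1:2])
  de_eq <- fold_change_and_test(count_matrix(m_eq, f, sm), s = rep(1, 4),
                                groups = sm$condition, kd = "kd")
  expect_equal(de_eq$lfc, rep(0, 20))

  # kd exactly 4x control with s = 1 -> lfc -> 2 for large counts
  m4 <- cbind(base[, 1:2], base[, 1:2] * 4L)
  de4 <- fold_change_and_test(count_matrix(m4, f, sm), s = rep(1, 4),
                              groups = sm$condition, kd = "kd")
  expect_true(all(abs(de4$lfc - 2) < 0.02))

  # swapping the kd label negates every lfc exactly
  de_swap <- fold_change_and_test(count_matrix(m4, f, sm), s = rep(1, 4),
                                  groups = sm$condition, kd = "ctrl")
  expect_equal(de_swap$lfc, -de4$lfc)
  expect_equal(de_swap$p, de4$p)

  # BH step-up hand example
  expect_equal(p.adjust(c(0.01, 0.02, 0.04, 0.05), method = "BH"),
               c(0.04, 0.04, 0.05, 0.05))

  # pluggable test is honoured
  de_plug <- fold_change_and_test(count_matrix(m4, f, sm), s = rep(1, 4),
                                  groups = sm$condition, kd = "kd",
                                  test = function(x, y) 0.123)
  expect_true(all(de_plug$p == 0.123))

  expect_error(
    fold_change_and_test(count_matrix(m4[, c(1, 3, 4)], f,
                                      sm[c(1, 3, 4)]),
                         s = rep(1, 3),
                         groups = sm$condition[c(1, 3, 4)], kd = "kd"),
    ">= 2 samples")
})

test_that("fold-change estimator recovers a planted lfc of 2.3", {
  est <- numeric(20L)
  for (s in 1:20) {
    set.seed(500 + s)
    mu0 <- 400
    m <- cbind(matrix(rnbinom(50L * 2L, mu = mu0, size = 20), ncol = 2),
               matrix(rnbinom(50L * 2L, mu = mu0 * 2^2.3, size = 20),
                      ncol = 2))
    f <- data.table::data.table(feature_id = paste0("f", 1:50),
                                class = "te_family", length = 1000L)
    sm <- data.table::data.table(sample = paste0("s", 1:4),
                                 condition = c("ctrl", "ctrl", "kd", "kd"))
    de <- fold_change_and_test(count_matrix(m, f, sm), s = rep(1, 4),
                               groups = sm$condition, kd = "kd")
    est[s] <- mean(de$lfc)
  }
  expect_lt(abs(mean(est) - 2.3), 0.2)
})

test_that("classify_de applies thresholds in the right precedence", {
  cfg <- pipeline_config()
  de <- data.table::data.table(
    feature_id = c("a", "b", "c", "d", "e"),
    class = "gene",
    lfc = c(2.5, 2.5, 5, -3, 0.5),
    p = 0.001, padj = c(0.01, 0.2, 1e-8, 0.001, 0.2),
    rpkm_mean = c(3, 3, 0.5, 10, 2))
  lab <- classify_de(de, cfg)$label
  expect_identical(lab, c("upregulated", "not_significant",
                          "low_expression", "downregulated",
                          "not_significant"))
})

test_that("ddct_fold_change matches hand computation", {
  expect_equal(ddct_fold_change(20, 15, 20, 15), 1)
  expect_equal(ddct_fold_change(18, 15, 20, 15), 4)      # ddCT = -2
  expect_equal(ddct_fold_change(20, 15, 23, 15.5), 2^2.5)
})

test_that("counts table round-trips through TSV", {
  f <- data.table::data.table(feature_id = c("g1", "te1"),
                              class = c("gene", "te_family"),
                              length = c(2000L, 500L))
  sm <- data.table::data.table(
    sample = c("rna_control_r1", "rna_control_r2",
               "rna_knockdown_r1", "rna_knockdown_r2"),
    condition = c("control", "control", "knockdown", "knockdown"))
  cm <- count_matrix(matrix(1:8, ncol = 4), f, sm)
  tf <- withr::local_tempfile(fileext = ".tsv")
  tab <- cbind(f, data.table::as.data.table(cm$counts))
  data.table::fwrite(tab, tf, sep = "\t")
  back <- read_counts_tsv(tf)
  expect_identical(back$counts, cm$counts)
  expect_identical(back$samples$condition, sm$condition)
})
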