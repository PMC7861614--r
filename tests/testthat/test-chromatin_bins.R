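flat_track <- function(genome, value = 1) {
  lapply(genome$lengths, function(L) rep(value, L))
}

test_that("make_filtered_bins tiles, drops partial bins and filters", {
  g <- te_genome(c(c1 = strrep("A", 10500), chrM = strrep("A", 3000)),
                 mito_name = "chrM")
  cfg <- pipeline_config()
  tr <- flat_track(g)
  bins <- make_filtered_bins(g, tr, cfg)
  expect_identical(nrow(bins), 10L)          # partial bin and chrM dropped
  expect_true(all(bins$end - bins$start == 1000L))

  # bin at mean mappability 0.4 removed, 0.6 kept, 0.5 removed (> rule)
  tr$c1[1:1000] <- 0.4
  tr$c1[1001:2000] <- 0.6
  tr$c1[2001:3000] <- 0.5
  bins2 <- make_filtered_bins(g, tr, cfg)
  expect_false(0L %in% bins2$start)
  expect_true(1000L %in% bins2$start)
  expect_false(2000L %in% bins2$start)

  # random track: retained set equals a per-bin loop oracle
  set.seed(141)
  tr$c1 <- runif(10500)
  bins3 <- make_filtered_bins(g, tr, cfg)
  want <- vapply(0:9, function(b) mean(tr$c1[(b * 1000 + 1):(b * 1000 + 1000)]),
                 numeric(1L))
  expect_identical(bins3$start, as.integer(which(want > 0.5) - 1L) * 1000L)
  expect_equal(bins3$mean_mappability, want[want > 0.5])
})

test_that("assign_categories follows the precedence truth table", {
  g <- te_genome(c(c1 = strrep("A", 40000), c4 = strrep("A", 60000)))
  cfg <- pipeline_config(het_region = list(chrom = "c4", start = 30000L,
                                           end = 60000L))
  tr <- flat_track(g)
  bins <- make_filtered_bins(g, tr, cfg)
  ins <- data.table::data.table(
    family = c("gypsy", "Juan", "roo"),
    chrom = c("c1", "c1", "c4"),
    start = c(1450L, 5450L, 44950L),
    end = c(1550L, 5550L, 45050L),
    strand = "+")
  out <- assign_categories(bins, ins, cfg)
  cat_of <- function(chrom, start)
    out$category[out$chrom == chrom & out$start == start]

  # gap 500 to a gypsy centre -> near_upregulated_te
  expect_identical(cat_of("c1", 0L), "near_upregulated_te")
  # containing bin
  expect_identical(cat_of("c1", 1000L), "near_upregulated_te")
  # within 1 kb of a Juan centre only -> near_other_te
  expect_identical(cat_of("c1", 6000L), "near_other_te")
  # far from everything, not in het -> unassigned
  expect_identical(cat_of("c1", 20000L), "unassigned")
  # inside het region, > 10 kb from the roo insertion -> control_het
  expect_identical(cat_of("c4", 58000L), "control_het")
  # inside het region but within 10 kb of an insertion -> unassigned
  expect_identical(cat_of("c4", 50000L), "unassigned")
  # near a non-listed family only ("roo") -> not near_*; fails het rule
  expect_identical(cat_of("c4", 44000L), "unassigned")

  # exhaustive precedence oracle over all flag combinations
  radius <- cfg$proximity_radius
  ctr <- insertion_centers(ins)
  for (i in seq_len(nrow(out))) {
    gap <- function(ctr_i, chrom_i) {
      if (chrom_i != out$chrom[i]) return(Inf)
      if (ctr_i >= out$start[i] && ctr_i < out$end[i]) return(0)
      min(abs(ctr_i - out$start[i]), abs(ctr_i - out$end[i]))
    }
    d <- vapply(seq_len(3L), function(j) gap(ctr[j], ins$chrom[j]),
                numeric(1L))
    near_up <- d[1] <= radius
    near_other <- d[2] <= radius
    in_het <- out$chrom[i] == "c4" & out$start[i] >= 30000L &
      out$end[i] <= 60000L
    far_all <- all(d > cfg$control_min_distance)
    want <- if (near_up) "near_upregulated_te"
            else if (near_other) "near_other_te"
            else if (in_het && far_all) "control_het"
            else "unassigned"
    expect_identical(out$category[i], want)
  }

  expect_error(assign_categories(bins, ins, pipeline_config()),
               "het_region")
})

test_that("bin_signal conserves counts and matches the midpoint oracle", {
  g <- rand_genome(c(chr1 = 20000L, chr2 = 15000L), seed = 151)
  cfg <- pipeline_config(fragment_length = 200L,
                         het_region = list(chrom = "chr2", start = 0L,
                                           end = 1000L))
  tr <- flat_track(g, 0.8)
  bins <- make_filtered_bins(g, tr, cfg)
  bins[, category := "unassigned"]
  set.seed(152)
  rec <- rand_records(1000L, g, samples = c("a", "b"),
                      mapq_pool = 255L, width = c(50L, 50L))
  out <- bin_signal(rec, bins, g, cfg)

  # oracle: midpoint of the extended+centred fragment, per bin
  frag <- fragment_transform(rec, 200L, center = TRUE, genome = g)
  mids <- (frag$start + frag$end) %/% 2L
  for (sm in c("a", "b")) {
    want <- integer(nrow(bins))
    sel <- which(frag$sample_id == sm)
    for (i in sel) {
      hit <- which(bins$chrom == frag$chrom[i] & bins$start <= mids[i] &
                     bins$end > mids[i])
      if (length(hit) == 1L) want[hit] <- want[hit] + 1L
    }
    expect_identical(out[[paste0("count.", sm)]], want)
    # conservation: totals equal fragments with midpoints inside kept bins
    expect_identical(sum(out[[paste0("count.", sm)]]), sum(want))
    # normalisation formula
    lib <- sum(rec$sample_id == sm)
    expect_equal(out[[paste0("norm.", sm)]],
                 want / bins$mean_mappability * 1e6 / lib)
  }

  # norm example: count 10, mappability 0.5, library 1e6 -> 20
  expect_equal(10 / 0.5 * 1e6 / 1e6, 20)
})

test_that("bin_signal excludes the mito contig from the library size", {
  g <- te_genome(c(c1 = strrep("A", 5000), chrM = strrep("A", 3000)),
                 mito_name = "chrM")
  cfg <- pipeline_config(fragment_length = 100L)
  bins <- make_filtered_bins(g, flat_track(g), cfg)
  bins[, category := "unassigned"]
  rec <- alignment_records(c("c1", "c1", "chrM", "chrM"),
                           c(1000, 2000, 100, 200),
                           c(1050, 2050, 150, 250),
                           "+", 255, "s")
  out <- bin_signal(rec, bins, g, cfg)
  # library size is 2 (chrM excluded), so each c1 bin hit has norm 5e5
  expect_equal(sort(unique(out$norm.s)), c(0, 5e5))
})

test_that("compare_categories: nulls, separation, antisymmetry, degenerate", {
  mk_bins <- function(kd, ctrl, category = "near_upregulated_te") {
    data.table::data.table(chrom = "c", start = seq_along(kd) * 1000L,
                           end = seq_along(kd) * 1000L + 1000L,
                           mean_mappability = 1,
                           category = category,
                           mean.knockdown = kd, mean.control = ctrl)
  }
  set.seed(161)
  v <- rgamma(500L, shape = 4, rate = 0.1)
  # kd identical to ctrl -> fc 1, p 1
  eq <- compare_categories(mk_bins(v, v), "knockdown", "control")
  expect_equal(eq$median_fc, 1)
  expect_equal(eq$p, 1)

  # kd = ctrl / 4 -> fc 0.25 exactly at pseudocount 0, tiny p, flag set
  q <- compare_categories(mk_bins(v / 4, v), "knockdown", "control",
                          pseudocount = 0)
  expect_equal(q$median_fc, 0.25)
  expect_lt(q$p, 1e-10)
  expect_true(q$significant)

  # antisymmetry: swapping conditions inverts fc, keeps p
  q_sw <- compare_categories(mk_bins(v, v / 4), "knockdown", "control",
                             pseudocount = 0)
  expect_equal(q_sw$median_fc, 1 / q$median_fc, tolerance = 1e-6)
  expect_equal(q_sw$p, q$p)

  # single-bin category -> NA statistics
  one <- compare_categories(mk_bins(1, 2), "knockdown", "control")
  expect_identical(one$n_bins, 1L)
  expect_true(is.na(one$median_fc) && is.na(one$p))
})

test_that("compare_categories effect recovery and null calibration", {
  # planted 4-fold depletion restricted to the target category recovers
  # the significance flag; an unaffected control category stays quiet
  flags_target <- logical(20L)
  flags_ctrl <- logical(20L)
  for (s in 1:20) {
    set.seed(1000 + s)
    n <- 250L
    ctrl_vals <- rgamma(2L * n, shape = 30, rate = 1)
    kd_vals <- rgamma(2L * n, shape = 30, rate = 1)
    cat <- rep(c("near_upregulated_te", "control_het"), each = n)
    kd_vals[cat == "near_upregulated_te"] <-
      kd_vals[cat == "near_upregulated_te"] / 4
    bins <- data.table::data.table(
      chrom = "c", start = 0L, end = 1000L, mean_mappability = 1,
      category = cat, mean.knockdown = kd_vals, mean.control = ctrl_vals)
    st <- compare_categories(bins, "knockdown", "control")
    flags_target[s] <- st$significant[st$category == "near_upregulated_te"]
    flags_ctrl[s] <- st$significant[st$category == "control_het"]
  }
  expect_gte(mean(flags_target), 0.95)
  expect_gte(mean(!flags_ctrl), 0.90)
})

test_that("coverage_track applies exact CPM scaling and accumulation", {
  g <- te_genome(c(c1 = strrep("A", 2000)))
  cfg <- pipeline_config(fragment_length = 260L)
  # one 50-bp read, chip mode: 50 bases at exactly 1e6, centred on the
  # fragment midpoint (read [100,150) -> fragment [100,360) -> [205,255))
  r <- alignment_records("c1", 100, 150, "+", 255, "s")
  tr <- coverage_track(r, g, cfg, mode = "chip")$s
  expect_equal(sum(tr$c1 > 0), 50L)
  expect_equal(unique(tr$c1[tr$c1 > 0]), 1e6)
  expect_equal(which(tr$c1 > 0), 206:255)

  # rna mode uses the raw span
  r2 <- alignment_records("c1", 100, 150, "+", 60, "s")
  tr2 <- coverage_track(r2, g, cfg, mode = "rna")$s
  expect_equal(which(tr2$c1 > 0), 101:150)

  # two non-overlapping equal-length reads: total mass r * 1e6
  r3 <- alignment_records(c("c1", "c1"), c(100, 1000), c(150, 1050),
                          "+", 255, "s")
  tr3 <- coverage_track(r3, g, cfg, mode = "rna")$s
  expect_equal(sum(tr3$c1), 50 * 1e6)

  # random reads match a direct accumulation oracle (rna mode)
  set.seed(171)
  rr <- rand_records(300L, g, samples = "s", mapq_pool = 255L)
  trr <- coverage_track(rr, g, cfg, mode = "rna")$s$c1
  want <- numeric(2000L)
  for (i in seq_len(nrow(rr)))
    want[(rr$start[i] + 1L):rr$end[i]] <-
      want[(rr$start[i] + 1L):rr$end[i]] + 1
  expect_equal(trr, want * 1e6 / 300)
})

test_that("consensus_coverage restricts to sense reads and validates", {
  lens <- c(gypsy = 500L, Juan = 300L)
  r <- alignment_records(c("gypsy", "gypsy"), c(10, 50), c(60, 100),
                         c("+", "-"), 255, "s")
  cov <- consensus_coverage(r, lens, sense_only = TRUE)$s
  expect_equal(which(cov$gypsy > 0), 11:60)
  expect_equal(unique(cov$gypsy[cov$gypsy > 0]), 1e6)  # N = 1 sense read
  expect_equal(sum(cov$Juan), 0)
  both <- consensus_coverage(r, lens, sense_only = FALSE)$s
  expect_equal(sum(both$gypsy > 0), 90L)
  expect_error(consensus_coverage(
    alignment_records("roo", 0, 10, "+", 255, "s"), lens),
    "unknown consensus")
})
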