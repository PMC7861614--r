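#' Simulation configuration
#'
#' Defaults describe the synthetic world the test-suite runs in: a small
#' multi-chromosome genome (3 x 500 kb plus a mitochondrial contig)
#' carrying planted TE-consensus insertions of 12 families (the 5
#' knockdown-responsive families plus 6 control families and one
#' bystander), H3K9me3 enrichment domains (~10 kb, 8-fold) around
#' insertions that lose signal 4-fold in the knockdown for responsive
#' families, negative-binomial RNA-seq counts with planted >4-fold TE
#' de-repression, and secondary upregulation of insertion-proximal
#' genes.
#'
#' @param n_chrom autosome count (a mitochondrial contig is added).
#' @param chrom_length autosome length in bp.
#' @param mito_length mitochondrial contig length in bp.
#' @param families character vector of TE family names; the first five
#'   default names are the knockdown-responsive ("upregulated") set.
#' @param insertions_per_family planted copies per family.
#' @param consensus_length_range min/max consensus length in bp.
#' @param divergence per-base substitution rate of planted copies.
#' @param min_insertion_gap minimum centre-to-centre spacing in bp of
#'   planted insertions (keeps the clustering filter a no-op on truth).
#' @param n_genes number of genes.
#' @param gene_length nominal gene length in bp (for RPKM).
#' @param frac_proximal fraction of genes whose TSS is planted inside the
#'   promoter window of a responsive insertion.
#' @param enrichment_factor ChIP rate multiplier `e` inside domains.
#' @param depletion_factor knockdown division factor `d` for responsive
#'   domains.
#' @param domain_width enrichment domain width in bp (flat-top).
#' @param read_length read length in bp.
#' @param multimapper_frac fraction of reads emitted with mapq 0.
#' @param duplicate_frac fraction of reads duplicated (PCR duplicates).
#' @param te_lfc_range planted log2 fold-change range for responsive TE
#'   families.
#' @param gene_lfc_range planted log2 fold-change range for proximal
#'   genes.
#' @param dispersion negative-binomial dispersion of RNA-seq counts.
#' @param chip_replicates,chip_depth ChIP libraries per condition and
#'   fragments per library.
#' @param rna_replicates,rna_depth RNA-seq libraries per condition and
#'   expected reads per library.
#' @param seed integer root seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 3L,
                       chrom_length = 500000L,
                       mito_length = 15000L,
                       families = c("gypsy", "mdg1", "blood", "297", "412",
                                    "Juan", "Bari1", "1360", "pogo",
                                    "Burdock", "diver", "roo"),
                       insertions_per_family = 5L,
                       consensus_length_range = c(1500L, 4000L),
                       divergence = 0.05,
                       min_insertion_gap = 12000L,
                       n_genes = 300L,
                       gene_length = 2000L,
                       frac_proximal = 0.25,
                       enrichment_factor = 8,
                       depletion_factor = 4,
                       domain_width = 10000L,
                       read_length = 50L,
                       multimapper_frac = 0.05,
                       duplicate_frac = 0.05,
                       te_lfc_range = c(2.5, 4),
                       gene_lfc_range = c(1, 3),
                       dispersion = 0.05,
                       chip_replicates = 2L,
                       chip_depth = 200000L,
                       rna_replicates = 4L,
                       rna_depth = 1e6,
                       seed = 1L) {
  sc <- as.list(environment())
  if (sc$enrichment_factor < 1 || sc$depletion_factor < 1)
    stop("sim_config: enrichment and depletion factors must be >= 1",
         call. = FALSE)
  if (sc$divergence < 0 || sc$divergence >= 1)
    stop("sim_config: divergence must be in [0, 1)", call. = FALSE)
  class(sc) <- "sim_config"
  sc
}

# substitute bases at the given per-base rate (never to the same base)
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(ch)) < rate)
  if (length(hit) > 0L) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    ch[hit] <- vapply(ch[hit],
                      function(b) sample(alt[[b]], 1L), character(1L))
  }
  paste(ch, collapse = "")
}

#' Simulate a genome with planted TE insertions, genes and truth
#'
#' Generates random background chromosomes, plants diverged copies of
#' random consensus sequences at recorded, well-spaced positions (kept
#' clear of the heterochromatin control region on the last autosome),
#' places gene TSSs with a configured fraction inside responsive-
#' insertion promoter windows, and returns a machine-readable truth
#' object with every planted effect. Deterministic under the seed.
#'
#' @param sim [sim_config()].
#' @return list(genome, insertions, genes, consensus, het_region, truth).
#' @export
simulate_genome <- function(sim = sim_config()) {
  set.seed(derive_seed(sim$seed, "genome"))
  chroms <- paste0("chr", seq_len(sim$n_chrom))
  seqs <- stats::setNames(
    c(vapply(chroms, function(x) random_dna(sim$chrom_length),
             character(1L)),
      random_dna(sim$mito_length)),
    c(chroms, "chrM"))

  fam <- sim$families
  up_fam <- fam[seq_len(min(5L, length(fam)))]
  consensus <- stats::setNames(vapply(fam, function(f) {
    random_dna(sample(sim$consensus_length_range[1L]:
                        sim$consensus_length_range[2L], 1L))
  }, character(1L)), fam)

  last_chr <- chroms[length(chroms)]
  het_start <- as.integer(0.8 * sim$chrom_length)
  het_region <- list(chrom = last_chr, start = het_start,
                     end = sim$chrom_length)
  het_margin <- 20000L  # keep insertions well clear of control bins

  # place insertions: pairwise spacing and het exclusion by rejection
  wanted <- data.table::data.table(
    family = rep(fam, each = sim$insertions_per_family))
  placed <- vector("list", nrow(wanted))
  centers <- list()
  for (i in seq_len(nrow(wanted))) {
    len <- nchar(consensus[[wanted$family[i]]])
    ok <- FALSE
    for (attempt in seq_len(2000L)) {
      chr <- sample(chroms, 1L)
      lo <- sim$domain_width %/% 2L + 1000L
      hi <- sim$chrom_length - len - lo
      if (hi <= lo) next
      pos <- sample(lo:hi, 1L)
      ctr <- pos + len %/% 2L
      if (chr == last_chr && ctr > het_start - het_margin) next
      prev <- centers[[chr]]
      if (!is.null(prev) && any(abs(prev - ctr) < sim$min_insertion_gap))
        next
      centers[[chr]] <- c(prev, ctr)
      placed[[i]] <- data.table::data.table(
        family = wanted$family[i], chrom = chr, start = pos,
        end = pos + len, strand = sample(c("+", "-"), 1L))
      ok <- TRUE
      break
    }
    if (!ok)
      stop("simulate_genome: could not place insertion ", i,
           " (genome too small for the requested insertion density)",
           call. = FALSE)
  }
  insertions <- data.table::rbindlist(placed)

  # write the (diverged) copies into the background sequence
  for (i in seq_len(nrow(insertions))) {
    copy <- mutate_sequence(consensus[[insertions$family[i]]],
                            sim$divergence)
    if (insertions$strand[i] == "-") copy <- revcomp(copy)
    chr <- insertions$chrom[i]
    s <- insertions$start[i]
    seqs[[chr]] <- paste0(substring(seqs[[chr]], 1L, s),
                          copy,
                          substring(seqs[[chr]], s + nchar(copy) + 1L))
  }
  genome <- te_genome(seqs, mito_name = "chrM")

  # genes: a planted fraction proximal to responsive insertions
  ins_up <- insertions[family %in% up_fam]
  ctr_up <- insertion_centers(ins_up)
  n_prox <- round(sim$frac_proximal * sim$n_genes)
  tss <- integer(sim$n_genes)
  chrv <- character(sim$n_genes)
  proximal <- c(rep(TRUE, n_prox), rep(FALSE, sim$n_genes - n_prox))
  for (i in seq_len(sim$n_genes)) {
    if (proximal[i]) {
      j <- sample.int(nrow(ins_up), 1L)
      off <- sample(seq(-9000L, 13900L), 1L)  # safely inside [-10k, 15k)
      if (ins_up$strand[j] == "-") off <- -off
      tss[i] <- ctr_up[j] + off
      chrv[i] <- ins_up$chrom[j]
    } else {
      repeat {
        chr <- sample(chroms, 1L)
        p <- sample(1000L:(sim$chrom_length - 1000L), 1L)
        cu <- ctr_up[ins_up$chrom == chr]
        if (length(cu) == 0L || all(abs(cu - p) > 16000L)) break
      }
      tss[i] <- p
      chrv[i] <- chr
    }
  }
  tss <- pmax(0L, pmin(tss, sim$chrom_length - 1L))
  genes <- data.table::data.table(
    gene_id = sprintf("g%04d", seq_len(sim$n_genes)),
    chrom = chrv, tss = tss,
    strand = sample(c("+", "-"), sim$n_genes, replace = TRUE))

  te_lfc <- stats::setNames(rep(0, length(fam)), fam)
  te_lfc[up_fam] <- runif(length(up_fam), sim$te_lfc_range[1L],
                          sim$te_lfc_range[2L])
  gene_lfc <- stats::setNames(rep(0, sim$n_genes), genes$gene_id)
  gene_lfc[proximal] <- runif(n_prox, sim$gene_lfc_range[1L],
                              sim$gene_lfc_range[2L])

  truth <- list(
    upregulated_families = up_fam,
    other_families = setdiff(fam, up_fam)[
      setdiff(fam, up_fam) %in% c("Juan", "Bari1", "1360", "pogo",
                                  "Burdock", "diver")],
    te_lfc = te_lfc,
    gene_lfc = gene_lfc,
    gene_proximal = stats::setNames(proximal, genes$gene_id),
    gene_length = sim$gene_length,
    consensus_lengths = stats::setNames(as.integer(nchar(consensus)), fam),
    enrichment_factor = sim$enrichment_factor,
    depletion_factor = sim$depletion_factor,
    domain_width = sim$domain_width,
    het_region = het_region,
    seed = sim$seed)

  list(genome = genome, insertions = insertions, genes = genes,
       consensus = consensus, het_region = het_region, truth = truth)
}

#' Simulate ChIP-seq alignment records with planted enrichment
#'
#' Fragment midpoints are drawn from a mixture of a uniform background
#' (all chromosomes including the mitochondrial contig) and flat-top
#' enrichment domains centred on insertion centres. For H3K9me3 the
#' domain rate is `e` in the control; the knockdown divides the rate of
#' responsive-family domains by `d`. H3K4me2 runs in the opposite
#' direction: flat in the control, gaining rate `d` at responsive
#' domains in the knockdown. Reads are emitted at their true positions
#' with mapq 255 (or 0 for the planted multimapper fraction); a
#' configurable fraction of reads is duplicated. Deterministic under the
#' seed.
#'
#' @param genome [te_genome()].
#' @param insertions insertion table.
#' @param truth truth object from [simulate_genome()].
#' @param condition `"control"` or `"knockdown"`.
#' @param mark `"H3K9me3"` or `"H3K4me2"`.
#' @param replicates number of replicate libraries.
#' @param depth fragments per replicate (before duplication).
#' @param sim [sim_config()] (read length, multimapper/duplicate
#'   fractions).
#' @param seed seed; default derived from `sim$seed`, condition and mark.
#' @return alignment-record table, samples named
#'   `<mark>_<condition>_r<i>`.
#' @export
simulate_chip <- function(genome, insertions, truth,
                          condition = c("control", "knockdown"),
                          mark = c("H3K9me3", "H3K4me2"),
                          replicates = 2L, depth = 200000L,
                          sim = sim_config(), seed = NULL) {
  condition <- match.arg(condition)
  mark <- match.arg(mark)
  if (depth < 1L) stop("depth must be >= 1", call. = FALSE)
  if (is.null(seed))
    seed <- derive_seed(sim$seed, paste("chip", condition, mark))
  set.seed(seed)

  e <- truth$enrichment_factor
  d <- truth$depletion_factor
  w <- truth$domain_width
  ctr <- insertion_centers(insertions)
  responsive <- insertions$family %in% truth$upregulated_families
  dom_rate <- if (mark == "H3K9me3") {
    r <- rep(e, nrow(insertions))
    if (condition == "knockdown") r[responsive] <- e / d
    r
  } else {
    r <- rep(1, nrow(insertions))
    if (condition == "knockdown") r[responsive] <- d
    r
  }

  # mixture segments: per-chromosome background plus domain increments
  segs <- data.table::rbindlist(list(
    data.table::data.table(chrom = names(genome$lengths), start = 0L,
                           end = as.integer(genome$lengths), rate = 1),
    data.table::data.table(chrom = insertions$chrom,
                           start = pmax(0L, ctr - w %/% 2L),
                           end = pmin(genome$lengths[insertions$chrom],
                                      ctr + w %/% 2L),
                           rate = dom_rate - 1)))
  segs <- segs[rate > 0 & end > start]
  weight <- (segs$end - segs$start) * segs$rate
  rl <- sim$read_length
  half <- 260L %/% 2L  # expected fragment midpoint offset

  out <- lapply(seq_len(replicates), function(rep_i) {
    nseg <- as.vector(stats::rmultinom(1L, depth, weight))
    mid <- unlist(lapply(which(nseg > 0L), function(k) {
      segs$start[k] + floor(runif(nseg[k]) * (segs$end[k] - segs$start[k]))
    }), use.names = FALSE)
    chrv <- rep(segs$chrom, nseg)
    L <- genome$lengths[chrv]
    strand <- sample(c("+", "-"), length(mid), replace = TRUE)
    start <- ifelse(strand == "+", mid - half, mid + half - rl)
    start <- pmax(0L, pmin(as.integer(start), as.integer(L) - rl))
    mapq <- ifelse(runif(length(mid)) < sim$multimapper_frac, 0L, 255L)
    rec <- data.table::data.table(
      chrom = chrv, start = as.integer(start),
      end = as.integer(start) + rl, strand = strand, mapq = mapq,
      sample_id = paste0(mark, "_", condition, "_r", rep_i))
    ndup <- floor(sim$duplicate_frac * nrow(rec))
    if (ndup > 0L) {
      rec <- rbind(rec, rec[sample.int(nrow(rec), ndup)])
    }
    rec
  })
  data.table::rbindlist(out)
}

#' Simulate RNA-seq counts with planted effects
#'
#' Negative-binomial counts for genes and TE families with
#' `mean = baseline * 2^(lfc * [condition == knockdown]) * library
#' factor` and the configured dispersion. Baselines are log-normal
#' across genes; TE families share a moderate baseline. Deterministic
#' under the seed.
#'
#' @param truth truth object from [simulate_genome()].
#' @param replicates replicates per condition.
#' @param depth expected reads per library.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param lib_factors optional numeric vector (length `2 * replicates`)
#'   of per-library scaling factors.
#' @param seed seed; default derived from `truth$seed`.
#' @return [count_matrix()] with conditions `control` / `knockdown`.
#' @export
simulate_rnaseq <- function(truth, replicates = 4L, depth = 1e6,
                            dispersion = 0.05, lib_factors = NULL,
                            seed = NULL) {
  if (replicates < 2L) stop("need >= 2 replicates per condition",
                            call. = FALSE)
  if (is.null(seed)) seed <- derive_seed(truth$seed, "rnaseq")
  set.seed(seed)
  gene_ids <- names(truth$gene_lfc)
  fam <- names(truth$te_lfc)
  base_gene <- exp(rnorm(length(gene_ids), mean = 0, sd = 1))
  base_te <- exp(rnorm(length(fam), mean = -0.5, sd = 0.7))
  base <- c(base_gene, base_te)
  lfc <- c(truth$gene_lfc, truth$te_lfc)
  n_samp <- 2L * replicates
  cond <- rep(c("control", "knockdown"), each = replicates)
  if (is.null(lib_factors)) lib_factors <- rep(1, n_samp)
  stopifnot(length(lib_factors) == n_samp)
  frac <- base / sum(base)
  counts <- matrix(0L, nrow = length(base), ncol = n_samp)
  for (j in seq_len(n_samp)) {
    mu <- depth * frac * 2^(lfc * (cond[j] == "knockdown")) *
      lib_factors[j]
    counts[, j] <- stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / dispersion)
  }
  features <- data.table::data.table(
    feature_id = c(gene_ids, fam),
    class = c(rep("gene", length(gene_ids)),
              rep("te_family", length(fam))),
    length = c(rep(truth$gene_length, length(gene_ids)),
               as.integer(truth$consensus_lengths[fam])))
  samples <- data.table::data.table(
    sample = paste0("rna_", cond, "_r",
                    c(seq_len(replicates), seq_len(replicates))),
    condition = cond)
  count_matrix(counts, features, samples)
}

#' Write a simulation to disk
#'
#' Emits genome and consensus FASTA, insertion and het-region BED, the
#' gene table, per-sample ChIP alignment tables, the RNA-seq count
#' matrix and the truth object as JSON.
#'
#' @param sim_result list from [simulate_genome()].
#' @param chip alignment-record table (all ChIP samples), or NULL.
#' @param rna [count_matrix()], or NULL.
#' @param dir output directory (created).
#' @return named list of written paths, invisibly.
#' @export
write_simulation <- function(sim_result, chip = NULL, rna = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- list(
    genome = file.path(dir, "genome.fa"),
    consensus = file.path(dir, "consensus.fa"),
    insertions = file.path(dir, "insertions.bed"),
    het_region = file.path(dir, "het_region.bed"),
    genes = file.path(dir, "genes.tsv"),
    truth = file.path(dir, "truth.json"))
  write_genome_fasta(sim_result$genome, p$genome)
  write_genome_fasta(sim_result$consensus, p$consensus)
  write_bed(sim_result$insertions, p$insertions)
  hr <- sim_result$het_region
  write_bed(data.table::data.table(family = "het_region",
                                   chrom = hr$chrom, start = hr$start,
                                   end = hr$end, strand = "."),
            p$het_region)
  write_gene_table(sim_result$genes, p$genes)
  truth <- sim_result$truth
  # named atomic vectors -> JSON objects (names survive the round trip)
  for (k in c("te_lfc", "gene_lfc", "gene_proximal", "consensus_lengths"))
    truth[[k]] <- as.list(truth[[k]])
  jsonlite::write_json(truth, p$truth, auto_unbox = TRUE, digits = NA)
  if (!is.null(chip)) {
    for (sm in unique(chip$sample_id)) {
      fp <- file.path(dir, paste0(sm, ".alignments.tsv"))
      write_alignments(chip[chip$sample_id == sm], fp)
      p[[paste0("chip_", sm)]] <- fp
    }
  }
  if (!is.null(rna)) {
    cm <- data.table::data.table(feature_id = rna$features$feature_id,
                                 class = rna$features$class,
                                 length = rna$features$length)
    cm <- cbind(cm, data.table::as.data.table(rna$counts))
    p$counts <- file.path(dir, "counts.tsv")
    data.table::fwrite(cm, p$counts, sep = "\t", quote = FALSE)
  }
  invisible(p)
}
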