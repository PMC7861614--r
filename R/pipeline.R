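#' Run the full pipeline end-to-end
#'
#' Executes, in order: simulate (when requested), mappability, counts,
#' de, proximity, bins, metaprofile, coverage. All randomness flows from
#' one root seed split per stage, so identical config + seed yields
#' byte-identical result tables. Floats are written with 6 significant
#' digits.
#'
#' @param config path to a JSON config file (see [read_config()]) or a
#'   list as returned by it. With `simulate: true` the synthetic-data
#'   generator provides all inputs; otherwise a `paths` object naming
#'   `genome`, `insertions`, `genes` and `alignments` files is required.
#' @param out output directory (created).
#' @param seed optional root seed overriding the config.
#' @return run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_all <- function(config, out, seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  cfg <- config$config
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stages <- list()
  outputs <- character()
  note <- function(stage, files) {
    for (f in files) {
      if (!file.exists(f) || file.size(f) == 0L)
        stop("stage '", stage, "': output missing or empty: ", f,
             call. = FALSE)
    }
    stages[[length(stages) + 1L]] <<- list(
      name = stage, status = "completed",
      outputs = as.list(basename(files)))
    outputs <<- c(outputs, files)
    message(sprintf("[%s] stage %-12s done (%d output file(s))",
                    format(Sys.time(), "%H:%M:%S"), stage, length(files)))
  }
  fail <- function(stage, e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  # ---- stage 1: simulate / load -------------------------------------------
  if (isTRUE(config$simulate)) {
    tryCatch({
      sim_args <- config$sim %||% list()
      sim_args$seed <- cfg$seed
      sim <- do.call(sim_config, sim_args)
      sr <- simulate_genome(sim)
      chip <- data.table::rbindlist(lapply(
        c("control", "knockdown"),
        function(cond) simulate_chip(sr$genome, sr$insertions, sr$truth,
                                     condition = cond, mark = "H3K9me3",
                                     replicates = sim$chip_replicates,
                                     depth = sim$chip_depth, sim = sim)))
      rna <- simulate_rnaseq(sr$truth, replicates = sim$rna_replicates,
                             depth = sim$rna_depth,
                             dispersion = sim$dispersion)
      paths <- write_simulation(sr, chip = chip, rna = rna,
                                dir = file.path(out, "sim"))
      genome <- sr$genome
      insertions <- sr$insertions
      genes <- sr$genes
      cfg$het_region <- sr$het_region
      note("simulate", unlist(paths))
    }, error = function(e) fail("simulate", e))
  } else {
    tryCatch({
      if (is.null(config$paths))
        stop("config: either 'simulate: true' or a 'paths' object is ",
             "required")
      inp <- load_inputs(config$paths, cfg)
      genome <- inp$genome
      insertions <- inp$insertions
      genes <- inp$genes
      chip <- inp$alignments
      rna <- if (!is.null(config$paths$counts))
        read_counts_tsv(config$paths$counts) else NULL
      note("load", character())
    }, error = function(e) fail("load", e))
  }

  # ---- stage 2: mappability -----------------------------------------------
  track <- tryCatch({
    tr <- kmer_mappability(genome, cfg$kmer_length)
    f <- file.path(out, "mappability.bedGraph")
    write_bedgraph(tr, f)
    note("mappability", f)
    tr
  }, error = function(e) fail("mappability", e))

  # ---- stage 3: counts ----------------------------------------------------
  tryCatch({
    if (!is.null(rna)) {
      f <- file.path(out, "counts.tsv")
      tab <- data.table::data.table(feature_id = rna$features$feature_id,
                                    class = rna$features$class,
                                    length = rna$features$length)
      tab <- cbind(tab, data.table::as.data.table(rna$counts))
      write_tsv(tab, f)
      note("counts", f)
    } else {
      note("counts", character())
    }
  }, error = function(e) fail("counts", e))

  # ---- stage 4: differential expression -----------------------------------
  de <- tryCatch({
    if (is.null(rna)) stop("no count matrix available")
    gene_ids <- rna$features$feature_id[rna$features$class == "gene"]
    s <- size_factors(rna, features = gene_ids)
    de <- fold_change_and_test(rna, s, groups = rna$samples$condition,
                               kd = "knockdown")
    de <- classify_de(de, cfg)
    f <- file.path(out, "de.tsv")
    write_tsv(de, f)
    note("de", f)
    de
  }, error = function(e) fail("de", e))

  # ---- stage 5: proximity -------------------------------------------------
  tryCatch({
    ins_f <- filter_clustered(insertions, cfg$cluster_min_gap)
    prox <- annotate_tss_proximity(genes, ins_f, cfg)
    strata <- stratified_fraction(de[class == "gene"], prox,
                                  rpkm_threshold = cfg$rpkm_threshold)
    f1 <- file.path(out, "proximity.tsv")
    f2 <- file.path(out, "stratified_fraction.tsv")
    write_tsv(prox, f1)
    write_tsv(strata, f2)
    note("proximity", c(f1, f2))
  }, error = function(e) fail("proximity", e))

  # ---- stage 6: chromatin bins --------------------------------------------
  chip_conditions <- NULL
  tryCatch({
    if (is.null(cfg$het_region))
      stop("config: 'het_region' is required for the bins stage")
    bins <- make_filtered_bins(genome, track, cfg)
    bins <- assign_categories(bins, insertions, cfg)
    rec <- deduplicate(chip[chip$mapq >= cfg$mapq_chip])
    smp <- sort(unique(rec$sample_id))
    chip_conditions <- stats::setNames(
      ifelse(grepl("knockdown", smp), "knockdown", "control"), smp)
    bins <- bin_signal(rec, bins, genome, cfg,
                       conditions = chip_conditions)
    stats <- compare_categories(bins, kd = "knockdown", ctrl = "control")
    f1 <- file.path(out, "bins.tsv")
    f2 <- file.path(out, "category_stats.tsv")
    write_tsv(bins, f1)
    write_tsv(stats, f2)
    note("bins", c(f1, f2))
  }, error = function(e) fail("bins", e))

  # ---- stage 7: metaprofile -----------------------------------------------
  cond_tracks <- tryCatch({
    tracks <- coverage_track(chip, genome, cfg, mode = "chip")
    cond_tracks <- lapply(c("control", "knockdown"), function(cond) {
      sms <- names(chip_conditions)[chip_conditions == cond]
      average_tracks(tracks[sms])
    })
    names(cond_tracks) <- c("control", "knockdown")
    up_ins <- insertions[family %in% cfg$upregulated_families]
    files <- character()
    for (cond in names(cond_tracks)) {
      mm <- reference_point_matrix(cond_tracks[[cond]], up_ins,
                                   before = cfg$matrix_before,
                                   after = cfg$matrix_after,
                                   bin_size = cfg$profile_bin)
      prof <- profile_bootstrap(mm, n_boot = cfg$n_bootstrap,
                                ci_level = cfg$ci_level,
                                seed = derive_seed(cfg$seed,
                                                   paste0("boot_", cond)))
      f <- file.path(out, paste0("profile_", cond, ".tsv"))
      write_tsv(prof, f)
      files <- c(files, f)
    }
    hm_ctrl <- reference_point_matrix(cond_tracks$control, up_ins,
                                      before = cfg$matrix_before,
                                      after = cfg$matrix_after,
                                      bin_size = cfg$heatmap_bin)
    hm_kd <- reference_point_matrix(cond_tracks$knockdown, up_ins,
                                    before = cfg$matrix_before,
                                    after = cfg$matrix_after,
                                    bin_size = cfg$heatmap_bin)
    hm <- heatmap_prepare(hm_kd, cap_percentile = cfg$heatmap_cap_percentile,
                          sort_reference = hm_ctrl)
    f <- file.path(out, "heatmap_knockdown.tsv")
    write_meta_matrix(hm, f)
    files <- c(files, f)
    note("metaprofile", files)
    cond_tracks
  }, error = function(e) fail("metaprofile", e))

  # ---- stage 8: coverage tracks -------------------------------------------
  tryCatch({
    files <- character()
    for (cond in names(cond_tracks)) {
      f <- file.path(out, paste0("coverage_", cond, ".bedGraph"))
      write_bedgraph(cond_tracks[[cond]], f)
      files <- c(files, f)
    }
    note("coverage", files)
  }, error = function(e) fail("coverage", e))

  manifest <- list(
    tool = "teinsite",
    version = as.character(utils::packageVersion("teinsite")),
    seed = cfg$seed,
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    config = cfg[setdiff(names(cfg), "het_region")],
    het_region = cfg$het_region,
    stages = stages,
    checksums = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# position-wise mean of a list of per-base tracks
average_tracks <- function(tracks) {
  chroms <- names(tracks[[1L]])
  out <- lapply(chroms, function(nm) {
    Reduce(`+`, lapply(tracks, `[[`, nm)) / length(tracks)
  })
  stats::setNames(out, chroms)
}
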