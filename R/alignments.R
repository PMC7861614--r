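#' Construct an alignment-record table
#'
#' One row per aligned read/fragment: 0-based half-open interval, strand,
#' mapping quality and library (sample) identifier. This table is the
#' unit that every counting operation in the package consumes.
#'
#' @param chrom,start,end,strand,mapq,sample_id record fields (recycled).
#' @return data.table(chrom, start, end, strand, mapq, sample_id).
#' @export
alignment_records <- function(chrom, start, end, strand, mapq, sample_id) {
  dt <- data.table::data.table(chrom = as.character(chrom),
                               start = as.integer(start),
                               end = as.integer(end),
                               strand = as.character(strand),
                               mapq = as.integer(mapq),
                               sample_id = as.character(sample_id))
  if (any(dt$mapq < 0L)) stop("mapq must be >= 0", call. = FALSE)
  bad <- which(!(dt$start >= 0L & dt$end > dt$start))
  if (length(bad) > 0L)
    stop("invalid alignment interval at row(s) ",
         paste(utils::head(bad, 5), collapse = ","), call. = FALSE)
  if (!all(dt$strand %in% c("+", "-")))
    stop("alignment strand must be '+' or '-'", call. = FALSE)
  dt
}

#' Read and write the native alignment table
#'
#' TSV with header `chrom start end strand mapq sample`; the reference
#' interchange format of the pipeline (no alignment software required).
#'
#' @param path TSV path.
#' @param genome optional [te_genome()] for coordinate validation.
#' @return alignment-record data.table.
#' @export
read_alignments <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("alignment table not found: ", path,
                               call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("chrom", "start", "end", "strand", "mapq", "sample")
  if (!all(need %in% names(dt)))
    stop("alignment table must have columns: ", paste(need, collapse = " "),
         call. = FALSE)
  rec <- alignment_records(dt$chrom, dt$start, dt$end, dt$strand, dt$mapq,
                           dt$sample)
  if (!is.null(genome)) validate_intervals(rec, genome, what = "alignment")
  rec
}

#' @rdname read_alignments
#' @param records alignment-record table.
#' @export
write_alignments <- function(records, path) {
  out <- data.table::data.table(chrom = records$chrom, start = records$start,
                                end = records$end, strand = records$strand,
                                mapq = records$mapq,
                                sample = records$sample_id)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a minimal SAM dialect into alignment records
#'
#' Parses mapped primary records: RNAME, 1-based POS, CIGAR reference
#' span (M/D/N/=/X), FLAG bit 0x10 for strand, and the MAPQ column.
#' Unmapped records (FLAG 0x4 or RNAME `*`) are skipped.
#'
#' @param path SAM file path.
#' @param sample_id sample label to assign (default: file name sans
#'   extension).
#' @param genome optional [te_genome()] for validation.
#' @return alignment-record data.table.
#' @export
read_sam <- function(path, sample_id = NULL, genome = NULL) {
  if (!file.exists(path)) stop("SAM not found: ", path, call. = FALSE)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L)
    return(alignment_records(character(), integer(), integer(),
                             character(), integer(), character()))
  fld <- data.table::tstrsplit(lines, "\t", fixed = TRUE, keep = 1:6)
  flag <- as.integer(fld[[2L]])
  rname <- fld[[3L]]
  keep <- bitwAnd(flag, 4L) == 0L & rname != "*"
  pos <- as.integer(fld[[4L]])[keep]
  mapq <- as.integer(fld[[5L]])[keep]
  cigar <- fld[[6L]][keep]
  span <- cigar_ref_span(cigar)
  alignment_records(chrom = rname[keep], start = pos - 1L,
                    end = pos - 1L + span,
                    strand = ifelse(bitwAnd(flag[keep], 16L) > 0L, "-", "+"),
                    mapq = mapq, sample_id = sample_id)
}

# reference-consuming CIGAR span (M, D, N, =, X)
cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(0L)
    n <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1L]])
    op <- regmatches(cg, gregexpr("[A-Z=]", cg))[[1L]]
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1L), USE.NAMES = FALSE)
}

#' Remove PCR duplicates
#'
#' Among records sharing (chrom, start, end, strand, sample) exactly one
#' survives (the one with the highest mapping quality). The duplicate key
#' includes the sample so replicate libraries never deduplicate against
#' each other. Output order is deterministic (coordinate sort) and
#' independent of input order; the operation is idempotent.
#'
#' @param records alignment-record table.
#' @return deduplicated alignment-record table.
#' @export
deduplicate <- function(records) {
  dt <- data.table::as.data.table(records)
  if (nrow(dt) == 0L) return(dt)
  data.table::setorder(dt, chrom, start, end, strand, sample_id, -mapq)
  unique(dt, by = c("chrom", "start", "end", "strand", "sample_id"))
}

#' Extend reads to fragment length and optionally centre them
#'
#' Each read is extended in its 3' direction to `fragment_length`
#' (clipped at chromosome bounds). With `center = TRUE` the returned
#' interval keeps the original read width but is centred on the extended
#' fragment's midpoint -- the expected midpoint of the sequenced insert.
#'
#' @param records alignment-record table.
#' @param fragment_length fragment length in bp (must be >= read length).
#' @param center logical; centre reads on the fragment midpoint.
#' @param genome [te_genome()] providing chromosome bounds.
#' @return alignment-record table with transformed start/end.
#' @export
#' @examples
#' g <- te_genome(c(c1 = strrep("A", 1000)))
#' r <- alignment_records("c1", 100, 150, "+", 255, "s")
#' fragment_transform(r, 260, center = TRUE, genome = g)[, .(start, end)]
fragment_transform <- function(records, fragment_length, center, genome) {
  dt <- data.table::as.data.table(records)
  w <- dt$end - dt$start
  if (any(w > fragment_length))
    stop("fragment_length (", fragment_length,
         ") smaller than read length (max ", max(w), ")", call. = FALSE)
  lens <- genome$lengths[dt$chrom]
  if (anyNA(lens)) stop("records on chromosomes absent from genome",
                        call. = FALSE)
  fwd <- dt$strand != "-"
  ext_start <- ifelse(fwd, dt$start, dt$end - fragment_length)
  ext_end <- ext_start + fragment_length
  ext_start <- pmax(0L, ext_start)
  ext_end <- pmin(as.integer(lens), as.integer(ext_end))
  if (center) {
    mid <- (ext_start + ext_end) %/% 2L
    new_start <- mid - w %/% 2L
    new_end <- new_start + w
    new_start <- pmax(0L, new_start)
    new_end <- pmin(as.integer(lens), as.integer(new_end))
  } else {
    new_start <- as.integer(ext_start)
    new_end <- as.integer(ext_end)
  }
  out <- data.table::copy(dt)
  out[, `:=`(start = as.integer(new_start), end = as.integer(new_end))]
  out
}

#' Load all pipeline inputs from files
#'
#' @param paths named list with elements `genome` (FASTA), `insertions`
#'   (BED4/6), `genes` (TSV), and `alignments` (character vector of
#'   alignment-table TSVs and/or `.sam` files).
#' @param config [pipeline_config()].
#' @return list(genome, insertions, genes, alignments).
#' @export
load_inputs <- function(paths, config = pipeline_config()) {
  need <- c("genome", "insertions", "genes", "alignments")
  miss <- setdiff(need, names(paths))
  if (length(miss) > 0L)
    stop("load_inputs: missing path(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  genome <- read_genome_fasta(paths$genome)
  insertions <- read_bed(paths$insertions, genome = genome)
  genes <- read_gene_table(paths$genes, genome = genome)
  aln <- data.table::rbindlist(lapply(paths$alignments, function(p) {
    if (grepl("\\.sam$", p, ignore.case = TRUE)) read_sam(p, genome = genome)
    else read_alignments(p, genome = genome)
  }))
  list(genome = genome, insertions = insertions, genes = genes,
       alignments = aln)
}
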