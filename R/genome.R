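#' Genome object
#'
#' A genome is a named set of chromosome sequences; all coordinates in the
#' package are 0-based half-open (BED convention) on these sequences. The
#' optional mitochondrial contig is excluded from library-size
#' normalisation downstream.
#'
#' @param sequences named character vector of nucleotide sequences.
#' @param mito_name optional chromosome name of the mitochondrial contig.
#' @return object of class `te_genome`: list with `sequences` (upper-case
#'   character vector), `lengths` (named integer vector) and `mito_name`.
#' @export
#' @examples
#' g <- te_genome(c(chr1 = "ACGTACGT", chrM = "AAAA"), mito_name = "chrM")
#' g$lengths
te_genome <- function(sequences, mito_name = NULL) {
  if (length(sequences) == 0L || is.null(names(sequences)) ||
      any(!nzchar(names(sequences))))
    stop("genome: sequences must be a non-empty named vector", call. = FALSE)
  if (anyDuplicated(names(sequences)))
    stop("genome: duplicated chromosome names", call. = FALSE)
  if (!is.null(mito_name) && !mito_name %in% names(sequences))
    stop("genome: mito_name '", mito_name, "' not among chromosomes",
         call. = FALSE)
  sequences <- toupper(sequences)
  g <- list(sequences = sequences,
            lengths = stats::setNames(as.integer(nchar(sequences)),
                                      names(sequences)),
            mito_name = mito_name)
  class(g) <- "te_genome"
  g
}

#' @export
print.te_genome <- function(x, ...) {
  cat("te_genome:", length(x$lengths), "sequence(s),",
      sum(as.numeric(x$lengths)), "bp total\n")
  for (nm in names(x$lengths)) {
    cat("  ", nm, ": ", x$lengths[[nm]], " bp",
        if (identical(nm, x$mito_name)) "  [mito]" else "", "\n", sep = "")
  }
  invisible(x)
}

#' Read and write genomes as FASTA
#'
#' Thin wrappers around Biostrings. A chromosome named `chrM` (or the
#' explicit `mito_name`) is flagged as mitochondrial on read.
#'
#' @param path FASTA file path.
#' @param mito_name mitochondrial contig name; `NA` (default) auto-detects
#'   a sequence called `chrM`.
#' @return [te_genome()] object for the reader; `path` invisibly for the
#'   writer.
#' @export
read_genome_fasta <- function(path, mito_name = NA) {
  if (!file.exists(path)) stop("FASTA not found: ", path, call. = FALSE)
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (is.na(mito_name) || isTRUE(is.na(mito_name)))
    mito_name <- if ("chrM" %in% names(seqs)) "chrM" else NULL
  te_genome(seqs, mito_name = mito_name)
}

#' @rdname read_genome_fasta
#' @param genome [te_genome()] object (or named character vector).
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- if (inherits(genome, "te_genome")) genome$sequences else genome
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Construct a table of genomic intervals
#'
#' All intervals are 0-based half-open. `strand` is one of `"+"`, `"-"`,
#' `"."`.
#'
#' @param chrom,start,end,strand vectors (recycled) of interval fields.
#' @return data.table with columns chrom, start, end, strand.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  iv <- data.table::data.table(chrom = as.character(chrom),
                               start = as.integer(start),
                               end = as.integer(end),
                               strand = as.character(strand))
  bad <- which(!(iv$start >= 0L & iv$end > iv$start))
  if (length(bad) > 0L)
    stop("invalid interval(s) at row(s) ", paste(head(bad, 5), collapse = ","),
         ": need 0 <= start < end", call. = FALSE)
  if (!all(iv$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'", call. = FALSE)
  iv
}

#' Validate intervals against a genome
#'
#' @param iv interval table (chrom, start, end).
#' @param genome [te_genome()] object, or a named vector of lengths.
#' @param what label used in error messages.
#' @return `iv`, invisibly.
#' @export
validate_intervals <- function(iv, genome, what = "interval") {
  lens <- if (inherits(genome, "te_genome")) genome$lengths else genome
  unknown <- setdiff(unique(iv$chrom), names(lens))
  if (length(unknown) > 0L)
    stop(what, ": unknown chromosome(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  beyond <- which(iv$end > lens[iv$chrom])
  if (length(beyond) > 0L)
    stop(what, " beyond chromosome end at row(s) ",
         paste(head(beyond, 5), collapse = ","), call. = FALSE)
  invisible(iv)
}

#' Overlap width of two intervals in bp
#'
#' Vectorised; intervals on different chromosomes overlap by 0.
#'
#' @param a,b interval tables (chrom, start, end), recycled row-wise.
#' @return integer vector of overlap widths.
#' @export
#' @examples
#' overlap_bp(genomic_intervals("c", 0, 100), genomic_intervals("c", 50, 150))
overlap_bp <- function(a, b) {
  w <- pmax(0L, pmin(a$end, b$end) - pmax(a$start, b$start))
  w[a$chrom != b$chrom] <- 0L
  as.integer(w)
}

# ---- BED ------------------------------------------------------------------

#' Read and write BED files (0-based half-open)
#'
#' BED4 at minimum; column 4 is interpreted as the TE family name for
#' insertion files. BED6 strand is read when present, else `"."`.
#'
#' @param path BED file path.
#' @param genome optional [te_genome()] used to validate coordinates.
#' @return data.table with columns family, chrom, start, end, strand.
#' @export
read_bed <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("BED not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (ncol(dt) < 4L)
    stop("BED needs >= 4 columns (chrom start end name): ", path,
         call. = FALSE)
  out <- data.table::data.table(
    family = as.character(dt[[4L]]),
    chrom = as.character(dt[[1L]]),
    start = as.integer(dt[[2L]]),
    end = as.integer(dt[[3L]]),
    strand = if (ncol(dt) >= 6L) as.character(dt[[6L]]) else ".")
  bad <- which(!(out$start >= 0L & out$end > out$start))
  if (length(bad) > 0L)
    stop("BED invalid interval at line(s) ",
         paste(head(bad, 5), collapse = ","), " of ", path, call. = FALSE)
  if (!is.null(genome)) validate_intervals(out, genome, what = "BED record")
  out[]
}

#' @rdname read_bed
#' @param x insertion/region table (family, chrom, start, end, strand).
#' @export
write_bed <- function(x, path) {
  x <- data.table::as.data.table(x)
  bed <- data.table::data.table(chrom = x$chrom, start = x$start,
                                end = x$end, name = x$family,
                                score = 0L,
                                strand = if ("strand" %in% names(x))
                                  x$strand else ".")
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- gene table -----------------------------------------------------------

#' Read and write the gene annotation table
#'
#' TSV with header `gene_id chrom tss strand`; `tss` is a single 0-based
#' base position (the transcription start site).
#'
#' @param path TSV file path.
#' @param genome optional [te_genome()] for validation.
#' @return data.table(gene_id, chrom, tss, strand).
#' @export
read_gene_table <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("gene table not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(dt)))
    stop("gene table must have columns: ", paste(need, collapse = " "),
         call. = FALSE)
  dt <- dt[, .(gene_id = as.character(gene_id), chrom = as.character(chrom),
               tss = as.integer(tss), strand = as.character(strand))]
  if (!is.null(genome)) {
    iv <- data.table::data.table(chrom = dt$chrom, start = dt$tss,
                                 end = dt$tss + 1L)
    validate_intervals(iv, genome, what = "gene TSS")
  }
  dt[]
}

#' @rdname read_gene_table
#' @param x gene table.
#' @export
write_gene_table <- function(x, path) {
  data.table::fwrite(data.table::as.data.table(x)[,
    .(gene_id, chrom, tss, strand)], path, sep = "\t", quote = FALSE)
  invisible(path)
}

# ---- bedGraph -------------------------------------------------------------

#' Write a per-base track as bedGraph
#'
#' Consecutive equal values are run-length merged; zero runs are kept so
#' that round-trips are exact. Values are written with 4 significant
#' digits.
#'
#' @param track named list of per-base numeric vectors (one per
#'   chromosome), or a `mappability_track`.
#' @param path output path.
#' @param digits significant digits for values.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, digits = 4) {
  values <- if (inherits(track, "mappability_track")) track$values else track
  rows <- lapply(names(values), function(nm) {
    v <- signif(values[[nm]], digits)
    r <- rle(v)
    ends <- cumsum(r$lengths)
    data.table::data.table(chrom = nm, start = ends - r$lengths, end = ends,
                           value = r$values)
  })
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t",
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a bedGraph file back into a per-base track
#'
#' @param path bedGraph path.
#' @param lengths named integer vector of chromosome lengths (positions not
#'   covered by any record become 0).
#' @return named list of per-base numeric vectors.
#' @export
read_bedgraph <- function(path, lengths) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"))
  out <- lapply(names(lengths), function(nm) {
    v <- numeric(lengths[[nm]])
    sub <- dt[chrom == nm]
    if (nrow(sub) > 0L) {
      for (i in seq_len(nrow(sub)))
        v[(sub$start[i] + 1L):sub$end[i]] <- sub$value[i]
    }
    v
  })
  stats::setNames(out, names(lengths))
}
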