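#' Reverse complement of DNA strings
#'
#' Vectorised exact reverse complement over the `ACGT` alphabet
#' (case preserved for lower-case input, `N` maps to `N`).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAAC"))
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgtN", "TGCAtgcaN", x))
}

#' Deterministic stage seed derived from a root seed
#'
#' Mixes a root integer seed with a stage label so that every stochastic
#' stage of a pipeline run draws from its own reproducible stream.
#' The result always fits in a 32-bit signed integer.
#'
#' @param seed integer root seed.
#' @param stage character scalar naming the stage.
#' @return integer scalar in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) + 7919 * h) %% 2147483647)
}

#' Write a data frame as TSV with stabilised floating-point columns
#'
#' Numeric (double) columns are rounded to 6 significant digits before
#' writing so that repeated runs with identical seeds produce
#' byte-identical files.
#'
#' @param x data.frame or data.table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  x <- data.table::as.data.table(x)
  for (j in names(x)) {
    if (is.double(x[[j]])) data.table::set(x, j = j, value = signif(x[[j]], 6))
  }
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA")
}

# random DNA of length n under the current RNG state
random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
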