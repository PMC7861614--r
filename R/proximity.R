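#' Insertion reference points
#'
#' The reference point of an insertion is its interval midpoint, matching
#' the centre anchoring used for meta-profiles.
#'
#' @param insertions insertion table (family, chrom, start, end, strand).
#' @return integer vector of midpoints.
#' @export
insertion_centers <- function(insertions) {
  as.integer((insertions$start + insertions$end) %/% 2L)
}

#' Drop clustered insertions
#'
#' Removes every insertion whose reference point lies closer than
#' `min_gap` to any other insertion's reference point on the same
#' chromosome (symmetric rule: both members of a close pair go).
#' Survivors are pairwise at least `min_gap` apart; the operation is
#' idempotent.
#'
#' @param insertions insertion table.
#' @param min_gap minimum centre-to-centre distance in bp (exclusive).
#' @return filtered insertion table.
#' @export
filter_clustered <- function(insertions, min_gap = 5000L) {
  dt <- data.table::as.data.table(insertions)
  if (nrow(dt) < 2L) return(dt)
  ctr <- insertion_centers(dt)
  ord <- order(dt$chrom, ctr)
  oc <- ctr[ord]
  och <- dt$chrom[ord]
  nn <- length(oc)
  dprev <- c(Inf, diff(oc))
  dprev[c(TRUE, och[-1L] != och[-nn])] <- Inf
  dnext <- c(dprev[-1L], Inf)
  drop_sorted <- dprev < min_gap | dnext < min_gap
  keep <- rep(TRUE, nn)
  keep[ord] <- !drop_sorted
  dt[keep]
}

#' Annotate gene promoters by insertion proximity
#'
#' A gene is near a TE insertion iff its TSS lies within
#' `tss_window_up` bp upstream and `tss_window_down` bp downstream of the
#' insertion reference point (centre) for at least one insertion of the
#' selected families. With `orientation = "insertion"` (default)
#' upstream/downstream follow the insertion's annotated strand; with
#' `"reference"` they follow the reference orientation regardless of
#' strand. Insertions should already be cluster-filtered
#' ([filter_clustered()]).
#'
#' @param genes gene table (gene_id, chrom, tss, strand).
#' @param insertions insertion table.
#' @param config [pipeline_config()] (window sizes, family list).
#' @param families families considered; default
#'   `config$upregulated_families`.
#' @param orientation `"insertion"` or `"reference"` (see above).
#' @return data.table(gene_id, near_te, nearest_family, distance) where
#'   `distance` is the signed bp offset (reference orientation) from the
#'   nearest qualifying insertion centre to the TSS.
#' @export
annotate_tss_proximity <- function(genes, insertions,
                                   config = pipeline_config(),
                                   families = config$upregulated_families,
                                   orientation = c("insertion",
                                                   "reference")) {
  orientation <- match.arg(orientation)
  genes <- data.table::as.data.table(genes)
  ins <- data.table::as.data.table(insertions)[family %in% families]
  up <- config$tss_window_up
  down <- config$tss_window_down
  out <- data.table::data.table(gene_id = genes$gene_id, near_te = FALSE,
                                nearest_family = NA_character_,
                                distance = NA_integer_)
  if (nrow(ins) == 0L || nrow(genes) == 0L) return(out)
  ctr <- insertion_centers(ins)
  flip <- orientation == "insertion" & ins$strand == "-"
  for (i in seq_len(nrow(genes))) {
    on_chrom <- ins$chrom == genes$chrom[i]
    if (!any(on_chrom)) next
    d <- genes$tss[i] - ctr[on_chrom]             # signed, reference frame
    doriented <- ifelse(flip[on_chrom], -d, d)    # insertion frame
    hit <- doriented >= -up & doriented < down
    if (any(hit)) {
      idx <- which(on_chrom)[hit]
      dh <- d[hit]
      best <- which.min(abs(dh))
      out[i, `:=`(near_te = TRUE,
                  nearest_family = ins$family[idx[best]],
                  distance = as.integer(dh[best]))]
    }
  }
  out
}

#' Proximity fraction stratified by fold change
#'
#' Restricts to expressed genes (`rpkm_mean > rpkm_threshold`),
#' partitions them into log2-fold-change strata and reports the fraction
#' of genes per stratum whose promoter is near a TE insertion.
#'
#' @param de [fold_change_and_test()] result for genes (feature_id
#'   matching `prox$gene_id`).
#' @param prox [annotate_tss_proximity()] result.
#' @param strata numeric vector of lfc bin edges (left-closed,
#'   right-open; use `-Inf`/`Inf` for open ends).
#' @param rpkm_threshold expression floor (exclusive).
#' @return data.table(stratum, n_genes, n_near, fraction); empty strata
#'   report `fraction = NA`.
#' @export
stratified_fraction <- function(de, prox,
                                strata = c(-Inf, -1, 0, 1, 2, Inf),
                                rpkm_threshold = 1) {
  de <- data.table::as.data.table(de)
  prox <- data.table::as.data.table(prox)
  tab <- merge(de[, .(gene_id = feature_id, lfc, rpkm_mean)],
               prox[, .(gene_id, near_te)], by = "gene_id")
  tab <- tab[rpkm_mean > rpkm_threshold]
  labs <- paste0("[", utils::head(strata, -1L), ",", strata[-1L], ")")
  tab[, stratum := cut(lfc, breaks = strata, labels = labs, right = FALSE)]
  out <- tab[, .(n_genes = .N, n_near = sum(near_te)), by = stratum]
  full <- data.table::data.table(stratum = factor(labs, levels = labs))
  out <- merge(full, out, by = "stratum", all.x = TRUE)
  out[is.na(n_genes), `:=`(n_genes = 0L, n_near = 0L)]
  out[, fraction := ifelse(n_genes > 0L, n_near / n_genes, NA_real_)]
  out[]
}
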