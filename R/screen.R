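# Transcript screening rules feeding the bait-design cascade:
# haploid-heterozygosity PSC flag, copy-number class from genome hits,
# mosaic self-hits, organelle and contaminant screens.

#' Flag transcripts with haploid heterozygosity (the PSC signal)
#'
#' Heterozygous calls from reads of haploid megagametophyte tissue can
#' only arise from paralog co-mapping (or residual error), so
#' `haploid_het` is TRUE when the ME-group observed heterozygosity is
#' above zero on a transcript with more than `min_callable` callable
#' sites. Transcripts without sufficient callable data are NA.
#'
#' @param stats a `het_stats` data.frame containing ME rows.
#' @param min_callable callable-site threshold.
#' @return data.frame with `contig_id` and logical `haploid_het`.
#' @export
flag_haploid_het <- function(stats, min_callable = 100) {
  s <- stats[stats$group == "ME", , drop = FALSE]
  if (!nrow(s)) stop("no ME-group statistics available")
  ok <- s$n_callable > min_callable & !is.na(s$Ho_per_bp)
  data.frame(contig_id = s$contig_id,
             haploid_het = ifelse(ok, s$Ho_per_bp > 0, NA))
}

#' Classify transcripts as single- or multi-copy from genome hits
#'
#' Each hit's query interval is trimmed by `edge_trim` bp per edge (to
#' avoid spurious alignment at the ends); hits whose trimmed interval is
#' empty are ignored. A transcript is `multi` when any query position is
#' covered by two or more trimmed hits with identity strictly above
#' `min_identity`; otherwise `single` when the trimmed hits cover at
#' least `min_cov` of the transcript length; otherwise `unassigned`.
#'
#' @param hits a hit data.frame (outfmt-6 columns).
#' @param transcript_lengths named vector of transcript lengths; its
#'   names define the classified universe.
#' @param min_identity identity threshold (strict, percent).
#' @param edge_trim bp removed from each alignment edge.
#' @param min_cov minimum covered fraction for single-copy assignment.
#' @return data.frame with `contig_id` and `copy_class` (factor
#'   single/multi/unassigned).
#' @export
classify_copy_number <- function(hits, transcript_lengths,
                                 min_identity = 85, edge_trim = 10,
                                 min_cov = 0.5) {
  stopifnot(!is.null(names(transcript_lengths)))
  cls <- rep("unassigned", length(transcript_lengths))
  names(cls) <- names(transcript_lengths)
  h <- hits[hits$pct_identity > min_identity, , drop = FALSE]
  if (nrow(h)) {
    h$qs <- h$q_start + edge_trim
    h$qe <- h$q_end - edge_trim
    h <- h[h$qe >= h$qs, , drop = FALSE]        # empty after trim: ignored
    for (id in unique(h$query_id)) {
      if (!id %in% names(cls)) next
      hh <- h[h$query_id == id, , drop = FALSE]
      ir <- IRanges::IRanges(start = hh$qs, end = hh$qe)
      if (max(max(IRanges::coverage(ir)), 0) >= 2) {
        cls[id] <- "multi"
      } else {
        cov_len <- sum(IRanges::width(IRanges::reduce(ir)))
        if (cov_len >= min_cov * transcript_lengths[id]) cls[id] <- "single"
      }
    }
  }
  data.frame(contig_id = names(cls),
             copy_class = factor(cls, levels = c("single", "multi",
                                                 "unassigned")),
             row.names = NULL)
}

#' Detect mosaic transcripts from self-alignment hits
#'
#' A transcript is a mosaic when it has a self-alignment hit other than
#' the trivial identity match -- i.e. a hit whose query and subject
#' intervals differ, indicating near-identical sequence blocks repeated
#' within the contig (merged divergent alleles or collapsed paralogs).
#' The result is invariant to hit order and to query/subject interval
#' swaps.
#'
#' @param self_hits hit data.frame from [self_align_contigs()] or an
#'   external self-BLAST (outfmt 6).
#' @param contig_ids universe of transcripts (default: those in
#'   `self_hits`).
#' @return data.frame with `contig_id` and logical `mosaic`.
#' @export
detect_mosaics <- function(self_hits, contig_ids = NULL) {
  h <- self_hits[self_hits$query_id == self_hits$subject_id, , drop = FALSE]
  nontrivial <- !(h$q_start == h$s_start & h$q_end == h$s_end)
  flagged <- unique(h$query_id[nontrivial])
  ids <- contig_ids %||% unique(self_hits$query_id)
  data.frame(contig_id = ids, mosaic = ids %in% flagged, row.names = NULL)
}

#' Screen transcripts against organelle genomes
#'
#' Flags transcripts with any organelle hit at e-value at most
#' `max_evalue` and identity at least `min_identity` (word size is the
#' upstream search's concern).
#'
#' @param hits hit data.frame vs an organelle subject set.
#' @param contig_ids universe of transcripts.
#' @param max_evalue e-value cutoff (inclusive).
#' @param min_identity identity cutoff in percent (inclusive).
#' @return data.frame with `contig_id` and logical flag column.
#' @export
screen_organelle <- function(hits, contig_ids = NULL, max_evalue = 5e-2,
                             min_identity = 80) {
  flagged <- unique(hits$query_id[hits$evalue <= max_evalue &
                                    hits$pct_identity >= min_identity])
  ids <- contig_ids %||% unique(hits$query_id)
  data.frame(contig_id = ids, organelle = ids %in% flagged,
             row.names = NULL)
}

#' Screen transcripts against contaminant proteins
#'
#' Flags transcripts with any contaminant-database hit at e-value at
#' most `max_evalue` and identity at least `min_identity`. The search
#' itself (e.g. BLASTx vs Swiss-Prot subsets) is consumed as tabular
#' input, never performed.
#'
#' @inheritParams screen_organelle
#' @export
screen_contaminants <- function(hits, contig_ids = NULL, max_evalue = 1e-5,
                                min_identity = 65) {
  flagged <- unique(hits$query_id[hits$evalue <= max_evalue &
                                    hits$pct_identity >= min_identity])
  ids <- contig_ids %||% unique(hits$query_id)
  data.frame(contig_id = ids, contaminant = ids %in% flagged,
             row.names = NULL)
}

#' Assemble the per-transcript flag table
#'
#' Joins the individual screens into one table: `haploid_het` (PSC
#' signal), `copy_class`, `mosaic`, `organelle`, `contaminant`,
#' `low_expression`. Screens not supplied default to FALSE (or
#' `unassigned` for copy class, NA for haploid het).
#'
#' @param contig_ids character vector of transcripts.
#' @param haploid_het,copy_class,mosaic,organelle,contaminant,low_expression
#'   data.frames as produced by the individual screen functions, or
#'   NULL.
#' @return data.frame of class `transcript_flags`.
#' @export
transcript_flags <- function(contig_ids, haploid_het = NULL,
                             copy_class = NULL, mosaic = NULL,
                             organelle = NULL, contaminant = NULL,
                             low_expression = NULL) {
  pull <- function(df, col, default) {
    if (is.null(df)) return(rep(default, length(contig_ids)))
    v <- df[[col]][match(contig_ids, df$contig_id)]
    if (is.factor(df[[col]])) v <- as.character(v)
    v[is.na(v) & !is.na(default)] <- default
    v
  }
  out <- data.frame(
    contig_id = contig_ids,
    haploid_het = pull(haploid_het, "haploid_het", NA),
    copy_class = factor(pull(copy_class, "copy_class", "unassigned"),
                        levels = c("single", "multi", "unassigned")),
    mosaic = pull(mosaic, "mosaic", FALSE),
    organelle = pull(organelle, "organelle", FALSE),
    contaminant = pull(contaminant, "contaminant", FALSE),
    low_expression = pull(low_expression, "low_expression", FALSE))
  class(out) <- c("transcript_flags", "data.frame")
  out
}
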