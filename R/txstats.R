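# Assembly-level and expression statistics: contig counts, N50, TPM,
# expression-weighted N50 (ExN50 / E90N50) and the low-expression filter.

.n50 <- function(lengths) {
  # descending-cumulative convention: the length L at which contigs of
  # length >= L first cover half the total bases
  l <- sort(lengths, decreasing = TRUE)
  l[which(cumsum(as.numeric(l)) >= sum(as.numeric(l)) / 2)[1L]]
}

#' Basic assembly statistics
#'
#' Contig count, total and mean length, and N50 under the
#' descending-cumulative convention (the contig length at which the
#' length-sorted cumulative sum first reaches half the assembly).
#'
#' @param x a FASTA path, a `Biostrings::DNAStringSet`, a
#'   `psc_reference`, or a numeric vector of contig lengths.
#' @return data.frame with `n_contigs`, `total_bases`, `mean_length`,
#'   `N50`.
#' @examples
#' assembly_stats(c(1000, 800, 600))  # N50 = 800
#' @export
assembly_stats <- function(x) {
  lengths <- if (is.numeric(x)) {
    x
  } else if (inherits(x, "psc_reference")) {
    x$index$length
  } else if (inherits(x, "DNAStringSet")) {
    Biostrings::width(x)
  } else if (is.character(x) && length(x) == 1L && file.exists(x)) {
    Biostrings::width(Biostrings::readDNAStringSet(x))
  } else stop("cannot interpret 'x' as an assembly")
  if (!length(lengths)) stop("empty assembly")
  data.frame(n_contigs = length(lengths),
             total_bases = sum(as.numeric(lengths)),
             mean_length = mean(lengths),
             N50 = .n50(lengths))
}

#' Transcripts-per-million normalization
#'
#' `TPM_i = (count_i / length_i) / sum_j (count_j / length_j) * 1e6`
#' per sample. Samples with all-zero counts get NA TPM and are recorded
#' in `zero_samples`.
#'
#' @param counts transcripts x samples matrix of effective counts (row
#'   names are transcript ids).
#' @param lengths per-transcript lengths (named or in row order).
#' @return An object of class `expression_matrix`: `counts`, `lengths`,
#'   `tpm`, `mean_tpm` and `zero_samples`.
#' @export
compute_tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  if (any(lengths <= 0)) stop("transcript lengths must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  rate <- counts / lengths
  tot <- colSums(rate)
  zero <- tot == 0
  tot[zero] <- NA_real_
  tpm <- sweep(rate, 2L, tot, "/") * 1e6
  structure(list(counts = counts, lengths = lengths, tpm = tpm,
                 mean_tpm = rowMeans(tpm, na.rm = TRUE),
                 zero_samples = colnames(counts)[zero] %||% which(zero)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d transcripts x %d samples (TPM computed)\n",
              nrow(x$counts), ncol(x$counts)))
  if (length(x$zero_samples))
    cat("  all-zero samples:", paste(x$zero_samples, collapse = ", "), "\n")
  invisible(x)
}

#' Expression-weighted N50 (ExN50)
#'
#' Ranks transcripts by pooled expression (summed counts across samples)
#' in decreasing order, takes the smallest prefix whose expression share
#' reaches `x` percent of the total, and returns the N50 of that
#' prefix's lengths. E90N50 is the conventional `x = 90`.
#'
#' @param em an `expression_matrix` from [compute_tpm()], or a counts
#'   matrix.
#' @param lengths transcript lengths (taken from `em` when absent).
#' @param x expression percentile in (0, 100].
#' @param per_sample if TRUE, return one ExN50 per sample instead of
#'   the pooled value.
#' @return ExN50 length (or named vector, when `per_sample`).
#' @export
exn50 <- function(em, lengths = NULL, x = 90, per_sample = FALSE) {
  if (x <= 0 || x > 100) stop("'x' must be in (0, 100]")
  if (inherits(em, "expression_matrix")) {
    counts <- em$counts
    lengths <- lengths %||% em$lengths
  } else counts <- as.matrix(em)
  if (is.null(lengths)) stop("'lengths' required")
  one <- function(expr) {
    if (sum(expr) <= 0) stop("expression totals must be positive")
    ord <- order(expr, decreasing = TRUE)
    share <- cumsum(expr[ord]) / sum(expr)
    n <- which(share >= x / 100)[1L]
    .n50(lengths[ord[seq_len(n)]])
  }
  if (per_sample)
    vapply(seq_len(ncol(counts)), function(j) one(counts[, j]),
           numeric(1)) |> stats::setNames(colnames(counts))
  else one(rowSums(counts))
}

#' Flag transcripts from lowly expressed genes
#'
#' Flags transcripts whose gene-level mean TPM (member transcript TPMs
#' summed within gene per sample, then averaged over samples) is at or
#' below `tpm_cutoff` -- the strict "> 10 TPM" retention rule.
#'
#' @param em an `expression_matrix`.
#' @param gene_ids gene of each transcript (default: each transcript is
#'   its own gene).
#' @param tpm_cutoff retention threshold (transcripts are kept when the
#'   gene mean TPM is strictly above it).
#' @return data.frame with `contig_id`, `gene_mean_tpm` and logical
#'   `low_expression`.
#' @export
low_expression_filter <- function(em, gene_ids = NULL, tpm_cutoff = 10) {
  stopifnot(inherits(em, "expression_matrix"))
  ids <- rownames(em$counts)
  gene_ids <- gene_ids %||% ids
  gsum <- rowsum(em$tpm, gene_ids, na.rm = TRUE)
  gmean <- rowMeans(gsum, na.rm = TRUE)
  gm <- gmean[match(gene_ids, rownames(gsum))]
  data.frame(contig_id = ids, gene_mean_tpm = unname(gm),
             low_expression = unname(gm) <= tpm_cutoff)
}

#' Isoform pre-filter for SuperTranscript construction
#'
#' Drops isoforms that are short (length at most `len_min`) or lowly
#' expressed (total effective count at most `count_min`). A gene losing
#' all its isoforms keeps its longest one, so no gene is ever removed
#' entirely.
#'
#' @param isoforms data.frame with columns `isoform_id`, `gene_id`,
#'   `length`, `total_count`.
#' @param len_min,count_min drop thresholds (inclusive).
#' @return character vector of retained isoform ids.
#' @export
isoform_prefilter <- function(isoforms, len_min = 300, count_min = 10) {
  stopifnot(all(c("isoform_id", "gene_id", "length", "total_count") %in%
                  names(isoforms)))
  keep <- isoforms$length > len_min & isoforms$total_count > count_min
  lost <- setdiff(isoforms$gene_id, isoforms$gene_id[keep])
  for (g in lost) {
    i <- which(isoforms$gene_id == g)
    keep[i[which.max(isoforms$length[i])]] <- TRUE
  }
  isoforms$isoform_id[keep]
}
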