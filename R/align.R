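# Seed-and-extend local aligner for desk-scale contig sets: exact k-mer
# seeds, per-diagonal X-drop ungapped extension, then affine-penalty
# chaining of collinear segments on nearby diagonals. Scoring and
# e-value parameters follow blastn conventions (reward 2 / penalty -3,
# gap open 5 / extend 2, lambda 0.625, K 0.41).

.kmer_codes <- function(x, k) {
  n <- length(x) - k + 1L
  if (n < 1L) return(integer(0))
  code <- numeric(n)
  for (j in 0:(k - 1L)) code <- code * 4 + (x[(1L + j):(n + j)] - 1)
  code
}

.as_intseq <- function(x) {
  if (is.character(x)) string_to_seq(x)
  else if (inherits(x, "DNAString")) string_to_seq(as.character(x))
  else as.integer(x)
}

# maximal scoring ungapped segments along one diagonal
.diag_segments <- function(eq, match, mismatch, xdrop) {
  sc <- ifelse(eq, match, mismatch)
  segs <- list()
  run <- 0; run_start <- 1L
  best <- 0; best_at <- 0L
  close_seg <- function() {
    if (best > 0)
      segs[[length(segs) + 1L]] <<- c(start = run_start, end = best_at,
                                      score = best)
  }
  for (i in seq_along(sc)) {
    run <- run + sc[i]
    if (run > best) { best <- run; best_at <- i }
    if (run < 0 || best - run > xdrop) {
      close_seg()
      run <- 0; best <- 0; run_start <- i + 1L; best_at <- i
    }
  }
  close_seg()
  segs
}

#' Local alignment of two sequences
#'
#' Seed-and-extend local alignment: exact `k`-mer seeds define candidate
#' diagonals; each seeded diagonal is scanned for maximal-scoring
#' ungapped segments under an X-drop rule; collinear segments on nearby
#' diagonals are then chained with affine gap penalties into single
#' hits. Hits are reported in BLAST tabular (outfmt 6) semantics with
#' 1-based inclusive coordinates. Deterministic.
#'
#' @param query,subject sequences: character strings, `DNAString`s or
#'   integer vectors over 1:4 = A,C,G,T.
#' @param query_id,subject_id identifiers for the output table.
#' @param k seed length.
#' @param min_len minimum alignment length to report.
#' @param min_identity minimum percent identity to report.
#' @param match,mismatch,gap_open,gap_extend alignment scores (penalties
#'   negative).
#' @param xdrop terminate ungapped extension when the running score
#'   falls this far below the segment maximum.
#' @param band maximum diagonal offset bridged when chaining segments.
#' @return data.frame of hits with the 12 outfmt-6 columns (`query_id`,
#'   `subject_id`, `pct_identity`, `aln_len`, `mismatches`, `gap_open`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `evalue`, `bitscore`).
#' @examples
#' a <- strrep("ACGT", 50)
#' local_align(a, a)
#' @export
local_align <- function(query, subject, query_id = "query",
                        subject_id = "subject", k = 11, min_len = 60,
                        min_identity = 80, match = 2, mismatch = -3,
                        gap_open = -5, gap_extend = -2, xdrop = 40,
                        band = 15) {
  q <- .as_intseq(query)
  s <- .as_intseq(subject)
  if (!length(q) || !length(s)) stop("empty sequence")
  qc <- .kmer_codes(q, k)
  sc <- .kmer_codes(s, k)
  if (!length(qc) || !length(sc)) return(.empty_hits())
  s_index <- split(seq_along(sc), sc)
  hit_idx <- s_index[as.character(qc)]
  n_per <- lengths(hit_idx)
  if (sum(n_per) == 0) return(.empty_hits())
  qpos <- rep(seq_along(qc), n_per)
  spos <- unlist(hit_idx, use.names = FALSE)
  diags <- unique(qpos - spos)

  segs <- list()
  for (d in diags) {
    # overlap of q and s along diagonal d (q = s + d)
    s_lo <- max(1L, 1L - d)
    s_hi <- min(length(s), length(q) - d)
    if (s_hi - s_lo + 1L < k) next
    eq <- q[(s_lo:s_hi) + d] == s[s_lo:s_hi]
    for (sg in .diag_segments(eq, match, mismatch, xdrop)) {
      st <- s_lo + sg[["start"]] - 1L
      en <- s_lo + sg[["end"]] - 1L
      seg_eq <- eq[sg[["start"]]:sg[["end"]]]
      segs[[length(segs) + 1L]] <- data.frame(
        diag = d, s_start = st, s_end = en, q_start = st + d,
        q_end = en + d, matches = sum(seg_eq),
        mism = sum(!seg_eq), score = sg[["score"]])
    }
  }
  if (!length(segs)) return(.empty_hits())
  segs <- do.call(rbind, segs)
  segs <- segs[order(segs$q_start, segs$s_start), , drop = FALSE]

  # greedy chaining of collinear segments on nearby diagonals
  used <- logical(nrow(segs))
  hits <- list()
  ord <- order(-segs$score)
  for (i0 in ord) {
    if (used[i0]) next
    chain <- i0
    used[i0] <- TRUE
    repeat {
      last <- chain[length(chain)]
      cand <- which(!used &
                      segs$q_start > segs$q_end[last] &
                      segs$s_start > segs$s_end[last] &
                      abs(segs$diag - segs$diag[last]) <= band &
                      segs$q_start - segs$q_end[last] <= band + 1L)
      if (!length(cand)) break
      nxt <- cand[which.max(segs$score[cand])]
      gap <- abs(segs$diag[nxt] - segs$diag[last])
      add <- segs$score[nxt] +
        (if (gap > 0) gap_open + gap_extend * (gap - 1L) else
           mismatch * (segs$q_start[nxt] - segs$q_end[last] - 1L))
      if (add <= 0) break
      used[nxt] <- TRUE
      chain <- c(chain, nxt)
    }
    ch <- segs[chain, , drop = FALSE]
    gaps <- if (nrow(ch) > 1L) abs(diff(ch$diag)) else integer(0)
    n_gapopen <- sum(gaps > 0)
    gap_bases <- sum(gaps)
    # ungapped stretches between chained segments count as mismatches
    inner_mm <- if (nrow(ch) > 1L)
      sum(pmax(0L, ch$q_start[-1L] - ch$q_end[-nrow(ch)] - 1L -
                 abs(diff(ch$diag)))) else 0L
    matches <- sum(ch$matches)
    mism <- sum(ch$mism) + inner_mm
    aln_len <- matches + mism + gap_bases
    score <- matches * match + mism * mismatch +
      n_gapopen * gap_open + (gap_bases - n_gapopen) * gap_extend
    hits[[length(hits) + 1L]] <- data.frame(
      query_id = query_id, subject_id = subject_id,
      pct_identity = 100 * matches / aln_len, aln_len = aln_len,
      mismatches = mism, gap_open = n_gapopen,
      q_start = ch$q_start[1L], q_end = ch$q_end[nrow(ch)],
      s_start = ch$s_start[1L], s_end = ch$s_end[nrow(ch)],
      evalue = NA_real_, bitscore = NA_real_, score = score)
  }
  out <- do.call(rbind, hits)
  bit <- (0.625 * out$score - log(0.41)) / log(2)
  out$bitscore <- round(bit, 1)
  out$evalue <- length(q) * length(s) * 2^(-bit)
  out$score <- NULL
  out <- out[out$aln_len >= min_len & out$pct_identity >= min_identity, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             pct_identity = numeric(), aln_len = integer(),
             mismatches = integer(), gap_open = integer(),
             q_start = integer(), q_end = integer(), s_start = integer(),
             s_end = integer(), evalue = numeric(), bitscore = numeric())
}

#' Align a set of queries against a set of subjects
#'
#' Shared-k-mer prescreening (a query/subject pair is aligned only when
#' it shares at least `min_shared_kmers` seeds) followed by
#' [local_align()] on each candidate pair.
#'
#' @param queries,subjects named lists (or named character vectors) of
#'   sequences.
#' @param min_shared_kmers candidate threshold.
#' @param ... passed to [local_align()].
#' @inheritParams local_align
#' @return combined hit data.frame (outfmt-6 columns).
#' @export
align_to_set <- function(queries, subjects, k = 11, min_shared_kmers = 5,
                         ...) {
  qs <- lapply(queries, .as_intseq)
  ss <- lapply(subjects, .as_intseq)
  if (is.null(names(qs)) || is.null(names(ss)))
    stop("'queries' and 'subjects' must be named")
  s_codes <- lapply(ss, .kmer_codes, k = k)
  s_tab <- split(rep(names(ss), lengths(s_codes)),
                 unlist(s_codes, use.names = FALSE))
  out <- list()
  for (qn in names(qs)) {
    qc <- unique(.kmer_codes(qs[[qn]], k))
    cand <- unlist(s_tab[as.character(qc)], use.names = FALSE)
    if (is.null(cand)) next
    cand <- table(cand)
    cand <- names(cand)[cand >= min_shared_kmers]
    for (sn in cand)
      out[[paste(qn, sn)]] <- local_align(qs[[qn]], ss[[sn]],
                                          query_id = qn, subject_id = sn,
                                          k = k, ...)
  }
  if (!length(out)) return(.empty_hits())
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  rownames(res) <- NULL
  res
}

#' Self-alignment of contigs (mosaic search)
#'
#' Aligns every contig against itself and returns all hits, including
#' the trivial full-length self-match (which [detect_mosaics()]
#' excludes).
#'
#' @param contigs named list (or character vector) of sequences.
#' @param ... passed to [local_align()].
#' @return combined hit data.frame.
#' @export
self_align_contigs <- function(contigs, ...) {
  seqs <- lapply(contigs, .as_intseq)
  out <- lapply(names(seqs), function(nm)
    local_align(seqs[[nm]], seqs[[nm]], query_id = nm, subject_id = nm, ...))
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(res)) return(.empty_hits())
  rownames(res) <- NULL
  res
}

#' Read and write BLAST tabular (outfmt 6) hit files
#'
#' Standard 12-column tab-separated format with 1-based inclusive
#' coordinates. On read, hits are orientation-normalized so that
#' `q_start <= q_end` (subject coordinates keep their strand).
#'
#' @param path file path.
#' @return `read_blast_tab` returns a hit data.frame with the same
#'   columns as [local_align()].
#' @export
read_blast_tab <- function(path) {
  cols <- c("query_id", "subject_id", "pct_identity", "aln_len",
            "mismatches", "gap_open", "q_start", "q_end", "s_start",
            "s_end", "evalue", "bitscore")
  x <- read.table(path, sep = "\t", header = FALSE, col.names = cols,
                  colClasses = c("character", "character", rep("numeric", 10)))
  flip <- x$q_start > x$q_end
  if (any(flip)) {
    tmp <- x$q_start[flip]
    x$q_start[flip] <- x$q_end[flip]
    x$q_end[flip] <- tmp
    tmp <- x$s_start[flip]
    x$s_start[flip] <- x$s_end[flip]
    x$s_end[flip] <- tmp
  }
  x
}

#' @rdname read_blast_tab
#' @param hits a hit data.frame.
#' @export
write_blast_tab <- function(hits, path) {
  cols <- c("query_id", "subject_id", "pct_identity", "aln_len",
            "mismatches", "gap_open", "q_start", "q_end", "s_start",
            "s_end", "evalue", "bitscore")
  write.table(hits[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
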