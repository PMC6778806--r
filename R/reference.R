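# Reference-building emulation.
#
# All haplotypes of a paralog family live in a shared coordinate space
# (member 2 of a family is a positional copy of member 1), so every
# contig records "placements": intervals of that shared space together
# with the contig position they start at. The mapping emulation uses
# placements to locate, for any read window, the contig region it would
# align to -- unrelated genes can never reach the mismatch ceiling, so
# only family-mates are candidates.

family_key <- function(truth, gene_ids) {
  fid <- truth$genes$family_id[match(gene_ids, truth$genes$gene_id)]
  ifelse(is.na(fid), gene_ids, sprintf("fam%04d", fid))
}

#' Build a reference transcriptome from a truth set
#'
#' Emulates three assembly strategies:
#' \describe{
#'   \item{redundant}{one contig per distinct expressed allele sequence
#'     per isoform (alleles with identical sequence over the isoform are
#'     already indistinguishable to an assembler and yield one contig).}
#'   \item{clustered}{greedy longest-first identity clustering of the
#'     redundant set (CD-HIT style): a contig joins a cluster iff its
#'     identity to the representative, measured over the shorter
#'     sequence, is at least `cluster_identity`; only the representative
#'     sequence is retained. Paralog families whose members exceed the
#'     cut-off are collapsed into a single contig (PSC).}
#'   \item{supertranscript}{per gene, isoforms failing the pre-filter
#'     (length <= 300 bp or total effective count <= 10) are dropped,
#'     keeping the longest isoform if all fail; surviving allele/isoform
#'     contigs are merged block-wise into one contig per gene. An
#'     incoming contig whose identity to the growing SuperTranscript is
#'     below `st_merge_identity` is appended as a new consecutive block,
#'     which duplicates gene sequence inside the contig (a mosaic).}
#' }
#'
#' @param truth a `truth_set`.
#' @param strategy one of `"redundant"`, `"clustered"`,
#'   `"supertranscript"`.
#' @param iso_len_min,iso_count_min SuperTranscript isoform pre-filter
#'   thresholds (length and total effective count, both inclusive drops).
#' @return An object of class `psc_reference`: named list of contig
#'   sequences, a placement table, a provenance table (contig, source
#'   gene, haplotype, isoform) and an index with a `collapsed` flag
#'   (TRUE when a contig has two or more distinct source genes).
#' @examples
#' truth <- simulate_population(sim_config(n_genes = 4, seed = 7))
#' ref <- build_reference(truth, "clustered")
#' ref$index
#' @export
build_reference <- function(truth, strategy = c("redundant", "clustered",
                                                "supertranscript"),
                            iso_len_min = 300, iso_count_min = 10) {
  stopifnot(inherits(truth, "truth_set"))
  strategy <- match.arg(strategy)
  red <- .redundant_contigs(truth)
  out <- switch(strategy,
    redundant = red,
    clustered = .cluster_contigs(truth, red),
    supertranscript = .supertranscripts(truth, red, iso_len_min,
                                        iso_count_min))
  out$strategy <- strategy
  out$index <- .reference_index(out, strategy)
  class(out) <- "psc_reference"
  out
}

.reference_index <- function(ref, strategy) {
  ids <- names(ref$contigs)
  n_src <- vapply(ids, function(id)
    length(unique(ref$provenance$gene_id[ref$provenance$contig_id == id])),
    1L)
  data.frame(contig_id = ids,
             length = vapply(ref$contigs, length, 1L),
             strategy = strategy,
             n_source_genes = n_src,
             collapsed = n_src >= 2L,
             row.names = NULL)
}

# one contig per distinct expressed allele sequence x isoform
.redundant_contigs <- function(truth) {
  contigs <- list()
  placements <- list()
  provenance <- list()
  for (g in truth$genes$gene_id) {
    ped <- truth$ped[[g]]
    expressed <- sort(unique(c(ped$mat, ped$pat)))
    pm <- gene_pool_matrix(truth, g, expressed)
    iso <- truth$isoforms[truth$isoforms$gene_id == g, , drop = FALSE]
    fk <- family_key(truth, g)
    for (i in seq_len(nrow(iso))) {
      rng <- iso$start[i]:iso$end[i]
      sub <- pm[rng, , drop = FALSE]
      key <- apply(sub, 2L, paste, collapse = "")
      for (u in unique(key)) {
        haps <- expressed[key == u]
        cid <- sprintf("%s_h%02d_i%d", g, haps[1L], i)
        contigs[[cid]] <- sub[, match(u, key)]
        placements[[cid]] <- data.frame(
          contig_id = cid, gene_id = g, family_key = fk,
          gene_start = iso$start[i], gene_end = iso$end[i],
          contig_start = 1L)
        provenance[[cid]] <- data.frame(
          contig_id = cid, gene_id = g, hap = haps,
          isoform_id = iso$isoform_id[i])
      }
    }
  }
  list(contigs = contigs,
       placements = do.call(rbind, c(placements, list(make.row.names = FALSE))),
       provenance = do.call(rbind, c(provenance, list(make.row.names = FALSE))))
}

# identity of contig b against representative a over the shared
# coordinate space, measured per CD-HIT convention over the shorter
# sequence (uncovered positions of the shorter count as mismatches)
.pair_identity <- function(pa, pb, seq_a, seq_b) {
  s <- max(pa$gene_start, pb$gene_start)
  e <- min(pa$gene_end, pb$gene_end)
  shorter <- min(length(seq_a), length(seq_b))
  if (e < s) return(0)
  ia <- pa$contig_start + (s:e) - pa$gene_start
  ib <- pb$contig_start + (s:e) - pb$gene_start
  sum(seq_a[ia] == seq_b[ib]) / shorter
}

.cluster_contigs <- function(truth, red) {
  keys <- red$placements$family_key[match(names(red$contigs),
                                          red$placements$contig_id)]
  contigs <- list()
  placements <- list()
  provenance <- list()
  cid_all <- names(red$contigs)
  for (k in unique(keys)) {
    ids <- cid_all[keys == k]
    lens <- vapply(red$contigs[ids], length, 1L)
    ids <- ids[order(-lens, ids)]
    unclustered <- ids
    while (length(unclustered)) {
      rep_id <- unclustered[1L]
      unclustered <- unclustered[-1L]
      pa <- red$placements[red$placements$contig_id == rep_id, ]
      members <- rep_id
      keep <- logical(length(unclustered))
      for (j in seq_along(unclustered)) {
        pb <- red$placements[red$placements$contig_id == unclustered[j], ]
        idy <- .pair_identity(pa, pb, red$contigs[[rep_id]],
                              red$contigs[[unclustered[j]]])
        if (idy >= truth$config$cluster_identity)
          members <- c(members, unclustered[j])
        else keep[j] <- TRUE
      }
      unclustered <- unclustered[keep]
      contigs[[rep_id]] <- red$contigs[[rep_id]]
      placements[[rep_id]] <- pa
      pv <- red$provenance[red$provenance$contig_id %in% members, ]
      pv$contig_id <- rep_id
      provenance[[rep_id]] <- pv
    }
  }
  list(contigs = contigs,
       placements = do.call(rbind, c(placements, list(make.row.names = FALSE))),
       provenance = do.call(rbind, c(provenance, list(make.row.names = FALSE))))
}

.supertranscripts <- function(truth, red, iso_len_min, iso_count_min) {
  contigs <- list()
  placements <- list()
  provenance <- list()
  L <- truth$config$gene_length
  for (g in truth$genes$gene_id) {
    iso <- truth$isoforms[truth$isoforms$gene_id == g, , drop = FALSE]
    iso$length <- iso$end - iso$start + 1L
    iso$total_count <- rowSums(truth$counts[iso$isoform_id, , drop = FALSE])
    keep <- isoform_prefilter(iso, len_min = iso_len_min,
                              count_min = iso_count_min)
    iso <- iso[iso$isoform_id %in% keep, , drop = FALSE]

    prov <- red$provenance[red$provenance$gene_id == g &
                             red$provenance$isoform_id %in% iso$isoform_id, ]
    ids <- unique(prov$contig_id)
    lens <- vapply(red$contigs[ids], length, 1L)
    ids <- ids[order(-lens, ids)]

    # growing body over gene coordinates + appended mosaic blocks
    body_seq <- rep(NA_integer_, L)
    covered <- logical(L)
    extra <- list()
    for (id in ids) {
      p <- red$placements[red$placements$contig_id == id, ]
      rng <- p$gene_start:p$gene_end
      sq <- red$contigs[[id]]
      ov <- covered[rng]
      idy <- if (any(ov)) mean(sq[ov] == body_seq[rng[ov]]) else 1
      if (idy >= truth$config$st_merge_identity) {
        new <- rng[!ov]
        body_seq[new] <- sq[!ov]
        covered[new] <- TRUE
      } else {
        extra[[length(extra) + 1L]] <- list(start = p$gene_start,
                                            end = p$gene_end, seq = sq)
      }
    }
    cid <- sprintf("%s_ST", g)
    fk <- family_key(truth, g)
    cov_pos <- which(covered)
    # runs of consecutive covered gene positions -> contig blocks
    brk <- c(0L, which(diff(cov_pos) != 1L), length(cov_pos))
    pl <- list()
    sq_out <- integer(0)
    for (b in seq_len(length(brk) - 1L)) {
      run <- cov_pos[(brk[b] + 1L):brk[b + 1L]]
      pl[[b]] <- data.frame(contig_id = cid, gene_id = g, family_key = fk,
                            gene_start = run[1L], gene_end = run[length(run)],
                            contig_start = length(sq_out) + 1L)
      sq_out <- c(sq_out, body_seq[run])
    }
    for (ex in extra) {
      pl[[length(pl) + 1L]] <- data.frame(
        contig_id = cid, gene_id = g, family_key = fk,
        gene_start = ex$start, gene_end = ex$end,
        contig_start = length(sq_out) + 1L)
      sq_out <- c(sq_out, ex$seq)
    }
    contigs[[cid]] <- sq_out
    placements[[cid]] <- do.call(rbind, pl)
    prov$contig_id <- cid
    provenance[[cid]] <- unique(prov)
  }
  list(contigs = contigs,
       placements = do.call(rbind, c(placements, list(make.row.names = FALSE))),
       provenance = do.call(rbind, c(provenance, list(make.row.names = FALSE))))
}

#' @export
print.psc_reference <- function(x, ...) {
  cat(sprintf("Reference transcriptome (psc_reference), strategy '%s'\n",
              x$strategy))
  cat(sprintf("  %d contigs, %d total bp, %d collapsed (>= 2 source genes)\n",
              nrow(x$index), sum(x$index$length), sum(x$index$collapsed)))
  invisible(x)
}

#' Write reference contigs to FASTA
#'
#' @param ref a `psc_reference`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path) {
  stopifnot(inherits(ref, "psc_reference"))
  ss <- Biostrings::DNAStringSet(vapply(ref$contigs, seq_to_string, ""))
  names(ss) <- names(ref$contigs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write truth tables (contig provenance and collapse flags) as TSV
#'
#' Emits two TSV files: `<prefix>_contigs.tsv` (per-contig index with the
#' truth collapse flag) and `<prefix>_provenance.tsv` (contig, source
#' gene, haplotype, isoform).
#'
#' @param ref a `psc_reference`.
#' @param prefix output path prefix.
#' @return character vector of the two paths, invisibly.
#' @export
write_truth_tables <- function(ref, prefix) {
  stopifnot(inherits(ref, "psc_reference"))
  p1 <- paste0(prefix, "_contigs.tsv")
  p2 <- paste0(prefix, "_provenance.tsv")
  write.table(ref$index, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ref$provenance, p2, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(p1, p2))
}
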