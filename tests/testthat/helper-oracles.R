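# Independent oracles and hand-built fixtures shared across tests.

BASES4 <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(BASES4, n, replace = TRUE), collapse = "")

# average pairwise difference over all allele pairs -- the brute-force
# counterpart of the unbiased per-site diversity estimator
pi_pairwise_oracle <- function(counts) {
  alleles <- rep(seq_along(counts), counts)
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  d <- outer(alleles, alleles, "!=")
  sum(d[upper.tri(d)]) / choose(n, 2)
}

# rule-based caller + full genotype-likelihood enumeration, written
# independently of the package implementation
caller_oracle <- function(cnt, e = 1e-4, min_count = 2, min_frac = 0.2) {
  depth <- sum(cnt)
  ret <- which(cnt >= min_count & cnt >= min_frac * depth & cnt > 0)
  if (depth == 0 || length(ret) == 0 || length(ret) > 2)
    return(list(a1 = 0L, a2 = 0L, qual = 0))
  a1 <- min(ret); a2 <- max(ret)
  ll <- numeric(0); lab <- character(0)
  for (i in 1:4) for (j in i:4) {
    pr <- 0.5 * ifelse(1:4 == i, 1 - e, e / 3) +
          0.5 * ifelse(1:4 == j, 1 - e, e / 3)
    ll <- c(ll, sum(cnt * log(pr)))
    lab <- c(lab, paste(i, j))
  }
  called <- match(paste(a1, a2), lab)
  list(a1 = a1, a2 = a2,
       qual = max(0, 10 / log(10) * (ll[called] - max(ll[-called]))))
}

# Smith-Waterman oracle via Biostrings (blastn-style scoring)
sw_oracle <- function(q, s) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(q, s, type = "local",
                                substitutionMatrix = mat,
                                gapOpening = 5, gapExtension = 2)
}

# hand-built truth set: monomorphic pools unless pool entries are
# overridden; one full-length isoform per gene unless given
manual_truth <- function(anc, config, mat = NULL, pat = NULL,
                         me_index = NULL, pools = NULL, family_id = NULL,
                         families = NULL, isoforms = NULL, counts = NULL) {
  gene_ids <- names(anc)
  n_m <- config$n_mothers
  pl <- lapply(anc, function(a)
    list(anc = a, pos = integer(), derived = integer(), carriers = list()))
  if (!is.null(pools))
    for (g in names(pools))
      for (nm in names(pools[[g]])) pl[[g]][[nm]] <- pools[[g]][[nm]]
  if (is.null(mat)) mat <- matrix(1L, n_m, 2L)
  if (is.null(pat)) pat <- rep(1L, n_m)
  ped <- lapply(gene_ids, function(g) list(mat = mat, pat = pat))
  names(ped) <- gene_ids
  if (is.null(isoforms))
    isoforms <- data.frame(gene_id = gene_ids,
                           isoform_id = paste0(gene_ids, "_i1"),
                           start = 1L,
                           end = vapply(anc, length, 1L),
                           expr_share = 1)
  samples <- data.frame(
    sample_id = c(sprintf("ME_m%d", seq_len(n_m)),
                  sprintf("EM_m%d", seq_len(n_m)),
                  sprintf("VEG_m%d", seq_len(n_m))),
    mother = rep(seq_len(n_m), 3L),
    group = rep(c("ME", "EM", "VEG"), each = n_m),
    ploidy = rep(c(1L, 2L, 2L), each = n_m))
  if (is.null(counts))
    counts <- matrix(1000L, nrow(isoforms), nrow(samples),
                     dimnames = list(isoforms$isoform_id, samples$sample_id))
  structure(list(
    config = config,
    genes = data.frame(gene_id = gene_ids,
                       length = vapply(anc, length, 1L),
                       family_id = family_id %||% rep(NA_integer_,
                                                      length(gene_ids)),
                       expr = 1),
    families = families %||% data.frame(family_id = integer(),
                                        gene1 = character(),
                                        gene2 = character(),
                                        realized_divergence = numeric()),
    pools = pl, ped = ped,
    me_index = me_index %||% rep(1L, n_m),
    isoforms = isoforms, samples = samples, counts = counts),
    class = "truth_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# site_evidence built directly from count arrays (4 x L x S)
manual_evidence <- function(arrs, groups, error_rate = 0.01) {
  S <- dim(arrs[[1]])[3]
  ids <- dimnames(arrs[[1]])[[3]] %||% sprintf("%s_m%d", groups, seq_len(S))
  arrs <- lapply(arrs, function(a) {
    dimnames(a) <- list(BASES4, NULL, ids)
    a
  })
  structure(list(
    contigs = arrs,
    samples = data.frame(sample_id = ids, mother = seq_len(S),
                         group = groups,
                         ploidy = ifelse(groups == "ME", 1L, 2L)),
    config = list(error_rate = error_rate)),
    class = "site_evidence")
}

# convenience: one-contig evidence from a sites x samples list of
# 4-vectors
evidence_from_sites <- function(site_counts, groups, error_rate = 0.01) {
  L <- length(site_counts)
  S <- length(site_counts[[1]])
  arr <- array(0L, dim = c(4L, L, length(groups)))
  for (i in seq_len(L))
    for (s in seq_along(groups))
      arr[, i, s] <- site_counts[[i]][[s]]
  manual_evidence(list(c1 = arr), groups, error_rate = error_rate)
}

# boundary fixture for the published site-filter chain:
# 6 diploid samples, 5 sites:
#  1: clean monomorphic, but sample 1 has depth 8 (observation voided)
#  2: missing in 4/6 samples (site dropped)
#  3: tri-allelic across samples at high quality (dropped if biallelic)
#  4: weak het at error 0.05 -> site quality below 20 (dropped)
#  5: clean balanced biallelic SNP (kept, polymorphic)
filter_fixture <- function() {
  mk <- function(a = 0, c = 0, g = 0, t = 0) as.integer(c(a, c, g, t))
  sites <- list(
    list(mk(a = 8), mk(a = 30), mk(a = 30), mk(a = 30), mk(a = 30), mk(a = 30)),
    list(mk(a = 30), mk(a = 30), mk(), mk(), mk(), mk()),
    list(mk(a = 15, c = 15), mk(a = 15, g = 15), mk(a = 30), mk(a = 30),
         mk(a = 30), mk(a = 30)),
    list(mk(a = 16, c = 4), mk(a = 30), mk(a = 30), mk(a = 30), mk(a = 30),
         mk(a = 30)),
    list(mk(a = 15, c = 15), mk(a = 30), mk(c = 30), mk(a = 15, c = 15),
         mk(a = 30), mk(c = 30)))
  evidence_from_sites(sites, rep("EM", 6), error_rate = 0.05)
}
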