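#' Simulate a population truth set under the seed-family design
#'
#' Generates, for each gene, a pool of population haplotypes whose
#' segregating sites carry derived-allele frequencies drawn from the
#' neutral site frequency spectrum (P(i) proportional to 1/i), with the
#' per-site segregation probability calibrated so that the pool's expected
#' pairwise diversity per bp equals `theta`. A fraction of genes form
#' two-member paralog families whose second member is a copy of the first
#' mutated at the configured per-bp divergence. Mothers are then sampled
#' from the pool: each contributes a haploid megagametophyte (ME, one of
#' the two maternal haplotypes), a diploid embryo (EM, the megagametophyte
#' haplotype plus a paternal haplotype from the pool -- panmixia with
#' unknown pollinating fathers) and a pooled diploid vegetative genotype
#' (VEG, the full maternal pair). Within a gene, haplotypes are assigned
#' to mothers and fathers without replacement whenever the pool is large
#' enough: the individuals are unrelated, so the sampled chromosomes
#' share no identity by descent and individual-based diversity estimates
#' are unbiased at `theta`. By construction the ME allele is contained
#' in the EM genotype at every site.
#'
#' Calibration: at a segregating site with derived-allele count i out of
#' n pooled haplotypes, the average pairwise difference is
#' 2 i (n - i) / (n (n - 1)); under the neutral SFS its expectation is
#' 1 / H(n-1) (the reciprocal harmonic number), so a per-site segregation
#' probability of `theta * H(n-1)` makes the pool's expected pairwise
#' diversity per bp exactly `theta`.
#'
#' @param config a [sim_config()].
#' @return An object of class `truth_set`: gene table, paralog family
#'   table, per-gene haplotype pools (ancestral sequence plus segregating
#'   sites and carrier sets), pedigree (maternal pairs, paternal
#'   haplotypes, megagametophyte index), isoform table, sample sheet and
#'   an isoform x sample effective-count matrix.
#' @examples
#' truth <- simulate_population(sim_config(n_genes = 5, seed = 42))
#' truth$genes
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "population"), {
    n_genes <- config$n_genes
    L <- config$gene_length
    n_pool <- config$n_pool_haplotypes
    gene_ids <- sprintf("g%04d", seq_len(n_genes))

    # ancestral sequences
    anc <- lapply(seq_len(n_genes), function(i)
      sample.int(4L, L, replace = TRUE))

    # paralog families: pair up genes, member 2 = mutated copy of member 1
    n_fam <- floor(round(config$paralog_fraction * n_genes) / 2)
    family_id <- rep(NA_integer_, n_genes)
    families <- data.frame(family_id = integer(), gene1 = character(),
                           gene2 = character(),
                           realized_divergence = numeric())
    if (n_fam > 0) {
      members <- sample.int(n_genes, 2L * n_fam)
      g1 <- members[seq_len(n_fam)]
      g2 <- members[n_fam + seq_len(n_fam)]
      realized <- numeric(n_fam)
      for (f in seq_len(n_fam)) {
        a <- anc[[g1[f]]]
        hit <- which(stats::runif(L) < config$paralog_divergence)
        b <- a
        if (length(hit))
          b[hit] <- 1L + (a[hit] - 1L + sample.int(3L, length(hit),
                                                   replace = TRUE)) %% 4L
        anc[[g2[f]]] <- b
        realized[f] <- length(hit) / L
        family_id[c(g1[f], g2[f])] <- f
      }
      families <- data.frame(family_id = seq_len(n_fam),
                             gene1 = gene_ids[g1], gene2 = gene_ids[g2],
                             realized_divergence = realized)
    }

    # segregating sites: neutral SFS, calibrated segregation probability
    harm <- sum(1 / seq_len(n_pool - 1L))
    p_seg <- config$theta * harm
    sfs_prob <- 1 / seq_len(n_pool - 1L)
    pools <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      pos <- which(stats::runif(L) < p_seg)
      k <- length(pos)
      der_count <- if (k) sample.int(n_pool - 1L, k, replace = TRUE,
                                     prob = sfs_prob) else integer()
      der_base <- if (k) 1L + (anc[[g]][pos] - 1L +
                               sample.int(3L, k, replace = TRUE)) %% 4L
                  else integer()
      carriers <- lapply(der_count, function(i) sample.int(n_pool, i))
      pools[[g]] <- list(anc = anc[[g]], pos = pos, derived = der_base,
                         carriers = carriers)
    }

    # pedigree: maternal pairs and paternal haplotype per gene (panmixia),
    # single megagametophyte meiotic product index per individual
    n_m <- config$n_mothers
    me_index <- sample.int(2L, n_m, replace = TRUE)
    # haplotypes are assigned without replacement within a gene when the
    # pool allows it: the mothers are unrelated and the pollinating
    # fathers unknown, so no two sampled chromosomes are identical by
    # descent (this also keeps individual-based diversity estimates
    # unbiased at theta)
    need <- 3L * n_m
    ped <- lapply(seq_len(n_genes), function(g) {
      draw <- sample.int(n_pool, need, replace = n_pool < need)
      list(mat = matrix(draw[seq_len(2L * n_m)], n_m, 2L),
           pat = draw[2L * n_m + seq_len(n_m)])
    })

    # expression and isoforms (isoform 1 is always the full-length gene;
    # extra isoforms are truncations, enough to exercise SuperTranscript
    # merging without a splicing model)
    expr <- stats::rlnorm(n_genes, config$expression_logmean,
                          config$expression_logsd)
    iso_rows <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      n_iso <- sample.int(length(config$isoforms_per_gene), 1L,
                          prob = config$isoforms_per_gene)
      start <- 1L
      end <- L
      if (n_iso > 1L) {
        len <- pmax(50L, as.integer(round(stats::runif(n_iso - 1L, 0.15, 0.8) * L)))
        s <- vapply(len, function(l) sample.int(L - l + 1L, 1L), 1L)
        start <- c(1L, s)
        end <- c(L, s + len - 1L)
      }
      share <- c(1, stats::runif(n_iso - 1L, 0.05, 0.5))
      share <- share / sum(share)
      iso_rows[[g]] <- data.frame(
        gene_id = gene_ids[g],
        isoform_id = sprintf("%s_i%d", gene_ids[g], seq_len(n_iso)),
        start = start, end = end, expr_share = share)
    }
    isoforms <- do.call(rbind, iso_rows)
    rownames(isoforms) <- NULL

    samples <- data.frame(
      sample_id = c(sprintf("ME_m%d", seq_len(n_m)),
                    sprintf("EM_m%d", seq_len(n_m)),
                    sprintf("VEG_m%d", seq_len(n_m))),
      mother = rep(seq_len(n_m), 3L),
      group = rep(c("ME", "EM", "VEG"), each = n_m),
      ploidy = rep(c(1L, 2L, 2L), each = n_m))

    # isoform x sample effective counts (consumed by the expression
    # statistics and the isoform pre-filter)
    iso_len <- isoforms$end - isoforms$start + 1L
    lambda <- expr[match(isoforms$gene_id, gene_ids)] * isoforms$expr_share *
      config$mean_depth * iso_len / config$read_len
    counts <- matrix(stats::rpois(length(lambda) * nrow(samples),
                                  rep(lambda, nrow(samples))),
                     nrow = length(lambda), ncol = nrow(samples),
                     dimnames = list(isoforms$isoform_id, samples$sample_id))

    truth <- list(
      config = config,
      genes = data.frame(gene_id = gene_ids, length = L,
                         family_id = family_id, expr = expr),
      families = families,
      pools = stats::setNames(pools, gene_ids),
      ped = stats::setNames(ped, gene_ids),
      me_index = me_index,
      isoforms = isoforms,
      samples = samples,
      counts = counts)
    class(truth) <- "truth_set"
    truth
  })
}

#' @export
print.truth_set <- function(x, ...) {
  cat("Simulated truth set (truth_set)\n")
  cat(sprintf("  %d genes x %d bp, %d paralog families, %d mothers\n",
              nrow(x$genes), x$config$gene_length, nrow(x$families),
              x$config$n_mothers))
  n_seg <- sum(vapply(x$pools, function(p) length(p$pos), 1L))
  cat(sprintf("  %d segregating sites in pools of %d haplotypes (theta = %.4g)\n",
              n_seg, x$config$n_pool_haplotypes, x$config$theta))
  cat(sprintf("  %d samples (%s)\n", nrow(x$samples),
              paste(unique(x$samples$group), collapse = "/")))
  invisible(x)
}

#' Materialize haplotype sequences from a truth set
#'
#' `haplotype_seq` returns one haplotype of a gene as an integer vector
#' over 1:4 = A,C,G,T; `gene_pool_matrix` returns several as columns of a
#' matrix.
#'
#' @param truth a `truth_set`.
#' @param gene_id gene identifier.
#' @param hap index of the haplotype in the gene's pool.
#' @return integer vector (or matrix) of bases coded 1:4.
#' @export
haplotype_seq <- function(truth, gene_id, hap) {
  gene_pool_matrix(truth, gene_id, hap)[, 1L]
}

#' @rdname haplotype_seq
#' @param haps indices of pool haplotypes (default: the whole pool).
#' @export
gene_pool_matrix <- function(truth, gene_id,
                             haps = seq_len(truth$config$n_pool_haplotypes)) {
  p <- truth$pools[[gene_id]]
  if (is.null(p)) stop("unknown gene: ", gene_id)
  m <- matrix(p$anc, nrow = length(p$anc), ncol = length(haps))
  for (s in seq_along(p$pos)) {
    hit <- haps %in% p$carriers[[s]]
    if (any(hit)) m[p$pos[s], hit] <- p$derived[s]
  }
  colnames(m) <- sprintf("h%02d", haps)
  m
}

#' True genotypes of every sample at one gene
#'
#' Returns the pool-haplotype indices each sample carries for `gene_id`:
#' one for haploid megagametophytes, two for diploid embryo and
#' vegetative samples. The megagametophyte haplotype is always an element
#' of the maternal pair and of the embryo genotype.
#'
#' @inheritParams haplotype_seq
#' @return named list (by sample id) of integer vectors of pool indices.
#' @export
sample_genotypes <- function(truth, gene_id) {
  ped <- truth$ped[[gene_id]]
  if (is.null(ped)) stop("unknown gene: ", gene_id)
  n_m <- truth$config$n_mothers
  me <- ped$mat[cbind(seq_len(n_m), truth$me_index)]
  out <- c(lapply(seq_len(n_m), function(m) me[m]),
           lapply(seq_len(n_m), function(m) c(me[m], ped$pat[m])),
           lapply(seq_len(n_m), function(m) ped$mat[m, ]))
  stats::setNames(out, truth$samples$sample_id)
}

#' Pool pairwise diversity of a truth set
#'
#' Average pairwise Hamming distance per bp over all haplotype pairs of
#' every gene pool -- the quantity the simulator calibrates to `theta`.
#' Computed from allele counts per segregating site (algebraically equal
#' to the all-pairs Hamming average).
#'
#' @param truth a `truth_set`.
#' @return mean pairwise diversity per bp across all genes.
#' @export
pool_diversity <- function(truth) {
  n <- truth$config$n_pool_haplotypes
  L <- truth$config$gene_length
  per_gene <- vapply(truth$pools, function(p) {
    if (!length(p$pos)) return(0)
    i <- lengths(p$carriers)
    sum(2 * i * (n - i) / (n * (n - 1))) / L
  }, numeric(1))
  mean(per_gene)
}
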