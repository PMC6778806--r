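# Window-level mapping emulation. Reads are emulated as non-overlapping
# read_len windows tiled along each source haplotype (matching 2 x 150 bp
# sequencing). A window is mapped iff its mismatch fraction against a
# contig placement is at most map_max_mismatch_frac and the best
# placement is unique; ties are discarded under unique-only mapping,
# mirroring a multimap limit of one locus. Mapped windows contribute
# Poisson-distributed read depth with per-base substitution errors.

#' Simulate per-site read evidence for a reference
#'
#' For every sample and every haplotype it carries, decides window
#' mappability against all candidate contig placements (contigs sharing
#' the gene's paralog-family coordinate space; unrelated genes cannot
#' pass the mismatch ceiling) and accumulates per-base counts.
#'
#' @param truth the `truth_set` the reference was built from.
#' @param reference a `psc_reference` built from `truth`.
#' @param config simulation parameters (defaults to `truth$config`).
#' @param groups tissue groups to simulate (`"ME"`, `"EM"`, `"VEG"`).
#' @param seed RNG seed (defaults to the `evidence` substream of the
#'   master seed).
#' @return An object of class `site_evidence`: per contig an integer
#'   array of base counts with dimensions (base A/C/G/T, position,
#'   sample), plus the sample sheet.
#' @examples
#' truth <- simulate_population(sim_config(n_genes = 3, seed = 11))
#' ref <- build_reference(truth, "clustered")
#' ev <- simulate_site_evidence(truth, ref, groups = "ME")
#' dim(ev$contigs[[1]])
#' @export
simulate_site_evidence <- function(truth, reference, config = truth$config,
                                   groups = c("ME", "EM", "VEG"),
                                   seed = derive_seed(config$seed, "evidence")) {
  stopifnot(inherits(truth, "truth_set"), inherits(reference, "psc_reference"))
  .check_reference_truth(truth, reference)
  groups <- match.arg(groups, c("ME", "EM", "VEG"), several.ok = TRUE)
  samples <- truth$samples[truth$samples$group %in% groups, , drop = FALSE]
  rownames(samples) <- NULL
  rl <- config$read_len
  max_mm <- floor(config$map_max_mismatch_frac * rl + 1e-9)
  L <- config$gene_length
  win_start <- seq.int(1L, L - rl + 1L, by = rl)
  n_win <- length(win_start)
  mean_expr <- exp(config$expression_logmean + config$expression_logsd^2 / 2)

  arrs <- lapply(reference$contigs, function(s)
    array(0L, dim = c(4L, length(s), nrow(samples)),
          dimnames = list(BASES, NULL, samples$sample_id)))

  with_seed(seed, {
    pl_all <- reference$placements
    for (g in truth$genes$gene_id) {
      fk <- family_key(truth, g)
      pl <- pl_all[pl_all$family_key == fk, , drop = FALSE]
      if (!nrow(pl)) next
      geno <- sample_genotypes(truth, g)[samples$sample_id]
      hap_set <- sort(unique(unlist(geno)))
      hm <- gene_pool_matrix(truth, g, hap_set)

      # mismatch count per (window, placement, haplotype); NA = window
      # not fully inside the placement
      mm <- array(NA_integer_, dim = c(n_win, nrow(pl), length(hap_set)))
      for (p in seq_len(nrow(pl))) {
        gs <- pl$gene_start[p]; ge <- pl$gene_end[p]
        ok <- win_start >= gs & (win_start + rl - 1L) <= ge
        if (!any(ok)) next
        rng <- gs:ge
        cpos <- pl$contig_start[p] + rng - gs
        cseq <- reference$contigs[[pl$contig_id[p]]][cpos]
        neq <- hm[rng, , drop = FALSE] != cseq
        cs <- rbind(0L, apply(neq, 2L, cumsum))
        off <- win_start[ok] - gs   # 0-based offset into rng
        mm[ok, p, ] <- cs[off + rl + 1L, , drop = FALSE] - cs[off + 1L, , drop = FALSE]
      }

      # best unique placement per (window, haplotype)
      best <- array(NA_integer_, dim = c(n_win, length(hap_set)))
      for (h in seq_along(hap_set)) {
        m <- mm[, , h, drop = FALSE]
        dim(m) <- c(n_win, nrow(pl))
        m[is.na(m) | m > max_mm] <- NA_integer_
        for (w in seq_len(n_win)) {
          row <- m[w, ]
          if (all(is.na(row))) next
          mn <- min(row, na.rm = TRUE)
          hits <- which(!is.na(row) & row == mn)
          if (length(hits) == 1L) best[w, h] <- hits
          else if (!config$map_unique_only) best[w, h] <- sample(hits, 1L)
        }
      }

      expr_rel <- truth$genes$expr[truth$genes$gene_id == g] / mean_expr
      for (si in seq_len(nrow(samples))) {
        lam <- config$mean_depth * expr_rel / samples$ploidy[si]
        for (hap in geno[[si]]) {            # one slot per carried copy
          h <- match(hap, hap_set)
          mapped <- which(!is.na(best[, h]))
          if (!length(mapped)) next
          D <- stats::rpois(length(mapped), lam)
          mapped <- mapped[D > 0L]
          D <- D[D > 0L]
          for (j in seq_along(mapped)) {
            w <- mapped[j]
            p <- best[w, h]
            rng <- win_start[w]:(win_start[w] + rl - 1L)
            cpos <- pl$contig_start[p] + rng - pl$gene_start[p]
            bases <- hm[rng, h]
            d <- D[j]
            cid <- pl$contig_id[p]
            if (config$error_rate > 0) {
              err <- stats::rbinom(rl, d, config$error_rate)
              idx <- cbind(bases, cpos, si)
              arrs[[cid]][idx] <- arrs[[cid]][idx] + (d - err)
              for (q in which(err > 0L)) {
                eb <- sample(setdiff(1:4, bases[q]), err[q], replace = TRUE)
                for (b in eb)
                  arrs[[cid]][b, cpos[q], si] <- arrs[[cid]][b, cpos[q], si] + 1L
              }
            } else {
              idx <- cbind(bases, cpos, si)
              arrs[[cid]][idx] <- arrs[[cid]][idx] + d
            }
          }
        }
      }
    }
  })
  structure(list(contigs = arrs, samples = samples, config = config),
            class = "site_evidence")
}

.check_reference_truth <- function(truth, reference) {
  genes <- unique(reference$placements$gene_id)
  if (!all(genes %in% truth$genes$gene_id))
    stop("reference/truth mismatch: reference names genes absent from the truth set")
  if (any(reference$placements$gene_end > truth$config$gene_length))
    stop("reference/truth mismatch: placement exceeds gene length")
  # spot-check: a redundant/clustered contig must equal its provenance
  # haplotype over its placement interval
  idx <- reference$index
  check <- head(idx$contig_id[!idx$collapsed], 3L)
  for (cid in check) {
    pl <- reference$placements[reference$placements$contig_id == cid, ][1L, ]
    pv <- reference$provenance[reference$provenance$contig_id == cid, ]
    pv <- pv[pv$gene_id == pl$gene_id, ]
    if (!nrow(pv)) next
    hs <- haplotype_seq(truth, pl$gene_id, pv$hap[1L])
    rng <- pl$gene_start:pl$gene_end
    cseq <- reference$contigs[[cid]][pl$contig_start + rng - pl$gene_start]
    if (reference$strategy %in% c("redundant", "clustered") &&
        !identical(as.integer(hs[rng]), as.integer(cseq)))
      stop("reference/truth mismatch: contig sequence does not match its provenance haplotype")
  }
  invisible(TRUE)
}

#' @export
print.site_evidence <- function(x, ...) {
  cat("Site evidence (site_evidence)\n")
  cat(sprintf("  %d contigs x %d samples (%s)\n", length(x$contigs),
              nrow(x$samples), paste(unique(x$samples$group), collapse = "/")))
  dp <- vapply(x$contigs, function(a) mean(colSums(a)), numeric(1))
  cat(sprintf("  mean per-sample depth per bp: %.2f\n", mean(dp)))
  invisible(x)
}

#' Simulate genotype evidence for independent sites under HWE
#'
#' Site-level generator used for estimator calibration: each site is
#' biallelic with a derived-allele frequency drawn from the neutral site
#' frequency spectrum of a pool of `sfs_pool_n` haplotypes (P(i)
#' proportional to 1/i, frequency i/n); diploid genotypes are drawn under
#' Hardy-Weinberg equilibrium; read counts at uniform depth split the two
#' alleles of a heterozygote Binomial(depth, 1/2), with optional per-base
#' sequencing error.
#'
#' @param n_sites number of independent biallelic sites.
#' @param n_diploids number of diploid individuals.
#' @param depth uniform per-site read depth.
#' @param error_rate per-base error probability.
#' @param sfs_pool_n pool size defining the SFS frequency grid.
#' @param seed RNG seed.
#' @param chunk_size sites per pseudo-contig (memory layout only).
#' @return a `site_evidence` object whose samples form one diploid
#'   `"VEG"` group.
#' @export
simulate_hwe_sites <- function(n_sites, n_diploids = 50, depth = 30,
                               error_rate = 0, sfs_pool_n = 40, seed = 1L,
                               chunk_size = 20000L) {
  stopifnot(n_sites >= 1, n_diploids >= 1, depth >= 1)
  samples <- data.frame(
    sample_id = sprintf("VEG_m%d", seq_len(n_diploids)),
    mother = seq_len(n_diploids), group = "VEG", ploidy = 2L)
  n_chunks <- ceiling(n_sites / chunk_size)
  arrs <- vector("list", n_chunks)
  with_seed(seed, {
    for (ch in seq_len(n_chunks)) {
      n <- min(chunk_size, n_sites - (ch - 1L) * chunk_size)
      i <- sample.int(sfs_pool_n - 1L, n, replace = TRUE,
                      prob = 1 / seq_len(sfs_pool_n - 1L))
      p <- i / sfs_pool_n
      nder <- matrix(stats::rbinom(n * n_diploids, 2L, rep(p, n_diploids)),
                     nrow = n, ncol = n_diploids)
      c2 <- matrix(0L, n, n_diploids)
      het <- nder == 1L
      c2[het] <- stats::rbinom(sum(het), depth, 0.5)
      c2[nder == 2L] <- depth
      c1 <- depth - c2
      if (error_rate > 0) {
        e1 <- matrix(stats::rbinom(n * n_diploids, as.vector(c1), error_rate),
                     n, n_diploids)
        e2 <- matrix(stats::rbinom(n * n_diploids, as.vector(c2), error_rate),
                     n, n_diploids)
        c1 <- c1 - e1
        c2 <- c2 - e2
      } else {
        e1 <- e2 <- matrix(0L, n, n_diploids)
      }
      arr <- array(0L, dim = c(4L, n, n_diploids),
                   dimnames = list(BASES, NULL, samples$sample_id))
      arr[1L, , ] <- c1
      arr[2L, , ] <- c2
      tot_err <- e1 + e2
      for (k in which(tot_err > 0L)) {
        s <- ((k - 1L) %/% n) + 1L
        st <- ((k - 1L) %% n) + 1L
        # errors land uniformly on the three bases other than the source;
        # sources 1 and 2 share targets 3 and 4
        for (r in seq_len(e1[st, s])) {
          b <- sample(c(2L, 3L, 4L), 1L)
          arr[b, st, s] <- arr[b, st, s] + 1L
        }
        for (r in seq_len(e2[st, s])) {
          b <- sample(c(1L, 3L, 4L), 1L)
          arr[b, st, s] <- arr[b, st, s] + 1L
        }
      }
      arrs[[ch]] <- arr
    }
  })
  names(arrs) <- sprintf("hwe_chunk%03d", seq_len(n_chunks))
  structure(list(contigs = arrs, samples = samples,
                 config = list(error_rate = error_rate)),
            class = "site_evidence")
}
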