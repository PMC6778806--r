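# Brute-force detection oracle for the collapse dose-response: given a
# truth set with monomorphic pools (no population polymorphism), zero
# sequencing error and uniform expression, window mappability is
# deterministic from the sequences, and the only randomness is the
# Poisson window depth. Per-site expectations of heterozygous and
# callable observations are then exact enumerations over the caller and
# filter rules, independent of the package implementation.

dose_oracle <- function(truth, ref) {
  cfg <- truth$config
  rl <- cfg$read_len
  max_mm <- floor(cfg$map_max_mismatch_frac * rl + 1e-9)
  lam <- cfg$mean_depth                      # haploid ME share
  n_m <- cfg$n_mothers
  L <- cfg$gene_length

  xs <- 0:200
  px <- dpois(xs, lam)
  X <- matrix(xs, length(xs), length(xs))
  Y <- t(X)
  PXY <- outer(px, px)
  S <- X + Y
  nv2 <- S >= 10
  het2 <- nv2 & X >= 2 & Y >= 2 & X >= 0.2 * S & Y >= 0.2 * S
  cls <- list(
    A  = c(nv = 1 - ppois(9, lam), het = 0),
    AB = c(nv = 1 - ppois(9, 2 * lam), het = 0),
    D  = c(nv = sum(PXY[nv2]), het = sum(PXY[het2])))

  per_contig <- list()
  for (cid in ref$index$contig_id[ref$index$collapsed]) {
    genes <- unique(ref$provenance$gene_id[ref$provenance$contig_id == cid])
    repg <- ref$placements$gene_id[ref$placements$contig_id == cid][1L]
    otherg <- setdiff(genes, repg)[1L]
    dpos <- which(truth$pools[[repg]]$anc != truth$pools[[otherg]]$anc)
    wins <- seq.int(1L, L - rl + 1L, by = rl)
    eh <- eo <- 0
    for (w in wins) {
      nd <- sum(dpos >= w & dpos <= w + rl - 1L)
      counts <- if (nd <= max_mm) c(D = nd, AB = rl - nd) else c(A = rl)
      for (cl in names(counts)) {
        pv <- 1 - cls[[cl]][["nv"]]
        pkeep <- pbinom(3, n_m - 1, pv)     # missing fraction <= 0.5
        eo <- eo + counts[[cl]] * n_m * cls[[cl]][["nv"]] * pkeep
        eh <- eh + counts[[cl]] * n_m * cls[[cl]][["het"]] * pkeep
      }
    }
    per_contig[[cid]] <- c(Ehet = eh, Eobs = eo)
  }
  tot <- Reduce(`+`, per_contig)
  list(ratio = tot[["Ehet"]] / tot[["Eobs"]], per_contig = per_contig)
}

# cluster-robust standard error of the aggregate ratio sum(h)/sum(o)
# with contigs as clusters
ratio_se <- function(h, o) {
  r <- sum(h) / sum(o)
  sqrt(sum((h - r * o)^2)) / sum(o)
}
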