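#' Simulation configuration
#'
#' Bundles every knob of the synthetic study: population parameters
#' (per-bp diversity `theta`, pool size), the paralog-family layout, the
#' seed-family sampling design (mothers contributing one haploid
#' megagametophyte, one diploid embryo and one pooled diploid vegetative
#' genotype each), sequencing depth and error, and the mapping /
#' clustering rules the reference-building and read-mapping emulations
#' apply.
#'
#' Defaults encode the study conditions: `theta = 0.0042` per bp (the
#' rough genome-wide estimate for Scots pine used as the diversity
#' expectation), six unrelated mothers, 2 x 150 bp reads emulated as
#' 150 bp windows, unique-best mapping with a 0.025 mismatch-fraction
#' ceiling, and a 0.95 identity cut-off for redundancy clustering.
#'
#' @param n_genes number of simulated genes.
#' @param gene_length gene length in bp.
#' @param paralog_fraction fraction of genes that belong to a two-member
#'   paralog family (rounded to an even gene count).
#' @param paralog_divergence per-bp substitution probability between the
#'   two members of a family.
#' @param theta per-bp scaled mutation rate; the haplotype pool is
#'   calibrated so its expected pairwise diversity per bp equals `theta`.
#' @param n_mothers number of unrelated maternal individuals.
#' @param n_pool_haplotypes population haplotypes per gene.
#' @param isoforms_per_gene probability vector over isoform counts 1, 2,
#'   ... per gene.
#' @param expression_logmean,expression_logsd log-normal parameters of the
#'   per-gene relative expression level.
#' @param mean_depth expected reads per bp per sample at relative
#'   expression 1.
#' @param error_rate per-base sequencing error probability.
#' @param map_max_mismatch_frac maximum mismatch fraction for a read
#'   window to be considered mapped.
#' @param map_unique_only discard windows whose best placement is tied
#'   across loci.
#' @param read_len read (window) length in bp.
#' @param cluster_identity identity cut-off for redundancy clustering.
#' @param st_merge_identity minimum identity for an isoform to be merged
#'   (rather than appended as a new, mosaic-forming block) during
#'   SuperTranscript construction.
#' @param seed master seed; every stage derives its own substream from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_genes = 10, seed = 1)
#' cfg$theta
#' @export
sim_config <- function(n_genes = 200,
                       gene_length = 1500,
                       paralog_fraction = 0.2,
                       paralog_divergence = 0.02,
                       theta = 0.0042,
                       n_mothers = 6,
                       n_pool_haplotypes = 40,
                       isoforms_per_gene = c(0.91, 0.06, 0.03),
                       expression_logmean = 0,
                       expression_logsd = 1,
                       mean_depth = 30,
                       error_rate = 0.001,
                       map_max_mismatch_frac = 0.025,
                       map_unique_only = TRUE,
                       read_len = 150,
                       cluster_identity = 0.95,
                       st_merge_identity = 0.99,
                       seed = 1L) {
  stopifnot_scalar(n_genes, "n_genes", 1)
  stopifnot_scalar(gene_length, "gene_length", 1)
  stopifnot_scalar(paralog_fraction, "paralog_fraction", 0, 1)
  stopifnot_scalar(paralog_divergence, "paralog_divergence", 0, 1)
  stopifnot_scalar(theta, "theta", 0)
  stopifnot_scalar(n_mothers, "n_mothers", 1)
  stopifnot_scalar(n_pool_haplotypes, "n_pool_haplotypes", 2)
  stopifnot_scalar(expression_logmean, "expression_logmean")
  stopifnot_scalar(expression_logsd, "expression_logsd", 0)
  stopifnot_scalar(mean_depth, "mean_depth", 0)
  stopifnot_scalar(error_rate, "error_rate", 0, 1)
  stopifnot_scalar(map_max_mismatch_frac, "map_max_mismatch_frac", 0, 1)
  stopifnot_scalar(read_len, "read_len", 1)
  stopifnot_scalar(cluster_identity, "cluster_identity", 0, 1)
  stopifnot_scalar(st_merge_identity, "st_merge_identity", 0, 1)
  stopifnot_scalar(seed, "seed", -2^31, 2^31)
  if (!isTRUE(map_unique_only) && !isFALSE(map_unique_only))
    stop("'map_unique_only' must be TRUE or FALSE")
  if (gene_length < read_len)
    stop("'gene_length' must be >= 'read_len'")
  if (!is.numeric(isoforms_per_gene) || any(isoforms_per_gene < 0) ||
      sum(isoforms_per_gene) <= 0)
    stop("'isoforms_per_gene' must be non-negative probabilities")

  # Calibration feasibility: per-site segregation probability is
  # theta * H_{n-1} (see simulate_population); it must stay inside [0, 1].
  n <- as.integer(n_pool_haplotypes)
  p_seg <- theta * sum(1 / seq_len(n - 1L))
  if (p_seg > 1)
    stop(sprintf(
      "theta = %g is too large: required per-site segregation probability %.3f > 1 for a pool of %d haplotypes",
      theta, p_seg, n))

  cfg <- list(
    n_genes = as.integer(n_genes),
    gene_length = as.integer(gene_length),
    paralog_fraction = paralog_fraction,
    paralog_divergence = paralog_divergence,
    theta = theta,
    n_mothers = as.integer(n_mothers),
    n_pool_haplotypes = n,
    isoforms_per_gene = isoforms_per_gene / sum(isoforms_per_gene),
    expression_logmean = expression_logmean,
    expression_logsd = expression_logsd,
    mean_depth = mean_depth,
    error_rate = error_rate,
    map_max_mismatch_frac = map_max_mismatch_frac,
    map_unique_only = map_unique_only,
    read_len = as.integer(read_len),
    cluster_identity = cluster_identity,
    st_merge_identity = st_merge_identity,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration (sim_config)\n")
  cat(sprintf("  genes: %d x %d bp, paralog fraction %.2f (divergence %.3g)\n",
              x$n_genes, x$gene_length, x$paralog_fraction,
              x$paralog_divergence))
  cat(sprintf("  population: theta = %.4g/bp, pool of %d haplotypes, %d mothers\n",
              x$theta, x$n_pool_haplotypes, x$n_mothers))
  cat(sprintf("  sequencing: depth %.3g, error %.3g, %d bp windows\n",
              x$mean_depth, x$error_rate, x$read_len))
  cat(sprintf("  mapping: mismatch <= %.3g, unique-only %s; clustering identity %.2f\n",
              x$map_max_mismatch_frac, x$map_unique_only, x$cluster_identity))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Read or write a simulation configuration as JSON
#'
#' Round-trippable serialization of a [sim_config()] so a run can be
#' reproduced from its logged configuration.
#'
#' @param config a `sim_config` object.
#' @param path file path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns the reconstructed `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(sim_config, x)
}
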