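# Reference-building emulation: clustering identity rule, collapse
# determinism, SuperTranscript pre-filter and mosaic blocks.

two_allele_truth <- function(n_diverged, L = 1500, st_merge = 0.99,
                             cluster_id = 0.95) {
  cfg <- sim_config(n_genes = 1, gene_length = L, n_mothers = 1,
                    theta = 0, cluster_identity = cluster_id,
                    st_merge_identity = st_merge, seed = 1)
  anc <- list(g1 = sample.int(4L, L, replace = TRUE))
  pos <- seq(10L, by = 17L, length.out = n_diverged)
  der <- 1L + (anc$g1[pos] %% 4L)
  manual_truth(anc, cfg,
               mat = matrix(c(1L, 2L), 1L, 2L), pat = 1L,
               pools = list(g1 = list(pos = pos, derived = der,
                                      carriers = rep(list(2L), n_diverged))))
}

test_that("alleles within the identity cut-off collapse to one contig, with provenance", {
  set.seed(5)
  truth <- two_allele_truth(7)          # 0.47% divergence
  red <- build_reference(truth, "redundant")
  expect_equal(nrow(red$index), 2L)
  clu <- build_reference(truth, "clustered")
  expect_equal(nrow(clu$index), 1L)
  expect_setequal(clu$provenance$hap, c(1L, 2L))
  expect_false(clu$index$collapsed)     # same gene: redundancy, not PSC
})

test_that("paralogs collapse iff pairwise identity reaches the cut-off, monotonically", {
  for (d in c(0.02, 0.10)) {
    cfg <- sim_config(n_genes = 2, paralog_fraction = 1,
                      paralog_divergence = d, theta = 0, seed = 21)
    truth <- simulate_population(cfg)
    realized <- truth$families$realized_divergence[1]
    collapsed_at <- function(cut) {
      truth$config$cluster_identity <- cut
      ref <- build_reference(truth, "clustered")
      sum(ref$index$collapsed) == 1L
    }
    for (cut in c(0.85, 0.90, 0.95, 0.99))
      expect_identical(collapsed_at(cut), (1 - realized) >= cut,
                       label = sprintf("d=%g cut=%g", d, cut))
    # monotone: the set of cut-offs that collapse is downward closed
    dec <- vapply(c(0.85, 0.90, 0.95, 0.99), collapsed_at, TRUE)
    expect_true(all(diff(as.integer(dec)) <= 0))
  }
})

test_that("supertranscript pre-filter drops short/low-count isoforms with keep-longest fallback", {
  cfg <- sim_config(n_genes = 1, gene_length = 1500, n_mothers = 1,
                    theta = 0, seed = 1)
  iso <- data.frame(gene_id = "g1",
                    isoform_id = c("g1_i1", "g1_i2"),
                    start = c(1L, 300L), end = c(250L, 499L),
                    expr_share = c(0.5, 0.5))
  truth <- manual_truth(list(g1 = sample.int(4L, 1500, replace = TRUE)),
                        cfg, isoforms = iso,
                        counts = matrix(2L, 2, 3,
                                        dimnames = list(iso$isoform_id,
                                                        NULL)))
  # both isoforms are <= 300 bp; total counts 6 <= 10: fallback keeps the
  # longest (250 bp) isoform only
  st <- build_reference(truth, "supertranscript")
  expect_equal(nrow(st$index), 1L)
  expect_equal(st$index$length, 250L)
  expect_equal(st$provenance$isoform_id, "g1_i1")
})

test_that("supertranscript appends divergent-allele isoforms as mosaic blocks", {
  set.seed(7)
  truth <- two_allele_truth(45)         # 3% divergence > 1% merge ceiling
  st <- build_reference(truth, "supertranscript")
  expect_equal(nrow(st$index), 1L)
  expect_equal(st$index$length, 3000L)  # body + appended block
  pl <- st$placements
  expect_equal(nrow(pl), 2L)            # duplicated gene interval
  expect_equal(pl$gene_start, c(1L, 1L))
  # and the duplication is visible to the mosaic screen
  hits <- self_align_contigs(setNames(st$contigs, names(st$contigs)))
  expect_true(detect_mosaics(hits)$mosaic)
  # identical alleles merge silently instead
  truth2 <- two_allele_truth(0)
  st2 <- build_reference(truth2, "supertranscript")
  expect_equal(st2$index$length, 1500L)
})

test_that("redundant references have one contig per distinct expressed allele sequence", {
  cfg <- sim_config(n_genes = 20, seed = 8)
  truth <- simulate_population(cfg)
  red <- build_reference(truth, "redundant")
  expect_true(all(table(red$provenance$contig_id) >= 1))
  # distinct contig sequences within each gene x isoform
  key <- paste(red$placements$gene_id,
               vapply(red$contigs[red$placements$contig_id], paste,
                      collapse = ",", ""))
  expect_false(any(duplicated(key)))
  # every contig's provenance is non-empty
  expect_setequal(unique(red$provenance$contig_id), red$index$contig_id)
})
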