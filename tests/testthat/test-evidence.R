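# Mapping emulation: mismatch ceiling, unique-best rule, purity of
# error-free evidence, determinism.

one_gene_truth <- function(L = 1500, error_rate = 0, theta = 0, seed = 1) {
  cfg <- sim_config(n_genes = 1, gene_length = L, n_mothers = 1,
                    theta = theta, error_rate = error_rate,
                    expression_logsd = 0, seed = seed)
  set.seed(seed)
  manual_truth(list(g1 = sample.int(4L, L, replace = TRUE)), cfg)
}

manual_reference <- function(truth, contig_seqs) {
  pl <- do.call(rbind, lapply(names(contig_seqs), function(cid)
    data.frame(contig_id = cid, gene_id = "g1", family_key = "g1",
               gene_start = 1L, gene_end = length(contig_seqs[[cid]]),
               contig_start = 1L)))
  prov <- data.frame(contig_id = names(contig_seqs), gene_id = "g1",
                     hap = 1L, isoform_id = "g1_i1")
  ref <- list(contigs = contig_seqs, placements = pl, provenance = prov,
              strategy = "supertranscript")
  ref$index <- data.frame(contig_id = names(contig_seqs),
                          length = vapply(contig_seqs, length, 1L),
                          strategy = "supertranscript",
                          n_source_genes = 1L, collapsed = FALSE)
  class(ref) <- "psc_reference"
  ref
}

test_that("error-free evidence from an identical haplotype is pure and complete", {
  truth <- one_gene_truth()
  ref <- build_reference(truth, "clustered")
  ev <- simulate_site_evidence(truth, ref, groups = "ME")
  arr <- ev$contigs[[1]]
  hap <- haplotype_seq(truth, "g1", 1L)
  for (pos in c(1, 77, 750, 1500)) {
    expect_equal(sum(arr[-hap[pos], pos, 1]), 0)   # only the true base
  }
  wrong <- sum(vapply(seq_len(1500), function(p) sum(arr[-hap[p], p, 1]), 1))
  expect_identical(wrong, 0)
  # window-level Poisson depth: constant within each 150 bp window
  d <- colSums(arr[, , 1])
  expect_true(all(tapply(d, rep(1:10, each = 150), function(x)
    length(unique(x))) == 1L))
})

test_that("a haplotype at 5% divergence from the only contig gets zero depth", {
  truth <- one_gene_truth()
  hap <- haplotype_seq(truth, "g1", 1L)
  div <- hap
  mut <- seq(10L, 1500L, by = 20L)                 # 5%, evenly spread
  div[mut] <- 1L + (div[mut] %% 4L)
  ref <- manual_reference(truth, list(c_div = div))
  ev <- simulate_site_evidence(truth, ref, groups = "ME")
  expect_identical(sum(ev$contigs[[1]]), 0L)
})

test_that("equidistant placements are discarded under unique-best mapping", {
  truth <- one_gene_truth()
  hap <- haplotype_seq(truth, "g1", 1L)
  c1 <- hap; c1[10L] <- 1L + (c1[10L] %% 4L)
  c2 <- hap; c2[20L] <- 1L + (c2[20L] %% 4L)
  ref <- manual_reference(truth, list(cA = c1, cB = c2))
  ev <- simulate_site_evidence(truth, ref, groups = "ME")
  expect_identical(sum(ev$contigs$cA) + sum(ev$contigs$cB), 0L)
  # without the unique-mapping rule, ties are assigned and depth appears
  truth$config$map_unique_only <- FALSE
  ev2 <- simulate_site_evidence(truth, ref, groups = "ME")
  expect_gt(sum(ev2$contigs$cA) + sum(ev2$contigs$cB), 0L)
})

test_that("evidence is deterministic under the seed and errors on truth mismatch", {
  cfg <- sim_config(n_genes = 4, seed = 19)
  truth <- simulate_population(cfg)
  ref <- build_reference(truth, "clustered")
  ev1 <- simulate_site_evidence(truth, ref, groups = c("ME", "EM"))
  ev2 <- simulate_site_evidence(truth, ref, groups = c("ME", "EM"))
  expect_identical(ev1$contigs, ev2$contigs)
  other <- simulate_population(sim_config(n_genes = 4, seed = 77))
  expect_error(simulate_site_evidence(other, ref), "mismatch")
})
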