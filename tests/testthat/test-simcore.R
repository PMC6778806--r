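# Population simulator: calibration, family design, determinism.

test_that("theta = 0 gives monomorphic pools and zero diversity", {
  truth <- simulate_population(sim_config(n_genes = 6, theta = 0, seed = 4))
  expect_true(all(vapply(truth$pools, function(p) length(p$pos), 1L) == 0L))
  expect_identical(pool_diversity(truth), 0)
})

test_that("pool diversity matches the all-pairs Hamming oracle and is calibrated to theta", {
  cfg <- sim_config(n_genes = 400, paralog_fraction = 0, seed = 17)
  truth <- simulate_population(cfg)
  # estimator == brute-force all-pairs Hamming on a subset of genes
  sub <- truth$genes$gene_id[seq(1, 400, by = 40)]
  for (g in sub) {
    pm <- gene_pool_matrix(truth, g)
    n <- ncol(pm)
    ham <- 0
    for (i in seq_len(n - 1))
      for (j in (i + 1):n) ham <- ham + sum(pm[, i] != pm[, j])
    oracle <- ham / choose(n, 2) / nrow(pm)
    p <- truth$pools[[g]]
    i <- lengths(p$carriers)
    est <- sum(2 * i * (n - i) / (n * (n - 1))) / nrow(pm)
    expect_equal(est, oracle, tolerance = 1e-12)
  }
  # Monte-Carlo calibration: mean pairwise diversity ~ theta within 5%
  expect_equal(pool_diversity(truth), cfg$theta, tolerance = 0.05)
})

test_that("paralog families are paired, counted and bounded in divergence", {
  cfg <- sim_config(n_genes = 100, paralog_fraction = 0.2,
                    paralog_divergence = 0.02, seed = 9)
  truth <- simulate_population(cfg)
  expect_equal(nrow(truth$families), 10L)
  expect_equal(sum(!is.na(truth$genes$family_id)), 20L)
  expect_true(all(truth$families$gene1 != truth$families$gene2))
  # realized divergence within 3 binomial SD of the target
  sd3 <- 3 * sqrt(0.02 * 0.98 / cfg$gene_length)
  expect_true(all(abs(truth$families$realized_divergence - 0.02) <= sd3))
  # member 2 really is a mutated copy of member 1
  f <- truth$families[1, ]
  d <- mean(truth$pools[[f$gene1]]$anc != truth$pools[[f$gene2]]$anc)
  expect_equal(d, f$realized_divergence)
})

test_that("family design: ME allele is in the EM genotype; VEG is the maternal pair", {
  cfg <- sim_config(n_genes = 10, seed = 2)
  truth <- simulate_population(cfg)
  for (g in truth$genes$gene_id) {
    geno <- sample_genotypes(truth, g)
    ped <- truth$ped[[g]]
    for (m in seq_len(cfg$n_mothers)) {
      me <- geno[[sprintf("ME_m%d", m)]]
      em <- geno[[sprintf("EM_m%d", m)]]
      veg <- geno[[sprintf("VEG_m%d", m)]]
      expect_length(me, 1L)
      expect_true(me %in% em)
      expect_true(me %in% ped$mat[m, ])
      expect_identical(sort(veg), sort(ped$mat[m, ]))
    }
  }
})

test_that("identical config and seed give byte-identical truth; seeds differ", {
  cfg <- sim_config(n_genes = 8, seed = 33)
  expect_identical(simulate_population(cfg), simulate_population(cfg))
  cfg2 <- sim_config(n_genes = 8, seed = 34)
  expect_false(identical(simulate_population(cfg)$pools,
                         simulate_population(cfg2)$pools))
})

test_that("infeasible theta calibration is rejected", {
  expect_error(sim_config(theta = 0.3), "segregation probability")
  expect_error(sim_config(paralog_fraction = 1.5), "paralog_fraction")
  expect_error(sim_config(gene_length = 100, read_len = 150), "read_len")
})

test_that("configurations round-trip through JSON", {
  cfg <- sim_config(n_genes = 7, theta = 0.003, seed = 12)
  p <- withr::local_tempfile(fileext = ".json")
  write_sim_config(cfg, p)
  expect_equal(read_sim_config(p), cfg)
})
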