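# Assembly and expression statistics: N50 convention, TPM
# normalization, expression-weighted N50, expression filters.

test_that("N50 follows the descending-cumulative convention", {
  expect_equal(assembly_stats(1000)$N50, 1000)
  expect_equal(assembly_stats(c(1000, 800, 600))$N50, 800)
  expect_equal(assembly_stats(c(500, 500, 500, 500))$N50, 500)
  expect_error(assembly_stats(numeric(0)), "empty")
  # FASTA route agrees with the length route
  p <- withr::local_tempfile(fileext = ".fasta")
  ss <- Biostrings::DNAStringSet(c(a = strrep("A", 1000),
                                   b = strrep("C", 800),
                                   c = strrep("G", 600)))
  Biostrings::writeXStringSet(ss, p)
  expect_equal(assembly_stats(p)$N50, 800)
  expect_equal(assembly_stats(p)$total_bases, 2400)
})

test_that("TPM normalizes to one million per sample", {
  em1 <- compute_tpm(matrix(5, 1, 2, dimnames = list("t1", NULL)), 500)
  expect_equal(unname(em1$tpm[1, ]), c(1e6, 1e6))
  cm <- matrix(c(10, 10), 2, 1, dimnames = list(c("t1", "t2"), NULL))
  em2 <- compute_tpm(cm, c(t1 = 1000, t2 = 2000))
  expect_equal(unname(em2$tpm[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  # zero-count transcript has TPM 0; random matrices sum to 1e6
  set.seed(2)
  cm3 <- matrix(rpois(50, 20), 10, 5)
  cm3[3, ] <- 0
  rownames(cm3) <- sprintf("t%02d", 1:10)
  em3 <- compute_tpm(cm3, rep(800, 10))
  expect_true(all(em3$tpm[3, ] == 0))
  expect_equal(unname(colSums(em3$tpm)), rep(1e6, 5), tolerance = 1e-6)
  # all-zero sample flagged
  cm3[, 2] <- 0
  em4 <- compute_tpm(cm3, rep(800, 10))
  expect_true(all(is.na(em4$tpm[, 2])))
  expect_length(em4$zero_samples, 1L)
})

test_that("ExN50 takes the N50 of the smallest prefix reaching the share", {
  lens <- c(1000, 800, 600, 400)
  counts <- matrix(c(0.70, 0.15, 0.10, 0.05) * 1000, 4, 1,
                   dimnames = list(sprintf("t%d", 1:4), NULL))
  expect_equal(exn50(counts, lens, x = 90), 800)   # prefix = first three
  expect_equal(exn50(counts[1, , drop = FALSE], lens[1], x = 37), 1000)
  uni <- matrix(1, 10, 1, dimnames = list(sprintf("u%d", 1:10), NULL))
  expect_equal(exn50(uni, rep(750, 10), x = 90), 750)
  expect_error(exn50(counts, lens, x = 0), "x")
  expect_error(exn50(counts, lens, x = 101), "x")
})

test_that("ExN50 at x = 100 equals the N50 of the expressed set", {
  set.seed(6)
  counts <- matrix(rpois(60, 30) + 1, 20, 3,
                   dimnames = list(sprintf("t%02d", 1:20), NULL))
  lens <- sample(300:3000, 20)
  expect_equal(exn50(counts, lens, x = 100), assembly_stats(lens)$N50)
})

test_that("low-expression filter is strict at the gene level", {
  counts <- matrix(c(100, 1, 2), 3, 1,
                   dimnames = list(c("g1_i1", "g2_i1", "g2_i2"), NULL))
  em <- compute_tpm(counts, rep(1000, 3))
  # craft exact boundary values via direct TPM inspection
  f <- low_expression_filter(em, gene_ids = c("g1", "g2", "g2"),
                             tpm_cutoff = sum(em$tpm[2:3, 1]))
  expect_identical(f$low_expression, c(FALSE, TRUE, TRUE))  # == cutoff drops
  f2 <- low_expression_filter(em, gene_ids = c("g1", "g2", "g2"),
                              tpm_cutoff = sum(em$tpm[2:3, 1]) - 1)
  expect_identical(f2$low_expression, c(FALSE, FALSE, FALSE))
  f3 <- low_expression_filter(em, tpm_cutoff = 2e6)
  expect_true(all(f3$low_expression))               # empty retained set
})

test_that("isoform pre-filter drops on inclusive boundaries but never empties a gene", {
  iso <- data.frame(
    isoform_id = c("a1", "a2", "a3", "b1", "b2"),
    gene_id = c("ga", "ga", "ga", "gb", "gb"),
    length = c(301, 300, 301, 250, 220),
    total_count = c(11, 100, 10, 5, 7))
  kept <- isoform_prefilter(iso)
  expect_setequal(kept, c("a1", "b1"))   # a2: length 300; a3: count 10;
                                         # gb: fallback keeps longest
  # property: no gene ever disappears
  set.seed(13)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    iso2 <- data.frame(isoform_id = sprintf("i%02d", 1:n),
                       gene_id = sample(c("g1", "g2", "g3"), n, TRUE),
                       length = sample(100:600, n, TRUE),
                       total_count = sample(0:30, n, TRUE))
    kept2 <- isoform_prefilter(iso2)
    expect_setequal(unique(iso2$gene_id),
                    unique(iso2$gene_id[iso2$isoform_id %in% kept2]))
  }
})
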