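# Screening rules: copy-number (identity/trim/coverage), mosaics,
# organelle and contaminant thresholds, monotonicity.

hit <- function(q, s = "genome", id, qs, qe, e = 1e-20, bits = 500) {
  data.frame(query_id = q, subject_id = s, pct_identity = id,
             aln_len = qe - qs + 1, mismatches = 0L, gap_open = 0L,
             q_start = qs, q_end = qe, s_start = qs, s_end = qe,
             evalue = e, bitscore = bits)
}

test_that("copy-number classification follows the identity/trim/coverage rules", {
  lens <- c(t_multi = 1000, t_single = 1200, t_short = 1000,
            t_border = 1000, t_lowid = 1000, t_trim = 1000)
  hits <- rbind(
    hit("t_multi", "gA", 90, 190, 610),    # both span 200-600 after trim
    hit("t_multi", "gB", 90, 190, 610),
    hit("t_single", "gA", 95, 90, 710),    # 601 bp covered >= 50% of 1200
    hit("t_short", "gA", 95, 100, 129),    # 30 bp: below both rules
    hit("t_border", "gA", 85, 190, 610),   # identity 85 is NOT > 85
    hit("t_border", "gB", 85, 190, 610),
    hit("t_lowid", "gA", 80, 1, 1000),     # full coverage, low identity
    hit("t_trim", "gA", 95, 100, 119),     # aln_len 20: empty after trim
    hit("t_trim", "gB", 95, 100, 119))
  cls <- classify_copy_number(hits, lens)
  got <- setNames(as.character(cls$copy_class), cls$contig_id)
  expect_identical(got[["t_multi"]], "multi")
  expect_identical(got[["t_single"]], "single")
  expect_identical(got[["t_short"]], "unassigned")
  expect_identical(got[["t_border"]], "unassigned")
  expect_identical(got[["t_lowid"]], "unassigned")
  expect_identical(got[["t_trim"]], "unassigned")
  # identity just above the threshold flips the border case to multi
  hits2 <- rbind(hit("t_border", "gA", 85.1, 190, 610),
                 hit("t_border", "gB", 85.1, 190, 610))
  cls2 <- classify_copy_number(hits2, lens["t_border"])
  expect_identical(as.character(cls2$copy_class), "multi")
})

test_that("mosaic detection ignores the trivial self-match and is order/swap invariant", {
  full <- hit("c1", "c1", 100, 1, 800)
  dup <- hit("c1", "c1", 98, 1, 300)
  dup$s_start <- 501; dup$s_end <- 800
  expect_false(detect_mosaics(full)$mosaic)
  expect_true(detect_mosaics(rbind(full, dup))$mosaic)
  # order invariance
  expect_true(detect_mosaics(rbind(dup, full))$mosaic)
  # query/subject interval swap invariance
  swap <- dup
  swap[, c("q_start", "q_end", "s_start", "s_end")] <-
    dup[, c("s_start", "s_end", "q_start", "q_end")]
  expect_true(detect_mosaics(rbind(full, swap))$mosaic)
  # cross-contig hits are not self-hits
  other <- hit("c1", "c2", 99, 1, 800)
  expect_false(detect_mosaics(rbind(full, other), contig_ids = "c1")$mosaic)
})

test_that("organelle and contaminant screens apply their thresholds inclusively", {
  org <- function(e, id) screen_organelle(hit("x", "chloro", id, 1, 200,
                                              e = e))$organelle
  expect_true(org(1e-3, 85))
  expect_false(org(0.2, 95))
  expect_true(org(5e-2, 80))       # boundary: inclusive
  expect_false(org(5e-2, 79.9))
  expect_false(screen_organelle(hit("x", "c", 90, 1, 200)[0, ],
                                contig_ids = "x")$organelle)  # no hits
  con <- function(e, id) screen_contaminants(hit("x", "sprot", id, 1, 200,
                                                 e = e))$contaminant
  expect_true(con(1e-6, 70))
  expect_false(con(1e-6, 60))
  expect_false(con(1e-4, 90))
  expect_true(con(1e-5, 65))       # boundary: inclusive
})

test_that("screens are monotone: relaxing thresholds never unflags", {
  set.seed(11)
  hits <- do.call(rbind, lapply(1:40, function(i)
    hit(sprintf("q%02d", i), "s", runif(1, 50, 100), 1, 300,
        e = 10^runif(1, -30, 1))))
  es <- c(1e-10, 1e-5, 1e-2, 1)
  ids <- c(90, 80, 65, 50)
  prev <- rep(FALSE, 40)
  for (j in seq_along(es)) {
    cur <- screen_contaminants(hits, contig_ids = sprintf("q%02d", 1:40),
                               max_evalue = es[j],
                               min_identity = ids[j])$contaminant
    expect_true(all(cur | !prev))   # once flagged, stays flagged
    prev <- cur
  }
})

test_that("haploid-het flag requires callable data and positive heterozygosity", {
  stats <- data.frame(contig_id = c("a", "b", "c"), group = "ME",
                      n_callable = c(500, 500, 50),
                      n_obs = c(3000, 3000, 300),
                      n_het = c(1, 0, 5),
                      Ho_per_bp = c(1 / 3000, 0, 5 / 300),
                      pi_sum = 0, n_pi_sites = 1, pi_per_bp = 0,
                      n_alleles_median = 6)
  f <- flag_haploid_het(stats)
  expect_identical(f$haploid_het, c(TRUE, FALSE, NA))
  expect_error(flag_haploid_het(stats[0, ]), "ME")
})
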