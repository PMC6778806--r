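# Heterozygosity statistics: the unbiased per-site diversity estimator
# against the pairwise-difference oracle, micro-averaging, ratio panel.

test_that("per-site diversity equals the pairwise-difference oracle exactly", {
  expect_equal(site_pi(c(6, 6)), 12 / 11 * 0.5)
  expect_equal(site_pi(c(5, 1)), 6 / 5 * (1 - 26 / 36))
  expect_equal(site_pi(c(5, 1)), 5 / 15)             # 5 of 15 pairs differ
  expect_equal(site_pi(c(12, 0, 0, 0)), 0)           # monomorphic
  expect_true(is.na(site_pi(c(1, 0, 0, 0))))         # n < 2 undefined
  set.seed(7)
  for (i in 1:1000) {
    counts <- rmultinom(1, sample(2:30, 1), prob = runif(4))[, 1]
    expect_equal(site_pi(counts), pi_pairwise_oracle(counts),
                 tolerance = 1e-12)
  }
})

test_that("observed heterozygosity is micro-averaged and NA when undefined", {
  # 6 diploids, 200 sites, 2 het calls in total
  mk <- function(a = 0, c = 0) as.integer(c(a, c, 0, 0))
  sites <- c(list(list(mk(a = 15, c = 15), mk(a = 15, c = 15), mk(a = 30),
                       mk(a = 30), mk(a = 30), mk(c = 30))),
             replicate(199, replicate(6, mk(a = 30), simplify = FALSE),
                       simplify = FALSE))
  ev <- evidence_from_sites(sites, rep("EM", 6), error_rate = 0)
  st <- transcript_het_stats(filter_sites(call_genotypes(ev)))
  expect_equal(st$n_obs, 1200L)
  expect_equal(st$n_het, 2L)
  expect_equal(st$Ho_per_bp, 2 / 1200)
  # pooled expected heterozygosity at the polymorphic site: 8 A, 4 C
  expect_equal(st$pi_sum, 12 / 11 * (1 - (8 / 12)^2 - (4 / 12)^2))
  expect_equal(st$pi_per_bp, st$pi_sum / 200)
  # zero callable data: statistics undefined, not zero
  ev0 <- evidence_from_sites(list(replicate(6, mk(), simplify = FALSE)),
                             rep("EM", 6), error_rate = 0)
  st0 <- transcript_het_stats(filter_sites(call_genotypes(ev0)))
  expect_true(is.na(st0$Ho_per_bp))
  expect_true(is.na(st0$pi_per_bp))
})

test_that("haploid calls pool one allele copy per homozygote", {
  mk <- function(a = 0, c = 0) as.integer(c(a, c, 0, 0))
  # 6 haploid megagametophytes: 5 carry A, 1 carries C
  sites <- list(list(mk(a = 30), mk(a = 30), mk(a = 30), mk(a = 30),
                     mk(a = 30), mk(c = 30)))
  ev <- evidence_from_sites(sites, rep("ME", 6), error_rate = 0)
  st <- transcript_het_stats(filter_sites(call_genotypes(ev)))
  expect_equal(st$n_alleles_median, 6)
  expect_equal(st$pi_sum, 6 / 5 * (1 - 26 / 36))
})

test_that("the ratio panel reproduces hand-computed aggregates and flags NA", {
  stats <- data.frame(
    contig_id = rep(c("t1", "t2", "t3"), each = 2),
    group = rep(c("ME", "EM"), 3),
    n_callable = c(1000, 1000, 1000, 1000, 100, 100),
    n_obs = c(6000, 6000, 4000, 4000, 600, 600),
    n_het = c(2, 6, 0, 1, 50, 50),
    pi_sum = c(0.8, 0.9, 0.2, 0.3, 9, 9),
    n_pi_sites = c(1000, 1000, 1000, 1000, 100, 100),
    pi_per_bp = NA, n_alleles_median = 12)
  sm <- summarize_ratios(stats, min_callable = 100)
  # transcript t3 (exactly 100 callable) is excluded by the > rule
  expect_equal(sm$groups$n_transcripts, c(2L, 2L))
  expect_equal(sm$groups$Ho_per_bp[sm$groups$group == "ME"], 2 / 10000)
  expect_equal(sm$groups$He_per_bp[sm$groups$group == "EM"], 1.2 / 2000)
  expect_equal(sm$ratios$value[1], (2 / 10000) / (7 / 10000))
  expect_true(is.na(sm$ratios$value[2]))             # VEG absent
  # published-style ratio: Ho(ME)=0.29, Ho(EM)=0.86 (x1000) -> 0.34
  st2 <- data.frame(contig_id = "t", group = c("ME", "EM"),
                    n_callable = 1e5, n_obs = 1e5 * 6,
                    n_het = c(0.29e-3, 0.86e-3) * 1e5 * 6,
                    pi_sum = 1, n_pi_sites = 1e5, pi_per_bp = NA,
                    n_alleles_median = 12)
  sm2 <- summarize_ratios(st2)
  expect_equal(round(sm2$ratios$value[1], 2), 0.34)
  # equal observed heterozygosity gives ratio 1; zero denominator is NA
  st2$n_het <- c(5, 5)
  expect_equal(summarize_ratios(st2)$ratios$value[1], 1)
  st2$n_het <- c(5, 0)
  expect_true(is.na(summarize_ratios(st2)$ratios$value[1]))
})

test_that("flag stratification attributes haploid heterozygosity to strata", {
  stats <- data.frame(
    contig_id = sprintf("t%d", 1:6), group = "ME",
    n_callable = 1000, n_obs = 6000,
    n_het = c(5, 3, 0, 0, 0, 2),
    Ho_per_bp = c(5, 3, 0, 0, 0, 2) / 6000,
    pi_sum = 0.5, n_pi_sites = 1000, pi_per_bp = 5e-4,
    n_alleles_median = 6)
  flags <- data.frame(contig_id = sprintf("t%d", 1:6),
                      copy_class = c("multi", "multi", "single", "single",
                                     "unassigned", "multi"),
                      mosaic = FALSE)
  out <- stratify_by_flags(stats, flags)
  expect_equal(out$n_transcripts[out$stratum == "multi"], 3L)
  expect_equal(out$n_het_pos[out$stratum == "multi"], 3L)
  expect_equal(out$frac_of_het_pos[out$stratum == "multi"], 1)
  expect_equal(out$n_het_pos[out$stratum == "single"], 0L)
  expect_gt(out$mean_Ho[out$stratum == "multi"],
            out$mean_Ho[out$stratum == "single"])
})
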