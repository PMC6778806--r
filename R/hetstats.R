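# Observed and expected heterozygosity (nucleotide diversity) per
# transcript over callable sites. Counts are micro-averaged: numerators
# and denominators are summed first and divided once, matching a pooled
# per-bp presentation.

# ploidy-aware pooled allele-count matrix (sites x 4 bases) for one
# group's calls: diploid calls contribute two allele copies, haploid
# (ME) homozygous calls one -- a het call on haploid tissue contributes
# both alleles, as the artifact it is
.pooled_allele_counts <- function(a1, a2, haploid) {
  ac <- matrix(0, nrow(a1), 4L)
  for (b in 1:4) {
    if (haploid)
      ac[, b] <- rowSums((a1 == b) + ((a2 == b) & (a2 != a1)))
    else
      ac[, b] <- rowSums((a1 == b) + (a2 == b))
  }
  ac
}

.group_site_data <- function(filtered, cid, grp) {
  cc <- filtered$contigs[[cid]]
  js <- which(filtered$samples$group == grp)
  keep <- filtered$site_keep[[cid]][, grp]
  a1 <- cc$a1[keep, js, drop = FALSE]
  a2 <- cc$a2[keep, js, drop = FALSE]
  list(a1 = a1, a2 = a2,
       haploid = all(filtered$samples$ploidy[js] == 1L))
}

#' Per-transcript heterozygosity statistics over callable sites
#'
#' For each contig and tissue group computes the number of callable
#' sites and callable site-observations, the heterozygous call count,
#' observed heterozygosity per bp (het calls / callable observations,
#' micro-averaged), and expected heterozygosity per bp: the mean over
#' callable sites of the per-site unbiased nucleotide diversity
#' `pi = n/(n-1) * (1 - sum p_k^2)` computed from the group's pooled
#' allele counts (monomorphic sites contribute zero; sites with fewer
#' than two pooled alleles are excluded from numerator and denominator).
#' Haploid megagametophyte calls pool one allele copy per homozygous
#' call.
#'
#' @param filtered a `filtered_calls` object from [filter_sites()].
#' @param groups groups to tabulate (default: all present).
#' @return An object of class `het_stats` (a data.frame): one row per
#'   contig x group with columns `n_callable`, `n_obs`, `n_het`,
#'   `Ho_per_bp`, `pi_per_bp`, `pi_sum`, `n_pi_sites`,
#'   `n_alleles_median`. Undefined statistics (zero denominator) are NA,
#'   never zero.
#' @examples
#' ev <- simulate_hwe_sites(500, n_diploids = 6, seed = 5)
#' st <- transcript_het_stats(filter_sites(call_genotypes(ev)))
#' head(st)
#' @export
transcript_het_stats <- function(filtered,
                                 groups = unique(filtered$samples$group)) {
  stopifnot(inherits(filtered, "filtered_calls"))
  rows <- list()
  for (cid in names(filtered$contigs)) {
    for (grp in groups) {
      sd <- .group_site_data(filtered, cid, grp)
      nonmiss <- sd$a1 > 0L
      n_obs <- sum(nonmiss)
      n_het <- sum(nonmiss & sd$a1 != sd$a2)
      ac <- .pooled_allele_counts(sd$a1, sd$a2, sd$haploid)
      n_all <- rowSums(ac)
      use <- n_all >= 2
      pi_site <- numeric(nrow(ac))
      if (any(use)) {
        p2 <- rowSums((ac[use, , drop = FALSE] / n_all[use])^2)
        pi_site[use] <- n_all[use] / (n_all[use] - 1) * (1 - p2)
      }
      rows[[paste(cid, grp)]] <- data.frame(
        contig_id = cid, group = grp,
        n_callable = nrow(sd$a1), n_obs = n_obs, n_het = n_het,
        Ho_per_bp = if (n_obs > 0) n_het / n_obs else NA_real_,
        pi_sum = sum(pi_site[use]),
        n_pi_sites = sum(use),
        pi_per_bp = if (any(use)) sum(pi_site[use]) / sum(use) else NA_real_,
        n_alleles_median = if (length(n_all)) stats::median(n_all) else NA_real_)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("het_stats", "data.frame")
  out
}

#' Observed heterozygosity per transcript
#'
#' Micro-averaged per-bp observed heterozygosity for one group: summed
#' heterozygous calls over summed callable site-observations.
#'
#' @inheritParams transcript_het_stats
#' @param group a single tissue group.
#' @return data.frame with `contig_id`, `n_callable`, `n_obs`, `n_het`,
#'   `Ho_per_bp` (NA when no callable observations).
#' @export
observed_het <- function(filtered, group) {
  st <- transcript_het_stats(filtered, groups = group)
  st[, c("contig_id", "group", "n_callable", "n_obs", "n_het", "Ho_per_bp")]
}

#' Expected heterozygosity (nucleotide diversity) per transcript
#'
#' Mean over callable sites of the unbiased per-site diversity estimate
#' from the group's pooled allele counts.
#'
#' @inheritParams observed_het
#' @return data.frame with `contig_id`, `n_callable`, `n_pi_sites`,
#'   `pi_per_bp`.
#' @export
expected_het <- function(filtered, group) {
  st <- transcript_het_stats(filtered, groups = group)
  st[, c("contig_id", "group", "n_callable", "n_pi_sites", "pi_sum",
         "pi_per_bp")]
}

#' Per-site unbiased nucleotide diversity from allele counts
#'
#' `pi = n/(n-1) * (1 - sum p_k^2)` for pooled allele counts `counts`
#' (algebraically identical to the average pairwise difference over all
#' allele pairs). Sites with fewer than two alleles return NA.
#'
#' @param counts numeric vector (one site) or matrix (sites x alleles)
#'   of pooled allele counts.
#' @return per-site diversity estimates.
#' @examples
#' site_pi(c(6, 6))   # 12/11 * (1 - 0.5)
#' site_pi(c(5, 1))   # 6/5 * (1 - 26/36)
#' @export
site_pi <- function(counts) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  n <- rowSums(counts)
  out <- rep(NA_real_, nrow(counts))
  use <- n >= 2
  if (any(use)) {
    p2 <- rowSums((counts[use, , drop = FALSE] / n[use])^2)
    out[use] <- n[use] / (n[use] - 1) * (1 - p2)
  }
  out
}

#' Assembly-wide summary and ratio panel
#'
#' Aggregates per-transcript statistics into the assembly-level panel:
#' per group, total callable sites and observed/expected heterozygosity
#' per bp (scaled x1000 for reporting), plus the haploid/diploid
#' observed-heterozygosity ratios ME/EM and ME/VEG and the Ho/He ratio
#' per group. Transcripts with `min_callable` or fewer callable sites in
#' a group are excluded from that group's aggregate. Ratios with a zero
#' or absent denominator are NA.
#'
#' @param stats a `het_stats` data.frame.
#' @param min_callable callable-site threshold (transcripts with more
#'   than this many callable sites are included).
#' @return An object of class `assembly_summary`: `groups` data.frame
#'   (per-group totals, x1000 scaled values and Ho/He ratio) and
#'   `ratios` (ME/EM, ME/VEG observed-heterozygosity ratios).
#' @export
summarize_ratios <- function(stats, min_callable = 100) {
  stopifnot(is.data.frame(stats))
  stats <- stats[stats$n_callable > min_callable, , drop = FALSE]
  grps <- unique(stats$group)
  agg <- do.call(rbind, lapply(grps, function(g) {
    s <- stats[stats$group == g, , drop = FALSE]
    Ho <- if (sum(s$n_obs) > 0) sum(s$n_het) / sum(s$n_obs) else NA_real_
    He <- if (sum(s$n_pi_sites) > 0)
      sum(s$pi_sum) / sum(s$n_pi_sites) else NA_real_
    data.frame(group = g, n_transcripts = nrow(s),
               total_callable = sum(s$n_callable),
               Ho_per_bp = Ho, He_per_bp = He,
               Ho_x1000 = 1000 * Ho, He_x1000 = 1000 * He,
               Ho_over_He = if (!is.na(He) && He > 0) Ho / He else NA_real_)
  }))
  gv <- function(g, col) {
    i <- match(g, agg$group)
    if (is.na(i)) NA_real_ else agg[[col]][i]
  }
  rat <- function(num, den) {
    if (is.na(num) || is.na(den) || den == 0) NA_real_ else num / den
  }
  ratios <- data.frame(
    ratio = c("Ho(ME)/Ho(EM)", "Ho(ME)/Ho(VEG)"),
    value = c(rat(gv("ME", "Ho_per_bp"), gv("EM", "Ho_per_bp")),
              rat(gv("ME", "Ho_per_bp"), gv("VEG", "Ho_per_bp"))))
  structure(list(groups = agg, ratios = ratios,
                 min_callable = min_callable),
            class = "assembly_summary")
}

#' @export
print.assembly_summary <- function(x, ...) {
  cat(sprintf("Assembly summary (transcripts with > %d callable sites)\n",
              x$min_callable))
  g <- x$groups
  for (i in seq_len(nrow(g)))
    cat(sprintf("  %-4s %7d transcripts, %10d callable; Ho=%.2f He=%.2f (x1000); Ho/He=%s\n",
                g$group[i], g$n_transcripts[i], g$total_callable[i],
                g$Ho_x1000[i], g$He_x1000[i],
                ifelse(is.na(g$Ho_over_He[i]), "NA",
                       sprintf("%.2f", g$Ho_over_He[i]))))
  for (i in seq_len(nrow(x$ratios)))
    cat(sprintf("  %s = %s\n", x$ratios$ratio[i],
                ifelse(is.na(x$ratios$value[i]), "NA",
                       sprintf("%.2f", x$ratios$value[i]))))
  invisible(x)
}

#' Stratify heterozygosity by screening flags
#'
#' Splits transcripts into single-copy, multi-copy, mosaic and other
#' strata and tabulates, per stratum, the transcript count, the count
#' and share of transcripts with observed heterozygosity above zero, and
#' mean observed/expected heterozygosity -- the single- vs multi-copy
#' contrast that corroborates the haploid-heterozygosity collapse
#' signal.
#'
#' @param stats a `het_stats` data.frame (typically the ME group).
#' @param flags a data.frame with `contig_id`, `copy_class` and
#'   `mosaic` columns (see [transcript_flags()]).
#' @param group group to stratify (default `"ME"`).
#' @return data.frame, one row per stratum.
#' @export
stratify_by_flags <- function(stats, flags, group = "ME") {
  s <- stats[stats$group == group & !is.na(stats$Ho_per_bp), , drop = FALSE]
  m <- match(s$contig_id, flags$contig_id)
  stratum <- ifelse(!is.na(m) & flags$mosaic[m], "mosaic",
              ifelse(!is.na(m) & flags$copy_class[m] == "multi", "multi",
               ifelse(!is.na(m) & flags$copy_class[m] == "single", "single",
                      "other")))
  het_pos_total <- sum(s$Ho_per_bp > 0)
  do.call(rbind, lapply(c("single", "multi", "mosaic", "other"), function(st) {
    ss <- s[stratum == st, , drop = FALSE]
    data.frame(stratum = st, n_transcripts = nrow(ss),
               n_het_pos = sum(ss$Ho_per_bp > 0),
               frac_of_het_pos = if (het_pos_total > 0)
                 sum(ss$Ho_per_bp > 0) / het_pos_total else NA_real_,
               mean_Ho = if (nrow(ss)) mean(ss$Ho_per_bp) else NA_real_,
               mean_pi = if (nrow(ss)) mean(ss$pi_per_bp, na.rm = TRUE)
                         else NA_real_)
  }))
}
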