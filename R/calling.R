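# Simplified diploid genotype caller. All groups -- including the
# haploid megagametophytes -- are genotyped in diploid mode, so that
# heterozygous calls on haploid tissue (the collapse diagnostic) are
# observable.

#' Caller parameters
#'
#' @param min_allele_count minimum reads supporting an allele for it to
#'   be retained.
#' @param min_allele_frac minimum fraction of the site depth supporting a
#'   retained allele.
#' @param error_rate per-base error probability used in the genotype
#'   likelihood; floored at `1e-4` so Phred quals stay finite when the
#'   simulation is error-free.
#' @return a `caller_params` list.
#' @export
caller_params <- function(min_allele_count = 2L, min_allele_frac = 0.2,
                          error_rate = 0.001) {
  structure(list(min_allele_count = as.integer(min_allele_count),
                 min_allele_frac = min_allele_frac,
                 error_rate = error_rate),
            class = "caller_params")
}

# log P(read base | genotype) for the 10 unordered diploid genotypes
.genotype_logprob <- function(e) {
  gts <- which(upper.tri(matrix(0, 4, 4), diag = TRUE), arr.ind = TRUE)
  lp <- matrix(NA_real_, nrow(gts), 4L)
  for (k in seq_len(nrow(gts))) {
    a <- gts[k, 1L]; b <- gts[k, 2L]
    pr <- 0.5 * ifelse(seq_len(4L) == a, 1 - e, e / 3) +
          0.5 * ifelse(seq_len(4L) == b, 1 - e, e / 3)
    lp[k, ] <- log(pr)
  }
  list(gts = gts, lp = lp)
}

#' Call genotypes from site evidence
#'
#' Alleles supported by at least `min_allele_count` reads and at least
#' `min_allele_frac` of the site depth are retained. One retained allele
#' gives a homozygous call, two a heterozygous call; more than two marks
#' the call multi-allelic (treated as missing at the sample level and
#' counted at the site level by [filter_sites()]). Zero depth, or no
#' retained allele, is a missing call. The call quality is the
#' Phred-scaled likelihood ratio of the called genotype against the best
#' alternative under a per-read error model, clamped at zero.
#'
#' @param evidence a `site_evidence`.
#' @param params a [caller_params()]; its `error_rate` defaults to the
#'   evidence's simulated error rate.
#' @return An object of class `genotype_calls`: per contig, integer
#'   matrices `a1`, `a2` (called alleles, 0 = missing), `c1`, `c2`
#'   (supporting read counts), `depth`, `nallele` (number of retained
#'   alleles) and a numeric `qual` matrix, all position x sample.
#' @examples
#' ev <- simulate_hwe_sites(100, n_diploids = 4, seed = 3)
#' calls <- call_genotypes(ev)
#' table(calls$contigs[[1]]$a1[, 1])
#' @export
call_genotypes <- function(evidence, params = NULL) {
  stopifnot(inherits(evidence, "site_evidence"))
  if (is.null(params))
    params <- caller_params(error_rate = evidence$config$error_rate %||% 0.001)
  e <- max(params$error_rate, 1e-4)
  gp <- .genotype_logprob(e)
  out <- lapply(evidence$contigs, function(arr) {
    if (any(arr < 0L)) stop("negative base counts")
    d <- dim(arr)
    L <- d[2L]; S <- d[3L]
    cnt <- matrix(arr, nrow = 4L)             # 4 x (L*S)
    depth <- colSums(cnt)
    keep <- cnt >= params$min_allele_count &
      cnt >= rep(depth, each = 4L) * params$min_allele_frac & cnt > 0L
    nall <- colSums(keep)

    a1 <- a2 <- integer(L * S)
    # top two retained alleles by count (ties: lower base index first)
    ord_score <- cnt - 0.1 * (1:4) / 4        # deterministic tie-break
    ord_score[!keep] <- -Inf
    top1 <- max.col(t(ord_score), ties.method = "first")
    sc2 <- ord_score
    sc2[cbind(top1, seq_len(L * S))] <- -Inf
    top2 <- max.col(t(sc2), ties.method = "first")
    het <- nall == 2L
    hom <- nall == 1L
    a1[hom] <- top1[hom]
    a2[hom] <- top1[hom]
    a1[het] <- pmin(top1[het], top2[het])
    a2[het] <- pmax(top1[het], top2[het])

    # Phred-scaled likelihood ratio of the called genotype vs the best
    # alternative (multinomial coefficient cancels)
    ll <- gp$lp %*% cnt                       # 10 x (L*S)
    called_gt <- integer(L * S)
    ok <- a1 > 0L
    gt_index <- matrix(0L, 4L, 4L)
    gt_index[cbind(gp$gts[, 1L], gp$gts[, 2L])] <- seq_len(nrow(gp$gts))
    called_gt[ok] <- gt_index[cbind(a1[ok], a2[ok])]
    qual <- numeric(L * S)
    if (any(ok)) {
      iok <- which(ok)
      ll_called <- ll[cbind(called_gt[iok], iok)]
      ll2 <- ll
      ll2[cbind(called_gt[iok], iok)] <- -Inf
      ll_best_other <- ll2[1L, iok]
      for (r in 2:nrow(ll2)) ll_best_other <- pmax(ll_best_other, ll2[r, iok])
      qual[iok] <- pmax(0, 10 / log(10) * (ll_called - ll_best_other))
    }

    c1 <- c2 <- integer(L * S)
    c1[ok] <- cnt[cbind(a1[ok], which(ok))]
    c2[ok] <- cnt[cbind(a2[ok], which(ok))]
    shape <- function(x) matrix(x, L, S, dimnames = list(NULL, dimnames(arr)[[3]]))
    list(a1 = shape(a1), a2 = shape(a2), c1 = shape(c1), c2 = shape(c2),
         depth = shape(as.integer(depth)), nallele = shape(as.integer(nall)),
         qual = shape(qual))
  })
  structure(list(contigs = out, samples = evidence$samples, params = params),
            class = "genotype_calls")
}

#' @export
print.genotype_calls <- function(x, ...) {
  n_sites <- sum(vapply(x$contigs, function(c) nrow(c$a1), 1L))
  het <- sum(vapply(x$contigs, function(c)
    sum(c$a1 != c$a2 & c$a1 > 0L), 1L))
  cat(sprintf("Genotype calls (%s): %d contigs, %d sites x %d samples, %d het calls\n",
              paste(class(x), collapse = "/"), length(x$contigs), n_sites,
              nrow(x$samples), het))
  invisible(x)
}

#' Site-filter parameters
#'
#' Defaults: per-sample minimum depth 10,
#' at most 50% missing data per site, and polymorphic sites kept only
#' when they are bi-allelic SNPs with quality above 20.
#'
#' @param min_depth minimum per-sample depth; shallower calls are voided.
#' @param max_missing maximum fraction of missing (or voided) calls per
#'   site; sites above it are dropped.
#' @param min_qual minimum site quality for polymorphic sites (site
#'   quality is the maximum per-sample call quality).
#' @param biallelic_only drop polymorphic sites with more than two
#'   alleles.
#' @return a `filter_params` list.
#' @export
filter_params <- function(min_depth = 10L, max_missing = 0.5,
                          min_qual = 20, biallelic_only = TRUE) {
  structure(list(min_depth = as.integer(min_depth),
                 max_missing = max_missing, min_qual = min_qual,
                 biallelic_only = biallelic_only),
            class = "filter_params")
}

#' Apply depth, missingness and quality filters; tabulate callable sites
#'
#' Filtering is per tissue group, mirroring one VCF per group: a
#' sample's call is voided when its depth is below `min_depth`; a site is
#' dropped for the group when its missing fraction exceeds `max_missing`;
#' polymorphic sites are retained only as bi-allelic SNPs with site
#' quality above `min_qual` (failing polymorphic sites are excluded from
#' the callable set). Surviving monomorphic plus polymorphic sites form
#' the callable-site table -- the denominator of all per-bp statistics.
#'
#' @param calls a `genotype_calls` object.
#' @param params a [filter_params()].
#' @return An object of class `filtered_calls` (a `genotype_calls` with
#'   voided calls set missing) carrying, per contig and group, a logical
#'   `callable` matrix, plus a `callable` data.frame with site- and
#'   observation-level totals per contig x group and a `per_sample`
#'   table.
#' @export
filter_sites <- function(calls, params = filter_params()) {
  stopifnot(inherits(calls, "genotype_calls"))
  groups <- unique(calls$samples$group)
  if (!all(groups %in% c("ME", "EM", "VEG")))
    stop("unknown group label: ",
         paste(setdiff(groups, c("ME", "EM", "VEG")), collapse = ", "))
  callable_rows <- list()
  per_sample_rows <- list()
  site_keep <- list()
  for (cid in names(calls$contigs)) {
    cc <- calls$contigs[[cid]]
    keep_mat <- matrix(FALSE, nrow(cc$a1), length(groups),
                       dimnames = list(NULL, groups))
    for (grp in groups) {
      js <- which(calls$samples$group == grp)
      depth_ok <- cc$depth[, js, drop = FALSE] >= params$min_depth
      void <- cc$a1[, js, drop = FALSE] == 0L | !depth_ok
      miss_frac <- rowMeans(void)
      a1 <- cc$a1[, js, drop = FALSE]; a1[void] <- 0L
      a2 <- cc$a2[, js, drop = FALSE]; a2[void] <- 0L
      # pooled allele counts per site among non-void calls
      ac <- vapply(1:4, function(b)
        rowSums((a1 == b) + (a2 == b)), numeric(nrow(a1)))
      if (is.null(dim(ac))) ac <- matrix(ac, nrow = 1L)
      n_distinct <- rowSums(ac > 0)
      major <- max.col(ac, ties.method = "first")
      # site quality: best call quality among samples carrying a
      # non-majority allele (variant-supporting calls)
      variant <- (a1 > 0L) & (a1 != major | a2 != major)
      qm <- cc$qual[, js, drop = FALSE]
      qm[!variant] <- -Inf
      poly_q <- qm[, 1L]
      if (ncol(qm) > 1L)
        for (r in 2:ncol(qm)) poly_q <- pmax(poly_q, qm[, r])
      # a sample with >2 retained alleles at adequate depth marks the
      # site multi-allelic even though its own call is missing
      multi_site <- rowSums(cc$nallele[, js, drop = FALSE] > 2L & depth_ok) > 0L
      keep <- miss_frac <= params$max_missing
      poly <- n_distinct >= 2L | multi_site
      bad_poly <- poly & ((params$biallelic_only &
                             (n_distinct > 2L | multi_site)) |
                            poly_q <= params$min_qual)
      keep <- keep & !bad_poly
      keep_mat[, grp] <- keep
      # void calls at kept sites become missing in the output
      cc$a1[, js][void | !keep] <- 0L
      cc$a2[, js][void | !keep] <- 0L
      cc$c1[, js][void | !keep] <- 0L
      cc$c2[, js][void | !keep] <- 0L
      cc$qual[, js][void | !keep] <- 0
      n_obs <- sum(!void[keep, , drop = FALSE])
      callable_rows[[paste(cid, grp)]] <- data.frame(
        contig_id = cid, group = grp, n_callable = sum(keep),
        n_callable_obs = n_obs)
      per_sample_rows[[paste(cid, grp)]] <- data.frame(
        contig_id = cid, group = grp,
        sample_id = calls$samples$sample_id[js],
        n_callable = colSums(!void[keep, , drop = FALSE]))
    }
    calls$contigs[[cid]] <- cc
    site_keep[[cid]] <- keep_mat
  }
  calls$callable <- do.call(rbind, c(callable_rows, list(make.row.names = FALSE)))
  calls$per_sample <- do.call(rbind, c(per_sample_rows, list(make.row.names = FALSE)))
  calls$site_keep <- site_keep
  calls$filter_params <- params
  class(calls) <- c("filtered_calls", "genotype_calls")
  calls
}
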