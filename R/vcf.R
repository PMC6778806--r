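# VCF v4.2 interchange for genotype calls. Internal coordinates are
# 1-based, matching VCF POS directly. Per-sample call quality travels as
# GQ; the site QUAL column carries the best variant-supporting call
# quality. Indel and MNP records are skipped on read (with a count),
# mirroring a SNP-only calling setup.

#' Write genotype calls to a VCF file
#'
#' Emits one record per site with at least one non-missing call, with
#' `GT:AD:DP:GQ` sample fields. The REF base is taken from the supplied
#' reference contig sequence (falling back to the pooled majority allele
#' when no reference is given).
#'
#' @param calls a `genotype_calls` or `filtered_calls` object.
#' @param path output path.
#' @param reference optional `psc_reference` supplying REF bases.
#' @param group optional single group; defaults to all samples.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, reference = NULL, group = NULL) {
  stopifnot(inherits(calls, "genotype_calls"))
  samples <- calls$samples
  js <- if (is.null(group)) seq_len(nrow(samples))
        else which(samples$group == group)
  if (!length(js)) stop("no samples in group: ", group)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=pscdetect",
    sprintf("##contig=<ID=%s,length=%d>", names(calls$contigs),
            vapply(calls$contigs, function(c) nrow(c$a1), 1L)),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Float,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples$sample_id[js]), collapse = "\t")), con)
  for (cid in names(calls$contigs)) {
    cc <- calls$contigs[[cid]]
    a1 <- cc$a1[, js, drop = FALSE]
    a2 <- cc$a2[, js, drop = FALSE]
    sites <- which(rowSums(a1 > 0L) > 0L)
    for (i in sites) {
      called <- a1[i, ] > 0L
      alleles <- sort(unique(c(a1[i, called], a2[i, called])))
      ref_base <- if (!is.null(reference)) reference$contigs[[cid]][i]
                  else alleles[1L]
      alt <- setdiff(alleles, ref_base)
      all_order <- c(ref_base, alt)
      gt <- character(length(js))
      ad <- character(length(js))
      gq <- numeric(length(js))
      for (s in seq_along(js)) {
        if (!called[s]) {
          gt[s] <- "./."
          ad[s] <- "."
          next
        }
        i1 <- match(a1[i, s], all_order) - 1L
        i2 <- match(a2[i, s], all_order) - 1L
        gt[s] <- paste(sort(c(i1, i2)), collapse = "/")
        adv <- integer(length(all_order))
        adv[i1 + 1L] <- cc$c1[i, js[s]]
        adv[i2 + 1L] <- cc$c2[i, js[s]]
        ad[s] <- paste(adv, collapse = ",")
        gq[s] <- cc$qual[i, js[s]]
      }
      qual <- if (length(alt)) sprintf("%.4f", max(gq[called])) else "."
      fields <- ifelse(called,
                       sprintf("%s:%s:%d:%.4f", gt, ad, cc$depth[i, js], gq),
                       sprintf("%s:%s:%d:.", gt, ad, cc$depth[i, js]))
      writeLines(paste(c(cid, i, ".", BASES[ref_base],
                         if (length(alt)) paste(BASES[alt], collapse = ",")
                         else ".",
                         qual, "PASS", sprintf("DP=%d", sum(cc$depth[i, js])),
                         "GT:AD:DP:GQ", fields), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read genotype calls from a VCF file
#'
#' Parses a VCF v4.x (via the vcfR reader), assigns samples to tissue
#' groups through `group_map`, skips indel/MNP records (counting them),
#' and reconstructs a `genotype_calls` object with depth (DP), allele
#' depths (AD) and per-sample qualities (GQ). Contig lengths are taken
#' from `##contig` header lines or, failing that, the largest observed
#' position.
#'
#' @param path VCF path.
#' @param group_map named character vector mapping sample id to group
#'   (`ME`, `EM` or `VEG`).
#' @return a `genotype_calls` object; the number of skipped non-SNP
#'   records is in `attr(, "skipped_indels")`.
#' @export
read_vcf <- function(path, group_map) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  sample_ids <- colnames(v@gt)[-1L]
  missing_samples <- setdiff(sample_ids, names(group_map))
  if (length(missing_samples))
    stop("sample(s) absent from group_map: ",
         paste(missing_samples, collapse = ", "))
  groups <- unname(group_map[sample_ids])
  if (!all(groups %in% c("ME", "EM", "VEG")))
    stop("unknown group label in group_map")

  alt_list <- strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]), ",",
                       fixed = TRUE)
  is_snp <- nchar(fix[, "REF"]) == 1L &
    vapply(alt_list, function(a) all(nchar(a) == 1L | a == ""), TRUE) &
    fix[, "REF"] %in% BASES
  n_skipped <- sum(!is_snp)
  if (n_skipped)
    message(n_skipped, " non-SNP record(s) skipped")

  contig_len <- .vcf_contig_lengths(path)
  chroms <- unique(fix[, "CHROM"])
  for (ch in setdiff(chroms, names(contig_len)))
    contig_len[ch] <- max(as.integer(fix[fix[, "CHROM"] == ch, "POS"]))

  S <- length(sample_ids)
  blank <- function(L) list(
    a1 = matrix(0L, L, S, dimnames = list(NULL, sample_ids)),
    a2 = matrix(0L, L, S, dimnames = list(NULL, sample_ids)),
    c1 = matrix(0L, L, S), c2 = matrix(0L, L, S),
    depth = matrix(0L, L, S), nallele = matrix(0L, L, S),
    qual = matrix(0, L, S))
  contigs <- lapply(contig_len, blank)

  gt <- vcfR::extract.gt(v, "GT")
  ad <- vcfR::extract.gt(v, "AD")
  dp <- vcfR::extract.gt(v, "DP")
  gq <- vcfR::extract.gt(v, "GQ")
  for (r in which(is_snp)) {
    ch <- fix[r, "CHROM"]
    pos <- as.integer(fix[r, "POS"])
    alleles <- match(c(fix[r, "REF"],
                       alt_list[[r]][alt_list[[r]] != ""]), BASES)
    for (s in seq_len(S)) {
      g <- gt[r, s]
      d <- suppressWarnings(as.integer(dp[r, s]))
      if (!is.na(d)) contigs[[ch]]$depth[pos, s] <- d
      if (is.na(g) || g %in% c("./.", ".")) next
      idx <- as.integer(strsplit(g, "[/|]")[[1]]) + 1L
      if (length(idx) == 1L) idx <- c(idx, idx)
      b <- sort(alleles[idx])
      contigs[[ch]]$a1[pos, s] <- b[1L]
      contigs[[ch]]$a2[pos, s] <- b[2L]
      adv <- suppressWarnings(as.integer(strsplit(ad[r, s], ",")[[1]]))
      if (length(adv) >= max(idx) && !anyNA(adv)) {
        contigs[[ch]]$c1[pos, s] <- adv[idx[order(alleles[idx])][1L]]
        contigs[[ch]]$c2[pos, s] <- adv[idx[order(alleles[idx])][2L]]
      }
      contigs[[ch]]$nallele[pos, s] <- length(unique(b))
      q <- suppressWarnings(as.numeric(gq[r, s]))
      if (!is.na(q)) contigs[[ch]]$qual[pos, s] <- q
    }
  }
  samples <- data.frame(sample_id = sample_ids, mother = NA_integer_,
                        group = groups,
                        ploidy = ifelse(groups == "ME", 1L, 2L))
  out <- structure(list(contigs = contigs, samples = samples,
                        params = caller_params()),
                   class = "genotype_calls")
  attr(out, "skipped_indels") <- n_skipped
  out
}

.vcf_contig_lengths <- function(path) {
  out <- integer(0)
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    l <- readLines(con, 1L)
    if (!length(l) || !startsWith(l, "##")) break
    m <- regmatches(l, regexec("^##contig=<ID=([^,>]+),length=([0-9]+)", l))[[1]]
    if (length(m) == 3L) out[m[2L]] <- as.integer(m[3L])
  }
  out
}
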