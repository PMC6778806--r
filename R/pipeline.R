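# End-to-end orchestration: simulate -> build reference -> site evidence
# -> call -> filter -> heterozygosity statistics -> screens -> report,
# per assembly strategy, under one master seed with per-stage
# substreams.

#' Run the full PSC-assessment pipeline on simulated data
#'
#' For each requested assembly strategy, builds a reference from one
#' shared truth set, emulates mapping and sequencing, calls and filters
#' genotypes per tissue group, computes the per-transcript and
#' assembly-wide heterozygosity panel, runs the in-package screens
#' (haploid het, copy number against the truth gene set, mosaic
#' self-hits, low expression) and scores the flags against truth
#' provenance.
#'
#' @param config a [sim_config()].
#' @param strategies assembly strategies to assess.
#' @param groups tissue groups to simulate.
#' @param filter site-filter thresholds, a [filter_params()].
#' @param caller caller thresholds, a [caller_params()] (defaults to the
#'   simulated error rate).
#' @param screens run the alignment-based screens (copy number, mosaic)
#'   and the expression filter; disable for statistics-only runs.
#' @param min_callable callable-site threshold for the summary panel and
#'   the haploid-het flag.
#' @param out_dir if non-NULL, persist intermediates (reference FASTA,
#'   truth tables, per-group VCFs, per-transcript TSVs, JSON summary).
#' @param verbose log stage boundaries with record counts.
#' @return An object of class `psc_report`: the truth set, and per
#'   strategy the reference index, `assembly_summary`, per-transcript
#'   `het_stats` and `transcript_flags`, the flag-vs-truth evaluation
#'   and the stratified heterozygosity table.
#' @examples
#' \donttest{
#' rep <- run_psc_pipeline(sim_config(n_genes = 20, seed = 1),
#'                         strategies = "clustered", verbose = FALSE)
#' rep
#' }
#' @export
run_psc_pipeline <- function(config,
                             strategies = c("redundant", "clustered",
                                            "supertranscript"),
                             groups = c("ME", "EM", "VEG"),
                             filter = filter_params(), caller = NULL,
                             screens = TRUE, min_callable = 100,
                             out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  strategies <- match.arg(strategies, c("redundant", "clustered",
                                        "supertranscript"),
                          several.ok = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed (seed %d): %s",
                   name, config$seed, conditionMessage(e)), call. = FALSE))
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  say("simulate: %d genes, seed %d", config$n_genes, config$seed)
  truth <- stage("simulate", simulate_population(config))
  say("simulate: %d segregating sites, %d samples",
      sum(vapply(truth$pools, function(p) length(p$pos), 1L)),
      nrow(truth$samples))
  if (!is.null(out_dir))
    write_sim_config(config, file.path(out_dir, "config.json"))

  res <- list()
  for (strat in strategies) {
    say("reference [%s]: building", strat)
    ref <- stage("reference", build_reference(truth, strat))
    say("reference [%s]: %d contigs, %d collapsed", strat,
        nrow(ref$index), sum(ref$index$collapsed))
    ev <- stage("evidence", simulate_site_evidence(
      truth, ref, groups = groups,
      seed = derive_seed(config$seed, paste0("evidence_", strat))))
    calls <- stage("calling", call_genotypes(ev, params = caller))
    filtered <- stage("filtering", filter_sites(calls, params = filter))
    stats <- stage("hetstats", transcript_het_stats(filtered))
    summary <- summarize_ratios(stats, min_callable = min_callable)
    say("hetstats [%s]: %d contig x group rows", strat, nrow(stats))

    flags <- NULL
    strat_tab <- NULL
    if (screens) {
      hh <- flag_haploid_het(stats, min_callable = min_callable)
      gene_seqs <- lapply(truth$pools, function(p) p$anc)
      contig_chr <- lapply(ref$contigs, identity)
      hits <- stage("screen", align_to_set(contig_chr, gene_seqs))
      lens <- stats::setNames(ref$index$length, ref$index$contig_id)
      cn <- classify_copy_number(hits, lens)
      self_hits <- stage("screen", self_align_contigs(contig_chr))
      mos <- detect_mosaics(self_hits, contig_ids = ref$index$contig_id)
      prov_counts <- rowsum(
        truth$counts[ref$provenance$isoform_id, , drop = FALSE],
        ref$provenance$contig_id)
      em <- compute_tpm(prov_counts,
                        stats::setNames(ref$index$length,
                                        ref$index$contig_id)[rownames(prov_counts)])
      gene_of <- vapply(rownames(prov_counts), function(cid)
        ref$provenance$gene_id[ref$provenance$contig_id == cid][1L], "")
      le <- low_expression_filter(em, gene_ids = gene_of)
      flags <- transcript_flags(ref$index$contig_id, haploid_het = hh,
                                copy_class = cn, mosaic = mos,
                                low_expression = le)
      strat_tab <- stratify_by_flags(stats, flags)
    }
    evaluation <- if (screens)
      evaluate_against_truth(flags, ref, truth) else NULL

    if (!is.null(out_dir)) {
      write_reference_fasta(ref, file.path(out_dir,
                                           paste0("reference_", strat, ".fasta")))
      write_truth_tables(ref, file.path(out_dir, paste0("truth_", strat)))
      for (grp in groups)
        write_vcf(filtered, file.path(out_dir,
                                      sprintf("calls_%s_%s.vcf", strat, grp)),
                  reference = ref, group = grp)
      write.table(stats, file.path(out_dir, paste0("hetstats_", strat, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(flags))
        write.table(flags, file.path(out_dir, paste0("flags_", strat, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
    res[[strat]] <- list(index = ref$index, summary = summary,
                         stats = stats, flags = flags,
                         stratified = strat_tab, evaluation = evaluation)
  }
  report <- structure(list(config = config, truth = truth,
                           strategies = res),
                      class = "psc_report")
  if (!is.null(out_dir)) {
    js <- lapply(res, function(r) list(
      groups = r$summary$groups, ratios = r$summary$ratios))
    jsonlite::write_json(js, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  report
}

#' @export
print.psc_report <- function(x, ...) {
  cat(sprintf("PSC assessment report: %d genes, seed %d\n",
              x$config$n_genes, x$config$seed))
  for (strat in names(x$strategies)) {
    r <- x$strategies[[strat]]
    cat(sprintf("-- strategy '%s' (%d contigs, %d truth-collapsed)\n",
                strat, nrow(r$index), sum(r$index$collapsed)))
    print(r$summary)
    if (!is.null(r$evaluation)) {
      ev <- r$evaluation
      cat(sprintf("  haploid-het vs truth collapse: precision %s, recall %s\n",
                  .fmt_na(ev$precision[1L]), .fmt_na(ev$recall[1L])))
    }
  }
  invisible(x)
}

.fmt_na <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", x))

#' Score screening flags against simulation truth
#'
#' Scores the haploid-heterozygosity flag against the truth collapse
#' status of each contig (two or more distinct source genes in its
#' provenance) and the copy-number class against paralog-family
#' membership of the source gene(s).
#'
#' @param flags a `transcript_flags` data.frame.
#' @param reference the `psc_reference` the flags were computed on.
#' @param truth the `truth_set` behind the reference; required.
#' @return data.frame with one row per comparison (`haploid_het`,
#'   `copy_class`): counts, precision, recall and accuracy.
#' @export
evaluate_against_truth <- function(flags, reference, truth) {
  if (missing(truth) || is.null(truth) || !inherits(truth, "truth_set"))
    stop("truth set absent: evaluation requires simulation provenance")
  stopifnot(inherits(reference, "psc_reference"))
  idx <- reference$index
  m <- match(idx$contig_id, flags$contig_id)
  hh <- flags$haploid_het[m]
  truth_pos <- idx$collapsed
  assessed <- !is.na(hh)
  tp <- sum(hh[assessed] & truth_pos[assessed])
  fp <- sum(hh[assessed] & !truth_pos[assessed])
  fn <- sum(!hh[assessed] & truth_pos[assessed])
  tn <- sum(!hh[assessed] & !truth_pos[assessed])
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_

  # truth multi-copy: any source gene belongs to a paralog family
  fam <- truth$genes$family_id[match(reference$provenance$gene_id,
                                     truth$genes$gene_id)]
  multi_truth_ids <- unique(reference$provenance$contig_id[!is.na(fam)])
  cc <- as.character(flags$copy_class[m])
  assessed_cc <- cc != "unassigned"
  truth_multi <- idx$contig_id %in% multi_truth_ids
  agree <- (cc == "multi") == truth_multi
  acc <- if (any(assessed_cc)) mean(agree[assessed_cc]) else NA_real_
  tp2 <- sum(cc == "multi" & truth_multi)
  prec2 <- if (sum(cc == "multi") > 0) tp2 / sum(cc == "multi") else NA_real_
  rec2 <- if (sum(truth_multi & assessed_cc) > 0)
    tp2 / sum(truth_multi & assessed_cc) else NA_real_

  data.frame(
    comparison = c("haploid_het_vs_collapse", "copy_class_vs_family"),
    n_assessed = c(sum(assessed), sum(assessed_cc)),
    tp = c(tp, tp2), fp = c(fp, sum(cc == "multi" & !truth_multi)),
    fn = c(fn, sum(truth_multi & assessed_cc & cc != "multi")),
    tn = c(tn, NA),
    precision = c(prec, prec2), recall = c(rec, rec2),
    accuracy = c((tp + tn) / max(1, sum(assessed)), acc))
}
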