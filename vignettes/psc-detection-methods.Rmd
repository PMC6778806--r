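---
title: "Detecting paralog sequence collapse with haploid tissue: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting paralog sequence collapse with haploid tissue: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pscdetect)
```

## The diagnostic

A de novo transcriptome reference sits between two failure modes.
When the two alleles of a gene assemble into separate contigs
(*allelic redundancy*), reads are split between them and — under
unique-best mapping — windows that cannot distinguish the alleles are
discarded altogether, deflating both coverage and measured diversity.
When redundancy reduction merges distinct paralogous gene copies into
one contig (*paralog sequence collapse*, PSC), reads from different
loci co-map and the fixed differences between the copies appear as
heterozygous SNPs at roughly the paralog divergence rate.

Haploid megagametophyte (ME) tissue separates these signals. The ME
genome is a single maternal haplotype, so after diploid-mode genotype
calling any ME heterozygous call is an artifact — paralog co-mapping or
sequencing/calling error. The package contrasts ME with two diploid
genotype sets from the same six mothers: the embryo (EM, the ME
haplotype plus an unknown paternal haplotype) and the pooled vegetative
tissues (VEG, the full maternal genotype). The per-transcript panel is

* `H_o` per bp: heterozygous calls over callable site-observations,
  micro-averaged (numerators and denominators summed before dividing,
  matching a pooled per-bp presentation);
* `H_E` (π) per bp: the mean over callable sites of the per-site
  unbiased diversity `π̂ = n/(n−1)(1 − Σ p̂_k²)` from the group's pooled
  allele counts — algebraically the average pairwise difference among
  the `n` pooled alleles;
* the ratios `H_o(ME)/H_o(EM)`, `H_o(ME)/H_o(VEG)` and `H_o/H_E` per
  group.

Without collapse or error the expectations are `H_o(ME) = 0` and, under
Hardy–Weinberg equilibrium, `H_o/H_E = 1` in the diploid groups, with π
equal to the population θ. Departures are the diagnostic: ME
heterozygosity localizes collapse; diploid `H_o/H_E` well above one
indicates excess heterozygous calls from co-mapping.

## The synthetic study design

`sim_config()` / `simulate_population()` generate the full truth:

* **Population.** Each gene carries a pool of 40 haplotypes. Sites
  segregate independently with probability `θ · H(n−1)` (`H` the
  harmonic number); a segregating site draws its derived-allele count
  `i` from the neutral site frequency spectrum `P(i) ∝ 1/i`. Because a
  site with `i` derived copies contributes `2i(n−i)/(n(n−1))` pairwise
  differences and this averages to `1/H(n−1)` under the SFS, the pool's
  expected pairwise diversity per bp is exactly θ. The default
  θ = 0.0042/bp is the rough genome-wide estimate for Scots pine used
  as the diversity expectation. There is no linkage: carrier sets are
  independent across sites, which is deliberate (per-site statistics
  need no LD model) and makes Monte-Carlo error scale with total bp.
* **Paralog families.** A configurable fraction of genes (default 0.2,
  reflecting the prevalence of recent duplicates in conifer genomes)
  form two-member families; the second member is a positional copy of
  the first mutated at rate `paralog_divergence` (default 0.02 — near
  the clustering boundary, the regime where collapse actually happens).
* **Families.** Six mothers each contribute one ME (one maternal
  haplotype, chosen by a per-individual meiotic index), one EM (the ME
  haplotype plus a paternal haplotype) and one VEG genotype (the
  maternal pair). Within a gene the 18 parental chromosomes are drawn
  *without replacement* from the pool whenever it is large enough: the
  individuals are unrelated, so sampled chromosomes share no identity
  by descent. This choice also keeps individual-based estimates
  unbiased — drawing with replacement from a finite pool of `n`
  haplotypes would shrink expected diversity by `(n−1)/n` (≈ 2.5% at
  `n = 40`).
* **Expression and isoforms.** Per-gene expression is log-normal
  (default log-sd 1, a typical RNA-seq spread); most genes have one
  full-length isoform, with ~9% multi-isoform genes whose extra
  isoforms are truncations — enough structure to exercise
  SuperTranscript merging and the isoform pre-filter without a splicing
  model.

### Assembly-strategy emulation

* `redundant`: one contig per distinct expressed allele sequence per
  isoform.
* `clustered`: greedy longest-first clustering of the redundant set; a
  member joins a cluster iff its identity to the representative —
  measured over the shorter sequence, uncovered positions counting as
  mismatches — reaches `cluster_identity` (default 0.95, the standard
  CD-HIT cut-off). Only the representative is retained. A contig whose
  provenance spans two genes is *truth-collapsed* (PSC-positive).
* `supertranscript`: per gene, isoforms failing the pre-filter
  (length ≤ 300 bp or total effective count ≤ 10) are dropped, keeping
  the longest if all fail; survivors merge block-wise over the shared
  gene coordinates. An incoming isoform whose identity to the growing
  body falls below `st_merge_identity` (default 0.99) is appended as a
  new consecutive block — the mosaic failure mode, in which
  near-identical sequence is duplicated within one contig.

### Mapping emulation

Reads are emulated at the level of 150 bp windows tiled without overlap
along each source haplotype (matching 2 × 150 bp sequencing), not as
individual read pairs: the mapping contract — a window maps iff its
mismatch fraction is ≤ 0.025 and its best placement is unique, ties
being discarded — is identical, and window-level Poisson depth makes
desk-scale simulation fast. Candidate placements are restricted to
contigs sharing the gene's paralog-family coordinate space; unrelated
genes cannot pass the mismatch ceiling, so nothing is lost. Mapped
windows contribute `Poisson(mean_depth × expression share / ploidy)`
reads per position with per-base substitution errors (default 10⁻³,
Illumina-like).

## Calling and filtering

All groups are genotyped in **diploid mode**, including the haploid
megagametophytes. A ploidy-aware caller run at ploidy 1 can never emit
a heterozygous ME call, which would silence the diagnostic entirely;
diploid-mode calling for every group is therefore the one convention
under which haploid heterozygosity is observable, and it is adopted
deliberately and uniformly.

The caller retains alleles with ≥ 2 supporting reads and ≥ 20% of the
site depth (both thresholds exposed in `caller_params()`; they are this
package's own defaults). One retained allele is a
homozygote, two a heterozygote, more a multi-allelic (missing) call;
quality is the Phred-scaled likelihood ratio of the called genotype
against the best alternative under a per-read error model, with the
error rate floored at 10⁻⁴ so quality stays finite in error-free
simulations.

Site filtering follows the standard vcftools-style chain, per group
(one VCF per tissue group): observations
with depth < 10 are voided; sites with > 0.5 missing data are dropped;
polymorphic sites survive only as bi-allelic SNPs with quality > 20.
Monomorphic sites that pass depth/missingness count as callable — they
are the denominator of every per-bp statistic. VCF filtering
conventionally acts on the site-level QUAL column; this package's
caller produces per-sample qualities, so site quality is defined as the best quality among
variant-supporting calls (homozygous-reference calls cannot vouch for a
variant). Per-sample qualities travel through VCF round-trips as GQ.

π pools allele counts per site across the group's non-missing calls,
with ploidy-aware pooling: diploid calls contribute two copies, haploid
homozygotes one (a haploid het — the artifact itself — contributes both
alleles). `H_E` could equally be defined as an average of
per-individual expectations; pooling across the group is the
implemented and documented choice (it uses every non-missing allele at
a site and degrades gracefully under missingness). Sites with fewer than two pooled alleles are excluded from
both the π numerator and denominator. Transcripts with ≤ 100 callable
sites are excluded from assembly aggregates, and aggregates are
callable-weighted (micro-averaged).

## Screening rules

* **Haploid-het flag**: `H_o(ME) > 0` on transcripts with > 100
  callable sites; others are NA, never silently FALSE.
* **Copy number**: query intervals of genome hits are trimmed 10 bp per
  edge (hits ≤ 20 bp vanish and are ignored); a transcript is *multi*
  if any position is covered by ≥ 2 trimmed hits with identity
  strictly > 85%, else *single* if trimmed hits cover ≥ 50% of its
  length, else *unassigned*. The 50% coverage requirement is applied
  only to single-copy assignment, which asserts genome-wide support
  for the transcript; multi-copy needs only overlapping hits, since
  duplicated coverage is evidence regardless of how much of the
  transcript aligns.
* **Mosaics**: any self-alignment hit other than the trivial identity
  match (query interval = subject interval). There is no
  field-standard threshold for this step, so the internal aligner's
  self-hit limits (≥ 60 bp, ≥ 80% identity) are exposed parameters.
* **Organelle**: any hit with e ≤ 5e−2 and identity ≥ 80% (inclusive,
  "at least"); **contaminant**: e ≤ 1e−5 and identity ≥ 65%
  (inclusive). The multi-copy 85% rule is strict ("more than"), the
  organelle/contaminant rules inclusive ("at least").
* **Expression**: transcripts of genes with mean TPM ≤ 10 are flagged
  (strict "> 10" retention), at gene level: member transcript TPMs
  are summed within gene before averaging across samples, so a gene is
  judged by its total output rather than by its best isoform
  (isoform-level filtering would penalize genes with many moderate
  isoforms).

The internal seed-and-extend aligner (exact 11-mer seeds, per-diagonal
X-drop ungapped extension, affine-penalty chaining of collinear
segments, blastn-convention scores and e-values) exists so synthetic
contig sets can be screened without external tools; real BLAST tabular
output is consumed through the same outfmt-6 reader. Alignments are
gap-chained rather than full dynamic programming; on the no-indel
synthetic data the two coincide, and the test suite checks hits against
a Smith–Waterman oracle.

## Numerical and coordinate conventions

Internal coordinates are 1-based inclusive throughout (the natural R
indexing); VCF and BLAST tabular I/O are 1-based inclusive by
definition, so no conversion ambiguity exists at the boundaries.
Sequences are stored as integers 1:4 = A,C,G,T. N50 uses the
descending-cumulative convention (the length at which sorted contigs
first cover half the assembly); ExN50 ranks transcripts by pooled
summed counts (per-sample ExN50 is available behind a flag). Clustering
ties (equal lengths) break lexicographically by contig id; caller
allele ties break toward the lower base index. Every stage derives its
own RNG substream from the master seed, so a stage rerun in isolation
reproduces its in-pipeline stream; identical configuration and seed
give byte-identical output.

Degenerate inputs are defined, not patched: zero callable sites yield
NA statistics (never 0); ratio denominators of zero yield NA; an empty assembly or empty sequence
is an error; the isoform pre-filter never empties a gene (keep-longest
fallback).

## What the tests do and do not show

The property suite ties each stage to an independent oracle: pool
diversity to all-pairs Hamming distance, the π estimator to exact
pairwise-difference enumeration, caller output to a full
genotype-likelihood enumeration, aligner hits to Smith–Waterman, and
the collapse dose–response to a brute-force Poisson/binomial
enumeration of the caller and filter rules. The dose–response
experiment runs at θ = 0, zero error and uniform expression at depth
30 so that window mappability is deterministic from the truth sequences
and the oracle is exact; the dose is then the paralog divergence alone.
The θ-recovery experiment runs paralog-free, because collapse inflates
π by construction — that inflation being the package's subject, not its
estimator's defect. Problem sizes (500–600 genes × 1500 bp for
expectation-panel checks, 10⁵ sites × 50 diploids for the HWE ratio, 60
genes for dose–response and redundancy-direction experiments) were
chosen so Monte-Carlo standard errors sit well inside the stated
tolerances.

Two behaviors of the emulation are more extreme than their real-data
counterparts and are worth naming. First, measured π passes through the
caller, so allele dropout at marginal depth (a heterozygote's minor
allele failing the ≥ 2 count / ≥ 20% rules near the depth-10 floor)
deflates `H_o` and π by a percent or two under the default log-normal
expression spread — a genuine property of threshold-based calling, not
a bug. Second, under the fully redundant strategy every allele contig
recruits reads from at most the one or two mothers carrying that exact
haplotype, so the 0.5-missingness filter leaves *no* callable sites:
complete redundancy annihilates measurable diversity, where the
partially redundant assemblies of real data merely deflate it.

## Limitations

The generator emulates SNP variation only (no indels, MNPs or
structural variation — the emulated calling setup excluded them
anyway), no linkage disequilibrium, no splice-graph realism beyond
truncation isoforms, no read-level FASTQ output, and window-level
rather than read-level mapping. Contaminant and organelle screens
consume alignment tables; no protein-space search is performed.
Passing tests therefore validate the statistical machinery and the
filtering cascade, not the behavior of any particular assembler or
aligner on real reads.
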