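Package: pscdetect
Title: Ploidy-Informed Detection of Paralog Sequence Collapse in De Novo
    Transcriptome References
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Diagnoses paralog sequence collapse (PSC) in de novo assembled
    transcriptome references by contrasting genotype calls from haploid
    (megagametophyte) and diploid (embryo, vegetative) tissues of the same
    conifer seed families. A haploid genome cannot be heterozygous, so
    heterozygous calls from haploid reads flag contigs where reads from
    distinct paralogous loci co-map. The package provides a calibrated
    population simulator (neutral site-frequency-spectrum haplotype pools,
    two-member paralog families, megagametophyte/embryo/vegetative family
    design), emulation of assembly strategies (redundant, identity
    clustering, SuperTranscript merging) and of unique-best read mapping
    with a mismatch ceiling, a depth-aware genotype caller with the
    depth/missingness/quality site filters, per-transcript observed and
    expected heterozygosity (nucleotide diversity) over callable sites,
    copy-number/mosaic/organelle/contaminant screens driven by alignment
    hits, and assembly expression statistics (TPM, N50, ExN50).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
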