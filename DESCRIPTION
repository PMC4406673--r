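Package: isoShift
Title: Detection of Genotype-Dependent 3' Length Shifts in Small RNA Isoforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting 3' end length changes in small RNA
    populations (piRNAs, endo-siRNAs, miRNAs) across genotypes from
    aligned small RNA sequencing reads. Reads are grouped by locus and
    5' start position, per-length read fractions are compared between
    each mutant genotype and a wild-type reference with a pooled
    two-proportion t statistic using read-count degrees of freedom,
    calls are gated by Benjamini-Hochberg FDR and Cohen's d, and a
    five-genotype concordance rule (null and catalytically dead rescue
    shift up; heterozygote and wild-type rescue do not) classifies loci
    whose 3' trimming depends on the Nibbler exonuclease. Includes a
    miRNA most-abundant-isoform ratio analysis and a synthetic read
    generator that emulates exonucleolytic 3' trimming with ground
    truth labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'io-write.R'
    'profiles.R'
    'stats.R'
    'classify.R'
    'io-alignments.R'
    'io-annotations.R'
    'mirna.R'
    'pipeline.R'
    'simulate.R'
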