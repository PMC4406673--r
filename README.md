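# isoShift

Detection of genotype-dependent 3′ length shifts in small RNA isoforms
from aligned small RNA sequencing libraries.

Many small RNAs — piRNAs in particular — are matured by 3′-to-5′
exonucleolytic trimming (by Nibbler/Nbr in *Drosophila*). Loss of the
trimmer does not change how many reads a locus produces; it changes
*how long* they are: reads sharing a 5′ start position accumulate at
longer lengths. `isoShift` is for groups analysing the standard
five-genotype rescue design (wild-type, deficiency/+ heterozygote,
null, wild-type rescue, catalytically dead rescue) who want to know
which loci depend on the trimmer.

## The method

Filtered reads (unique, 0 mismatches, 19–31 nt) are grouped by
(locus, strand, 5′ start, length). For each length *L* at a start, the
fraction of reads of that length is compared between a mutant genotype
and wild-type with the pooled two-proportion statistic

&nbsp;&nbsp;&nbsp;&nbsp;*t* = (f₁ − f₂) / √( p̄(1−p̄)(1/n₁ + 1/n₂) ),&nbsp;&nbsp; p̄ = (k₁+k₂)/(n₁+n₂),

referred to a Student t distribution with the sum total of reads
(n₁ + n₂) as degrees of freedom. P-values are Benjamini–Hochberg
adjusted per comparison, and peaks are called where q ≤ 0.05 and
Cohen's d ≥ 0.6. A locus is **trimmer-affected** when, for at least one
(start, length) pair with length above the wild-type modal length at
that start, the fraction shifted up in *both* the null and the
catalytically dead rescue and in *neither* the heterozygote nor the
wild-type rescue. A companion miRNA module reports, per mature arm, the
null/wild-type ratio of the most-abundant-isoform fraction (arms with
> 70 raw anchor reads in both genotypes).

A synthetic-data generator (`simulateExperiment()`) emulates the whole
design — per-start precursor length distributions, Bernoulli trimming
with geometric trim sizes, genotype structure, library-size jitter —
with ground-truth labels, so the complete pipeline is testable at desk
scale.

## Worked example

```r
library(isoShift)

cfg <- simConfig(nLoci = 60L, depth = 2e4, nMirna = 5L, mirnaDepth = 5e3)
sim <- simulateExperiment(cfg, seed = 1)
ana <- runTrimmingAnalysis(sim$reads, sim$loci, sim$librarySizes,
                           mirna = sim$mirna)
ana$results
#> LengthShiftResults: 6006 length-fraction tests (pooled SE, reference wild_type)
#>   significant peaks at FDR <= 0.05, d >= 0.6: 93 up, 7 down
ana$summary
#>   class n_input n_eligible n_affected pct_affected
#> 1 piRNA      60         60         15           25

calls <- locusCalls(ana$calls)
truth <- sim$truth$loci
table(called = calls$affected[match(truth$locus_id, calls$locus_id)],
      planted = truth$affected)
#>        planted
#> called  FALSE TRUE
#>   FALSE    45    0
#>   TRUE      0   15
```

All 6,006 tests compare one length's read fraction at one (locus,
start) between a mutant and wild-type; 15 of 60 loci carry at least one
concordant upward shift of a long isoform and are called affected —
here exactly the 15 loci the generator planted as trimmer-dependent
(affected fraction 0.25 of eligible loci, the `pct_affected` column).

The same analysis runs file-to-file from a five-library manifest with
`runPipeline(manifest, loci.bed, outDir, mirnaGff = ...)`, writing
deterministic TSVs (`shift_tests.tsv`, `locus_calls.tsv`,
`call_summary.tsv`, `mirna_ratios.tsv`, …) and a run report.

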