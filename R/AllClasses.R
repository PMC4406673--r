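#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData
NULL

#' Genotype labels used throughout the package
#'
#' The five-genotype design contrasts a wild-type reference against a
#' deficiency heterozygote (`def_het`), the nbr null (`null`), a wild-type
#' genomic rescue of the null (`rescue_wt`) and a catalytically dead rescue
#' (`rescue_catdead`). Genotypes with functional Nibbler exonuclease
#' activity are `wild_type`, `def_het` and `rescue_wt`.
#'
#' @return `isoShiftGenotypes()` returns the five genotype labels in their
#'   canonical order; `functionalGenotypes()` returns the subset with
#'   active 3' trimming.
#' @examples
#' isoShiftGenotypes()
#' @export
isoShiftGenotypes <- function() {
  c("wild_type", "def_het", "null", "rescue_wt", "rescue_catdead")
}

#' @rdname isoShiftGenotypes
#' @export
functionalGenotypes <- function() {
  c("wild_type", "def_het", "rescue_wt")
}

## size window retained after read filtering (nt)
MIN_READ_LENGTH <- 19L
MAX_READ_LENGTH <- 31L

#' IsoformExperiment: per-isoform small RNA counts across genotypes
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding collapsed
#' read counts indexed by small RNA isoform. Each row is one
#' (locus, strand, 5' start, length) combination; each column is one
#' sequenced library (genotype). `rowData()` carries `locus_id`, `strand`,
#' `start5` (1-based, strand-aware position of the 5'-most nucleotide) and
#' `length` (nt, restricted to 19-31 after filtering). `colData()` carries
#' `genotype` and `library_size` (total reads in the library after adapter
#' trimming, the depth-normalisation denominator).
#'
#' @export
setClass("IsoformExperiment", contains = "SummarizedExperiment")

setValidity("IsoformExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% names(assays(object)))
    msg <- c(msg, "assay 'counts' is required")
  rd <- rowData(object)
  need <- c("locus_id", "strand", "start5", "length")
  if (!all(need %in% names(rd)))
    msg <- c(msg, sprintf("rowData must contain %s",
                          paste(need, collapse = ", ")))
  cd <- colData(object)
  if (!all(c("genotype", "library_size") %in% names(cd)))
    msg <- c(msg, "colData must contain 'genotype' and 'library_size'")
  if (length(msg))
    return(msg)
  cts <- assay(object, "counts")
  if (any(cts < 0) || any(cts != round(cts)))
    msg <- c(msg, "counts must be non-negative integers")
  if (any(rd$length < MIN_READ_LENGTH | rd$length > MAX_READ_LENGTH))
    msg <- c(msg, sprintf("isoform lengths must lie in %d..%d nt",
                          MIN_READ_LENGTH, MAX_READ_LENGTH))
  if (any(rd$start5 < 1))
    msg <- c(msg, "start5 must be >= 1 (1-based coordinates)")
  if (any(cd$library_size <= 0))
    msg <- c(msg, "library_size must be positive")
  if (anyDuplicated(cd$genotype))
    msg <- c(msg, "duplicated genotype columns")
  if (length(msg)) msg else TRUE
})

#' Results of per-isoform length-fraction tests
#'
#' Container for the per-(locus, start, length, genotype) comparisons of
#' length fractions against the wild-type reference. The underlying table
#' (accessible with [shiftResults()]) has one row per test with the observed
#' and reference fractions, read totals, the t statistic, read-count degrees
#' of freedom, two-sided P-value, BH-adjusted q-value, Cohen's d and the
#' peak direction call (`up`, `down` or `none`).
#'
#' @slot results `DataFrame` of test rows.
#' @slot reference character, the reference genotype.
#' @slot statistic `"pooled"` or `"one_sample"` standard error form.
#' @slot alpha FDR threshold used for direction calls.
#' @slot dMin Cohen's d threshold used for direction calls.
#' @slot fdrFamily `"per_comparison"` or `"global"` BH family.
#' @slot minTotal locus expression filter threshold.
#' @slot minStartReads per-start read floor in each compared library.
#' @export
setClass("LengthShiftResults",
         representation(results = "DataFrame",
                        reference = "character",
                        statistic = "character",
                        alpha = "numeric",
                        dMin = "numeric",
                        fdrFamily = "character",
                        minTotal = "numeric",
                        minStartReads = "numeric"))

setValidity("LengthShiftResults", function(object) {
  res <- object@results
  need <- c("locus_id", "strand", "start5", "length", "genotype",
            "k_obs", "n_obs", "k_ref", "n_ref", "f_obs", "f_ref",
            "t", "df", "p", "q", "d", "direction")
  if (!all(need %in% names(res)))
    return(sprintf("results must contain columns: %s",
                   paste(setdiff(need, names(res)), collapse = ", ")))
  if (nrow(res)) {
    if (any(res$p < 0 | res$p > 1)) return("p outside [0,1]")
    if (any(res$q < 0 | res$q > 1)) return("q outside [0,1]")
    if (any(res$df != res$n_obs + res$n_ref))
      return("df must equal n_obs + n_ref")
  }
  TRUE
})

#' Per-locus verdicts from the five-genotype trimming rule
#'
#' Holds one row per input locus (accessor [locusCalls()]) with its
#' eligibility status and the affected/not-affected verdict, plus the table
#' of supporting (start, length) pairs (accessor [supportingPairs()]) that
#' satisfied the concordance rule: significant upward shift in both the
#' null and the catalytically dead rescue, and no upward shift in the
#' heterozygote or the wild-type rescue, at the same start and length.
#'
#' @slot calls `DataFrame`, one row per locus.
#' @slot supporting `DataFrame`, one row per supporting (start, length) pair.
#' @slot thresholds list of thresholds the calls were made under.
#' @export
setClass("LocusCalls",
         representation(calls = "DataFrame",
                        supporting = "DataFrame",
                        thresholds = "list"))

setValidity("LocusCalls", function(object) {
  calls <- object@calls
  need <- c("locus_id", "class", "eligible", "reason", "affected",
            "n_supporting")
  if (!all(need %in% names(calls)))
    return(sprintf("calls must contain columns: %s",
                   paste(setdiff(need, names(calls)), collapse = ", ")))
  if (any(calls$affected & !calls$eligible))
    return("affected loci must be eligible")
  if (any(calls$affected & calls$n_supporting < 1))
    return("affected loci must have at least one supporting pair")
  TRUE
})

#' miRNA hairpin and mature-arm annotation
#'
#' Genomic intervals of miRNA hairpins (primary transcripts) and their
#' mature arms, with each arm linked to its hairpin and labelled `5p` or
#' `3p` by proximity to the hairpin 5' end.
#'
#' @slot hairpins `GRanges` with `mirna_id` metadata column.
#' @slot matures `GRanges` with `mirna_id`, `hairpin_id` and `arm` columns.
#' @export
setClass("MirnaAnnotation",
         representation(hairpins = "GRanges", matures = "GRanges"))

setValidity("MirnaAnnotation", function(object) {
  if (!"mirna_id" %in% names(mcols(object@hairpins)))
    return("hairpins need an mirna_id column")
  mm <- mcols(object@matures)
  if (!all(c("mirna_id", "hairpin_id", "arm") %in% names(mm)))
    return("matures need mirna_id, hairpin_id and arm columns")
  if (length(object@matures) && !all(mm$arm %in% c("5p", "3p")))
    return("arm must be '5p' or '3p'")
  if (length(object@matures) &&
      !all(mm$hairpin_id %in% mcols(object@hairpins)$mirna_id))
    return("every mature arm must reference an annotated hairpin")
  TRUE
})

#' Simulation configuration for the trimming read generator
#'
#' Parameters of the synthetic small RNA library generator. The generator
#' plants `nLoci` piRNA-like loci, each with a few 5' start positions, and
#' draws reads whose untrimmed precursor 3' ends follow
#' `precursorProbs` over 19-31 nt. In genotypes with functional Nibbler
#' (or at loci whose trimming is not Nibbler-dependent) each read is
#' trimmed with probability `trimRate` by a truncated-geometric number of
#' nucleotides (1..`trimMaxSize`, success probability `trimGeomProb`,
#' floored at 19 nt). miRNA-like hairpins are generated analogously with
#' their own precursor distribution and (stronger) trimming rate.
#'
#' @export
setClass("SimConfig",
         representation(nLoci = "integer",
                        startsPerLocus = "integer",
                        locusWidth = "integer",
                        locusGap = "integer",
                        chromLength = "numeric",
                        precursorProbs = "numeric",
                        trimRate = "numeric",
                        trimGeomProb = "numeric",
                        trimMaxSize = "integer",
                        trimFloor = "integer",
                        affectedFraction = "numeric",
                        depth = "numeric",
                        libraryJitter = "numeric",
                        startWeightShape = "numeric",
                        nMirna = "integer",
                        mirnaDepth = "numeric",
                        mirnaPrecursorProbs = "numeric",
                        mirnaTrimRate = "numeric",
                        mirnaAffectedFraction = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- character()
  chkProb <- function(p, what) {
    if (abs(sum(p) - 1) > 1e-8 || any(p < 0))
      sprintf("%s must be a probability vector over 19..31", what)
    else if (!identical(as.integer(names(p)), 19:31))
      sprintf("%s must be named by lengths 19..31", what)
    else character()
  }
  msg <- c(msg, chkProb(object@precursorProbs, "precursorProbs"),
           chkProb(object@mirnaPrecursorProbs, "mirnaPrecursorProbs"))
  for (r in c(object@trimRate, object@mirnaTrimRate,
              object@affectedFraction, object@mirnaAffectedFraction))
    if (r < 0 || r > 1) msg <- c(msg, "rates/fractions must be in [0,1]")
  if (object@trimGeomProb <= 0 || object@trimGeomProb >= 1)
    msg <- c(msg, "trimGeomProb must be in (0,1)")
  if (object@depth <= 0) msg <- c(msg, "depth must be positive")
  if (object@nLoci < 0) msg <- c(msg, "nLoci must be >= 0")
  if (length(object@startsPerLocus) != 2 ||
      any(object@startsPerLocus < 1) ||
      object@startsPerLocus[1] > object@startsPerLocus[2])
    msg <- c(msg, "startsPerLocus must be an increasing range of >= 1")
  if (length(object@libraryJitter) != 2 ||
      any(object@libraryJitter <= 0) ||
      object@libraryJitter[1] > object@libraryJitter[2])
    msg <- c(msg, "libraryJitter must be a positive increasing range")
  if (object@trimFloor < MIN_READ_LENGTH)
    msg <- c(msg, "trimFloor below the 19 nt window")
  if (length(msg)) msg else TRUE
})
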