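#' @include AllClasses.R
NULL

#' Accessors for isoShift result containers
#'
#' `isoCounts()` returns the isoform count matrix of an
#' [IsoformExperiment]; `genotypes()` its column genotypes;
#' `librarySizes()` the per-library depth-normalisation totals;
#' `shiftResults()` the per-test table of a [LengthShiftResults];
#' `locusCalls()` and `supportingPairs()` the per-locus verdicts and the
#' supporting (start, length) pairs of a [LocusCalls] object.
#'
#' @param x an isoShift container.
#' @return A matrix (`isoCounts`), character vector (`genotypes`), named
#'   numeric vector (`librarySizes`) or `DataFrame` (the rest).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("isoCounts", function(x) standardGeneric("isoCounts"))

#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname accessors
#' @export
setGeneric("librarySizes", function(x) standardGeneric("librarySizes"))

#' @rdname accessors
#' @export
setGeneric("shiftResults", function(x) standardGeneric("shiftResults"))

#' @rdname accessors
#' @export
setGeneric("locusCalls", function(x) standardGeneric("locusCalls"))

#' @rdname accessors
#' @export
setGeneric("supportingPairs", function(x) standardGeneric("supportingPairs"))

#' @rdname accessors
#' @export
setMethod("isoCounts", "IsoformExperiment", function(x) assay(x, "counts"))

#' @rdname accessors
#' @export
setMethod("genotypes", "IsoformExperiment",
          function(x) as.character(colData(x)$genotype))

#' @rdname accessors
#' @export
setMethod("librarySizes", "IsoformExperiment", function(x) {
  setNames(as.numeric(colData(x)$library_size),
           as.character(colData(x)$genotype))
})

#' @rdname accessors
#' @export
setMethod("shiftResults", "LengthShiftResults", function(x) x@results)

#' @rdname accessors
#' @export
setMethod("locusCalls", "LocusCalls", function(x) x@calls)

#' @rdname accessors
#' @export
setMethod("supportingPairs", "LocusCalls", function(x) x@supporting)

setMethod("show", "IsoformExperiment", function(object) {
  rd <- rowData(object)
  cat("IsoformExperiment with", nrow(object), "isoforms across",
      ncol(object), "libraries\n")
  if (nrow(object)) {
    cat("  loci:", length(unique(rd$locus_id)),
        " 5' starts:", length(unique(paste(rd$locus_id, rd$strand,
                                           rd$start5))),
        " lengths:", paste(range(rd$length), collapse = "-"), "nt\n")
  }
  cat("  genotypes:", paste(genotypes(object), collapse = ", "), "\n")
})

setMethod("show", "LengthShiftResults", function(object) {
  res <- object@results
  cat("LengthShiftResults:", nrow(res), "length-fraction tests",
      sprintf("(%s SE, reference %s)\n", object@statistic,
              object@reference))
  if (nrow(res)) {
    up <- sum(res$direction == "up")
    dn <- sum(res$direction == "down")
    cat(sprintf("  significant peaks at FDR <= %g, d >= %g: %d up, %d down\n",
                object@alpha, object@dMin, up, dn))
  }
})

setMethod("show", "LocusCalls", function(object) {
  calls <- object@calls
  cat("LocusCalls:", nrow(calls), "loci;",
      sum(calls$eligible), "eligible;",
      sum(calls$affected), "called trimming-affected\n")
})

setMethod("show", "MirnaAnnotation", function(object) {
  cat("MirnaAnnotation:", length(object@hairpins), "hairpins,",
      length(object@matures), "mature arms\n")
})

#' @rdname MirnaAnnotation-class
#' @param x a `MirnaAnnotation`.
#' @aliases hairpins matures
#' @export
hairpins <- function(x) x@hairpins

#' @rdname MirnaAnnotation-class
#' @export
matures <- function(x) x@matures
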