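#' @include AllClasses.R stats.R classify.R mirna.R
NULL

#' Analysis thresholds and options
#'
#' Bundles the tunable analysis settings: the FDR threshold `alpha`
#' (default 0.05), the Cohen's d gate `dMin` (default 0.6), the locus
#' expression filter `minTotal` (default 5 reads), the per-start read
#' floor `minStartReads` (default 2), the miRNA anchor raw-read filter
#' `minReadsMirna` (default 70, strict), the standard error form and the
#' BH family.
#'
#' @param alpha FDR threshold.
#' @param dMin Cohen's d threshold.
#' @param minTotal locus expression filter.
#' @param minStartReads per-start read floor.
#' @param minReadsMirna miRNA anchor read filter.
#' @param statistic `"pooled"` or `"one_sample"`.
#' @param fdrFamily `"per_comparison"` or `"global"`.
#' @return Named list of settings.
#' @export
pipelineConfig <- function(alpha = 0.05, dMin = 0.6, minTotal = 5,
                           minStartReads = 2, minReadsMirna = 70,
                           statistic = "pooled",
                           fdrFamily = "per_comparison") {
  stopifnot(alpha > 0, dMin >= 0, minTotal > 0, minStartReads > 0,
            minReadsMirna >= 0)
  list(alpha = alpha, dMin = dMin, minTotal = minTotal,
       minStartReads = minStartReads, minReadsMirna = minReadsMirna,
       statistic = match.arg(statistic, c("pooled", "one_sample")),
       fdrFamily = match.arg(fdrFamily, c("per_comparison", "global")))
}

#' Run the length-shift analysis on in-memory objects
#'
#' The object-level pipeline behind [runPipeline()]: builds the isoform
#' table, applies the expression filter, computes all length-fraction
#' tests against wild-type, classifies loci with the five-genotype rule
#' and summarises the calls. Optionally runs the miRNA ratio analysis.
#'
#' @param readsList named list of filtered read `GRanges`, one per
#'   genotype (all five for classification).
#' @param loci locus `GRanges` (see [readLocusBed()]).
#' @param librarySizes named per-library totals for normalisation.
#' @param config a [pipelineConfig()] list.
#' @param mirna optional [MirnaAnnotation] for the ratio analysis.
#' @param verbose log stage counts.
#' @return List with `ise` ([IsoformExperiment]), `status` (expression
#'   filter table), `results` ([LengthShiftResults]), `calls`
#'   ([LocusCalls]), `summary` (per-class counts) and `mirnaRatios`
#'   (or NULL).
#' @export
runTrimmingAnalysis <- function(readsList, loci, librarySizes,
                                config = pipelineConfig(), mirna = NULL,
                                verbose = FALSE) {
  ise <- buildIsoformTable(readsList, loci, librarySizes,
                           verbose = verbose)
  status <- expressionFilter(ise, minTotal = config$minTotal)
  results <- lengthShiftTests(ise, reference = "wild_type",
                              statistic = config$statistic,
                              alpha = config$alpha, dMin = config$dMin,
                              minTotal = config$minTotal,
                              minStartReads = config$minStartReads,
                              fdrFamily = config$fdrFamily)
  calls <- classifyLoci(results, ise, loci = loci)
  summ <- summarizeCalls(calls)
  mr <- NULL
  if (!is.null(mirna)) {
    iso <- buildMirnaIsoforms(readsList, mirna, verbose = verbose)
    mr <- mirnaRatios(iso, minReads = config$minReadsMirna)
  }
  list(ise = ise, status = status, results = results, calls = calls,
       summary = summ, mirnaRatios = mr)
}

#' Run the full file-to-file pipeline
#'
#' End-to-end orchestration: reads the five libraries named in the
#' manifest, applies the read filters, runs the length-shift analysis
#' and the optional miRNA ratio analysis, and writes deterministic TSV
#' result tables plus a machine-readable run report to `outDir`.
#' Identical inputs and settings produce byte-identical outputs. On any
#' stage error, partially written outputs are removed.
#'
#' Outputs: `isoform_counts.tsv`, `expression_status.tsv`,
#' `shift_tests.tsv`, `locus_calls.tsv`, `supporting_pairs.tsv`,
#' `call_summary.tsv`, `mirna_ratios.tsv` (when annotations are given)
#' and `run_report.txt`.
#'
#' @param manifestPath library manifest (see [readLibraryManifest()]).
#' @param lociBed locus annotation BED.
#' @param outDir output directory, created if needed.
#' @param mirnaGff optional miRNA GFF3.
#' @param lociClass class label for the locus annotations.
#' @param config a [pipelineConfig()] list.
#' @param filters a [readFilters()] list.
#' @param verbose log stage progress.
#' @return Invisibly, the [runTrimmingAnalysis()] result list.
#' @export
runPipeline <- function(manifestPath, lociBed, outDir, mirnaGff = NULL,
                        lociClass = "piRNA", config = pipelineConfig(),
                        filters = readFilters(), verbose = TRUE) {
  written <- character()
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  manifest <- stage("manifest", readLibraryManifest(manifestPath))
  loci <- stage("annotations", readLocusBed(lociBed, class = lociClass))
  mirna <- if (!is.null(mirnaGff))
    stage("annotations", readMirnaGff(mirnaGff)) else NULL
  readsList <- stage("alignments", {
    rl <- lapply(seq_len(nrow(manifest)), function(i)
      readAlignments(manifest$path[i], manifest$format[i],
                     filters = filters, verbose = verbose))
    names(rl) <- manifest$genotype
    rl
  })
  librarySizes <- setNames(manifest$total_reads, manifest$genotype)
  ana <- stage("analysis",
               runTrimmingAnalysis(readsList, loci, librarySizes,
                                   config = config, mirna = mirna,
                                   verbose = verbose))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) {
    p <- file.path(outDir, f)
    written <<- c(written, p)
    p
  }
  stage("write", {
    writeIsoformTable(ana$ise, out("isoform_counts.tsv"))
    writeResultTable(ana$status, out("expression_status.tsv"))
    writeResultTable(shiftResults(ana$results), out("shift_tests.tsv"))
    writeResultTable(locusCalls(ana$calls), out("locus_calls.tsv"))
    writeResultTable(supportingPairs(ana$calls),
                     out("supporting_pairs.tsv"))
    writeResultTable(ana$summary, out("call_summary.tsv"))
    if (!is.null(ana$mirnaRatios))
      writeResultTable(ana$mirnaRatios, out("mirna_ratios.tsv"))
    .writeRunReport(out("run_report.txt"), manifest, readsList, ana,
                    config, filters)
  })
  ok <- TRUE
  invisible(ana)
}

.writeRunReport <- function(path, manifest, readsList, ana, config,
                            filters) {
  kv <- function(k, v) sprintf("%s\t%s", k, paste(v, collapse = ","))
  lines <- c(
    kv("alpha", config$alpha), kv("d_min", config$dMin),
    kv("min_total", config$minTotal),
    kv("min_start_reads", config$minStartReads),
    kv("min_reads_mirna", config$minReadsMirna),
    kv("statistic_form", config$statistic),
    kv("fdr_family", config$fdrFamily),
    kv("filter_length", paste0(filters$minLength, "-", filters$maxLength)),
    kv("filter_max_mismatches", filters$maxMismatches),
    kv("filter_unique_only", filters$uniqueOnly))
  for (g in names(readsList)) {
    fc <- metadata(readsList[[g]])$filter_counts
    lines <- c(lines,
               kv(paste0("library_total_", g),
                  manifest$total_reads[manifest$genotype == g]),
               kv(paste0("reads_input_", g), fc["input"]),
               kv(paste0("reads_retained_", g), fc["retained"]),
               kv(paste0("reads_discarded_", g),
                  fc["input"] - fc["retained"]))
  }
  calls <- locusCalls(ana$calls)
  lines <- c(lines,
             kv("loci_input", nrow(calls)),
             kv("loci_eligible", sum(calls$eligible)),
             kv("loci_ineligible", sum(!calls$eligible)),
             kv("loci_affected", sum(calls$affected)),
             kv("tests_total", nrow(shiftResults(ana$results))),
             kv("peaks_up",
                sum(shiftResults(ana$results)$direction == "up")),
             kv("peaks_down",
                sum(shiftResults(ana$results)$direction == "down")))
  writeLines(lines, path)
  invisible(path)
}
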