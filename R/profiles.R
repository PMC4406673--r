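#' @include AllClasses.R io-write.R
NULL

#' Assign filtered reads to annotated loci
#'
#' A read belongs to a locus when its 5'-end coordinate (strand-aware)
#' lies inside the locus interval; read strand must match the locus
#' strand when the locus is stranded and is ignored for unstranded (`*`)
#' dual-strand clusters. Reads whose 3' ends overhang the locus boundary
#' are still assigned, so 3'-extended isoforms never drop out of their
#' locus. Reads matching no locus and reads assigned to several
#' overlapping loci are counted and logged, not errors.
#'
#' @param reads filtered read `GRanges` (see [readAlignments()]).
#' @param loci locus `GRanges` from [readLocusBed()].
#' @param verbose log assignment counts.
#' @return `GRanges` of assigned reads (duplicated when a read hits
#'   several loci) with a `locus_id` metadata column;
#'   `metadata()$assign_counts` holds input/assigned/unassigned/multi
#'   tallies.
#' @export
assignReadsToLoci <- function(reads, loci, verbose = TRUE) {
  stopifnot(is(reads, "GRanges"), is(loci, "GRanges"))
  fp <- GRanges(seqnames(reads),
                IRanges(fivePrimeStart(reads), width = 1L),
                strand = strand(reads))
  hits <- findOverlaps(fp, loci, ignore.strand = FALSE)
  nhit <- tabulate(S4Vectors::queryHits(hits), length(reads))
  out <- reads[S4Vectors::queryHits(hits)]
  mcols(out)$locus_id <- mcols(loci)$locus_id[S4Vectors::subjectHits(hits)]
  counts <- c(input = length(reads),
              assigned = sum(nhit > 0),
              unassigned = sum(nhit == 0),
              multi_locus = sum(nhit > 1))
  if (verbose)
    message(sprintf(
      "assignReadsToLoci: %d reads, %d assigned (%d to multiple loci), %d outside all loci",
      counts["input"], counts["assigned"], counts["multi_locus"],
      counts["unassigned"]))
  metadata(out)$assign_counts <- counts
  out
}

#' Build the per-isoform count table
#'
#' Aggregates assigned reads (weighted by their collapsed-read
#' multiplicity) into counts indexed by (locus, strand, 5' start, length)
#' for each genotype library. Keys observed in any library are
#' zero-filled in all others. For unstranded clusters the two strands are
#' tracked separately, so a (start5, strand) pair is a distinct key.
#'
#' @param readsList named list of filtered read `GRanges`, one per
#'   genotype (names are genotype labels).
#' @param loci locus `GRanges`.
#' @param librarySizes named numeric vector of per-library total read
#'   counts after adapter trimming (same names as `readsList`).
#' @param verbose log assignment counts.
#' @return An [IsoformExperiment].
#' @export
buildIsoformTable <- function(readsList, loci, librarySizes,
                              verbose = TRUE) {
  stopifnot(is.list(readsList), length(readsList) >= 1,
            !is.null(names(readsList)),
            all(names(readsList) %in% isoShiftGenotypes()))
  if (!all(names(readsList) %in% names(librarySizes)))
    stop("librarySizes must cover every genotype in readsList")
  if (any(librarySizes[names(readsList)] <= 0))
    stop("library sizes must be positive")
  gts <- intersect(isoShiftGenotypes(), names(readsList))
  keyed <- lapply(gts, function(g) {
    asg <- assignReadsToLoci(readsList[[g]], loci, verbose = verbose)
    if (!length(asg))
      return(data.frame(key = character(), count = integer()))
    key <- paste(mcols(asg)$locus_id, as.character(strand(asg)),
                 fivePrimeStart(asg), width(asg), sep = "\r")
    agg <- rowsum(as.numeric(mcols(asg)$copies), key)
    data.frame(key = rownames(agg), count = as.integer(agg[, 1]),
               stringsAsFactors = FALSE)
  })
  names(keyed) <- gts
  ukey <- unique(unlist(lapply(keyed, `[[`, "key"), use.names = FALSE))
  if (!length(ukey)) {
    cts <- matrix(0L, 0, length(gts), dimnames = list(NULL, gts))
    rd <- DataFrame(locus_id = character(), strand = character(),
                    start5 = integer(), length = integer())
    return(.newIsoformExperiment(cts, rd, librarySizes[gts]))
  }
  cts <- matrix(0L, length(ukey), length(gts),
                dimnames = list(NULL, gts))
  for (g in gts) {
    k <- keyed[[g]]
    cts[match(k$key, ukey), g] <- k$count
  }
  parts <- strsplit(ukey, "\r", fixed = TRUE)
  rd <- DataFrame(locus_id = vapply(parts, `[`, "", 1),
                  strand = vapply(parts, `[`, "", 2),
                  start5 = as.integer(vapply(parts, `[`, "", 3)),
                  length = as.integer(vapply(parts, `[`, "", 4)))
  .newIsoformExperiment(cts, rd, librarySizes[gts])
}

#' Depth-normalised abundance
#'
#' Reads-per-million normalisation: `count / libraryTotal * 1e6`. Used to
#' compare locus abundances between libraries of different depth.
#'
#' @param counts numeric vector of read counts.
#' @param libraryTotal total small RNA reads in the library after
#'   adapter trimming; must be positive.
#' @return Numeric vector of RPM values.
#' @examples
#' normalizeDepth(50, 1e6)   # 50 RPM
#' @export
normalizeDepth <- function(counts, libraryTotal) {
  if (length(libraryTotal) != 1 || is.na(libraryTotal) || libraryTotal <= 0)
    stop("libraryTotal must be a single positive number")
  counts / libraryTotal * 1e6
}

#' Per-locus abundance across genotypes
#'
#' Sums isoform counts per locus and, by default, converts them to
#' reads-per-million with each library's total.
#'
#' @param ise an [IsoformExperiment].
#' @param normalized return RPM (default) or raw summed counts.
#' @return Matrix of loci x genotypes.
#' @export
locusTotals <- function(ise, normalized = TRUE) {
  stopifnot(is(ise, "IsoformExperiment"))
  rd <- rowData(ise)
  if (!nrow(ise))
    return(matrix(0, 0, ncol(ise), dimnames = list(NULL, genotypes(ise))))
  tot <- rowsum(isoCounts(ise), rd$locus_id)
  if (normalized) {
    ls <- librarySizes(ise)
    tot <- sweep(tot, 2, ls[colnames(tot)], "/") * 1e6
  }
  tot
}

#' Locus expression filter
#'
#' A locus enters the length-shift analysis only when it is (i) expressed
#' (>= 1 read) in every genotype, (ii) comprised of reads from two or
#' more length categories within 19-31 nt, and (iii) supported by a total
#' read count of at least `minTotal` in at least one genotype. Adding
#' reads can never make an eligible locus ineligible.
#'
#' @param ise an [IsoformExperiment] with all five genotypes.
#' @param minTotal minimum total read count in the best genotype
#'   (default 5).
#' @return `DataFrame` with columns `locus_id`, `eligible` and `reason`
#'   (`ok`, `not_expressed_all_genotypes`, `single_length_category` or
#'   `below_min_reads`).
#' @export
expressionFilter <- function(ise, minTotal = 5) {
  stopifnot(is(ise, "IsoformExperiment"))
  rd <- rowData(ise)
  loci <- unique(rd$locus_id)
  if (!length(loci))
    return(DataFrame(locus_id = character(), eligible = logical(),
                     reason = character()))
  tot <- rowsum(isoCounts(ise), rd$locus_id)          # loci x genotypes
  tot <- tot[loci, , drop = FALSE]
  expressed_all <- apply(tot >= 1, 1, all)
  nlen <- vapply(split(rd$length[rowSums(isoCounts(ise)) > 0],
                       rd$locus_id[rowSums(isoCounts(ise)) > 0]),
                 function(x) length(unique(x)), integer(1))
  nlen <- setNames(nlen[loci], loci)
  nlen[is.na(nlen)] <- 0L
  enough <- apply(tot, 1, max) >= minTotal
  reason <- rep("ok", length(loci))
  reason[!enough] <- "below_min_reads"
  reason[nlen < 2] <- "single_length_category"
  reason[!expressed_all] <- "not_expressed_all_genotypes"
  DataFrame(locus_id = loci, eligible = reason == "ok", reason = reason)
}

#' Length fractions at one 5' start
#'
#' Fraction of reads of each length among all reads sharing a (locus,
#' strand, 5' start) key, per genotype — the quantity the length-shift
#' test compares between genotypes. With zero reads at a key the
#' fractions are undefined and returned as `NA`.
#'
#' `lengthFractions()` on a bare counts vector normalises it to sum to 1;
#' on an [IsoformExperiment] it returns a matrix parallel to
#' `isoCounts()` with each entry divided by its per-start per-genotype
#' total.
#'
#' @param x numeric count vector, or an [IsoformExperiment].
#' @return Numeric vector or matrix of fractions.
#' @examples
#' lengthFractions(c(`24` = 10, `25` = 30, `26` = 60))
#' @export
lengthFractions <- function(x) {
  if (is(x, "IsoformExperiment")) {
    rd <- rowData(x)
    key <- paste(rd$locus_id, rd$strand, rd$start5, sep = "\r")
    cts <- isoCounts(x)
    if (!nrow(cts)) return(cts)
    tot <- rowsum(cts, key)[key, , drop = FALSE]
    frac <- cts / tot
    frac[tot == 0] <- NA_real_
    return(frac)
  }
  tot <- sum(x)
  if (tot < 1) stop("length fractions undefined for total < 1")
  x / tot
}

#' Per-start read totals
#'
#' Total reads at each (locus, strand, start5) key per genotype, mapped
#' back to the rows of the experiment. These totals are the `n` of each
#' two-proportion comparison and the source of its degrees of freedom.
#'
#' @param ise an [IsoformExperiment].
#' @return Numeric matrix parallel to `isoCounts(ise)`.
#' @keywords internal
.startTotals <- function(ise) {
  rd <- rowData(ise)
  key <- paste(rd$locus_id, rd$strand, rd$start5, sep = "\r")
  cts <- isoCounts(ise)
  rowsum(cts, key)[key, , drop = FALSE]
}

#' Per-position read density of a locus
#'
#' Read counts summed over lengths at each 5' start position of one
#' locus, for density-track export (the per-locus read landscape).
#'
#' @param ise an [IsoformExperiment].
#' @param locus a `locus_id` present in the experiment.
#' @param genotype one genotype label, or `NULL` for all.
#' @return `DataFrame` with `locus_id`, `strand`, `start5` and one count
#'   column per requested genotype.
#' @export
densityProfile <- function(ise, locus, genotype = NULL) {
  rd <- rowData(ise)
  sel <- rd$locus_id == locus
  gts <- if (is.null(genotype)) genotypes(ise) else genotype
  stopifnot(all(gts %in% genotypes(ise)))
  if (!any(sel)) {
    out <- DataFrame(locus_id = character(), strand = character(),
                     start5 = integer())
    for (g in gts) out[[g]] <- numeric()
    return(out)
  }
  key <- paste(rd$strand[sel], rd$start5[sel], sep = "\r")
  agg <- rowsum(isoCounts(ise)[sel, gts, drop = FALSE], key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  out <- DataFrame(locus_id = locus,
                   strand = vapply(parts, `[`, "", 1),
                   start5 = as.integer(vapply(parts, `[`, "", 2)))
  for (g in gts) out[[g]] <- as.numeric(agg[, g])
  out[order(out$strand, out$start5), ]
}
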