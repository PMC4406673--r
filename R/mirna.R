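#' @include AllClasses.R io-annotations.R
NULL

#' Per-arm miRNA isoform counts
#'
#' Assigns filtered reads to mature miRNA arms by 5'-end containment
#' within the mature interval (strand-aware) and tabulates raw counts by
#' (hairpin, arm, 5' start, length) per genotype. Start positions are
#' reported relative to the hairpin 5' end (1-based). Reads falling in
#' overlapping hairpins count toward each of them.
#'
#' @param readsList named list of filtered read `GRanges` per genotype.
#' @param annot a [MirnaAnnotation].
#' @param verbose log assignment counts.
#' @return `DataFrame` with columns `hairpin_id`, `arm`, `mirna_id`,
#'   `start5`, `length` and one raw-count column per genotype.
#' @export
buildMirnaIsoforms <- function(readsList, annot, verbose = TRUE) {
  stopifnot(is.list(readsList), !is.null(names(readsList)),
            is(annot, "MirnaAnnotation"))
  mat <- matures(annot)
  hp <- hairpins(annot)
  hpIdx <- match(mcols(mat)$hairpin_id, mcols(hp)$mirna_id)
  gts <- intersect(isoShiftGenotypes(), names(readsList))
  keyed <- lapply(gts, function(g) {
    reads <- readsList[[g]]
    fp <- GRanges(seqnames(reads),
                  IRanges(fivePrimeStart(reads), width = 1L),
                  strand = strand(reads))
    hits <- findOverlaps(fp, mat, ignore.strand = FALSE)
    if (verbose)
      message(sprintf("buildMirnaIsoforms[%s]: %d of %d reads on arms", g,
                      length(unique(S4Vectors::queryHits(hits))),
                      length(reads)))
    if (!length(hits))
      return(data.frame(key = character(), count = integer()))
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    h <- hpIdx[s]
    neg <- as.character(strand(hp)[h]) == "-"
    rel5 <- ifelse(neg, end(hp)[h] - fivePrimeStart(reads)[q] + 1L,
                   fivePrimeStart(reads)[q] - start(hp)[h] + 1L)
    key <- paste(mcols(mat)$hairpin_id[s], mcols(mat)$arm[s],
                 mcols(mat)$mirna_id[s], rel5, width(reads)[q], sep = "\r")
    agg <- rowsum(as.numeric(mcols(reads)$copies[q]), key)
    data.frame(key = rownames(agg), count = as.integer(agg[, 1]),
               stringsAsFactors = FALSE)
  })
  names(keyed) <- gts
  ukey <- unique(unlist(lapply(keyed, `[[`, "key"), use.names = FALSE))
  parts <- strsplit(ukey, "\r", fixed = TRUE)
  out <- DataFrame(hairpin_id = vapply(parts, `[`, "", 1),
                   arm = vapply(parts, `[`, "", 2),
                   mirna_id = vapply(parts, `[`, "", 3),
                   start5 = as.integer(vapply(parts, `[`, "", 4)),
                   length = as.integer(vapply(parts, `[`, "", 5)))
  for (g in gts) {
    v <- integer(length(ukey))
    v[match(keyed[[g]]$key, ukey)] <- keyed[[g]]$count
    out[[g]] <- v
  }
  out[order(out$hairpin_id, out$arm, out$start5, out$length), ]
}

#' Most abundant isoform of a miRNA arm
#'
#' The anchor isoform of the ratio analysis: the (start5, length) with
#' the maximal raw count on the arm in the anchor genotype (wild-type by
#' default, the baseline the mutant erodes). Ties go to the shorter
#' length, then to the smaller start.
#'
#' @param iso per-arm isoform table from [buildMirnaIsoforms()].
#' @param genotype anchor genotype column.
#' @return `DataFrame` with one row per (hairpin, arm) holding the
#'   anchor's `start5`, `length` and raw count; arms with zero reads in
#'   the anchor genotype are dropped with a message.
#' @export
mostAbundantIsoform <- function(iso, genotype = "wild_type") {
  stopifnot(genotype %in% names(iso))
  cnt <- iso[[genotype]]
  key <- paste(iso$hairpin_id, iso$arm, sep = "\r")
  o <- order(key, -cnt, iso$length, iso$start5)
  first <- o[!duplicated(key[o])]
  empty <- cnt[first] == 0
  if (any(empty))
    message(sum(empty), " arm(s) with no ", genotype,
            " reads skipped")
  first <- first[!empty]
  iso[first, c("hairpin_id", "arm", "mirna_id", "start5", "length",
               genotype)]
}

#' miRNA isoform-fraction ratios between null and wild-type
#'
#' For each mature arm, the most abundant wild-type isoform is taken as
#' anchor; in each genotype the anchor's fraction among all isoforms
#' sharing its 5' start position is computed, and the ratio
#' `f_null / f_wt` is reported. A ratio below 1 means the dominant
#' (trimmed) isoform lost share in the null — the signature of a
#' Nibbler-dependent miRNA. Arms pass the read filter when the anchor
#' isoform has more than `minReads` raw reads in both genotypes
#' (strictly greater).
#'
#' @param iso per-arm isoform table from [buildMirnaIsoforms()].
#' @param nullGenotype tested genotype column (default `"null"`).
#' @param reference anchor/reference genotype column (default
#'   `"wild_type"`).
#' @param minReads raw-read filter threshold (default 70, strict).
#' @return `DataFrame` with one row per arm: anchor coordinates, raw
#'   anchor counts, `f_wt`, `f_null`, `ratio` and `passes_filter`. Arms
#'   whose anchor fraction is undefined in the tested genotype (no reads
#'   at the anchor start) are skipped with a message.
#' @export
mirnaRatios <- function(iso, nullGenotype = "null",
                        reference = "wild_type", minReads = 70) {
  stopifnot(all(c(nullGenotype, reference) %in% names(iso)))
  anchors <- mostAbundantIsoform(iso, genotype = reference)
  if (!nrow(anchors))
    return(DataFrame(hairpin_id = character(), arm = character(),
                     mirna_id = character(), start5 = integer(),
                     length = integer(), anchor_ref = numeric(),
                     anchor_null = numeric(), f_wt = numeric(),
                     f_null = numeric(), ratio = numeric(),
                     passes_filter = logical()))
  skey <- paste(iso$hairpin_id, iso$arm, iso$start5, sep = "\r")
  akey <- paste(anchors$hairpin_id, anchors$arm, anchors$start5,
                sep = "\r")
  denomRef <- rowsum(as.numeric(iso[[reference]]), skey)
  denomNull <- rowsum(as.numeric(iso[[nullGenotype]]), skey)
  ikey <- paste(iso$hairpin_id, iso$arm, iso$start5, iso$length,
                sep = "\r")
  aikey <- paste(akey, anchors$length, sep = "\r")
  ai <- match(aikey, ikey)
  anchorRef <- as.numeric(iso[[reference]][ai])
  anchorNull <- as.numeric(iso[[nullGenotype]][ai])
  dRef <- unname(denomRef[match(akey, rownames(denomRef)), 1])
  dNull <- unname(denomNull[match(akey, rownames(denomNull)), 1])
  f_wt <- anchorRef / dRef
  f_null <- ifelse(dNull > 0, anchorNull / dNull, NA_real_)
  drop <- is.na(f_null)
  if (any(drop))
    message(sum(drop), " arm(s) without ", nullGenotype,
            " reads at the anchor start skipped")
  out <- DataFrame(hairpin_id = anchors$hairpin_id, arm = anchors$arm,
                   mirna_id = anchors$mirna_id,
                   start5 = anchors$start5, length = anchors$length,
                   anchor_ref = anchorRef, anchor_null = anchorNull,
                   f_wt = f_wt, f_null = f_null,
                   ratio = f_null / f_wt,
                   passes_filter = anchorRef > minReads &
                     anchorNull > minReads)
  out[!drop, ]
}
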