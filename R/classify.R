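#' @include AllClasses.R stats.R
NULL

#' Wild-type reference length at each 5' start
#'
#' The modal read length at each (locus, strand, start5) key in the
#' reference genotype, with ties broken toward the shorter length.
#' "Long isoforms" in the locus classifier are lengths strictly greater
#' than this reference.
#'
#' @param ise an [IsoformExperiment].
#' @param reference reference genotype (default `wild_type`).
#' @return `DataFrame` with `locus_id`, `strand`, `start5`,
#'   `ref_length`; starts with zero reference reads are omitted.
#' @examples
#' # modal length of a bare count vector
#' modalLength(c(24, 25, 26), c(10, 50, 5))   # 25
#' modalLength(c(24, 26), c(30, 30))          # tie -> 24
#' @export
referenceLengths <- function(ise, reference = "wild_type") {
  stopifnot(is(ise, "IsoformExperiment"),
            reference %in% genotypes(ise))
  rd <- rowData(ise)
  cts <- isoCounts(ise)[, reference]
  key <- paste(rd$locus_id, rd$strand, rd$start5, sep = "\r")
  ## order by key then (count desc, length asc); first row per key = mode
  o <- order(key, -cts, rd$length)
  first <- o[!duplicated(key[o])]
  keep <- cts[first] > 0
  first <- first[keep]
  DataFrame(locus_id = rd$locus_id[first], strand = rd$strand[first],
            start5 = rd$start5[first], ref_length = rd$length[first])
}

#' @rdname referenceLengths
#' @param lengths,counts parallel vectors of lengths and read counts at
#'   one start position.
#' @export
modalLength <- function(lengths, counts) {
  stopifnot(length(lengths) == length(counts), sum(counts) >= 1)
  o <- order(-counts, lengths)
  lengths[o[1]]
}

#' Classify loci by the five-genotype trimming rule
#'
#' A (start5, length) pair supports Nibbler dependence of its locus when
#' the length is strictly greater than the wild-type reference (modal)
#' length at that start, the length fraction shifted significantly
#' upward in *both* the null and the catalytically dead rescue
#' comparisons, and did *not* shift significantly upward in either the
#' deficiency heterozygote or the wild-type rescue comparison — all at
#' that same start and length. A comparison missing at a pair (because
#' of the per-start read floor) counts as "not up". A locus is affected
#' when at least one supporting pair exists. Downward calls at lengths
#' up to the reference length are tallied alongside
#' (`n_short_down` in the calls table) but do not gate the verdict.
#'
#' @param results a [LengthShiftResults] over all four mutant-vs-reference
#'   comparisons.
#' @param ise the [IsoformExperiment] the tests were computed from.
#' @param loci optional locus `GRanges` (from [readLocusBed()]) supplying
#'   the full input locus set and each locus's class; loci with no reads
#'   then appear as ineligible calls. Defaults to the loci present in
#'   `ise`.
#' @return A [LocusCalls] object.
#' @export
classifyLoci <- function(results, ise, loci = NULL) {
  stopifnot(is(results, "LengthShiftResults"), is(ise, "IsoformExperiment"))
  reference <- results@reference
  needed <- c("def_het", "null", "rescue_wt", "rescue_catdead")
  have <- unique(shiftResults(results)$genotype)
  gts <- genotypes(ise)
  missingCmp <- setdiff(intersect(needed, isoShiftGenotypes()),
                        gts)
  if (length(setdiff(needed, gts)))
    stop("classification requires comparisons for genotypes: ",
         paste(setdiff(needed, gts), collapse = ", "))
  status <- expressionFilter(ise, minTotal = results@minTotal)
  if (is.null(loci)) {
    locus_ids <- status$locus_id
    locus_class <- rep("piRNA", length(locus_ids))
  } else {
    locus_ids <- mcols(loci)$locus_id
    locus_class <- as.character(mcols(loci)$class)
  }
  eligible <- setNames(rep(FALSE, length(locus_ids)), locus_ids)
  reason <- setNames(rep("not_expressed_all_genotypes", length(locus_ids)),
                     locus_ids)
  hit <- match(status$locus_id, locus_ids)
  eligible[hit[!is.na(hit)]] <- status$eligible[!is.na(hit)]
  reason[hit[!is.na(hit)]] <- status$reason[!is.na(hit)]

  res <- as.data.frame(shiftResults(results))
  refl <- as.data.frame(referenceLengths(ise, reference))
  sup <- DataFrame(locus_id = character(), strand = character(),
                   start5 = integer(), length = integer(),
                   ref_length = integer())
  n_short_down <- setNames(rep(0L, length(locus_ids)), locus_ids)
  if (nrow(res)) {
    rkey <- paste(res$locus_id, res$strand, res$start5, sep = "\r")
    fkey <- paste(refl$locus_id, refl$strand, refl$start5, sep = "\r")
    res$ref_length <- refl$ref_length[match(rkey, fkey)]
    res <- res[!is.na(res$ref_length), , drop = FALSE]

    pkey <- paste(res$locus_id, res$strand, res$start5, res$length,
                  sep = "\r")
    upOf <- function(g) {
      k <- pkey[res$genotype == g & res$direction == "up"]
      k
    }
    long <- res$length > res$ref_length
    cand <- unique(pkey[long])
    supporting <- cand[cand %in% upOf("null") &
                       cand %in% upOf("rescue_catdead") &
                       !(cand %in% upOf("def_het")) &
                       !(cand %in% upOf("rescue_wt"))]
    if (length(supporting)) {
      i <- match(supporting, pkey)
      sup <- DataFrame(locus_id = res$locus_id[i], strand = res$strand[i],
                       start5 = res$start5[i], length = res$length[i],
                       ref_length = res$ref_length[i])
      sup <- sup[order(sup$locus_id, sup$strand, sup$start5, sup$length), ]
    }
    dn <- res$genotype == "null" & res$direction == "down" &
      res$length <= res$ref_length
    if (any(dn)) {
      tab <- table(res$locus_id[dn])
      n_short_down[names(tab)] <- as.integer(tab)
    }
  }
  n_sup <- setNames(rep(0L, length(locus_ids)), locus_ids)
  if (nrow(sup)) {
    tab <- table(sup$locus_id)
    n_sup[names(tab)] <- as.integer(tab)
  }
  calls <- DataFrame(locus_id = locus_ids,
                     class = locus_class,
                     eligible = unname(eligible),
                     reason = unname(reason),
                     affected = unname(eligible & n_sup > 0),
                     n_supporting = unname(n_sup),
                     n_short_down = unname(n_short_down))
  calls <- calls[order(calls$locus_id), ]
  new("LocusCalls", calls = calls, supporting = sup,
      thresholds = list(alpha = results@alpha, dMin = results@dMin,
                        minTotal = results@minTotal,
                        minStartReads = results@minStartReads,
                        statistic = results@statistic,
                        fdrFamily = results@fdrFamily,
                        reference = reference))
}

#' Summarise locus calls per small RNA class
#'
#' Counts of input, eligible and affected loci per annotation class,
#' with the affected fraction among eligible loci rounded to a whole
#' percent (e.g. 48 affected of 138 eligible reports 35).
#'
#' @param calls a [LocusCalls] object, or its `calls` table.
#' @return `data.frame` with one row per class: `class`, `n_input`,
#'   `n_eligible`, `n_affected`, `pct_affected`.
#' @export
summarizeCalls <- function(calls) {
  df <- if (is(calls, "LocusCalls")) as.data.frame(locusCalls(calls))
        else as.data.frame(calls)
  stopifnot(all(c("class", "eligible", "affected") %in% names(df)))
  out <- do.call(rbind, lapply(split(df, df$class), function(x) {
    nel <- sum(x$eligible)
    naf <- sum(x$affected)
    data.frame(class = x$class[1], n_input = nrow(x), n_eligible = nel,
               n_affected = naf,
               pct_affected = if (nel > 0) round(100 * naf / nel) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$class), , drop = FALSE]
}
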