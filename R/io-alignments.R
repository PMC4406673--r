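#' @include AllClasses.R
#' @importFrom GenomicRanges GRanges strand start end width resize
#'   findOverlaps seqnames
#' @importFrom IRanges IRanges
#' @importFrom Rsamtools asBam scanBam ScanBamParam scanBamFlag
#' @importFrom rtracklayer import export
#' @importFrom stats setNames
NULL

#' Read filter settings
#'
#' The read-level filters applied before any counting: only uniquely
#' mapping reads, with no mismatches, of 19-31 nt are retained. Each
#' filter can be relaxed for exploratory use; the defaults reproduce the
#' analysis contract.
#'
#' @param minLength,maxLength retained read length window in nt.
#' @param maxMismatches maximum mismatch count (default 0).
#' @param uniqueOnly keep only reads with a single best placement.
#' @return A named list of filter settings.
#' @examples
#' readFilters()
#' @export
readFilters <- function(minLength = 19L, maxLength = 31L,
                        maxMismatches = 0L, uniqueOnly = TRUE) {
  stopifnot(minLength >= 1, maxLength >= minLength, maxMismatches >= 0)
  list(minLength = as.integer(minLength), maxLength = as.integer(maxLength),
       maxMismatches = as.integer(maxMismatches),
       uniqueOnly = isTRUE(uniqueOnly))
}

#' 5' start coordinates of aligned reads
#'
#' The 5'-most nucleotide of a read on its own strand: the leftmost
#' genomic coordinate for plus-strand reads and the rightmost for
#' minus-strand reads. This position is the grouping key for isoform
#' length comparisons.
#'
#' @param reads a `GRanges` of aligned reads.
#' @return Integer vector of 1-based genomic positions.
#' @export
fivePrimeStart <- function(reads) {
  ifelse(as.character(strand(reads)) == "-", end(reads), start(reads))
}

## parse "NM=0;NH=1"-style tokens out of a BED name column
.bedNameTag <- function(nm, tag) {
  pat <- paste0("(?:^|;)", tag, "=(-?[0-9]+)(?:;|$)")
  m <- regmatches(nm, regexpr(pat, nm, perl = TRUE))
  out <- rep(NA_integer_, length(nm))
  hit <- grepl(pat, nm, perl = TRUE)
  out[hit] <- as.integer(sub(pat, "\\1",
                             regmatches(nm, regexpr(pat, nm, perl = TRUE)),
                             perl = TRUE))
  out
}

.readBed6 <- function(path, filters) {
  gr <- rtracklayer::import(path, format = "BED")
  if (any(as.character(strand(gr)) == "*"))
    stop("BED6 alignments require an explicit strand (column 6)")
  nm <- if ("name" %in% names(mcols(gr))) as.character(mcols(gr)$name)
        else rep("", length(gr))
  score <- if ("score" %in% names(mcols(gr))) mcols(gr)$score else NULL
  copies <- rep(1L, length(gr))
  if (!is.null(score)) {
    ok <- !is.na(score) & score >= 1 & score == round(score)
    copies[ok] <- as.integer(score[ok])
  }
  mismatches <- .bedNameTag(nm, "NM")
  nh <- .bedNameTag(nm, "NH")
  if (anyNA(mismatches))
    stop("BED6 dialect: mismatch filtering requires an 'NM=<int>' token in ",
         "the name column (e.g. 'read1;NM=0;NH=1'); missing at records: ",
         paste(utils::head(which(is.na(mismatches)), 5), collapse = ", "))
  if (filters$uniqueOnly && anyNA(nh))
    stop("BED6 dialect: uniqueness filtering requires an 'NH=<int>' token ",
         "in the name column (e.g. 'read1;NM=0;NH=1'); missing at records: ",
         paste(utils::head(which(is.na(nh)), 5), collapse = ", "))
  unique_map <- ifelse(is.na(nh), TRUE, nh == 1L)
  mcols(gr) <- DataFrame(copies = copies, mismatches = mismatches,
                         unique = unique_map)
  gr
}

.readSam <- function(path, filters) {
  first <- readLines(path, n = 1L)
  if (!length(first) || !startsWith(first, "@"))
    stop("headerless SAM rejected: a header with @SQ lines is required")
  bam <- suppressMessages(Rsamtools::asBam(
    path, destination = tempfile(), overwrite = TRUE, indexDestination = FALSE))
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "strand", "qwidth", "flag"),
    tag = c("NM", "NH"))
  full <- Rsamtools::scanBam(bam, param = param)[[1]]
  flag <- full$flag
  mapped <- bitwAnd(flag, 4L) == 0L
  n_unmapped <- sum(!mapped)
  keep <- mapped
  rec <- lapply(full[c("rname", "pos", "strand", "qwidth")],
                function(x) x[keep])
  nm <- full$tag$NM[keep]
  nh <- if (!is.null(full$tag$NH)) full$tag$NH[keep]
        else rep(NA_integer_, sum(keep))
  secondary <- bitwAnd(flag[keep], 256L) > 0 | bitwAnd(flag[keep], 2048L) > 0
  if (is.null(nm) || anyNA(nm))
    stop("SAM dialect: the NM tag (mismatch count) is required on every ",
         "mapped record")
  gr <- GRanges(rec$rname,
                IRanges(rec$pos, width = rec$qwidth),
                strand = rec$strand)
  unique_map <- !secondary & (is.na(nh) | nh == 1L)
  mcols(gr) <- DataFrame(copies = 1L, mismatches = as.integer(nm),
                         unique = unique_map)
  metadata(gr)$n_unmapped <- n_unmapped
  gr
}

#' Apply the read-level filters
#'
#' Retains reads that map uniquely, carry no mismatches and are 19-31 nt
#' long (or whatever `filters` specifies). Discards are attributed to the
#' first failing filter, in the order uniqueness, mismatches, length, and
#' reported in `metadata()$filter_counts` and on the message stream.
#' Filtering is idempotent.
#'
#' @param reads `GRanges` with `copies`, `mismatches` and `unique`
#'   metadata columns, as returned by [readAlignments()].
#' @param filters a [readFilters()] list.
#' @param verbose emit a per-filter discard summary via `message()`.
#' @return The retained reads, with `metadata()$filter_counts`.
#' @export
filterReads <- function(reads, filters = readFilters(), verbose = TRUE) {
  mc <- mcols(reads)
  stopifnot(all(c("copies", "mismatches", "unique") %in% names(mc)))
  fail_unique <- filters$uniqueOnly & !mc$unique
  fail_mm <- !fail_unique & mc$mismatches > filters$maxMismatches
  len <- width(reads)
  fail_len <- !fail_unique & !fail_mm &
    (len < filters$minLength | len > filters$maxLength)
  keep <- !(fail_unique | fail_mm | fail_len)
  counts <- c(input = length(reads),
              retained = sum(keep),
              non_unique = sum(fail_unique),
              mismatched = sum(fail_mm),
              out_of_length = sum(fail_len))
  if (verbose)
    message(sprintf(
      "filterReads: %d records in, %d retained (%d multimapper, %d mismatched, %d outside %d-%d nt)",
      counts["input"], counts["retained"], counts["non_unique"],
      counts["mismatched"], counts["out_of_length"],
      filters$minLength, filters$maxLength))
  out <- reads[keep]
  metadata(out)$filter_counts <- counts
  out
}

#' Read aligned small RNA reads
#'
#' Parses one aligned small RNA library in BED6 or SAM form into a
#' `GRanges` and applies the read-level filters (unique placement, zero
#' mismatches, 19-31 nt). In the BED6 dialect, column 5 (score) carries
#' the collapsed-read multiplicity when it is an integer >= 1, and the
#' name column may carry `NM=<int>` / `NH=<int>` tokens (semicolon
#' separated) providing the mismatch count and number of genomic hits;
#' both tokens are required when the corresponding filter is active. In
#' the SAM dialect mismatches come from the `NM` tag (required), and a
#' read is unique when it is neither secondary nor supplementary and its
#' `NH` tag (when present) equals 1.
#'
#' @param path path to the alignment file.
#' @param format `"bed6"` or `"sam"`.
#' @param filters a [readFilters()] list.
#' @param verbose emit filter summaries.
#' @return `GRanges` of retained reads with metadata columns `copies`,
#'   `mismatches`, `unique`; discard counts in `metadata()$filter_counts`.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr2L\t99\t124\tr1;NM=0;NH=1\t3\t+",
#'              "chr2L\t199\t217\tr2;NM=0;NH=1\t1\t-"), bed)
#' rd <- readAlignments(bed, verbose = FALSE)
#' width(rd)                 # the 18 nt read was discarded
#' @export
readAlignments <- function(path, format = c("bed6", "sam"),
                           filters = readFilters(), verbose = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("alignment file not found: ", path)
  gr <- switch(format,
               bed6 = .readBed6(path, filters),
               sam = .readSam(path, filters))
  filterReads(gr, filters, verbose = verbose)
}

#' Write aligned reads as BED6
#'
#' Inverse of [readAlignments()] for the BED6 dialect: multiplicities go
#' to the score column and `NM=`/`NH=` tokens to the name column, so the
#' output is re-readable under the same filters.
#'
#' @param reads `GRanges` with `copies`, `mismatches`, `unique` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAlignmentsBed <- function(reads, path) {
  mc <- mcols(reads)
  out <- reads
  mcols(out) <- DataFrame(
    name = sprintf("r%d;NM=%d;NH=%d", seq_along(reads),
                   as.integer(mc$mismatches),
                   ifelse(mc$unique, 1L, 2L)),
    score = as.integer(mc$copies))
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}
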