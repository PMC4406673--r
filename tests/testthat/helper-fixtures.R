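suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
  library(SummarizedExperiment)
})

## a GRanges of reads from a compact spec:
## data.frame(chrom, start5 (1-based, strand-aware), length, strand,
##            copies, mismatches, nh)
makeReads <- function(df) {
  df$copies <- if (is.null(df$copies)) 1L else df$copies
  df$mismatches <- if (is.null(df$mismatches)) 0L else df$mismatches
  df$nh <- if (is.null(df$nh)) 1L else df$nh
  neg <- df$strand == "-"
  gstart <- ifelse(neg, df$start5 - df$length + 1L, df$start5)
  gr <- GRanges(df$chrom, IRanges(gstart, width = df$length),
                strand = df$strand)
  mcols(gr) <- DataFrame(copies = as.integer(df$copies),
                         mismatches = as.integer(df$mismatches),
                         unique = df$nh == 1L)
  gr
}

## write the same compact spec as a BED6 file readable by readAlignments()
writeBed6 <- function(df, path) {
  df$copies <- if (is.null(df$copies)) 1L else df$copies
  df$mismatches <- if (is.null(df$mismatches)) 0L else df$mismatches
  df$nh <- if (is.null(df$nh)) 1L else df$nh
  neg <- df$strand == "-"
  gstart <- ifelse(neg, df$start5 - df$length + 1L, df$start5)
  lines <- sprintf("%s\t%d\t%d\tr%d;NM=%d;NH=%d\t%d\t%s",
                   df$chrom, gstart - 1L, gstart - 1L + df$length,
                   seq_len(nrow(df)), df$mismatches, df$nh, df$copies,
                   df$strand)
  writeLines(lines, path)
  path
}

## minimal single-chromosome SAM file
writeSam <- function(df, path, chromLen = 100000L, dropNM = FALSE) {
  df$mismatches <- if (is.null(df$mismatches)) 0L else df$mismatches
  df$secondary <- if (is.null(df$secondary)) FALSE else df$secondary
  df$nh <- if (is.null(df$nh)) 1L else df$nh
  neg <- df$strand == "-"
  pos <- ifelse(neg, df$start5 - df$length + 1L, df$start5)
  flag <- ifelse(neg, 16L, 0L) + ifelse(df$secondary, 256L, 0L)
  seqs <- vapply(df$length, function(n)
    paste(rep("A", n), collapse = ""), character(1))
  recs <- sprintf("q%d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                  seq_len(nrow(df)), flag, df$chrom, pos, df$length, seqs)
  if (!dropNM)
    recs <- sprintf("%s\tNM:i:%d\tNH:i:%d", recs, df$mismatches, df$nh)
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", unique(df$chrom), chromLen),
               recs), path)
  path
}

makeLoci <- function(df) {
  gr <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand)
  mcols(gr) <- DataFrame(
    locus_id = df$locus_id,
    class = if (is.null(df$class)) rep("piRNA", nrow(df)) else df$class)
  gr
}

## IsoformExperiment straight from a long count table:
## data.frame(locus_id, strand, start5, length, <genotype columns...>)
makeIse <- function(df, librarySizes = NULL) {
  gts <- setdiff(names(df), c("locus_id", "strand", "start5", "length"))
  cts <- as.matrix(df[gts])
  storage.mode(cts) <- "integer"
  if (is.null(librarySizes))
    librarySizes <- setNames(rep(1e6, length(gts)), gts)
  isoShift:::.newIsoformExperiment(
    cts,
    DataFrame(locus_id = df$locus_id, strand = df$strand,
              start5 = as.integer(df$start5),
              length = as.integer(df$length)),
    librarySizes[gts])
}

## brute-force BH step-up oracle: q_(i) = min_{j>=i} p_(j) * m / j
bruteForceBH <- function(p) {
  m <- length(p)
  if (!m) return(numeric())
  o <- order(p)
  ps <- p[o]
  pm <- ps * m / seq_len(m)
  qs <- vapply(seq_len(m), function(i) min(1, min(pm[i:m])), numeric(1))
  q <- numeric(m)
  q[o] <- qs
  q
}

## hand-built LengthShiftResults for classifier tests
makeResults <- function(df, alpha = 0.05, dMin = 0.6) {
  res <- DataFrame(
    locus_id = df$locus_id, strand = df$strand,
    start5 = as.integer(df$start5), length = as.integer(df$length),
    genotype = df$genotype,
    k_obs = 50, n_obs = 100, k_ref = 20, n_ref = 100,
    f_obs = 0.5, f_ref = 0.2,
    t = ifelse(df$direction == "up", 4, ifelse(df$direction == "down", -4, 0)),
    df = 200L,
    p = ifelse(df$direction == "none", 0.9, 1e-4),
    q = ifelse(df$direction == "none", 0.9, 1e-3),
    d = ifelse(df$direction == "none", 0.1, 0.9),
    direction = df$direction)
  new("LengthShiftResults", results = res, reference = "wild_type",
      statistic = "pooled", alpha = alpha, dMin = dMin,
      fdrFamily = "per_comparison", minTotal = 5, minStartReads = 2)
}
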