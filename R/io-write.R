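#' @include AllClasses.R
NULL

## format numeric columns to 6 significant digits, leave the rest alone
.formatTable <- function(df) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]]))
      df[[j]] <- formatC(signif(df[[j]], 6), format = "g", digits = 6)
  }
  df
}

#' Write a result table as TSV
#'
#' Deterministic writer used for all result tables: rows are sorted by
#' any of `locus_id`, `strand`, `start5`, `length`, `genotype` columns
#' present (in that precedence), floating point values are printed with 6
#' significant digits, and re-running on identical input produces a
#' byte-identical file. An empty table yields a header-only file.
#'
#' @param df a `data.frame` or `DataFrame`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeResultTable <- function(df, path) {
  df <- as.data.frame(df)
  keys <- intersect(c("locus_id", "strand", "start5", "length", "genotype",
                      "mirna_id", "arm"), names(df))
  if (length(keys) && nrow(df))
    df <- df[do.call(order, df[keys]), , drop = FALSE]
  out <- .formatTable(df)
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Export and re-import isoform count tables
#'
#' `writeIsoformTable()` serialises an [IsoformExperiment] to a long TSV
#' (`locus_id`, `strand`, `start5`, `length`, `genotype`, `count`) with
#' library sizes in `#library_size` header comments;
#' `readIsoformTable()` reconstructs an identical object, so a write/read
#' round trip preserves all counts.
#'
#' @param ise an [IsoformExperiment].
#' @param path TSV file.
#' @return `writeIsoformTable()` returns `path` invisibly;
#'   `readIsoformTable()` returns an [IsoformExperiment].
#' @export
writeIsoformTable <- function(ise, path) {
  rd <- rowData(ise)
  cts <- isoCounts(ise)
  gts <- genotypes(ise)
  long <- do.call(rbind, lapply(seq_along(gts), function(j) {
    data.frame(locus_id = rd$locus_id, strand = rd$strand,
               start5 = rd$start5, length = rd$length,
               genotype = gts[j], count = cts[, j],
               stringsAsFactors = FALSE)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  ls <- librarySizes(ise)
  writeLines(sprintf("#library_size\t%s\t%s", names(ls),
                     format(ls, scientific = FALSE, trim = TRUE)), con)
  long <- long[do.call(order, long[c("locus_id", "strand", "start5",
                                     "length", "genotype")]), ]
  utils::write.table(long, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeIsoformTable
#' @export
readIsoformTable <- function(path) {
  ln <- readLines(path)
  hdr <- ln[startsWith(ln, "#library_size")]
  if (!length(hdr)) stop("missing #library_size header lines in ", path)
  hp <- strsplit(hdr, "\t")
  libs <- setNames(as.numeric(vapply(hp, `[`, "", 3)),
                   vapply(hp, `[`, "", 2))
  df <- utils::read.table(text = ln[!startsWith(ln, "#")], sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  gts <- intersect(isoShiftGenotypes(), unique(df$genotype))
  key <- paste(df$locus_id, df$strand, df$start5, df$length, sep = "\r")
  ukey <- unique(key)
  cts <- matrix(0L, length(ukey), length(gts),
                dimnames = list(NULL, gts))
  for (g in gts) {
    sel <- df$genotype == g
    cts[match(key[sel], ukey), g] <- as.integer(df$count[sel])
  }
  first <- match(ukey, key)
  rd <- DataFrame(locus_id = df$locus_id[first],
                  strand = df$strand[first],
                  start5 = as.integer(df$start5[first]),
                  length = as.integer(df$length[first]))
  .newIsoformExperiment(cts, rd, libs[gts])
}

## shared constructor; orders rows deterministically
.newIsoformExperiment <- function(counts, rowdat, librarySizes) {
  o <- order(rowdat$locus_id, rowdat$strand, rowdat$start5, rowdat$length)
  counts <- counts[o, , drop = FALSE]
  rowdat <- rowdat[o, , drop = FALSE]
  cd <- DataFrame(genotype = colnames(counts),
                  library_size = as.numeric(librarySizes),
                  row.names = colnames(counts))
  new("IsoformExperiment",
      SummarizedExperiment(assays = list(counts = counts),
                           rowData = rowdat, colData = cd))
}
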