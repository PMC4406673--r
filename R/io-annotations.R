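#' @include AllClasses.R
NULL

#' Read locus annotations from BED
#'
#' Reads piRNA cluster or endo-siRNA locus annotations from a BED3+ file.
#' The name column (when present) provides `locus_id`; otherwise ids are
#' auto-generated as `chrom:start-end` in the file's 0-based coordinates.
#' A `.` / missing strand denotes an unstranded (dual-strand) cluster
#' which accepts reads from both strands. Duplicate locus ids are
#' rejected.
#'
#' @param path BED3+ file.
#' @param class annotation class label, e.g. `"piRNA"` or `"endo-siRNA"`,
#'   recycled over records.
#' @return `GRanges` with metadata columns `locus_id` and `class`.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr2L\t100\t200\tlocus1\t0\t+", bed)
#' readLocusBed(bed)
#' @export
readLocusBed <- function(path, class = "piRNA") {
  if (!file.exists(path)) stop("locus BED not found: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) && any(width(gr) < 1))
    stop("locus with start >= end in ", path)
  ids <- if ("name" %in% names(mcols(gr)) && !anyNA(mcols(gr)$name))
    as.character(mcols(gr)$name)
  else
    sprintf("%s:%d-%d", as.character(seqnames(gr)), start(gr) - 1L, end(gr))
  if (anyDuplicated(ids))
    stop("duplicate locus_id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  mcols(gr) <- DataFrame(locus_id = ids,
                         class = rep_len(class, length(gr)))
  gr
}

#' Read miRNA hairpin annotations from GFF3
#'
#' Parses a miRBase-style GFF3 with `miRNA_primary_transcript` (hairpin)
#' and `miRNA` (mature arm) features. Mature arms are linked to their
#' hairpin through the `Derives_from` (or `Parent`) attribute and
#' labelled `5p`/`3p` by the distance of their 5' end from the hairpin's
#' 5' end; a lone mature arm is labelled by which half of the hairpin it
#' occupies. Matures without a matching hairpin are skipped with a
#' warning. Overlapping hairpins are all kept; reads may later count
#' toward each of them.
#'
#' @param path GFF3 file.
#' @return A [MirnaAnnotation] object.
#' @export
readMirnaGff <- function(path) {
  if (!file.exists(path)) stop("miRNA GFF3 not found: ", path)
  gff <- rtracklayer::import(path, format = "GFF3")
  type <- as.character(gff$type)
  hp <- gff[type == "miRNA_primary_transcript"]
  mat <- gff[type == "miRNA"]
  if (!length(hp)) stop("no miRNA_primary_transcript features in ", path)
  .attr1 <- function(gr, field) {
    v <- mcols(gr)[[field]]
    if (is.null(v)) return(rep(NA_character_, length(gr)))
    if (is(v, "List") || is.list(v))
      vapply(v, function(x) if (length(x)) as.character(x[1])
                            else NA_character_, character(1))
    else as.character(v)
  }
  hp_id <- .attr1(hp, "Name")
  hp_id[is.na(hp_id)] <- .attr1(hp, "ID")[is.na(hp_id)]
  if (anyNA(hp_id) || anyDuplicated(hp_id))
    stop("hairpins must carry unique Name/ID attributes")
  mcols(hp) <- DataFrame(mirna_id = hp_id)
  hp_key <- .attr1(gff[type == "miRNA_primary_transcript"], "ID")
  hp_key[is.na(hp_key)] <- hp_id[is.na(hp_key)]

  parent <- .attr1(mat, "Derives_from")
  pp <- .attr1(mat, "Parent")
  parent[is.na(parent)] <- pp[is.na(parent)]
  idx <- match(parent, hp_key)
  idx[is.na(idx)] <- match(parent[is.na(idx)], hp_id)
  orphan <- is.na(idx)
  if (any(orphan)) {
    warning(sum(orphan), " mature miRNA feature(s) without a parent ",
            "hairpin skipped")
    mat <- mat[!orphan]
    idx <- idx[!orphan]
  }
  mat_id <- .attr1(mat, "Name")
  mat_id[is.na(mat_id)] <- .attr1(mat, "ID")[is.na(mat_id)]

  # distance of the mature 5' end from the hairpin 5' end, strand aware
  hp_neg <- as.character(strand(hp)[idx]) == "-"
  d5 <- ifelse(hp_neg, end(hp)[idx] - end(mat), start(mat) - start(hp)[idx])
  arm <- rep(NA_character_, length(mat))
  for (h in unique(idx)) {
    sel <- which(idx == h)
    if (length(sel) >= 2) {
      ord <- sel[order(d5[sel])]
      arm[ord[1]] <- "5p"
      arm[ord[-1]] <- "3p"
    } else {
      arm[sel] <- if (d5[sel] <= width(hp)[h] / 2) "5p" else "3p"
    }
  }
  mcols(mat) <- DataFrame(mirna_id = mat_id,
                          hairpin_id = mcols(hp)$mirna_id[idx],
                          arm = arm)
  new("MirnaAnnotation", hairpins = hp, matures = mat)
}

#' Read a library manifest
#'
#' A manifest is a whitespace-separated text file with one line per
#' sequenced library: `genotype path format total_reads`, where
#' `genotype` is one of [isoShiftGenotypes()], `format` is `bed6` or
#' `sam` and `total_reads` is the library's total small RNA read count
#' after adapter trimming (the depth-normalisation denominator). Lines
#' starting with `#` are comments. A full run requires each of the five
#' genotypes exactly once; relative paths are resolved against the
#' manifest's directory.
#'
#' @param path manifest file.
#' @param requireAll require all five genotypes (default `TRUE`).
#' @return `data.frame` with columns `genotype`, `path`, `format`,
#'   `total_reads`.
#' @export
readLibraryManifest <- function(path, requireAll = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  ln <- readLines(path)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (!length(ln)) stop("empty manifest: ", path)
  parts <- strsplit(ln, "[ \t]+")
  if (any(lengths(parts) != 4))
    stop("manifest lines must be 'genotype path format total_reads'")
  df <- data.frame(genotype = vapply(parts, `[`, "", 1),
                   path = vapply(parts, `[`, "", 2),
                   format = vapply(parts, `[`, "", 3),
                   total_reads = as.numeric(vapply(parts, `[`, "", 4)),
                   stringsAsFactors = FALSE)
  bad <- setdiff(df$genotype, isoShiftGenotypes())
  if (length(bad)) stop("unknown genotype(s) in manifest: ",
                        paste(bad, collapse = ", "))
  if (anyDuplicated(df$genotype))
    stop("duplicated genotype in manifest")
  if (requireAll) {
    missing <- setdiff(isoShiftGenotypes(), df$genotype)
    if (length(missing))
      stop("manifest is missing genotype(s): ",
           paste(missing, collapse = ", "))
  }
  if (!all(df$format %in% c("bed6", "sam")))
    stop("manifest format must be 'bed6' or 'sam'")
  if (anyNA(df$total_reads) || any(df$total_reads <= 0))
    stop("total_reads must be positive numbers")
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  df[match(intersect(isoShiftGenotypes(), df$genotype), df$genotype), ,
     drop = FALSE]
}
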