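#' @include AllClasses.R io-alignments.R
#' @importFrom stats rgamma runif
NULL

.defaultPrecursorProbs <- function() {
  p <- setNames(numeric(13), 19:31)
  p[c("27", "28", "29", "30", "31")] <- c(0.03, 0.05, 0.12, 0.25, 0.55)
  p
}

.defaultMirnaPrecursorProbs <- function() {
  p <- setNames(numeric(13), 19:31)
  p[c("22", "23", "24")] <- c(0.05, 0.20, 0.75)
  p
}

#' Construct a simulation configuration
#'
#' Defaults describe the reference desk-scale study conditions: 200
#' piRNA-like loci with 2-4 5' starts each, untrimmed precursor 3' ends
#' concentrated at the top of the 19-31 nt window, per-read trimming
#' probability 0.7 with a truncated-geometric trim of mean ~2 nt
#' (success probability 0.335 over 1-4 nt, floored at 19 nt), a quarter
#' of loci Nibbler-dependent, 50,000 locus reads per library with +/-20%
#' library-size jitter, and 10 miRNA-like hairpins sequenced to 10,000
#' arm reads with near-complete (rate 0.9) trimming of the
#' Nibbler-dependent arms.
#'
#' @param nLoci number of piRNA-like loci.
#' @param startsPerLocus inclusive range of 5' start positions per locus.
#' @param locusWidth,locusGap locus size and spacing (bp) on the
#'   synthetic chromosome.
#' @param chromLength synthetic chromosome length (placement capacity).
#' @param precursorProbs named probability vector over lengths 19..31
#'   for untrimmed precursor 3' ends at piRNA-like loci.
#' @param trimRate per-read probability that functional Nibbler trims.
#' @param trimGeomProb success probability of the truncated geometric
#'   trim-size distribution on 1..`trimMaxSize`.
#' @param trimMaxSize maximal trim (nt).
#' @param trimFloor shortest length trimming may produce (>= 19).
#' @param affectedFraction fraction of loci whose trimming is
#'   Nibbler-dependent (exact count, drawn without replacement).
#' @param depth expected locus reads per library.
#' @param libraryJitter multiplicative library-size factor range.
#' @param startWeightShape gamma shape of random start-abundance
#'   weights; larger = more even coverage.
#' @param nMirna number of miRNA-like hairpins (0 disables).
#' @param mirnaDepth expected miRNA arm reads per library.
#' @param mirnaPrecursorProbs precursor length distribution for miRNA
#'   arms (peaked at 24 nt).
#' @param mirnaTrimRate trimming probability on miRNA arms.
#' @param mirnaAffectedFraction fraction of Nibbler-dependent arms.
#' @return A validated [SimConfig] object.
#' @examples
#' cfg <- simConfig(nLoci = 20L, depth = 5e3)
#' @export
simConfig <- function(nLoci = 200L,
                      startsPerLocus = c(2L, 4L),
                      locusWidth = 2000L,
                      locusGap = 1000L,
                      chromLength = 3e7,
                      precursorProbs = .defaultPrecursorProbs(),
                      trimRate = 0.7,
                      trimGeomProb = 0.335,
                      trimMaxSize = 4L,
                      trimFloor = 19L,
                      affectedFraction = 0.25,
                      depth = 5e4,
                      libraryJitter = c(0.8, 1.2),
                      startWeightShape = 20,
                      nMirna = 10L,
                      mirnaDepth = 1e4,
                      mirnaPrecursorProbs = .defaultMirnaPrecursorProbs(),
                      mirnaTrimRate = 0.9,
                      mirnaAffectedFraction = 0.5) {
  new("SimConfig",
      nLoci = as.integer(nLoci),
      startsPerLocus = as.integer(startsPerLocus),
      locusWidth = as.integer(locusWidth),
      locusGap = as.integer(locusGap),
      chromLength = as.numeric(chromLength),
      precursorProbs = precursorProbs,
      trimRate = trimRate,
      trimGeomProb = trimGeomProb,
      trimMaxSize = as.integer(trimMaxSize),
      trimFloor = as.integer(trimFloor),
      affectedFraction = affectedFraction,
      depth = as.numeric(depth),
      libraryJitter = as.numeric(libraryJitter),
      startWeightShape = as.numeric(startWeightShape),
      nMirna = as.integer(nMirna),
      mirnaDepth = as.numeric(mirnaDepth),
      mirnaPrecursorProbs = mirnaPrecursorProbs,
      mirnaTrimRate = mirnaTrimRate,
      mirnaAffectedFraction = mirnaAffectedFraction)
}

## deterministic per-genotype RNG stream offsets
.genotypeSeed <- function(seed, genotype) {
  off <- match(genotype, isoShiftGenotypes())
  if (is.na(off)) stop("unknown genotype: ", genotype)
  as.integer(seed) + off * 1009L
}

## truncated geometric trim sizes on 1..maxSize
.rTrimSize <- function(n, prob, maxSize) {
  w <- prob * (1 - prob)^(seq_len(maxSize) - 1)
  sample.int(maxSize, n, replace = TRUE, prob = w)
}

#' Simulate locus and miRNA annotations
#'
#' Places `nLoci` non-overlapping piRNA-like loci on a synthetic
#' chromosome (`simChr`), assigns each 2-4 fixed 5' start positions with
#' random abundance weights, and lays out `nMirna` hairpins with 5p/3p
#' mature arms on a second chromosome (`simChrM`). Deterministic given
#' the seed.
#'
#' @param config a [SimConfig].
#' @param seed integer RNG seed.
#' @return List with `loci` (`GRanges`), `starts` (`DataFrame` of start
#'   positions, strands and weights) and `mirna`
#'   ([MirnaAnnotation] plus arm start bookkeeping), used by
#'   [simulateLibrary()].
#' @export
simulateAnnotations <- function(config, seed = 1L) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(as.integer(seed))
  n <- config@nLoci
  span <- config@locusWidth + config@locusGap
  if (n * span > config@chromLength)
    stop("infeasible placement: ", n, " loci of span ", span,
         " exceed chromosome length ", config@chromLength)
  if (n > 0) {
    ls <- 1L + (seq_len(n) - 1L) * span
    strands <- sample(c("+", "-", "*"), n, replace = TRUE,
                      prob = c(0.4, 0.4, 0.2))
    loci <- GRanges("simChr", IRanges(ls, width = config@locusWidth),
                    strand = strands)
    mcols(loci) <- DataFrame(locus_id = sprintf("locus%03d", seq_len(n)),
                             class = "piRNA")
    nStarts <- sample(seq(config@startsPerLocus[1],
                          config@startsPerLocus[2]),
                      n, replace = TRUE)
    li <- rep(seq_len(n), nStarts)
    margin <- MAX_READ_LENGTH
    rstrand <- as.character(strand(loci))[li]
    flip <- rstrand == "*"
    rstrand[flip] <- sample(c("+", "-"), sum(flip), replace = TRUE)
    pos <- integer(length(li))
    plus <- rstrand == "+"
    pos[plus] <- start(loci)[li[plus]] +
      sample.int(config@locusWidth - 2L * margin, sum(plus),
                 replace = TRUE) + margin
    pos[!plus] <- start(loci)[li[!plus]] +
      sample.int(config@locusWidth - 2L * margin, sum(!plus),
                 replace = TRUE) + margin
    w <- rgamma(length(li), shape = config@startWeightShape, rate = 1)
    starts <- DataFrame(locus_id = mcols(loci)$locus_id[li],
                        strand = rstrand, pos = pos,
                        weight = w / sum(w))
  } else {
    loci <- GRanges()
    mcols(loci) <- DataFrame(locus_id = character(), class = character())
    starts <- DataFrame(locus_id = character(), strand = character(),
                        pos = integer(), weight = numeric())
  }

  m <- config@nMirna
  if (m > 0) {
    hpw <- 120L
    hs <- 1L + (seq_len(m) - 1L) * 500L
    hp <- GRanges("simChrM", IRanges(hs, width = hpw), strand = "+")
    mcols(hp) <- DataFrame(mirna_id = sprintf("mir%03d", seq_len(m)))
    armw <- 40L
    m5 <- GRanges("simChrM", IRanges(hs + 5L, width = armw), strand = "+")
    m3 <- GRanges("simChrM", IRanges(hs + hpw - 5L - armw, width = armw),
                  strand = "+")
    mm <- c(m5, m3)
    mcols(mm) <- DataFrame(
      mirna_id = c(sprintf("mir%03d-5p", seq_len(m)),
                   sprintf("mir%03d-3p", seq_len(m))),
      hairpin_id = rep(mcols(hp)$mirna_id, 2),
      arm = rep(c("5p", "3p"), each = m))
    armW <- rgamma(2L * m, shape = config@startWeightShape, rate = 1)
    armStarts <- DataFrame(hairpin_id = mcols(mm)$hairpin_id,
                           arm = mcols(mm)$arm,
                           pos = start(mm) + 2L,   # fixed 5' site per arm
                           strand = "+",
                           weight = armW / sum(armW))
    mirna <- list(annotation = new("MirnaAnnotation", hairpins = hp,
                                   matures = mm),
                  armStarts = armStarts)
  } else {
    mirna <- NULL
  }
  list(loci = loci, starts = starts, mirna = mirna)
}

#' Draw the ground truth of a simulated experiment
#'
#' Samples exactly `round(nLoci * affectedFraction)` loci (and the
#' corresponding fraction of miRNA arms) without replacement as
#' Nibbler-dependent: in genotypes lacking functional Nibbler the reads
#' of these loci keep their untrimmed precursor lengths.
#'
#' @param config a [SimConfig].
#' @param ann annotations from [simulateAnnotations()].
#' @param seed integer RNG seed.
#' @return List with `loci` (`DataFrame`: `locus_id`, `affected`) and
#'   `arms` (`DataFrame`: `hairpin_id`, `arm`, `affected`, or NULL).
#' @export
simulateTruth <- function(config, ann, seed = 1L) {
  set.seed(as.integer(seed) + 7919L)
  ids <- mcols(ann$loci)$locus_id
  nAff <- round(length(ids) * config@affectedFraction)
  aff <- ids %in% sample(ids, nAff)
  truthLoci <- DataFrame(locus_id = ids, affected = aff)
  truthArms <- NULL
  if (!is.null(ann$mirna)) {
    ak <- paste(ann$mirna$armStarts$hairpin_id, ann$mirna$armStarts$arm)
    nA <- round(length(ak) * config@mirnaAffectedFraction)
    affA <- ak %in% sample(ak, nA)
    truthArms <- DataFrame(hairpin_id = ann$mirna$armStarts$hairpin_id,
                           arm = ann$mirna$armStarts$arm,
                           affected = affA)
  }
  list(loci = truthLoci, arms = truthArms)
}

## vectorised read drawing shared by locus and miRNA reads
.drawReads <- function(n, startTab, chrom, precProbs, trimmedMask,
                       trimRate, trimGeomProb, trimMaxSize, trimFloor) {
  if (n == 0 || nrow(startTab) == 0) return(GRanges())
  i <- sample.int(nrow(startTab), n, replace = TRUE,
                  prob = startTab$weight)
  prec <- sample(19:31, n, replace = TRUE, prob = precProbs)
  doTrim <- trimmedMask[i] & (runif(n) < trimRate)
  size <- integer(n)
  if (any(doTrim))
    size[doTrim] <- .rTrimSize(sum(doTrim), trimGeomProb, trimMaxSize)
  len <- pmax(prec - size, trimFloor)
  pos <- startTab$pos[i]
  neg <- startTab$strand[i] == "-"
  gstart <- ifelse(neg, pos - len + 1L, pos)
  gr <- GRanges(chrom, IRanges(gstart, width = len),
                strand = startTab$strand[i])
  ## collapse identical reads into multiplicities
  key <- paste(start(gr), end(gr), as.character(strand(gr)), sep = "\r")
  agg <- rowsum(rep(1L, n), key)
  first <- !duplicated(key)
  out <- gr[first]
  mcols(out) <- DataFrame(copies = as.integer(agg[key[first], 1]),
                          mismatches = 0L, unique = TRUE)
  out
}

#' Simulate one aligned small RNA library
#'
#' Draws reads for one genotype given annotations and ground truth:
#' each read picks a (locus, start) by weight, a precursor length, and
#' is 3'-trimmed when the genotype has functional Nibbler or the locus
#' is not Nibbler-dependent. The null and catalytically dead rescue
#' genotypes skip trimming at affected loci/arms, accumulating long
#' isoforms there. Library size is jittered multiplicatively. Reads are
#' returned collapsed, with multiplicities, and are deterministic given
#' `(seed, genotype)`.
#'
#' @param config a [SimConfig].
#' @param genotype one of [isoShiftGenotypes()].
#' @param ann annotations from [simulateAnnotations()].
#' @param truth ground truth from [simulateTruth()].
#' @param seed integer master seed (a per-genotype stream is derived).
#' @return `GRanges` of collapsed reads with `copies`, `mismatches`,
#'   `unique` metadata columns.
#' @export
simulateLibrary <- function(config, genotype, ann, truth, seed = 1L) {
  stopifnot(is(config, "SimConfig"))
  genotype <- match.arg(genotype, isoShiftGenotypes())
  set.seed(.genotypeSeed(seed, genotype))
  functional <- genotype %in% functionalGenotypes()
  jit <- runif(1, config@libraryJitter[1], config@libraryJitter[2])

  st <- ann$starts
  affLocus <- truth$loci$affected[match(st$locus_id,
                                        truth$loci$locus_id)]
  trimmedMask <- functional | !affLocus
  nReads <- round(config@depth * jit)
  reads <- .drawReads(nReads, st, "simChr", config@precursorProbs,
                      trimmedMask, config@trimRate, config@trimGeomProb,
                      config@trimMaxSize, config@trimFloor)

  if (!is.null(ann$mirna)) {
    as <- ann$mirna$armStarts
    ak <- paste(as$hairpin_id, as$arm)
    tk <- paste(truth$arms$hairpin_id, truth$arms$arm)
    affArm <- truth$arms$affected[match(ak, tk)]
    trimmedArm <- functional | !affArm
    nM <- round(config@mirnaDepth * jit)
    mreads <- .drawReads(nM, as, "simChrM", config@mirnaPrecursorProbs,
                         trimmedArm, config@mirnaTrimRate,
                         config@trimGeomProb, config@trimMaxSize,
                         config@trimFloor)
    reads <- suppressWarnings(c(reads, mreads))
  }
  reads
}

#' Simulate a full five-genotype experiment
#'
#' Convenience wrapper producing annotations, ground truth and one
#' aligned library per genotype, plus per-library totals for depth
#' normalisation.
#'
#' @param config a [SimConfig].
#' @param seed integer master seed.
#' @return List with elements `reads` (named list of `GRanges`), `loci`,
#'   `starts`, `mirna` (annotation or NULL), `truth`, `librarySizes` and
#'   `config`.
#' @export
simulateExperiment <- function(config = simConfig(), seed = 1L) {
  ann <- simulateAnnotations(config, seed)
  truth <- simulateTruth(config, ann, seed)
  reads <- lapply(isoShiftGenotypes(), simulateLibrary,
                  config = config, ann = ann, truth = truth, seed = seed)
  names(reads) <- isoShiftGenotypes()
  libs <- vapply(reads, function(gr) sum(mcols(gr)$copies), numeric(1))
  list(reads = reads, loci = ann$loci, starts = ann$starts,
       mirna = if (is.null(ann$mirna)) NULL else ann$mirna$annotation,
       truth = truth, librarySizes = libs, config = config)
}

#' Export ground truth as TSV
#'
#' One row per locus with its Nibbler-dependence flag (plus per-arm rows
#' for miRNAs when simulated), for evaluation joins against classifier
#' output.
#'
#' @param truth ground truth from [simulateTruth()] (or the `truth`
#'   element of [simulateExperiment()]).
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
exportGroundTruth <- function(truth, path) {
  df <- data.frame(unit = "locus",
                   id = truth$loci$locus_id,
                   arm = NA_character_,
                   affected = truth$loci$affected,
                   stringsAsFactors = FALSE)
  if (!is.null(truth$arms))
    df <- rbind(df, data.frame(unit = "mirna_arm",
                               id = truth$arms$hairpin_id,
                               arm = truth$arms$arm,
                               affected = truth$arms$affected,
                               stringsAsFactors = FALSE))
  df <- df[order(df$unit, df$id, df$arm), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a simulated experiment to disk
#'
#' Materialises a simulated experiment in the package's input formats:
#' one BED6 read file per genotype, the locus BED, the miRNA GFF3 (when
#' simulated), a library manifest and the ground-truth TSV — a complete,
#' self-contained input set for [runPipeline()].
#'
#' @param sim result of [simulateExperiment()].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
writeSimulatedData <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gts <- names(sim$reads)
  bedPaths <- file.path(dir, sprintf("reads_%s.bed", gts))
  for (i in seq_along(gts))
    writeAlignmentsBed(sim$reads[[i]], bedPaths[i])
  lociOut <- sim$loci
  mcols(lociOut) <- DataFrame(name = mcols(sim$loci)$locus_id, score = 0L)
  rtracklayer::export(lociOut, file.path(dir, "loci.bed"),
                      format = "BED")
  if (!is.null(sim$mirna)) {
    hp <- hairpins(sim$mirna)
    mm <- matures(sim$mirna)
    g1 <- hp
    mcols(g1) <- DataFrame(type = "miRNA_primary_transcript",
                           ID = mcols(hp)$mirna_id,
                           Name = mcols(hp)$mirna_id)
    g2 <- mm
    mcols(g2) <- DataFrame(type = "miRNA",
                           ID = mcols(mm)$mirna_id,
                           Name = mcols(mm)$mirna_id,
                           Derives_from = mcols(mm)$hairpin_id)
    gff <- suppressWarnings(c(g1, g2))
    mcols(gff)$type <- factor(mcols(gff)$type)
    rtracklayer::export(gff, file.path(dir, "mirna.gff3"),
                        format = "GFF3")
  }
  exportGroundTruth(sim$truth, file.path(dir, "truth.tsv"))
  manifest <- file.path(dir, "manifest.txt")
  writeLines(c("# genotype path format total_reads",
               sprintf("%s %s bed6 %d", gts, basename(bedPaths),
                       as.integer(sim$librarySizes[gts]))),
             manifest)
  invisible(manifest)
}
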