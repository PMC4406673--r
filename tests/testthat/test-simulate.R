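test_that("simulated annotations are disjoint and deterministic", {
  cfg <- simConfig(nLoci = 10L, nMirna = 2L)
  a1 <- simulateAnnotations(cfg, seed = 3)
  a2 <- simulateAnnotations(cfg, seed = 3)
  expect_identical(as.data.frame(a1$loci), as.data.frame(a2$loci))
  expect_identical(as.data.frame(a1$starts), as.data.frame(a2$starts))
  expect_length(a1$loci, 10)
  ov <- findOverlaps(a1$loci, a1$loci, ignore.strand = TRUE)
  expect_equal(length(ov), 10)   # self-hits only: pairwise disjoint
  ## every start lies inside its locus
  li <- match(a1$starts$locus_id, mcols(a1$loci)$locus_id)
  expect_true(all(a1$starts$pos >= start(a1$loci)[li] &
                  a1$starts$pos <= end(a1$loci)[li]))
  ## zero loci -> empty annotation
  a0 <- simulateAnnotations(simConfig(nLoci = 0L, nMirna = 0L), seed = 1)
  expect_length(a0$loci, 0)
  ## infeasible placement errors
  expect_error(simulateAnnotations(simConfig(nLoci = 100L, chromLength = 1e4),
                                   seed = 1), "infeasible")
})

test_that("libraries are deterministic given (seed, genotype) and bounded 19-31 nt", {
  cfg <- simConfig(nLoci = 20L, depth = 5e3, nMirna = 2L)
  ann <- simulateAnnotations(cfg, seed = 8)
  tr <- simulateTruth(cfg, ann, seed = 8)
  l1 <- simulateLibrary(cfg, "null", ann, tr, seed = 8)
  l2 <- simulateLibrary(cfg, "null", ann, tr, seed = 8)
  expect_identical(as.data.frame(l1), as.data.frame(l2))
  l3 <- simulateLibrary(cfg, "wild_type", ann, tr, seed = 8)
  expect_false(identical(as.data.frame(l1), as.data.frame(l3)))
  expect_true(all(width(l1) >= 19 & width(l1) <= 31))
  expect_true(all(width(l3) >= 19 & width(l3) <= 31))
})

test_that("ground truth plants the exact affected count and exports stably", {
  cfg <- simConfig(nLoci = 200L, affectedFraction = 0.25, nMirna = 0L)
  ann <- simulateAnnotations(cfg, seed = 4)
  tr <- simulateTruth(cfg, ann, seed = 4)
  expect_equal(sum(tr$loci$affected), 50)   # exact, without replacement
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  exportGroundTruth(tr, f1)
  exportGroundTruth(tr, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(nrow(read.delim(f1)), 200)
})

test_that("the no-trimming limit removes all genotype differences", {
  cfg <- simConfig(nLoci = 5L, depth = 5e3, trimRate = 0,
                   mirnaTrimRate = 0, nMirna = 0L,
                   affectedFraction = 0.5)
  sim <- simulateExperiment(cfg, seed = 13)
  ## every read keeps its precursor length; pooled length distributions
  ## of all genotypes agree within sampling noise (chi-square on 29-31)
  lens <- lapply(sim$reads, function(gr)
    rep(width(gr), mcols(gr)$copies))
  tab <- sapply(lens, function(x) tabulate(factor(x, levels = 27:31)))
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.001)
})

test_that("the deterministic trimming limit separates genotypes exactly", {
  p <- setNames(numeric(13), 19:31)
  p["29"] <- 1
  cfg <- simConfig(nLoci = 4L, depth = 2e3, trimRate = 1,
                   trimMaxSize = 1L, precursorProbs = p,
                   affectedFraction = 1, nMirna = 0L)
  sim <- simulateExperiment(cfg, seed = 2)
  ## functional genotypes: every read trimmed by exactly 1 nt
  expect_true(all(width(sim$reads$wild_type) == 28))
  expect_true(all(width(sim$reads$rescue_wt) == 28))
  ## null and cat-dead keep full-length precursors at affected loci
  expect_true(all(width(sim$reads$null) == 29))
  expect_true(all(width(sim$reads$rescue_catdead) == 29))
})

test_that("mean length difference at an affected locus matches the trimming model", {
  cfg <- simConfig(nLoci = 1L, startsPerLocus = c(1L, 1L), depth = 1e4,
                   affectedFraction = 1, nMirna = 0L)
  sim <- simulateExperiment(cfg, seed = 31)
  mlen <- function(gr) {
    w <- rep(width(gr), mcols(gr)$copies)
    c(mean = mean(w), se = sd(w) / sqrt(length(w)), n = length(w))
  }
  wt <- mlen(sim$reads$wild_type)
  nl <- mlen(sim$reads$null)
  ## analytic expectation: E[diff] = trimRate * E[trim size] minus the
  ## small part absorbed by the 19 nt floor (negligible here)
  q <- 0.335; k <- 1:4
  w <- q * (1 - q)^(k - 1)
  expDiff <- 0.7 * sum(k * w) / sum(w)
  se <- sqrt(wt["se"]^2 + nl["se"]^2)
  expect_lt(abs((nl["mean"] - wt["mean"]) - expDiff), 3 * se)
})

test_that("unaffected loci have exchangeable length distributions across genotypes", {
  cfg <- simConfig(nLoci = 40L, depth = 1e4, affectedFraction = 0,
                   nMirna = 0L)
  sim <- simulateExperiment(cfg, seed = 17)
  ise <- buildIsoformTable(sim$reads, sim$loci, sim$librarySizes,
                           verbose = FALSE)
  rd <- rowData(ise)
  cts <- isoCounts(ise)
  rejected <- vapply(unique(rd$locus_id), function(l) {
    sel <- rd$locus_id == l
    wt <- rep(rd$length[sel], cts[sel, "wild_type"])
    nl <- rep(rd$length[sel], cts[sel, "null"])
    p <- suppressWarnings(ks.test(wt, nl)$p.value)
    p < 0.01
  }, logical(1))
  expect_gte(mean(!rejected), 0.95)
})

test_that("a simulated experiment round-trips through files into the pipeline", {
  dir <- withr::local_tempdir()
  cfg <- simConfig(nLoci = 10L, depth = 4e3, nMirna = 3L,
                   mirnaDepth = 2e3)
  sim <- simulateExperiment(cfg, seed = 23)
  manifest <- writeSimulatedData(sim, dir)
  expect_true(file.exists(manifest))
  ## re-read one library and compare collapsed counts
  mf <- readLibraryManifest(manifest)
  rd <- readAlignments(mf$path[mf$genotype == "null"], "bed6",
                       verbose = FALSE)
  expect_equal(sum(mcols(rd)$copies),
               sum(mcols(sim$reads$null)$copies))
  loci <- readLocusBed(file.path(dir, "loci.bed"))
  expect_equal(sort(mcols(loci)$locus_id),
               sort(mcols(sim$loci)$locus_id))
  ann <- readMirnaGff(file.path(dir, "mirna.gff3"))
  expect_length(hairpins(ann), 3)
  expect_length(matures(ann), 6)
  expect_setequal(mcols(matures(ann))$arm, c("5p", "3p"))
})
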