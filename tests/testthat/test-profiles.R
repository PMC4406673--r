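test_that("reads are assigned to loci by strand-aware 5'-end containment", {
  loci <- makeLoci(data.frame(chrom = "chr2L",
                              start = c(101, 1001, 5001),
                              end = c(200, 1100, 5100),
                              strand = c("+", "-", "*"),
                              locus_id = c("plus", "minus", "dual")))
  rd <- makeReads(data.frame(
    chrom = "chr2L",
    start5 = c(150,   # inside 'plus', same strand
               195,   # 5' inside, 3' end overhangs the boundary
               150,   # wrong strand for 'plus'
               1050,  # minus-strand read in minus locus
               5050,  # plus read in unstranded locus
               5060,  # minus read in unstranded locus
               900),  # outside all loci
    length = c(25, 25, 25, 25, 25, 25, 25),
    strand = c("+", "+", "-", "-", "+", "-", "+")))
  asg <- assignReadsToLoci(rd, loci, verbose = FALSE)
  expect_equal(mcols(asg)$locus_id,
               c("plus", "plus", "minus", "dual", "dual"))
  ac <- metadata(asg)$assign_counts
  expect_equal(unname(ac["unassigned"]), 2)  # wrong-strand + outside
  ## the overhanging read keeps its locus
  expect_true(195 %in% fivePrimeStart(asg))
})

test_that("isoform tables aggregate multiplicities and zero-fill across genotypes", {
  loci <- makeLoci(data.frame(chrom = "c", start = 1, end = 1000,
                              strand = "+", locus_id = "L1"))
  wt <- makeReads(data.frame(chrom = "c", start5 = c(100, 100, 100, 200),
                             length = c(25, 25, 26, 24), strand = "+",
                             copies = c(3, 2, 1, 4)))
  nul <- makeReads(data.frame(chrom = "c", start5 = 100, length = 27,
                              strand = "+", copies = 2))
  ise <- buildIsoformTable(
    list(wild_type = wt, null = nul), loci,
    c(wild_type = 1e6, null = 1e6), verbose = FALSE)
  rd <- as.data.frame(rowData(ise))
  cts <- isoCounts(ise)
  ## identical reads with copies 3 and 2 -> count 5
  expect_equal(unname(cts[rd$start5 == 100 & rd$length == 25, "wild_type"]),
               5L)
  ## key seen only in null exists, zero-filled, in wild_type
  expect_equal(unname(cts[rd$start5 == 100 & rd$length == 27, "wild_type"]),
               0L)
  expect_equal(unname(cts[rd$start5 == 100 & rd$length == 27, "null"]), 2L)
  ## conservation: total counts equal copies of assigned reads
  expect_equal(sum(cts[, "wild_type"]), sum(mcols(wt)$copies))
  expect_equal(sum(cts[, "null"]), sum(mcols(nul)$copies))
  ## empty library -> all-zero column
  ise0 <- buildIsoformTable(
    list(wild_type = wt, null = nul[0]), loci,
    c(wild_type = 1e6, null = 1e6), verbose = FALSE)
  expect_true(all(isoCounts(ise0)[, "null"] == 0))
})

test_that("hand-tabulated fixture counts match buildIsoformTable", {
  loci <- makeLoci(data.frame(chrom = "c", start = c(1, 2001),
                              end = c(1000, 3000), strand = c("+", "-"),
                              locus_id = c("A", "B")))
  ## 8 reads over 2 loci, 3 starts; tabulated by hand below
  rd <- makeReads(data.frame(
    chrom = "c",
    start5 = c(50, 50, 50, 120, 120, 2500, 2500, 2500),
    length = c(24, 24, 25, 26, 26, 30, 30, 29),
    strand = c("+", "+", "+", "+", "+", "-", "-", "-"),
    copies = c(1, 2, 1, 1, 1, 1, 1, 3)))
  ise <- buildIsoformTable(list(wild_type = rd), loci,
                           c(wild_type = 1e6), verbose = FALSE)
  got <- as.data.frame(rowData(ise))
  got$count <- as.integer(isoCounts(ise)[, 1])
  expected <- data.frame(
    locus_id = c("A", "A", "A", "B", "B"),
    strand = c("+", "+", "+", "-", "-"),
    start5 = c(50L, 50L, 120L, 2500L, 2500L),
    length = c(24L, 25L, 26L, 29L, 30L),
    count = c(3L, 1L, 2L, 3L, 2L))
  expect_equal(got, expected)
})

test_that("depth normalisation is count / total * 1e6", {
  expect_equal(normalizeDepth(50, 1e6), 50)
  expect_equal(normalizeDepth(0, 1e6), 0)
  expect_equal(normalizeDepth(7, 2e6), 3.5)
  expect_error(normalizeDepth(5, 0), "positive")
  expect_error(normalizeDepth(5, -10), "positive")
})

test_that("expression filter applies the three eligibility rules", {
  gts <- isoShiftGenotypes()
  df <- rbind(
    ## eligible: expressed everywhere, 2 lengths, max total >= 5
    data.frame(locus_id = "ok", strand = "+", start5 = 10L,
               length = c(25L, 26L), wild_type = c(3L, 3L), def_het = 1L,
               null = 1L, rescue_wt = 1L, rescue_catdead = 1L),
    ## below_min_reads: best genotype total is 4
    data.frame(locus_id = "low", strand = "+", start5 = 10L,
               length = c(25L, 26L), wild_type = c(2L, 2L), def_het = 1L,
               null = 1L, rescue_wt = 1L, rescue_catdead = 1L),
    ## single_length_category: every read is 25 nt
    data.frame(locus_id = "mono", strand = "+", start5 = 10L,
               length = 25L, wild_type = 9L, def_het = 9L, null = 9L,
               rescue_wt = 9L, rescue_catdead = 9L),
    ## not_expressed_all_genotypes: zero reads in rescue_wt
    data.frame(locus_id = "gap", strand = "+", start5 = 10L,
               length = c(25L, 26L), wild_type = 9L, def_het = 9L,
               null = 9L, rescue_wt = 0L, rescue_catdead = 9L))
  ise <- makeIse(df)
  st <- expressionFilter(ise, minTotal = 5)
  got <- setNames(st$reason, st$locus_id)
  expect_equal(got[["ok"]], "ok")
  expect_equal(got[["low"]], "below_min_reads")
  expect_equal(got[["mono"]], "single_length_category")
  expect_equal(got[["gap"]], "not_expressed_all_genotypes")
  expect_equal(st$eligible, st$reason == "ok")
})

test_that("expression filter is monotone: adding reads never revokes eligibility", {
  gts <- isoShiftGenotypes()
  set.seed(4)
  for (rep in 1:20) {
    base <- data.frame(locus_id = "L", strand = "+", start5 = 10L,
                       length = sample(19:31, 3))
    for (g in gts) base[[g]] <- rpois(3, 2)
    more <- base
    for (g in gts) more[[g]] <- more[[g]] + rpois(3, 3)
    before <- expressionFilter(makeIse(base))$eligible
    after <- expressionFilter(makeIse(more))$eligible
    expect_false(before && !after)
  }
})

test_that("length fractions normalise per start and are scale invariant", {
  expect_equal(lengthFractions(c(`24` = 10, `25` = 30, `26` = 60)),
               c(`24` = 0.1, `25` = 0.3, `26` = 0.6))
  expect_equal(unname(lengthFractions(c(`27` = 8))), 1)
  expect_equal(unname(lengthFractions(setNames(rep(1, 13), 19:31))),
               rep(1 / 13, 13))
  expect_error(lengthFractions(c(`25` = 0)), "undefined")

  df <- data.frame(locus_id = "L", strand = "+", start5 = 10L,
                   length = 24:26, wild_type = c(1L, 3L, 6L),
                   def_het = c(2L, 6L, 12L), null = c(5L, 15L, 30L),
                   rescue_wt = c(1L, 3L, 6L), rescue_catdead = c(10L, 30L, 60L))
  fr <- lengthFractions(makeIse(df))
  ## uniform scaling of counts leaves fractions unchanged
  for (g in isoShiftGenotypes())
    expect_equal(unname(fr[, g]), c(0.1, 0.3, 0.6))
})

test_that("density profiles equal isoform-table sums over lengths", {
  df <- expand.grid(locus_id = "L", strand = "+",
                    start5 = c(10L, 50L), length = 24:26,
                    stringsAsFactors = FALSE)
  set.seed(2)
  for (g in isoShiftGenotypes()) df[[g]] <- rpois(nrow(df), 5)
  ise <- makeIse(df)
  dp <- densityProfile(ise, "L")
  expect_equal(nrow(dp), 2)
  for (g in isoShiftGenotypes())
    expect_equal(dp[[g]], tapply(df[[g]], df$start5, sum, simplify = TRUE),
                 ignore_attr = TRUE)
  ## absent locus -> empty track
  expect_equal(nrow(densityProfile(ise, "nope")), 0)
})
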