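test_that("t statistic matches the pooled two-proportion form", {
  ## equal fractions -> 0
  r <- tStatistic(40, 100, 40, 100)
  expect_equal(r$t, 0)
  expect_equal(r$df, 200L)
  ## frozen: pbar = 0.5, SE = sqrt(0.005)
  r <- tStatistic(60, 100, 40, 100)
  expect_equal(r$t, 0.2 / sqrt(0.005), tolerance = 1e-12)
  expect_equal(r$t, 2.8284271, tolerance = 1e-6)
  ## antisymmetry under swapping samples
  set.seed(1)
  for (i in 1:25) {
    n1 <- sample(2:500, 1); n2 <- sample(2:500, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    a <- tStatistic(k1, n1, k2, n2)
    b <- tStatistic(k2, n2, k1, n1)
    expect_equal(a$t, -b$t, tolerance = 1e-12)
    expect_equal(a$df, b$df)
  }
  ## degenerate pooled fraction (0 or 1) -> fractions equal, t = 0
  expect_equal(tStatistic(0, 10, 0, 20)$t, 0)
  expect_equal(tStatistic(10, 10, 20, 20)$t, 0)
  ## preconditions
  expect_error(tStatistic(1, 1, 5, 10), "at least 2")
  expect_error(tStatistic(11, 10, 5, 10), "0 <= k <= n")
})

test_that("t statistic agrees with an independent chi-square computation", {
  ## |t| equals sqrt of the Pearson chi-square of the 2x2 table
  set.seed(7)
  for (i in 1:50) {
    n1 <- sample(2:400, 1); n2 <- sample(2:400, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    pbar <- (k1 + k2) / (n1 + n2)
    if (pbar %in% c(0, 1)) next
    z2 <- suppressWarnings(
      prop.test(c(k1, k2), c(n1, n2), correct = FALSE)$statistic)
    expect_equal(abs(tStatistic(k1, n1, k2, n2)$t), sqrt(unname(z2)),
                 tolerance = 1e-9)
  }
})

test_that("P-values come from the Student t tail with read-count df", {
  expect_equal(tPValue(0, 10), 1)
  ## large-df limit agrees with the normal quantile
  expect_equal(tPValue(1.959964, 1e7), 0.05, tolerance = 1e-5)
  ## numerical-integration oracle at the frozen example
  t0 <- 2.8284271; df0 <- 200
  oracle <- 2 * integrate(dt, abs(t0), Inf, df = df0,
                          rel.tol = 1e-12)$value
  expect_equal(tPValue(t0, df0), oracle, tolerance = 1e-9)
  ## p strictly decreasing in |t| at fixed df, symmetric in sign
  ts <- seq(0, 6, by = 0.25)
  ps <- tPValue(ts, 37)
  expect_true(all(diff(ps) < 0))
  expect_equal(tPValue(-ts, 37), ps)
  expect_error(tPValue(1, 0), "df")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(fdrAdjust(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(fdrAdjust(0.2), 0.2)
  expect_equal(fdrAdjust(rep(0.07, 5)), rep(0.07, 5))
  expect_identical(fdrAdjust(numeric()), numeric())
  set.seed(11)
  for (i in 1:200) {
    m <- sample(1:60, 1)
    p <- round(runif(m), sample(1:3, 1))   # rounding forces ties
    q <- fdrAdjust(p)
    expect_equal(q, bruteForceBH(p), tolerance = 1e-12)
    expect_true(all(q >= p))
  }
})

test_that("Cohen's d uses the pooled Bernoulli SD", {
  expect_equal(cohensD(40, 100, 40, 100), 0)
  expect_equal(cohensD(60, 100, 40, 100), 0.2 / sqrt(0.24),
               tolerance = 1e-12)
  expect_equal(cohensD(60, 100, 40, 100), 0.4082483, tolerance = 1e-6)
  ## degenerate full separation
  expect_equal(cohensD(0, 50, 50, 50), Inf)
  expect_true(all(cohensD(c(10, 20), 50, c(40, 5), 50) >= 0))
  expect_error(cohensD(1, 1, 5, 10), "at least 2")
})

test_that("peak calls require direction, FDR and effect size together", {
  expect_equal(callPeaks(3.1, 0.01, 0.9), "up")
  expect_equal(callPeaks(-3.1, 0.01, 0.9), "down")
  expect_equal(callPeaks(3.1, 0.01, 0.4), "none")   # effect-size gate
  expect_equal(callPeaks(3.1, 0.06, 0.9), "none")   # FDR gate
  expect_equal(callPeaks(0, 0.01, 0.9), "none")
  expect_equal(callPeaks(c(2, -2, 2), c(0.01, 0.01, 0.2), c(1, 1, 1)),
               c("up", "down", "none"))
})

test_that("lengthShiftTests builds one gated test per present length", {
  df <- rbind(
    data.frame(locus_id = "L", strand = "+", start5 = 10L,
               length = c(25L, 26L, 27L),
               wild_type = c(70L, 25L, 5L), def_het = c(68L, 26L, 6L),
               null = c(20L, 30L, 50L), rescue_wt = c(69L, 26L, 5L),
               rescue_catdead = c(22L, 28L, 50L)),
    ## a start below the per-start read floor in null: skipped there
    data.frame(locus_id = "L", strand = "+", start5 = 400L,
               length = c(25L, 26L), wild_type = c(4L, 4L),
               def_het = c(4L, 4L), null = c(1L, 0L),
               rescue_wt = c(4L, 4L), rescue_catdead = c(4L, 4L)))
  ise <- makeIse(df)
  res <- shiftResults(lengthShiftTests(ise))
  expect_setequal(unique(res$genotype),
                  c("def_het", "null", "rescue_wt", "rescue_catdead"))
  ## df is the sum total of reads at the (locus, start) pair
  expect_true(all(res$df == res$n_obs + res$n_ref))
  ## start 400 skipped for null (1 read) but tested for def_het
  expect_false(any(res$genotype == "null" & res$start5 == 400))
  expect_true(any(res$genotype == "def_het" & res$start5 == 400))
  ## q >= p within each comparison family
  expect_true(all(res$q >= res$p - 1e-12))
  ## the planted 27 nt increase in null is an upward peak
  up <- res[res$genotype == "null" & res$length == 27, ]
  expect_equal(up$direction, "up")
  expect_true(up$t > 0 && up$q <= 0.05 && up$d >= 0.6)
  ## def_het tracks wild-type: no calls
  expect_true(all(res$direction[res$genotype == "def_het"] == "none"))
  ## one-sample SE variant is exposed and differs from pooled
  res1 <- shiftResults(lengthShiftTests(ise, statistic = "one_sample"))
  both <- merge(as.data.frame(res), as.data.frame(res1),
                by = c("locus_id", "strand", "start5", "length", "genotype"))
  expect_true(any(abs(both$t.x - both$t.y) > 1e-9))
})

test_that("ineligible loci are excluded from testing", {
  df <- data.frame(locus_id = "mono", strand = "+", start5 = 10L,
                   length = 25L, wild_type = 50L, def_het = 50L,
                   null = 50L, rescue_wt = 50L, rescue_catdead = 50L)
  ise <- makeIse(df)
  expect_equal(nrow(shiftResults(lengthShiftTests(ise))), 0)
})
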