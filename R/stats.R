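#' @include AllClasses.R profiles.R
#' @importFrom stats pt p.adjust
NULL

#' Two-proportion t statistic on length fractions
#'
#' The departure of an observed length fraction from its wild-type
#' expectation, as (observed - expected) / standard error. With the
#' default pooled form the standard error is the pooled binomial SE
#' \eqn{\sqrt{\bar p(1-\bar p)(1/n_{obs}+1/n_{ref})}} with
#' \eqn{\bar p = (k_{obs}+k_{ref})/(n_{obs}+n_{ref})} — the classical
#' pooled two-proportion z statistic. The `one_sample` alternative takes
#' the SE from the reference fraction alone,
#' \eqn{\sqrt{f_{ref}(1-f_{ref})/n_{obs}}}. Degrees of freedom are the
#' sum total of reads considered, `n_obs + n_ref`. When the SE is zero
#' because the pooled fraction is 0 or 1, both fractions are necessarily
#' equal and t is 0 by convention.
#'
#' All arguments are vectorised.
#'
#' @param kObs,nObs reads of the tested length and total reads at the
#'   (locus, start) in the tested genotype.
#' @param kRef,nRef the same in the reference (wild-type) genotype.
#' @param statistic `"pooled"` (default) or `"one_sample"`.
#' @return `data.frame` with columns `t` (signed; positive = enrichment
#'   in the tested genotype) and `df`.
#' @examples
#' tStatistic(60, 100, 40, 100)   # t ~ 2.83, df 200
#' @export
tStatistic <- function(kObs, nObs, kRef, nRef,
                       statistic = c("pooled", "one_sample")) {
  statistic <- match.arg(statistic)
  if (any(nObs < 2) || any(nRef < 2))
    stop("tStatistic requires at least 2 reads at the start position in ",
         "both libraries")
  if (any(kObs < 0 | kObs > nObs) || any(kRef < 0 | kRef > nRef))
    stop("counts must satisfy 0 <= k <= n")
  fObs <- kObs / nObs
  fRef <- kRef / nRef
  se <- if (statistic == "pooled") {
    pbar <- (kObs + kRef) / (nObs + nRef)
    sqrt(pbar * (1 - pbar) * (1 / nObs + 1 / nRef))
  } else {
    sqrt(fRef * (1 - fRef) / nObs)
  }
  t <- ifelse(se > 0, (fObs - fRef) / se,
              ifelse(fObs == fRef, 0, Inf * sign(fObs - fRef)))
  data.frame(t = t, df = as.integer(nObs + nRef))
}

#' Two-sided P-value from the t statistic
#'
#' Converts the statistic to a two-sided P-value with the Student t
#' distribution, using the read-count degrees of freedom.
#'
#' @param t t statistics.
#' @param df degrees of freedom (>= 1), recycled.
#' @return P-values in `[0, 1]` (`(0, 1]` for finite `t`).
#' @examples
#' tPValue(0, 10)        # 1
#' tPValue(2.8284, 200)  # ~ 0.0052
#' @export
tPValue <- function(t, df) {
  if (any(df < 1)) stop("df must be >= 1")
  2 * stats::pt(-abs(t), df = df)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment within one comparison family:
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1, returned in
#' input order. Implemented through [stats::p.adjust()].
#'
#' @param p P-values in `[0, 1]`.
#' @return q-values, `q >= p` elementwise.
#' @examples
#' fdrAdjust(c(0.01, 0.04, 0.03))   # 0.03 0.04 0.04
#' @export
fdrAdjust <- function(p) {
  if (!length(p)) return(numeric())
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Cohen's d for two proportions
#'
#' Standardised effect size of a fraction difference,
#' \eqn{d = |f_{obs}-f_{ref}| / s_{pool}} with the pooled Bernoulli SD
#' \eqn{s_{pool} = \sqrt{(f_{obs}(1-f_{obs}) + f_{ref}(1-f_{ref}))/2}}.
#' When `s_pool` is 0, d is 0 for equal fractions and `Inf` for the
#' degenerate fully separated case. Vectorised.
#'
#' @inheritParams tStatistic
#' @return Non-negative effect sizes.
#' @examples
#' cohensD(60, 100, 40, 100)   # ~ 0.408
#' @export
cohensD <- function(kObs, nObs, kRef, nRef) {
  if (any(nObs < 2) || any(nRef < 2))
    stop("cohensD requires at least 2 reads in both libraries")
  if (any(kObs < 0 | kObs > nObs) || any(kRef < 0 | kRef > nRef))
    stop("counts must satisfy 0 <= k <= n")
  fObs <- kObs / nObs
  fRef <- kRef / nRef
  spool <- sqrt((fObs * (1 - fObs) + fRef * (1 - fRef)) / 2)
  ifelse(spool > 0, abs(fObs - fRef) / spool,
         ifelse(fObs == fRef, 0, Inf))
}

#' Call significant upward/downward peaks
#'
#' A length category is an upward peak in the tested genotype when its
#' fraction increased (`t > 0`) with `q <= alpha` and `d >= dMin`; a
#' downward peak when it decreased under the same gates; otherwise no
#' call.
#'
#' @param t,q,d vectors of statistics, q-values and effect sizes.
#' @param alpha FDR threshold (default 0.05).
#' @param dMin Cohen's d threshold (default 0.6, a moderate-to-large
#'   effect).
#' @return Character vector in `c("up", "down", "none")`.
#' @export
callPeaks <- function(t, q, d, alpha = 0.05, dMin = 0.6) {
  sig <- q <= alpha & d >= dMin
  out <- rep("none", length(t))
  out[sig & t > 0] <- "up"
  out[sig & t < 0] <- "down"
  out
}

#' Length-fraction tests of every mutant genotype against wild-type
#'
#' The core screen: for each eligible locus, each 5' start position and
#' each length category present, the fraction of reads of that length is
#' compared between each non-reference genotype and the wild-type
#' reference with [tStatistic()], converted to a two-sided P-value with
#' read-count degrees of freedom, BH-adjusted within the comparison
#' family, gated by Cohen's d, and called as an upward or downward peak.
#'
#' Start positions with fewer than `minStartReads` reads in either
#' compared library are skipped (the SE would be undefined or
#' degenerate). By default each genotype-vs-wild-type comparison forms
#' its own BH family; `fdrFamily = "global"` corrects all comparisons
#' jointly.
#'
#' @param ise an [IsoformExperiment] containing the reference genotype.
#' @param reference reference genotype (default `wild_type`).
#' @param statistic SE form, `"pooled"` or `"one_sample"`.
#' @param alpha FDR threshold for peak calls.
#' @param dMin Cohen's d threshold for peak calls.
#' @param minTotal locus expression-filter threshold (see
#'   [expressionFilter()]).
#' @param minStartReads per-start read floor in each compared library.
#' @param fdrFamily `"per_comparison"` or `"global"`.
#' @return A [LengthShiftResults] object.
#' @export
lengthShiftTests <- function(ise, reference = "wild_type",
                             statistic = c("pooled", "one_sample"),
                             alpha = 0.05, dMin = 0.6, minTotal = 5,
                             minStartReads = 2,
                             fdrFamily = c("per_comparison", "global")) {
  statistic <- match.arg(statistic)
  fdrFamily <- match.arg(fdrFamily)
  stopifnot(is(ise, "IsoformExperiment"))
  gts <- genotypes(ise)
  if (!reference %in% gts)
    stop("reference genotype '", reference, "' absent from the experiment")
  status <- expressionFilter(ise, minTotal = minTotal)
  keepLoci <- status$locus_id[status$eligible]
  rd <- rowData(ise)
  sel <- rd$locus_id %in% keepLoci
  cts <- isoCounts(ise)
  ntot <- .startTotals(ise)
  testGts <- setdiff(gts, reference)
  pieces <- lapply(testGts, function(g) {
    kObs <- cts[, g]; nObs <- ntot[, g]
    kRef <- cts[, reference]; nRef <- ntot[, reference]
    use <- sel & nObs >= minStartReads & nRef >= minStartReads &
      (kObs + kRef) > 0
    if (!any(use)) return(NULL)
    st <- tStatistic(kObs[use], nObs[use], kRef[use], nRef[use],
                     statistic = statistic)
    DataFrame(locus_id = rd$locus_id[use], strand = rd$strand[use],
              start5 = rd$start5[use], length = rd$length[use],
              genotype = g,
              k_obs = as.numeric(kObs[use]), n_obs = as.numeric(nObs[use]),
              k_ref = as.numeric(kRef[use]), n_ref = as.numeric(nRef[use]),
              f_obs = kObs[use] / nObs[use], f_ref = kRef[use] / nRef[use],
              t = st$t, df = st$df,
              p = tPValue(st$t, st$df),
              d = cohensD(kObs[use], nObs[use], kRef[use], nRef[use]))
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (!length(pieces)) {
    res <- DataFrame(locus_id = character(), strand = character(),
                     start5 = integer(), length = integer(),
                     genotype = character(), k_obs = numeric(),
                     n_obs = numeric(), k_ref = numeric(),
                     n_ref = numeric(), f_obs = numeric(),
                     f_ref = numeric(), t = numeric(), df = integer(),
                     p = numeric(), q = numeric(), d = numeric(),
                     direction = character())
  } else {
    res <- do.call(rbind, pieces)
    if (fdrFamily == "global") {
      res$q <- fdrAdjust(res$p)
    } else {
      res$q <- NA_real_
      for (g in unique(res$genotype)) {
        i <- res$genotype == g
        res$q[i] <- fdrAdjust(res$p[i])
      }
    }
    res$direction <- callPeaks(res$t, res$q, res$d, alpha, dMin)
    res <- res[order(res$genotype, res$locus_id, res$strand, res$start5,
                     res$length), ]
    res <- res[, c("locus_id", "strand", "start5", "length", "genotype",
                   "k_obs", "n_obs", "k_ref", "n_ref", "f_obs", "f_ref",
                   "t", "df", "p", "q", "d", "direction")]
  }
  new("LengthShiftResults", results = res, reference = reference,
      statistic = statistic, alpha = alpha, dMin = dMin,
      fdrFamily = fdrFamily, minTotal = minTotal,
      minStartReads = minStartReads)
}
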