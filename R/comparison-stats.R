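#' Reconstruct null/positive counts from a published frequency
#'
#' Reference panels typically store (n, null genotype frequency) pairs;
#' contingency tests need counts. \code{round_nearest} rounds n * fNull half
#' away from zero, \code{floor} truncates, and \code{exact_fractional} keeps
#' the fractional expectation (acceptable for a Pearson statistic, invalid
#' for Fisher's exact test, which is defined on integer tables).
#'
#' @param n population sample size.
#' @param fNull null genotype frequency.
#' @param policy one of "round_nearest", "floor", "exact_fractional".
#' @return named numeric vector \code{c(nNull, nPositive)}.
#' @export
#' @examples
#' reconstructCounts(120, 0.510)  # 61 null, 59 positive
reconstructCounts <- function(n, fNull,
                              policy = c("round_nearest", "floor",
                                         "exact_fractional")) {
  policy <- match.arg(policy)
  stopifnot(n >= 1, fNull >= 0, fNull <= 1)
  x <- n * fNull
  nNull <- switch(policy,
                  round_nearest = roundHalfUp(x),
                  floor = floor(x),
                  exact_fractional = x)
  c(nNull = nNull, nPositive = n - nNull)
}

#' Build a labeled 2x2 null/positive contingency table
#'
#' Rows are populations, columns are the (null, positive) phenotype counts.
#' A provenance flag records whether the counts were observed directly or
#' reconstructed from a published frequency, so that downstream reports can
#' mark reconstructed-count p-values as approximate.
#'
#' @param labels length-2 character, population names.
#' @param nullCounts,positiveCounts length-2 numeric counts.
#' @param provenance "observed" or "reconstructed".
#' @return 2x2 numeric matrix with dimnames and a "provenance" attribute.
#' @export
contingency2x2 <- function(labels, nullCounts, positiveCounts,
                           provenance = c("observed", "reconstructed")) {
  provenance <- match.arg(provenance)
  tab <- cbind(null = nullCounts, positive = positiveCounts)
  rownames(tab) <- labels
  tab <- checkSymmetric2x2(tab)
  attr(tab, "provenance") <- provenance
  tab
}

expectedCounts <- function(tab) {
  outer(rowSums(tab), colSums(tab)) / sum(tab)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected by default; with \code{yates = TRUE} the continuity
#' correction max(0, |O - E| - 0.5) is applied. The p-value is the upper
#' tail of the chi-square distribution with 1 df.
#'
#' @param table 2x2 matrix of counts (fractional entries allowed).
#' @param yates apply Yates continuity correction.
#' @return one-row data.frame: \code{statistic}, \code{df}, \code{p},
#'   \code{method}, \code{minExpected}.
#' @export
pearsonChi2 <- function(table, yates = FALSE) {
  tab <- checkSymmetric2x2(table)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal total: the chi-square test is undefined; use fisherExact()")
  ht <- suppressWarnings(chisq.test(tab, correct = yates))
  data.frame(statistic = unname(ht$statistic), df = 1L,
             p = ht$p.value,
             method = if (yates) "pearson_yates" else "pearson",
             minExpected = min(ht$expected),
             stringsAsFactors = FALSE)
}

#' Fisher's exact test on a 2x2 table
#'
#' Conditional on the margins, the first cell is hypergeometric. The
#' two-sided p-value sums, over all tables with the same margins, the point
#' probabilities not exceeding that of the observed table (within a relative
#' tie tolerance of 1e-7) — the usual point-probability convention. The
#' alternative "double one-sided" definition (twice the smaller tail,
#' capped at 1) is available via \code{twoSided}.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param twoSided "point_probability" (default) or "double_one_sided".
#' @return one-row data.frame: \code{statistic} (NA: the test has no
#'   statistic), \code{df}, \code{p}, \code{method}, \code{minExpected}.
#' @export
#' @examples
#' fisherExact(matrix(c(5, 0, 0, 5), 2, byrow = TRUE))  # p = 2/252
fisherExact <- function(table,
                        twoSided = c("point_probability",
                                     "double_one_sided")) {
  twoSided <- match.arg(twoSided)
  tab <- checkSymmetric2x2(table)
  if (any(abs(tab - round(tab)) > 1e-9))
    stop("Fisher's exact test requires integer counts")
  tab <- round(tab)
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  xs <- max(0, k - n2):min(k, m)
  pr <- dhyper(xs, m, n2, k)
  pObs <- dhyper(a, m, n2, k)
  p <- if (twoSided == "point_probability") {
    sum(pr[pr <= pObs * (1 + 1e-7)])
  } else {
    lo <- phyper(a, m, n2, k)
    hi <- phyper(a - 1, m, n2, k, lower.tail = FALSE)
    min(1, 2 * min(lo, hi))
  }
  data.frame(statistic = NA_real_, df = NA_integer_, p = min(1, p),
             method = "fisher",
             minExpected = if (sum(tab) > 0) min(expectedCounts(tab)) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Compare a cohort's locus frequency against every panel population
#'
#' Reconstructs counts for each panel population from its (n, frequency)
#' pair and tests it against the cohort's observed counts. Panel rows
#' lacking n or lacking the locus frequency cannot be tested and are skipped
#' with a notice. Under the "auto" policy Fisher's exact test is chosen when
#' the smallest expected cell count falls below \code{fisherThreshold},
#' otherwise the Pearson test.
#'
#' @param current a \linkS4class{LocusFrequency} for the cohort.
#' @param panel a \linkS4class{ReferencePanel}.
#' @param locus locus to compare (must be in the panel).
#' @param method "auto", "pearson" or "fisher".
#' @param countPolicy count reconstruction policy, see
#'   [reconstructCounts()].
#' @param yates Yates correction for Pearson tests.
#' @param fisherThreshold expected-count threshold for "auto".
#' @param adjust multiple-testing adjustment for the added \code{pAdj}
#'   column; default "none" (no adjustment is applied or reported).
#' @return data.frame with one row per comparable population: population, n,
#'   fNull, nNull, method, statistic, p, minExpected, provenance. Skipped
#'   populations are listed in attribute \code{skipped}.
#' @export
comparePanel <- function(current, panel, locus,
                         method = c("auto", "pearson", "fisher"),
                         countPolicy = "round_nearest", yates = FALSE,
                         fisherThreshold = 5,
                         adjust = c("none", "bonferroni", "BH")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  stopifnot(is(current, "LocusFrequency"), is(panel, "ReferencePanel"))
  freqs <- nullFreq(panel, locus)
  sizes <- panelSizes(panel)
  pops <- populations(panel)
  usable <- !is.na(freqs) & !is.na(sizes)
  skipped <- pops[!usable]
  if (length(skipped))
    message("skipping (missing n or ", locus, " frequency): ",
            paste(skipped, collapse = ", "))
  rows <- lapply(pops[usable], function(pp) {
    cnt <- reconstructCounts(sizes[[pp]], freqs[[pp]], policy = countPolicy)
    tab <- contingency2x2(c(current@locus, pp),
                          nullCounts = c(current@nNull, cnt[["nNull"]]),
                          positiveCounts = c(current@n - current@nNull,
                                             cnt[["nPositive"]]),
                          provenance = "reconstructed")
    use <- method
    if (use == "auto") {
      minE <- min(expectedCounts(tab))
      use <- if (minE < fisherThreshold) "fisher" else "pearson"
    }
    res <- if (use == "fisher") fisherExact(tab) else pearsonChi2(tab, yates)
    data.frame(population = pp, n = sizes[[pp]], fNull = freqs[[pp]],
               nNull = cnt[["nNull"]], method = res$method,
               statistic = res$statistic, p = res$p,
               minExpected = res$minExpected, provenance = "reconstructed",
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(population = character(), n = integer(), fNull = numeric(),
               nNull = numeric(), method = character(), statistic = numeric(),
               p = numeric(), minExpected = numeric(),
               provenance = character(), stringsAsFactors = FALSE)
  if (adjust != "none")
    out$pAdj <- stats::p.adjust(out$p, method = adjust)
  attr(out, "skipped") <- skipped
  out
}
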