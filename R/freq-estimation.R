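#' LocusFrequency: genotype counts and HWE-derived allele frequencies
#'
#' Summary of one locus in one population: observed null-genotype count and
#' frequency, the Hardy-Weinberg-derived null allele frequency
#' \eqn{q = \sqrt{f_{null}}}, its complement \eqn{p = 1 - q}, and (optionally)
#' a standard error and confidence interval for q. Because the marker is
#' dominant, q is identifiable only through the HWE assumption, and HWE
#' itself is untestable from the phenotype data (the positive class collapses
#' two genotypes): the class therefore carries no HWE test result.
#'
#' @slot locus locus label.
#' @slot n number of individuals typed.
#' @slot nNull number with the null phenotype.
#' @slot fNull observed null genotype frequency, nNull/n at full precision.
#' @slot q,p HWE-derived allele frequencies.
#' @slot seQ delta-method or bootstrap standard error of q (NA if not asked).
#' @slot ciQ length-2 confidence bounds for q, truncated to [0, 1].
#' @slot ciLevel nominal level of ciQ.
#' @slot ciMethod one of "delta", "bootstrap", "clopper_pearson_sqrt", "none".
#' @aliases LocusFrequency-class
#' @exportClass LocusFrequency
setClass("LocusFrequency",
         representation(locus = "character", n = "integer", nNull = "integer",
                        fNull = "numeric", q = "numeric", p = "numeric",
                        seQ = "numeric", ciQ = "numeric", ciLevel = "numeric",
                        ciMethod = "character"))

setValidity("LocusFrequency", function(object) {
  msg <- character()
  if (object@nNull > object@n || object@nNull < 0)
    msg <- c(msg, "nNull must lie in [0, n]")
  if (object@fNull < 0 || object@fNull > 1)
    msg <- c(msg, "fNull must lie in [0, 1]")
  if (abs(object@q - sqrt(object@fNull)) > 1e-12)
    msg <- c(msg, "q must equal sqrt(fNull)")
  if (abs(object@p + object@q - 1) > 1e-12)
    msg <- c(msg, "p + q must equal 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LocusFrequency", function(object) {
  cat(sprintf("LocusFrequency for %s (n = %d)\n", object@locus, object@n))
  cat(sprintf("  null genotype: %d/%d (%s%%)\n", object@nNull, object@n,
              fmtPercent(object@fNull)))
  cat(sprintf("  HWE allele frequencies: q = %s, p = %s\n",
              fmtFreq4(object@q), fmtFreq4(object@p)))
  if (!is.na(object@seQ) || !all(is.na(object@ciQ)))
    cat(sprintf("  se(q) = %s, %d%% CI [%s, %s] (%s)\n",
                ifelse(is.na(object@seQ), "NA", fmtFreq4(object@seQ)),
                round(100 * object@ciLevel), fmtFreq4(object@ciQ[1]),
                fmtFreq4(object@ciQ[2]), object@ciMethod))
  invisible(NULL)
})

#' Null-allele frequency under Hardy-Weinberg equilibrium
#'
#' For a dominant deletion marker the null phenotype is the q^2 class of the
#' HWE expansion p^2 + 2pq + q^2 = 1, so the null allele frequency is the
#' square root of the observed null genotype frequency and p = 1 - q.
#'
#' @param fNull observed null genotype frequency in [0, 1] (vectorized).
#' @return named numeric (or 2-column matrix for vector input) with
#'   components \code{q} and \code{p}, at full precision; rounding is left to
#'   the presentation layer.
#' @export
#' @examples
#' estimateNullAllele(116 / 300)  # q ~ 0.6218, p ~ 0.3782
estimateNullAllele <- function(fNull) {
  if (any(!is.finite(fNull)) || any(fNull < 0 | fNull > 1))
    stop("fNull must lie in [0, 1]")
  q <- sqrt(fNull)
  if (length(fNull) == 1L) c(q = q, p = 1 - q)
  else cbind(q = q, p = 1 - q)
}

#' Uncertainty of the HWE null-allele frequency estimate
#'
#' Delta method: with fHat ~ Binomial(n, f)/n and q = sqrt(f),
#' se(q) = sqrt(f (1 - f) / n) / (2 sqrt(f)), giving a Wald interval
#' truncated to [0, 1]. The percentile bootstrap resamples the n phenotype
#' calls (equivalently, binomial draws at fNull) with a fixed seed. At the
#' boundaries fNull = 0 or 1 the delta method degenerates; a Clopper-Pearson
#' interval on fNull is computed and square-root transformed instead.
#'
#' @param n number of individuals.
#' @param fNull observed null genotype frequency.
#' @param level confidence level (default 0.95).
#' @param method "delta" or "bootstrap".
#' @param B bootstrap replicates.
#' @param seed seed for the bootstrap (required for reproducibility).
#' @return list with \code{seQ}, \code{ciQ} (length 2) and \code{method}.
#' @export
alleleUncertainty <- function(n, fNull, level = 0.95,
                              method = c("delta", "bootstrap"),
                              B = 2000L, seed = NULL) {
  method <- match.arg(method)
  stopifnot(n >= 1, fNull >= 0, fNull <= 1)
  alpha <- 1 - level
  q <- sqrt(fNull)
  if (method == "delta") {
    if (fNull == 0 || fNull == 1) {
      x <- round(n * fNull)
      lo <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
      hi <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
      return(list(seQ = NA_real_, ciQ = sqrt(c(lo, hi)),
                  method = "clopper_pearson_sqrt"))
    }
    se <- sqrt(fNull * (1 - fNull) / n) / (2 * sqrt(fNull))
    z <- qnorm(1 - alpha / 2)
    ci <- pmin(1, pmax(0, q + c(-1, 1) * z * se))
    list(seQ = se, ciQ = ci, method = "delta")
  } else {
    if (!is.null(seed)) set.seed(seed)
    qs <- sqrt(rbinom(B, n, fNull) / n)
    ci <- unname(quantile(qs, c(alpha / 2, 1 - alpha / 2), type = 7))
    list(seQ = sd(qs), ciQ = ci, method = "bootstrap")
  }
}

#' Phenotype and allele frequencies at one locus
#'
#' Tabulates the null phenotype at a locus, derives the HWE allele
#' frequencies, and optionally attaches uncertainty for q.
#'
#' @param cohort a \linkS4class{GenotypeCohort}.
#' @param locus locus name (must be typed in the cohort).
#' @param ci "none", "delta" or "bootstrap".
#' @param level,B,seed passed to [alleleUncertainty()].
#' @return a \linkS4class{LocusFrequency}.
#' @export
#' @examples
#' m <- rbind(GSTM1 = rep(c(TRUE, FALSE), c(116, 184)))
#' colnames(m) <- sprintf("S%03d", 1:300)
#' phenotypeFrequencies(GenotypeCohort(m), "GSTM1")
phenotypeFrequencies <- function(cohort, locus,
                                 ci = c("none", "delta", "bootstrap"),
                                 level = 0.95, B = 2000L, seed = NULL) {
  ci <- match.arg(ci)
  stopifnot(is(cohort, "GenotypeCohort"))
  if (!locus %in% loci(cohort))
    stop("locus '", locus, "' not typed in this cohort")
  n <- ncol(cohort)
  if (n == 0L)
    stop("cohort is empty at locus '", locus, "'")
  nNull <- sum(nullCalls(cohort)[locus, ])
  fNull <- nNull / n
  qp <- estimateNullAllele(fNull)
  unc <- if (ci == "none")
    list(seQ = NA_real_, ciQ = c(NA_real_, NA_real_), method = "none")
  else alleleUncertainty(n, fNull, level = level, method = ci, B = B,
                         seed = seed)
  new("LocusFrequency", locus = locus, n = as.integer(n),
      nNull = as.integer(nNull), fNull = fNull,
      q = unname(qp["q"]), p = unname(qp["p"]),
      seQ = unc$seQ, ciQ = unc$ciQ, ciLevel = level, ciMethod = unc$method)
}

#' Two-locus phenotype combination table
#'
#' Joint tabulation of the four phenotype combinations (+/+, +/null,
#' null/+, null/null) across two loci, by direct counting.
#'
#' @param cohort a \linkS4class{GenotypeCohort}.
#' @param locusA,locusB locus names; the first locus varies slowest in the
#'   output rows.
#' @return data.frame with columns \code{combination}, \code{count},
#'   \code{frequency} and \code{percent} (half-up rounded string); the cohort
#'   size is attached as attribute \code{n}.
#' @export
combinationFrequencies <- function(cohort, locusA, locusB) {
  stopifnot(is(cohort, "GenotypeCohort"))
  for (l in c(locusA, locusB))
    if (!l %in% loci(cohort))
      stop("locus '", l, "' not typed in this cohort")
  n <- ncol(cohort)
  if (n == 0L) stop("cohort is empty")
  a <- nullCalls(cohort)[locusA, ]
  b <- nullCalls(cohort)[locusB, ]
  counts <- c(sum(!a & !b), sum(!a & b), sum(a & !b), sum(a & b))
  lab <- c(sprintf("%s+/%s+", locusA, locusB),
           sprintf("%s+/%s null", locusA, locusB),
           sprintf("%s null/%s+", locusA, locusB),
           sprintf("%s null/%s null", locusA, locusB))
  out <- data.frame(combination = lab, count = counts,
                    frequency = counts / n,
                    percent = fmtPercent(counts / n),
                    stringsAsFactors = FALSE)
  attr(out, "n") <- n
  attr(out, "loci") <- c(locusA, locusB)
  out
}

#' Genotype summary table for several loci
#'
#' One positive and one null row per locus, mirroring the usual published
#' layout (counts, observed frequency, HWE allele frequency). Frequencies
#' are full precision; the \code{*_txt} columns carry the half-up rounded
#' presentation strings (4 decimals for frequencies, 2 for percentages).
#'
#' @param cohort a \linkS4class{GenotypeCohort}.
#' @param whichLoci loci to summarize (default: all typed).
#' @return data.frame with two rows per locus.
#' @export
genotypeSummary <- function(cohort, whichLoci = loci(cohort)) {
  rows <- lapply(whichLoci, function(l) {
    lf <- phenotypeFrequencies(cohort, l)
    data.frame(
      locus = l,
      genotype = c("positive", "null"),
      count = c(lf@n - lf@nNull, lf@nNull),
      frequency = c(1 - lf@fNull, lf@fNull),
      allele = c("p", "q"),
      allele_frequency = c(lf@p, lf@q),
      frequency_txt = fmtFreq4(c(1 - lf@fNull, lf@fNull)),
      percent_txt = fmtPercent(c(1 - lf@fNull, lf@fNull)),
      allele_frequency_txt = fmtFreq4(c(lf@p, lf@q)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
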