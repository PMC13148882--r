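#' Nei's normalized genetic identity for one biallelic locus
#'
#' For allele profiles (p, q) = (1 - q, q) in two populations,
#' \deqn{I = (p_a p_b + q_a q_b) / \sqrt{(p_a^2 + q_a^2)(p_b^2 + q_b^2)}.}
#' For biallelic profiles the denominator is bounded below by 1/2, so I is
#' always defined; I = 1 iff the profiles coincide and I = 0 only for
#' opposite fixations.
#'
#' @param qa,qb null allele frequencies in the two populations (vectorized).
#' @return identity values in [0, 1].
#' @export
neiIdentity <- function(qa, qb) {
  if (any(qa < 0 | qa > 1 | qb < 0 | qb > 1, na.rm = TRUE))
    stop("allele frequencies must lie in [0, 1]")
  pa <- 1 - qa; pb <- 1 - qb
  (pa * pb + qa * qb) / sqrt((pa^2 + qa^2) * (pb^2 + qb^2))
}

#' Nei's standard genetic distance for one biallelic locus
#'
#' D = -ln(I). Zero for identical profiles; +Inf (represented explicitly,
#' never clamped) when the populations are fixed for opposite alleles.
#'
#' @inheritParams neiIdentity
#' @return distances in [0, Inf].
#' @export
#' @examples
#' neiDistance(sqrt(0.3867), sqrt(0.372))  # ~ 0.0003 at the GSTM1 locus
neiDistance <- function(qa, qb) {
  I <- neiIdentity(qa, qb)
  ifelse(I <= 0, Inf, -log(pmin(I, 1)))
}

#' Average Nei distance over loci
#'
#' Arithmetic mean of per-locus distances. Missing loci (NA) are excluded
#' and reported via the \code{used} attribute; infinite distances (opposite
#' fixation) are excluded with a warning rather than silently absorbed.
#'
#' @param d named numeric vector of per-locus distances.
#' @return mean distance, with attribute \code{used} naming the loci that
#'   entered the average.
#' @export
averageDistance <- function(d) {
  keep <- !is.na(d)
  if (any(is.infinite(d[keep]))) {
    warning("infinite per-locus distance excluded from the average")
    keep <- keep & is.finite(d)
  }
  if (!any(keep))
    stop("no shared loci with finite distance")
  out <- mean(d[keep])
  attr(out, "used") <- if (!is.null(names(d))) names(d)[keep] else which(keep)
  out
}

#' Pairwise Nei distance matrix over panel populations
#'
#' Converts each population's null genotype frequencies to HWE allele
#' profiles (q = sqrt(fNull)) and computes the pairwise Nei distance per
#' locus, averaging over the loci available to each pair. A population
#' missing a locus contributes only its remaining loci to pairs involving
#' it; a pair sharing no loci is an error.
#'
#' @param panel a \linkS4class{ReferencePanel}.
#' @param whichLoci loci to use (default: all panel loci).
#' @param subset optional subset of population labels, in the order given;
#'   the first population is the focal one for downstream ordination.
#' @param perLocus if TRUE, return a list with the average matrix and one
#'   matrix per locus.
#' @param dropIncomplete if TRUE, populations missing a frequency at any
#'   requested locus are dropped with a notice instead of contributing
#'   partial averages (useful for single-locus matrices).
#' @return symmetric numeric matrix with zero diagonal (or a list, see
#'   \code{perLocus}).
#' @export
neiDistanceMatrix <- function(panel, whichLoci = loci(panel),
                              subset = NULL, perLocus = FALSE,
                              dropIncomplete = FALSE) {
  stopifnot(is(panel, "ReferencePanel"))
  if (!is.null(subset))
    panel <- panel[subset]
  if (dropIncomplete) {
    ok <- Reduce(`&`, lapply(whichLoci, function(l) !is.na(nullFreq(panel, l))))
    if (!all(ok))
      message("dropping populations missing a requested locus: ",
              paste(populations(panel)[!ok], collapse = ", "))
    panel <- panel[which(ok)]
  }
  labs <- populations(panel)
  if (length(labs) == 0L)
    stop("empty population selection")
  bad <- setdiff(whichLoci, loci(panel))
  if (length(bad))
    stop("loci not in panel: ", paste(bad, collapse = ", "))
  qmat <- sapply(whichLoci, function(l) sqrt(nullFreq(panel, l)))
  qmat <- matrix(qmat, nrow = length(labs),
                 dimnames = list(labs, whichLoci))
  per <- lapply(whichLoci, function(l) {
    q <- qmat[, l]
    D <- outer(q, q, neiDistance)
    diag(D) <- ifelse(is.na(q), NA_real_, 0)
    D
  })
  names(per) <- whichLoci
  arr <- array(unlist(per), dim = c(length(labs), length(labs),
                                    length(whichLoci)))
  avg <- apply(arr, c(1, 2), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v[is.finite(v)])
  })
  ## a pair with an infinite distance at every shared locus keeps Inf
  allInf <- apply(arr, c(1, 2), function(v) any(!is.na(v)) && all(!is.finite(v[!is.na(v)])))
  avg[allInf] <- Inf
  if (anyNA(avg)) {
    idx <- which(is.na(avg), arr.ind = TRUE)[1, ]
    stop(sprintf("populations '%s' and '%s' share no typed loci",
                 labs[idx[1]], labs[idx[2]]))
  }
  dimnames(avg) <- list(labs, labs)
  if (perLocus) list(average = avg, perLocus = per, loci = whichLoci)
  else avg
}
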