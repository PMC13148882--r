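#' AdmixtureSpec: one-generation admixture model for null-allele loci
#'
#' Describes a cohort of unrelated diploid individuals formed by mixing up
#' to a few ancestral sources (classically the tri-hybrid
#' Amerindian/European/African setting) in stated proportions, followed by
#' one generation of random mating. Under the default panmictic model the
#' mixed null allele frequency at each locus is the weighted mean of the
#' ancestral frequencies and the null phenotype occurs with probability
#' q_mix^2 (HWE). Loci are simulated independently (unlinked).
#'
#' @slot loci locus labels.
#' @slot ancestralQ sources x loci matrix of ancestral null allele
#'   frequencies.
#' @slot weights admixture proportions, non-negative, summing to 1.
#' @slot n cohort size.
#' @slot seed integer seed recorded in the simulated cohort's metadata.
#' @aliases AdmixtureSpec-class
#' @exportClass AdmixtureSpec
setClass("AdmixtureSpec",
         representation(loci = "character", ancestralQ = "matrix",
                        weights = "numeric", n = "integer", seed = "integer"))

setValidity("AdmixtureSpec", function(object) {
  msg <- character()
  if (nrow(object@ancestralQ) != length(object@weights))
    msg <- c(msg, "one weight per ancestral source is required")
  if (ncol(object@ancestralQ) != length(object@loci))
    msg <- c(msg, "one ancestralQ column per locus is required")
  if (any(object@weights < 0))
    msg <- c(msg, "weights must be non-negative")
  if (abs(sum(object@weights) - 1) > 1e-9)
    msg <- c(msg, "weights must sum to 1 (within 1e-9)")
  if (any(object@ancestralQ < 0 | object@ancestralQ > 1))
    msg <- c(msg, "ancestral allele frequencies must lie in [0, 1]")
  if (object@n < 1)
    msg <- c(msg, "n must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AdmixtureSpec", function(object) {
  cat(sprintf("AdmixtureSpec: %d sources, %d loci, n = %d, seed = %d\n",
              nrow(object@ancestralQ), length(object@loci), object@n,
              object@seed))
  cat("  weights:", paste(sprintf("%s=%.3g", rownames(object@ancestralQ),
                                  object@weights), collapse = ", "), "\n")
  invisible(NULL)
})

#' Construct an AdmixtureSpec
#'
#' @param loci locus labels.
#' @param ancestralQ either a sources x loci matrix or a named list of
#'   per-source numeric vectors (each of length \code{length(loci)}).
#' @param weights named or unnamed admixture proportions, one per source.
#' @param n cohort size.
#' @param seed integer seed.
#' @return an \linkS4class{AdmixtureSpec}.
#' @export
#' @examples
#' admixtureSpec(
#'   loci = c("GSTM1", "GSTT1"),
#'   ancestralQ = list(amerindian = c(0.60, 0.05),
#'                     european = c(0.65, 0.42),
#'                     african = c(0.50, 0.62)),
#'   weights = c(amerindian = 0.3, european = 0.5, african = 0.2),
#'   n = 300, seed = 1)
admixtureSpec <- function(loci, ancestralQ, weights, n, seed = 1L) {
  if (is.list(ancestralQ))
    ancestralQ <- do.call(rbind, ancestralQ)
  if (is.null(rownames(ancestralQ)))
    rownames(ancestralQ) <- if (!is.null(names(weights))) names(weights)
      else paste0("source", seq_len(nrow(ancestralQ)))
  colnames(ancestralQ) <- loci
  if (!is.null(names(weights)))
    weights <- weights[rownames(ancestralQ)]
  new("AdmixtureSpec", loci = as.character(loci),
      ancestralQ = ancestralQ, weights = unname(as.numeric(weights)),
      n = as.integer(n), seed = as.integer(seed))
}

#' @rdname nullmark-generics
#' @export
setMethod("loci", "AdmixtureSpec", function(x) x@loci)

#' Mixed null allele frequency after one generation of admixture
#'
#' q_mix = sum over sources of weight * ancestral q; deterministic.
#'
#' @param spec an \linkS4class{AdmixtureSpec}.
#' @param locus optional single locus; default: all loci.
#' @return named numeric vector of mixed null allele frequencies.
#' @export
mixedAlleleFreq <- function(spec, locus = NULL) {
  stopifnot(is(spec, "AdmixtureSpec"))
  q <- setNames(as.vector(spec@weights %*% spec@ancestralQ), spec@loci)
  if (is.null(locus)) q else {
    if (!locus %in% spec@loci) stop("unknown locus: ", locus)
    q[locus]
  }
}

#' Simulate a cohort of presence/absence calls
#'
#' Under the default panmictic model each individual is null at a locus
#' with probability q_mix^2 (random mating at the mixed allele frequency,
#' i.e. HWE). The alternative Wahlund model draws each individual's source
#' by the admixture weights and uses that source's q^2, producing the
#' well-known excess of null homozygotes (sum w q_s^2 >= q_mix^2); it
#' exists to let analyses demonstrate the HWE estimator's sensitivity to
#' hidden structure. Loci are independent; the seed is recorded in the
#' cohort metadata.
#'
#' @param spec an \linkS4class{AdmixtureSpec}.
#' @param model "panmictic" (default) or "wahlund".
#' @return a \linkS4class{GenotypeCohort} with metadata fields seed, model
#'   and qMix.
#' @export
simulateCohort <- function(spec, model = c("panmictic", "wahlund")) {
  model <- match.arg(model)
  stopifnot(is(spec, "AdmixtureSpec"))
  set.seed(spec@seed)
  n <- spec@n
  qMix <- mixedAlleleFreq(spec)
  m <- matrix(FALSE, nrow = length(spec@loci), ncol = n,
              dimnames = list(spec@loci,
                              sprintf("S%0*d", nchar(n), seq_len(n))))
  if (model == "panmictic") {
    for (l in spec@loci)
      m[l, ] <- rbinom(n, 1L, qMix[[l]]^2) == 1L
  } else {
    src <- sample.int(nrow(spec@ancestralQ), n, replace = TRUE,
                      prob = spec@weights)
    for (l in spec@loci)
      m[l, ] <- rbinom(n, 1L, spec@ancestralQ[src, l]^2) == 1L
  }
  GenotypeCohort(m, metadata = list(seed = spec@seed, model = model,
                                    qMix = qMix, weights = spec@weights))
}

#' Parameter-recovery experiment for the HWE estimator
#'
#' Repeatedly simulates a cohort under the spec's panmictic model, estimates
#' q as sqrt(null fraction), and scores each replicate's delta-method
#' confidence interval against the true mixed frequency. Reported are the
#' empirical CI coverage, the fraction of estimates within 3 standard
#' errors, and the mean bias (the sqrt transform is biased at small n;
#' the bias is reported, not hidden).
#'
#' @param spec an \linkS4class{AdmixtureSpec}; its seed fixes the whole
#'   experiment.
#' @param replicates number of simulated cohorts.
#' @param locus locus to score (default: first).
#' @param level nominal CI level.
#' @return list with elements \code{results} (per-replicate data.frame:
#'   fHat, qHat, seQ, lo, hi, covered, z), \code{coverage},
#'   \code{withinThreeSe}, \code{bias}, \code{qTrue}, \code{n},
#'   \code{level}, \code{replicates}.
#' @export
recoveryExperiment <- function(spec, replicates = 1000L,
                               locus = loci(spec)[1], level = 0.95) {
  stopifnot(is(spec, "AdmixtureSpec"), replicates >= 1)
  qTrue <- unname(mixedAlleleFreq(spec, locus))
  f <- qTrue^2
  n <- spec@n
  set.seed(spec@seed)
  x <- rbinom(replicates, n, f)       # null counts, one cohort per draw
  fHat <- x / n
  qHat <- sqrt(fHat)
  res <- lapply(seq_len(replicates), function(i) {
    u <- alleleUncertainty(n, fHat[i], level = level, method = "delta")
    c(lo = u$ciQ[1], hi = u$ciQ[2], se = u$seQ)
  })
  res <- do.call(rbind, res)
  covered <- res[, "lo"] <= qTrue & qTrue <= res[, "hi"]
  z <- abs(qHat - qTrue) / res[, "se"]
  out <- data.frame(replicate = seq_len(replicates), fHat = fHat,
                    qHat = qHat, seQ = res[, "se"], lo = res[, "lo"],
                    hi = res[, "hi"], covered = covered, z = z)
  list(results = out,
       coverage = mean(covered),
       withinThreeSe = mean(z <= 3, na.rm = TRUE),
       bias = mean(qHat) - qTrue,
       qTrue = qTrue, n = n, level = level, replicates = replicates)
}
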