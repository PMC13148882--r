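#' GenotypeCohort: binary presence/absence calls for a cohort
#'
#' A cohort of unrelated diploid individuals typed at one or more dominant
#' null-allele loci. The single assay \code{"calls"} is a logical
#' loci x samples matrix with \code{TRUE} for the null (deletion) phenotype
#' and \code{FALSE} for the positive (band-present) phenotype. Because the
#' assay is dominant, a \code{FALSE} collapses the +/+ and +/- genotypes.
#'
#' @slot .Data inherits all slots from
#'   \link[SummarizedExperiment]{SummarizedExperiment}.
#' @aliases GenotypeCohort-class
#' @exportClass GenotypeCohort
setClass("GenotypeCohort", contains = "SummarizedExperiment")

setValidity("GenotypeCohort", function(object) {
  msg <- character()
  if (!("calls" %in% assayNames(object)))
    msg <- c(msg, "assay 'calls' is required")
  else {
    m <- assay(object, "calls")
    if (!is.logical(m))
      msg <- c(msg, "assay 'calls' must be logical (TRUE = null phenotype)")
    if (anyNA(m))
      msg <- c(msg, "calls must not contain NA: every sample needs a call at every locus")
  }
  if (is.null(rownames(object)) && nrow(object) > 0)
    msg <- c(msg, "loci (rownames) must be named")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "locus names must be unique")
  if (is.null(colnames(object)) && ncol(object) > 0)
    msg <- c(msg, "samples (colnames) must be named")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample ids")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeCohort
#'
#' @param calls a loci x samples matrix: either logical (TRUE = null) or
#'   character with values \code{"NULL"}/\code{"PRESENT"}.
#' @param metadata list of free-form provenance (source path, simulation
#'   seed, ...).
#' @return a \linkS4class{GenotypeCohort}.
#' @export
#' @examples
#' m <- rbind(GSTM1 = c(TRUE, FALSE, FALSE), GSTT1 = c(FALSE, FALSE, TRUE))
#' colnames(m) <- c("S1", "S2", "S3")
#' GenotypeCohort(m)
GenotypeCohort <- function(calls, metadata = list()) {
  if (is.character(calls)) {
    up <- toupper(calls)
    bad <- !(up %in% c("NULL", "PRESENT"))
    if (any(bad))
      stop("character calls must be 'NULL' or 'PRESENT'; found: ",
           paste(unique(calls[bad]), collapse = ", "))
    dimn <- dimnames(calls)
    calls <- matrix(up == "NULL", nrow = nrow(calls), dimnames = dimn)
  }
  if (!is.matrix(calls))
    stop("'calls' must be a matrix (loci in rows, samples in columns)")
  se <- SummarizedExperiment(assays = list(calls = calls),
                             metadata = metadata)
  new("GenotypeCohort", se)
}

#' @rdname nullmark-generics
#' @export
setMethod("nullCalls", "GenotypeCohort", function(x) assay(x, "calls"))

#' @rdname nullmark-generics
#' @export
setMethod("loci", "GenotypeCohort", function(x) rownames(x))

#' @rdname nullmark-generics
#' @export
setMethod("sampleIds", "GenotypeCohort", function(x) colnames(x))

#' @rdname nullmark-generics
#' @export
setMethod("nullCounts", "GenotypeCohort", function(x) {
  if (ncol(x) == 0L)
    return(setNames(integer(nrow(x)), rownames(x)))
  rowSums(assay(x, "calls"))
})

setMethod("show", "GenotypeCohort", function(object) {
  cat("GenotypeCohort with", ncol(object), "samples at",
      nrow(object), "loci\n")
  if (nrow(object) > 0 && ncol(object) > 0) {
    nn <- nullCounts(object)
    for (l in rownames(object))
      cat(sprintf("  %s: %d/%d null (%s%%)\n", l, nn[[l]], ncol(object),
                  fmtPercent(nn[[l]] / ncol(object))))
  }
  if (!is.null(metadata(object)$seed))
    cat("  simulated with seed", metadata(object)$seed, "\n")
  invisible(NULL)
})
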