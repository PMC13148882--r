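#' ReferencePanel: published per-population null-genotype frequencies
#'
#' An ordered collection of population records, each carrying a label,
#' an optional region, an optional sample size n, and the observed null
#' genotype frequency at each locus. Frequencies may be missing for a locus
#' (first-class NA, never coerced to 0): such populations simply drop out of
#' comparisons and single-locus distances at that locus.
#'
#' @slot data a \link[S4Vectors]{DataFrame} with columns \code{population},
#'   \code{region}, \code{n} and one numeric column per locus.
#' @slot loci character vector of locus column names.
#' @slot provenance free-text description of where the panel came from.
#' @aliases ReferencePanel-class
#' @exportClass ReferencePanel
setClass("ReferencePanel",
         representation(data = "DataFrame",
                        loci = "character",
                        provenance = "character"))

setValidity("ReferencePanel", function(object) {
  d <- object@data
  msg <- character()
  need <- c("population", "region", "n")
  if (!all(need %in% colnames(d)))
    return(paste("panel data must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(d$population))
    msg <- c(msg, paste("duplicate population labels:",
                        paste(unique(d$population[duplicated(d$population)]),
                              collapse = ", ")))
  if (!all(object@loci %in% colnames(d)))
    msg <- c(msg, "every locus must have a frequency column")
  nn <- d$n
  if (any(!is.na(nn) & (nn < 1 | nn != floor(nn))))
    msg <- c(msg, "n must be a positive integer (or missing)")
  for (l in object@loci) {
    f <- d[[l]]
    if (!is.numeric(f) || any(!is.na(f) & (f < 0 | f > 1)))
      msg <- c(msg, sprintf("null frequencies for %s must lie in [0, 1]", l))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ReferencePanel
#'
#' @param data data.frame (or DataFrame) with columns \code{population},
#'   optionally \code{region} and \code{n}, plus one numeric null-genotype
#'   frequency column per locus.
#' @param loci locus column names; by default every column other than
#'   population/region/n.
#' @param provenance free-text provenance string.
#' @return a \linkS4class{ReferencePanel}.
#' @export
ReferencePanel <- function(data, loci = NULL, provenance = "") {
  d <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!"region" %in% colnames(d)) d$region <- NA_character_
  if (!"n" %in% colnames(d)) d$n <- NA_integer_
  if (is.null(loci))
    loci <- setdiff(colnames(d), c("population", "region", "n"))
  if (length(loci) == 0L)
    stop("panel has no locus frequency columns")
  d$n <- as.integer(d$n)
  for (l in loci) d[[l]] <- as.numeric(d[[l]])
  d <- d[, c("population", "region", "n", loci), drop = FALSE]
  new("ReferencePanel", data = DataFrame(d, check.names = FALSE),
      loci = as.character(loci), provenance = provenance)
}

#' @rdname nullmark-generics
#' @export
setMethod("populations", "ReferencePanel", function(x) x@data$population)

#' @rdname nullmark-generics
#' @export
setMethod("panelRegions", "ReferencePanel",
          function(x) setNames(x@data$region, x@data$population))

#' @rdname nullmark-generics
#' @export
setMethod("panelSizes", "ReferencePanel",
          function(x) setNames(x@data$n, x@data$population))

#' @rdname nullmark-generics
#' @export
setMethod("loci", "ReferencePanel", function(x) x@loci)

#' @rdname nullmark-generics
#' @export
setMethod("provenance", "ReferencePanel", function(x) x@provenance)

#' @describeIn ReferencePanel null genotype frequency of every population at
#'   one locus (named numeric, NA where the panel has a blank cell).
#' @param x,locus panel and locus name.
#' @export
setMethod("nullFreq", "ReferencePanel", function(x, locus) {
  if (!locus %in% x@loci)
    stop("locus '", locus, "' not in panel (has: ",
         paste(x@loci, collapse = ", "), ")")
  setNames(as.numeric(x@data[[locus]]), x@data$population)
})

#' @describeIn ReferencePanel subset by population label or index, keeping
#'   row order.
#' @param i character labels or numeric/logical index.
#' @param j,drop ignored (panels are one-dimensional collections).
#' @export
setMethod("[", "ReferencePanel", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    miss <- setdiff(i, x@data$population)
    if (length(miss))
      stop("unknown populations: ", paste(miss, collapse = ", "))
    i <- match(i, x@data$population)
  }
  initialize(x, data = x@data[i, , drop = FALSE])
})

#' @describeIn ReferencePanel number of population records.
#' @export
setMethod("length", "ReferencePanel", function(x) nrow(x@data))

#' Coerce a ReferencePanel to data.frame
#'
#' @param x a \linkS4class{ReferencePanel}.
#' @param ... unused.
#' @return base data.frame with one row per population.
#' @export
#' @method as.data.frame ReferencePanel
as.data.frame.ReferencePanel <- function(x, ...) {
  as.data.frame(x@data, stringsAsFactors = FALSE)
}

setMethod("show", "ReferencePanel", function(object) {
  cat("ReferencePanel with", nrow(object@data), "populations at loci:",
      paste(object@loci, collapse = ", "), "\n")
  reg <- table(object@data$region, useNA = "ifany")
  cat("  regions:", paste(sprintf("%s (%d)", names(reg), reg), collapse = ", "),
      "\n")
  if (nzchar(object@provenance))
    cat("  provenance:", object@provenance, "\n")
  invisible(NULL)
})

#' Add a population record to a panel
#'
#' Typically used to place a freshly typed cohort alongside published
#' reference populations before computing distances.
#'
#' @param panel a \linkS4class{ReferencePanel}.
#' @param population new unique label.
#' @param nullFreq named numeric vector of null genotype frequencies; names
#'   must be panel loci. Loci not named are recorded as missing.
#' @param n sample size (NA allowed; such records feed distances but not
#'   count-based tests).
#' @param region optional region label.
#' @param before if TRUE the record is prepended, making it the first-listed
#'   (focal) population for downstream ordination.
#' @return a new \linkS4class{ReferencePanel}.
#' @export
addPopulation <- function(panel, population, nullFreq, n = NA_integer_,
                          region = NA_character_, before = FALSE) {
  stopifnot(is(panel, "ReferencePanel"))
  extra <- setdiff(names(nullFreq), loci(panel))
  if (length(extra))
    stop("loci not in panel: ", paste(extra, collapse = ", "))
  row <- as.data.frame(panel@data[0, , drop = FALSE])
  row[1, "population"] <- population
  row[1, "region"] <- region
  row[1, "n"] <- as.integer(n)
  for (l in loci(panel))
    row[1, l] <- if (l %in% names(nullFreq)) unname(nullFreq[[l]]) else NA_real_
  old <- as.data.frame(panel@data)
  d <- if (before) rbind(row, old) else rbind(old, row)
  ReferencePanel(d, loci = loci(panel), provenance = provenance(panel))
}
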