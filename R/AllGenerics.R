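#' @name nullmark-generics
#' @title Accessor generics
#' @description Accessor generics for the package's S4 classes. Slot access
#'   in user code should always go through these.
#' @param x an object.
#' @param ... further arguments for methods.
NULL

#' @rdname nullmark-generics
#' @export
setGeneric("nullCalls", function(x) standardGeneric("nullCalls"))

#' @rdname nullmark-generics
#' @export
setGeneric("loci", function(x) standardGeneric("loci"))

#' @rdname nullmark-generics
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname nullmark-generics
#' @export
setGeneric("nullCounts", function(x) standardGeneric("nullCounts"))

#' @rdname nullmark-generics
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname nullmark-generics
#' @export
setGeneric("panelRegions", function(x) standardGeneric("panelRegions"))

#' @rdname nullmark-generics
#' @export
setGeneric("panelSizes", function(x) standardGeneric("panelSizes"))

#' @rdname nullmark-generics
#' @export
setGeneric("nullFreq", function(x, locus) standardGeneric("nullFreq"))

#' @rdname nullmark-generics
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname nullmark-generics
#' @export
setGeneric("coordinates", function(x) standardGeneric("coordinates"))

#' @rdname nullmark-generics
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname nullmark-generics
#' @export
setGeneric("reconstructionError", function(x) standardGeneric("reconstructionError"))

#' @rdname nullmark-generics
#' @export
setGeneric("mergeHeights", function(x) standardGeneric("mergeHeights"))

#' @rdname nullmark-generics
#' @export
setGeneric("leafLabels", function(x) standardGeneric("leafLabels"))

#' @rdname nullmark-generics
#' @export
setGeneric("newick", function(x) standardGeneric("newick"))
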