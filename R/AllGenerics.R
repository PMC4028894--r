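#' @rdname GenotypeMatrix-class
#' @param x,object a \code{GenotypeMatrix}
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("individuals", function(x) standardGeneric("individuals"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("readDepth", function(x) standardGeneric("readDepth"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("families", function(x) standardGeneric("families"))

#' Total map length in centiMorgans
#' @param x a \code{ParentalMap}
#' @return numeric, the position of the last marker (0 for maps with < 2 markers).
#' @export
setGeneric("mapLength", function(x) standardGeneric("mapLength"))

#' Ledger steps as a data.frame
#' @param x a \code{FilterLedger}
#' @export
setGeneric("ledgerSteps", function(x) standardGeneric("ledgerSteps"))
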