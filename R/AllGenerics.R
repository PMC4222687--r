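#' @rdname NetworkModel-accessors
#' @export
setGeneric("stoichiometry", function(x) standardGeneric("stoichiometry"))

#' @rdname NetworkModel-accessors
#' @export
setGeneric("metaboliteIds", function(x) standardGeneric("metaboliteIds"))

#' @rdname NetworkModel-accessors
#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))

#' @rdname NetworkModel-accessors
#' @export
setGeneric("isReversible", function(x) standardGeneric("isReversible"))

#' @rdname NetworkModel-accessors
#' @export
setGeneric("exchangeReactions", function(x) standardGeneric("exchangeReactions"))

#' @rdname NetworkModel-accessors
#' @export
setGeneric("lowerBounds", function(x) standardGeneric("lowerBounds"))

#' @rdname NetworkModel-accessors
#' @export
setGeneric("upperBounds", function(x) standardGeneric("upperBounds"))

#' @rdname NetworkModel-accessors
#' @export
setGeneric("nReactions", function(x) standardGeneric("nReactions"))

#' @rdname NetworkModel-accessors
#' @export
setGeneric("nMetabolites", function(x) standardGeneric("nMetabolites"))

#' @rdname FvaResult-accessors
#' @export
setGeneric("fluxMin", function(x) standardGeneric("fluxMin"))

#' @rdname FvaResult-accessors
#' @export
setGeneric("fluxMax", function(x) standardGeneric("fluxMax"))

#' @rdname NullspaceBasis-accessors
#' @export
setGeneric("basisMatrix", function(x) standardGeneric("basisMatrix"))

#' @rdname NullspaceBasis-accessors
#' @export
setGeneric("kernelDim", function(x) standardGeneric("kernelDim"))
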