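#' Accessors for NetworkModel objects
#'
#' Read the components of a [NetworkModel-class] without touching its slots.
#'
#' @param x a \code{NetworkModel}.
#' @return \code{stoichiometry}: the m x n numeric matrix (with dimnames set
#'   to the metabolite and reaction identifiers); \code{metaboliteIds},
#'   \code{reactionIds}: character vectors; \code{isReversible}: logical
#'   vector; \code{exchangeReactions}: integer column indices;
#'   \code{lowerBounds}, \code{upperBounds}: numeric vectors;
#'   \code{nReactions}, \code{nMetabolites}: integer scalars.
#' @name NetworkModel-accessors
#' @examples
#' net <- fixtureNetwork("net-b")$model
#' stoichiometry(net)
#' reactionIds(net)
NULL

#' @rdname NetworkModel-accessors
#' @export
setMethod("stoichiometry", "NetworkModel", function(x) {
  out <- x@S
  dimnames(out) <- list(x@metaboliteIds, x@reactionIds)
  out
})

#' @rdname NetworkModel-accessors
#' @export
setMethod("metaboliteIds", "NetworkModel", function(x) x@metaboliteIds)

#' @rdname NetworkModel-accessors
#' @export
setMethod("reactionIds", "NetworkModel", function(x) x@reactionIds)

#' @rdname NetworkModel-accessors
#' @export
setMethod("isReversible", "NetworkModel", function(x) x@reversible)

#' @rdname NetworkModel-accessors
#' @export
setMethod("exchangeReactions", "NetworkModel", function(x) x@exchange)

#' @rdname NetworkModel-accessors
#' @export
setMethod("lowerBounds", "NetworkModel", function(x) x@lowerBounds)

#' @rdname NetworkModel-accessors
#' @export
setMethod("upperBounds", "NetworkModel", function(x) x@upperBounds)

#' @rdname NetworkModel-accessors
#' @export
setMethod("nReactions", "NetworkModel", function(x) ncol(x@S))

#' @rdname NetworkModel-accessors
#' @export
setMethod("nMetabolites", "NetworkModel", function(x) nrow(x@S))

#' Accessors for FvaResult objects
#'
#' @param x an [FvaResult-class].
#' @return \code{fluxMin} / \code{fluxMax}: named numeric vectors of the
#'   per-reaction flux range optima.
#' @name FvaResult-accessors
NULL

#' @rdname FvaResult-accessors
#' @export
setMethod("fluxMin", "FvaResult", function(x) {
  stats::setNames(x@vMin, x@reactionIds)
})

#' @rdname FvaResult-accessors
#' @export
setMethod("fluxMax", "FvaResult", function(x) {
  stats::setNames(x@vMax, x@reactionIds)
})

#' @rdname FvaResult-accessors
#' @export
setMethod("reactionIds", "FvaResult", function(x) x@reactionIds)

#' Accessors for NullspaceBasis objects
#'
#' @param x a [NullspaceBasis-class].
#' @return \code{basisMatrix}: the n x p matrix whose columns span the
#'   kernel of S; \code{kernelDim}: p.
#' @name NullspaceBasis-accessors
NULL

#' @rdname NullspaceBasis-accessors
#' @export
setMethod("basisMatrix", "NullspaceBasis", function(x) x@basis)

#' @rdname NullspaceBasis-accessors
#' @export
setMethod("kernelDim", "NullspaceBasis", function(x) ncol(x@basis))

#' @rdname NullspaceBasis-accessors
#' @export
setMethod("reactionIds", "NullspaceBasis", function(x) x@reactionIds)

setMethod("show", "NetworkModel", function(object) {
  st <- modelStatistics(object)
  cat("NetworkModel with", st$nMetabolites, "internal metabolites and",
      st$nReactions, "reactions\n")
  cat("  reversible:", st$nReversible,
      " exchange:", st$nExchange, "\n")
  src <- object@metadata$source
  if (!is.null(src)) cat("  source:", src, "\n")
  invisible(object)
})

setMethod("show", "NullspaceBasis", function(object) {
  cat("NullspaceBasis:", nrow(object@basis), "reactions, kernel dimension",
      ncol(object@basis), "\n")
  invisible(object)
})

setMethod("show", "FvaResult", function(object) {
  n <- length(object@reactionIds)
  cat("FvaResult over", n, "reactions\n")
  show <- utils::head(data.frame(
    reaction = object@reactionIds,
    vMin = object@vMin,
    vMax = object@vMax
  ), 6L)
  print(show, row.names = FALSE)
  if (n > 6L) cat("  ...", n - 6L, "more\n")
  invisible(object)
})

setMethod("show", "CheckReport", function(object) {
  cat(renderReport(object), sep = "")
  invisible(object)
})
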