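#' @import methods
NULL

#' NetworkModel: a stoichiometric model ready for steady-state analysis
#'
#' Container for a stoichiometric matrix together with the identities of its
#' internal metabolites (rows) and reactions (columns), per-reaction
#' reversibility flags, the set of exchange reactions, and flux bounds.
#' External metabolites are stripped before construction: every row of the
#' matrix is an internal metabolite subject to the steady-state constraint
#' \eqn{Sv = 0}.
#'
#' @slot metaboliteIds character vector of unique internal metabolite
#'   identifiers (length m, one per row of \code{S}).
#' @slot reactionIds character vector of unique reaction identifiers
#'   (length n, one per column of \code{S}).
#' @slot S numeric m x n matrix of stoichiometric coefficients; negative
#'   entries are reactants, positive entries products.
#' @slot reversible logical vector of length n.
#' @slot exchange integer vector of column indices designated as exchange
#'   reactions (reactions crossing the model boundary).
#' @slot lowerBounds,upperBounds numeric flux bound vectors of length n;
#'   irreversible reactions have a nonnegative lower bound.
#' @slot userBounds logical vector of length n; \code{TRUE} where the bound
#'   was supplied by the user rather than filled with the default.  Exchange
#'   bounds are widened during flux variability analysis only where this is
#'   \code{FALSE}.
#' @slot metadata list of free-form provenance (source file, format).
#'
#' @seealso [readTabularModel()], [readSBMLModel()], [checkModel()]
#' @export
setClass("NetworkModel",
  representation(
    metaboliteIds = "character",
    reactionIds = "character",
    S = "matrix",
    reversible = "logical",
    exchange = "integer",
    lowerBounds = "numeric",
    upperBounds = "numeric",
    userBounds = "logical",
    metadata = "list"
  )
)

setValidity("NetworkModel", function(object) {
  msg <- character(0)
  m <- nrow(object@S)
  n <- ncol(object@S)
  if (!is.numeric(object@S)) {
    msg <- c(msg, "S must be numeric")
  }
  if (length(object@metaboliteIds) != m) {
    msg <- c(msg, "length(metaboliteIds) must equal nrow(S)")
  }
  if (length(object@reactionIds) != n) {
    msg <- c(msg, "length(reactionIds) must equal ncol(S)")
  }
  if (anyDuplicated(object@metaboliteIds)) {
    msg <- c(msg, "metabolite identifiers must be unique")
  }
  if (anyDuplicated(object@reactionIds)) {
    msg <- c(msg, "reaction identifiers must be unique")
  }
  if (length(object@reversible) != n) {
    msg <- c(msg, "length(reversible) must equal ncol(S)")
  }
  if (length(object@lowerBounds) != n || length(object@upperBounds) != n) {
    msg <- c(msg, "bound vectors must have one entry per reaction")
  } else {
    if (any(object@lowerBounds > object@upperBounds)) {
      msg <- c(msg, "lowerBounds must not exceed upperBounds")
    }
    if (any(!object@reversible & object@lowerBounds < 0)) {
      msg <- c(msg, "irreversible reactions must have lowerBounds >= 0")
    }
  }
  if (length(object@userBounds) != n) {
    msg <- c(msg, "length(userBounds) must equal ncol(S)")
  }
  if (length(object@exchange) &&
      (min(object@exchange) < 1L || max(object@exchange) > n)) {
    msg <- c(msg, "exchange indices out of range")
  }
  if (anyDuplicated(object@exchange)) {
    msg <- c(msg, "exchange indices must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' NullspaceBasis: an orthonormal basis of the kernel of S
#'
#' Columns of \code{basis} span \eqn{\{v : Sv = 0\}}.  Row i describes how
#' reaction i participates in every steady-state flux distribution (ignoring
#' directionality bounds); an all-zero row means the reaction can carry no
#' steady-state flux at all.
#'
#' @slot basis numeric n x p matrix with orthonormal columns; p may be 0.
#' @slot rankTolerance numeric singular-value threshold used to decide the
#'   rank of \code{S}.
#' @slot reactionIds character vector of length n naming the rows.
#'
#' @seealso [computeNullBasis()], [findCoupled()], [findBasisZeroRows()]
#' @export
setClass("NullspaceBasis",
  representation(
    basis = "matrix",
    rankTolerance = "numeric",
    reactionIds = "character"
  )
)

setValidity("NullspaceBasis", function(object) {
  msg <- character(0)
  if (length(object@reactionIds) != nrow(object@basis)) {
    msg <- c(msg, "length(reactionIds) must equal nrow(basis)")
  }
  if (length(object@rankTolerance) != 1L || object@rankTolerance < 0) {
    msg <- c(msg, "rankTolerance must be a single nonnegative number")
  }
  if (length(msg)) msg else TRUE
})

#' FvaResult: per-reaction flux ranges from flux variability analysis
#'
#' For each reaction j, \code{vMin[j]} and \code{vMax[j]} are the optima of
#' minimising / maximising \eqn{v_j} subject to \eqn{Sv = 0} and the
#' effective flux bounds (2n linear programs in total).
#'
#' @slot vMin,vMax numeric vectors of length n.
#' @slot status character vector of per-reaction solver status codes.
#' @slot lowerUsed,upperUsed the effective bound vectors the LPs were
#'   solved under (after exchange widening and user overrides).
#' @slot reactionIds character vector of length n.
#'
#' @seealso [runFVA()], [findZeroFlux()], [findUnsatisfiedReversibility()]
#' @export
setClass("FvaResult",
  representation(
    vMin = "numeric",
    vMax = "numeric",
    status = "character",
    lowerUsed = "numeric",
    upperUsed = "numeric",
    reactionIds = "character"
  )
)

setValidity("FvaResult", function(object) {
  msg <- character(0)
  n <- length(object@reactionIds)
  if (length(object@vMin) != n || length(object@vMax) != n) {
    msg <- c(msg, "vMin/vMax must have one entry per reaction")
  } else if (any(object@vMin > object@vMax + 1e-9)) {
    msg <- c(msg, "vMin must not exceed vMax (within tolerance)")
  }
  if (length(object@lowerUsed) != n || length(object@upperUsed) != n) {
    msg <- c(msg, "bound vectors must have one entry per reaction")
  } else if (any(object@lowerUsed > object@upperUsed)) {
    msg <- c(msg, "lowerUsed must not exceed upperUsed")
  }
  if (length(msg)) msg else TRUE
})

#' CheckReport: the results of a full consistency check
#'
#' Holds model statistics plus the six condition result sets: singly
#' connected metabolites (SCM), dead-end metabolites (DEM), zero-flux
#' reactions (ZFR), unsatisfied reversibility (UR), coupled reaction pairs
#' (CR) and reversibly coupled pairs (RCR).  Which sets are populated is
#' governed by \code{checkType}: 0 runs only the null-space-basis checks
#' (CR, RCR), 1 only the FVA checks (ZFR, UR), 2 both; connectivity checks
#' (SCM, DEM) always run.
#'
#' @slot statistics list with nReactions, nReversible, nExchange,
#'   nMetabolites.
#' @slot scm,dem,orphans integer metabolite indices (1-based).
#' @slot basisZero,zfr,ur integer reaction indices (1-based).
#' @slot urDirection character vector parallel to \code{ur}; each entry is
#'   "only-forward", "only-backward" or "zero".
#' @slot crPairs,rcrPairs data.frame with columns i, j (reaction indices,
#'   i < j) and ratio (the common coupling ratio).
#' @slot checkType integer scalar in 0:2.
#' @slot enabled named logical vector with elements connectivity, basis,
#'   fva.
#' @slot fva the [FvaResult-class] when FVA checks ran, else \code{NULL}.
#' @slot metaboliteIds,reactionIds identifier vectors used to render the
#'   report.
#' @slot tolerances list of the numeric tolerances used.
#'
#' @seealso [checkModel()], [renderReport()], [renderJSON()]
#' @export
setClass("CheckReport",
  representation(
    statistics = "list",
    scm = "integer",
    dem = "integer",
    orphans = "integer",
    basisZero = "integer",
    zfr = "integer",
    ur = "integer",
    urDirection = "character",
    crPairs = "data.frame",
    rcrPairs = "data.frame",
    checkType = "integer",
    enabled = "logical",
    fva = "ANY",
    metaboliteIds = "character",
    reactionIds = "character",
    tolerances = "list"
  )
)

setValidity("CheckReport", function(object) {
  msg <- character(0)
  if (!object@checkType %in% 0:2) {
    msg <- c(msg, "checkType must be 0, 1 or 2")
  }
  if (!all(c("connectivity", "basis", "fva") %in% names(object@enabled))) {
    msg <- c(msg, "enabled must name connectivity, basis and fva")
  }
  if (length(object@urDirection) != length(object@ur)) {
    msg <- c(msg, "urDirection must parallel ur")
  }
  if (!all(object@scm %in% c(object@dem, object@orphans))) {
    msg <- c(msg, "scm must be contained in dem plus orphan rows")
  }
  if (nrow(object@rcrPairs) > 0 && nrow(object@crPairs) > 0) {
    keyAll <- paste(object@crPairs$i, object@crPairs$j)
    keyRcr <- paste(object@rcrPairs$i, object@rcrPairs$j)
    if (!all(keyRcr %in% keyAll)) {
      msg <- c(msg, "rcrPairs must be a subset of crPairs")
    }
  } else if (nrow(object@rcrPairs) > 0) {
    msg <- c(msg, "rcrPairs must be a subset of crPairs")
  }
  if (length(msg)) msg else TRUE
})
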