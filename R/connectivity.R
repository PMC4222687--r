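#' Singly connected metabolites (SCM)
#'
#' A metabolite is singly connected iff its row of the stoichiometric
#' matrix has exactly one non-zero entry, i.e. it participates in exactly
#' one reaction.  The result depends only on the sparsity pattern of S,
#' never on bounds or reversibility.
#'
#' @param model a [NetworkModel-class].
#' @param tol entries with absolute value at or below this are treated as
#'   zero; guards against float artifacts from file parsing (stoichiometric
#'   coefficients in practice are far larger).
#' @return sorted integer vector of metabolite row indices (1-based).
#' @export
#' @examples
#' findSinglyConnected(fixtureNetwork("net-b")$model)  # metabolite C
findSinglyConnected <- function(model, tol = 1e-12) {
  stopifnot(is(model, "NetworkModel"))
  which(rowSums(abs(model@S) > tol) == 1L)
}

#' Dead-end metabolites (DEM)
#'
#' A metabolite is a dead end iff all the non-zero entries of its row share
#' one sign: it is only produced or only consumed, so any flux through its
#' reactions would violate the steady-state constraint.  All-zero rows
#' (orphan metabolites) are excluded here and reported separately via
#' [findOrphanMetabolites()].  Singly connected metabolites are dead ends
#' by construction.
#'
#' The default evaluates the condition literally on the signs of S,
#' ignoring reversibility.  With `reversibilityAware = TRUE`, a reversible
#' reaction is considered to both produce and consume each of its
#' participants, so metabolites touched by a reversible reaction are never
#' dead ends; this variant is off by default because the literal rule is
#' the one whose counts are comparable across tools.
#'
#' @inheritParams findSinglyConnected
#' @param reversibilityAware logical; see Details.
#' @return sorted integer vector of metabolite row indices (1-based).
#' @export
#' @examples
#' findDeadEnd(fixtureNetwork("net-c")$model)  # metabolite D
findDeadEnd <- function(model, tol = 1e-12, reversibilityAware = FALSE) {
  stopifnot(is(model, "NetworkModel"))
  S <- model@S
  pos <- S > tol
  neg <- S < -tol
  if (reversibilityAware && any(model@reversible)) {
    rev <- model@reversible
    nz <- pos | neg
    pos[, rev] <- nz[, rev]
    neg[, rev] <- nz[, rev]
  }
  nPos <- rowSums(pos)
  nNeg <- rowSums(neg)
  which((nPos + nNeg) > 0L & (nPos == 0L | nNeg == 0L))
}

#' Orphan metabolites
#'
#' Metabolites whose row is entirely zero after external-metabolite
#' stripping.  They are retained in the model (deleting them would change
#' the metabolite count) but excluded from the dead-end set.
#'
#' @inheritParams findSinglyConnected
#' @return sorted integer vector of metabolite row indices (1-based).
#' @export
findOrphanMetabolites <- function(model, tol = 1e-12) {
  stopifnot(is(model, "NetworkModel"))
  which(rowSums(abs(model@S) > tol) == 0L)
}
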