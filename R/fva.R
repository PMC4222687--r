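# ---------------------------------------------------------------------------
# LP backend
#
# Solver abstraction contract: given (objective index, sense, S, lower,
# upper) return list(status, value).  Any LP backend honouring this is
# pluggable; the default is the package's two-phase simplex (R/lp.R).
# The LP  min/max v_j  s.t.  S v = 0,  lb <= v <= ub  is shifted to
# nonnegative variables x = v - lb.
# ---------------------------------------------------------------------------

solveFluxLP <- function(S, lb, ub, j, maximise, eps = 1e-9) {
  n <- ncol(S)
  cvec <- numeric(n)
  cvec[j] <- 1
  res <- simplexBoxLP(S, b = -as.vector(S %*% lb), u = ub - lb,
                      cvec = cvec, maximise = maximise, tol = eps)
  list(status = res$status,
       value = if (is.na(res$value)) NA_real_ else res$value + lb[j])
}

# drop all-zero rows and linearly dependent rows; the solution set of
# S v = 0 is unchanged and the LPs become smaller and better conditioned
reducedRows <- function(S, tol = 1e-12) {
  nz <- rowSums(abs(S) > tol) > 0L
  S <- S[nz, , drop = FALSE]
  if (nrow(S) > 1L) {
    dec <- qr(t(S))
    S <- S[dec$pivot[seq_len(dec$rank)], , drop = FALSE]
  }
  S
}

# effective bounds for consistency checking: user-specified bounds win;
# otherwise exchange reactions are widened to the full default range so
# that medium composition never masks a structural issue
effectiveBounds <- function(model, bounds = NULL) {
  n <- ncol(model@S)
  if (!is.null(bounds)) {
    bounds <- as.matrix(bounds)
    if (ncol(bounds) != 2L || nrow(bounds) != n) {
      stop("bounds override must have one row per reaction and two columns")
    }
    return(list(lower = bounds[, 1], upper = bounds[, 2]))
  }
  lb <- model@lowerBounds
  ub <- model@upperBounds
  defs <- defaultBoundsForReversibility(model@reversible)
  widen <- intersect(model@exchange, which(!model@userBounds))
  lb[widen] <- defs$lower[widen]
  ub[widen] <- defs$upper[widen]
  list(lower = lb, upper = ub)
}

#' Flux variability analysis (FVA)
#'
#' Solves 2n linear programs: for each reaction j, minimise and maximise
#' \eqn{v_j} subject to the steady-state constraint \eqn{Sv = 0} and the
#' effective flux bounds.  Effective bounds are the user override when
#' given, otherwise the model's bounds with exchange reactions reset to
#' the wide defaults (`[-1000, 1000]` reversible, `[0, 1000]`
#' irreversible) unless the user explicitly set them — the point of the
#' widening is that a restrictive growth medium should not masquerade as a
#' structural inconsistency.  LPs are solved independently, so results are
#' deterministic and order-independent.
#'
#' @param model a [NetworkModel-class].
#' @param bounds optional n x 2 matrix (lower, upper) overriding all
#'   bounds.
#' @param eps solver feasibility/optimality tolerance.
#' @return an [FvaResult-class].
#' @export
#' @examples
#' fluxMax(runFVA(fixtureNetwork("net-d")$model))
runFVA <- function(model, bounds = NULL, eps = 1e-9) {
  stopifnot(is(model, "NetworkModel"))
  eff <- effectiveBounds(model, bounds)
  if (any(eff$lower > eff$upper)) {
    stop("effective bounds are inconsistent (lower > upper)")
  }
  n <- ncol(model@S)
  Sred <- reducedRows(model@S)
  vMin <- vMax <- numeric(n)
  status <- character(n)
  for (j in seq_len(n)) {
    lo <- solveFluxLP(Sred, eff$lower, eff$upper, j, maximise = FALSE,
                      eps = eps)
    hi <- solveFluxLP(Sred, eff$lower, eff$upper, j, maximise = TRUE,
                      eps = eps)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("internal consistency error: LP for reaction '",
           model@reactionIds[j], "' returned status ",
           lo$status, "/", hi$status,
           " (the zero flux vector should always be feasible)")
    }
    vMin[j] <- lo$value
    vMax[j] <- hi$value
    status[j] <- "optimal"
  }
  new("FvaResult", vMin = vMin, vMax = vMax, status = status,
      lowerUsed = eff$lower, upperUsed = eff$upper,
      reactionIds = model@reactionIds)
}

#' Zero-flux (blocked) reactions (ZFR)
#'
#' A reaction is blocked iff its FVA minimum and maximum are both zero: no
#' steady state assigns it flux.  Unlike the basis test
#' ([findBasisZeroRows()]) this also catches reactions blocked by
#' directionality conflicts, so the FVA-detected set is a superset of the
#' basis-detected set.
#'
#' @param fva an [FvaResult-class].
#' @param tol zero tolerance on the optima; well below the bound scale of
#'   1000 yet above LP round-off.
#' @return sorted integer vector of reaction indices (1-based).
#' @export
#' @examples
#' findZeroFlux(runFVA(fixtureNetwork("net-c")$model))  # all four
findZeroFlux <- function(fva, tol = 1e-9) {
  stopifnot(is(fva, "FvaResult"))
  which(abs(fva@vMin) <= tol & abs(fva@vMax) <= tol)
}

#' Unsatisfied reversibility (UR)
#'
#' A reaction declared reversible whose feasible flux range lies entirely
#' on one side of zero never actually uses its reverse direction.  The
#' condition is \eqn{v_{max} \le 0} or \eqn{v_{min} \ge 0}, which also
#' covers reversible reactions restricted to strictly positive or strictly
#' negative flux.  Each flagged reaction is annotated `"only-forward"`
#' (range in `[0, +)` with positive maximum), `"only-backward"` (range in
#' `(-, 0]` with negative minimum), or `"zero"` (also blocked).
#'
#' @param fva an [FvaResult-class].
#' @param model the matching [NetworkModel-class].
#' @param tol zero tolerance on the optima.
#' @return sorted integer vector of reaction indices with a character
#'   attribute `direction` parallel to it.
#' @export
#' @examples
#' findUnsatisfiedReversibility(runFVA(fixtureNetwork("net-d")$model),
#'                              fixtureNetwork("net-d")$model)
findUnsatisfiedReversibility <- function(fva, model, tol = 1e-9) {
  stopifnot(is(fva, "FvaResult"), is(model, "NetworkModel"))
  if (length(fva@reactionIds) != ncol(model@S)) {
    stop("FVA result and model disagree on the number of reactions")
  }
  hit <- which(model@reversible &
               (fva@vMax <= tol | fva@vMin >= -tol))
  direction <- vapply(hit, function(j) {
    zeroMin <- fva@vMin[j] >= -tol
    zeroMax <- fva@vMax[j] <= tol
    if (zeroMin && zeroMax) "zero"
    else if (zeroMin) "only-forward"
    else "only-backward"
  }, character(1))
  structure(hit, direction = direction)
}
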