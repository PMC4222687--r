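#' Compute an orthonormal basis of the kernel of S
#'
#' Every steady-state flux vector satisfies \eqn{Sv = 0}, i.e. lives in the
#' kernel (null space) of S.  The basis is computed from the singular value
#' decomposition; the rank of S is the number of singular values above
#' `max(m, n) * max(sigma) * eps` (the standard rank rule), and the
#' remaining right singular vectors span the kernel.  The kernel dimension
#' p may be 0 (full column rank) or n (zero matrix), both legal.
#'
#' @param model a [NetworkModel-class], or a numeric matrix.
#' @return a [NullspaceBasis-class] with orthonormal columns.
#' @export
#' @examples
#' basisMatrix(computeNullBasis(fixtureNetwork("net-c")$model))
computeNullBasis <- function(model) {
  if (is(model, "NetworkModel")) {
    S <- model@S
    rxnIds <- model@reactionIds
  } else {
    S <- as.matrix(model)
    rxnIds <- if (!is.null(colnames(S))) colnames(S) else
      paste0("R", seq_len(ncol(S)))
  }
  n <- ncol(S)
  if (n < 1L) stop("S must have at least one column")
  if (nrow(S) == 0L || all(S == 0)) {
    # no constraints: the kernel is all of R^n
    return(new("NullspaceBasis", basis = diag(n),
               rankTolerance = 0, reactionIds = rxnIds))
  }
  sv <- svd(S, nu = 0, nv = n)
  tolRank <- max(dim(S)) * max(sv$d) * .Machine$double.eps
  rank <- sum(sv$d > tolRank)
  basis <- if (rank < n) sv$v[, (rank + 1L):n, drop = FALSE] else
    matrix(0, n, 0)
  new("NullspaceBasis", basis = basis, rankTolerance = tolRank,
      reactionIds = rxnIds)
}

# threshold below which a basis entry counts as zero
basisZeroTol <- function(basis) {
  B <- basis@basis
  if (ncol(B) == 0L || max(abs(B)) == 0) 0 else 1e-9 * max(abs(B))
}

#' Reactions with an all-zero null-space basis row
#'
#' A reaction whose row of the kernel basis is entirely zero carries zero
#' flux in every steady state, so it is a zero-flux (blocked) reaction.
#' This detects only a subset of blocked reactions: the basis is oblivious
#' to directionality bounds, so reactions blocked purely by irreversibility
#' conflicts are missed (FVA finds those; see [findZeroFlux()]).  If the
#' kernel is empty (p = 0) every reaction is returned.
#'
#' @param basis a [NullspaceBasis-class] computed for the model under test.
#' @param tol entry-zero threshold; default `1e-9 * max(abs(B))`.
#' @return sorted integer vector of reaction indices (1-based).
#' @export
#' @examples
#' net <- fixtureNetwork("net-b")$model
#' findBasisZeroRows(computeNullBasis(net))  # R3
findBasisZeroRows <- function(basis, tol = NULL) {
  stopifnot(is(basis, "NullspaceBasis"))
  B <- basis@basis
  if (ncol(B) == 0L) return(seq_len(nrow(B)))
  if (is.null(tol)) tol <- basisZeroTol(basis)
  which(apply(abs(B) <= tol, 1L, all))
}

#' Coupled reaction pairs (CR)
#'
#' Two irreversible reactions are coupled iff their rows of the kernel
#' basis are proportional with matching zero patterns: every steady-state
#' flux distribution then assigns them fluxes in a fixed ratio.  Coupled
#' groups ("enzyme subsets") tend to be co-expressed and co-regulated, and
#' an incorrect ratio sign flags directionality problems (see
#' [findReversiblyCoupled()]).
#'
#' Rows are compared after normalising each by its entry of largest
#' magnitude, which makes the comparison invariant to the particular basis
#' returned by the decomposition.  Candidate rows are first grouped by
#' their zero/sign pattern, then clustered within a group by elementwise
#' agreement of the normalised rows within `relTol`, so the cost is
#' near-linear in n rather than quadratic.  Reversible reactions and
#' basis-zero rows are excluded; an opt-in flag admits reversible
#' reactions for exploratory use.
#'
#' @param basis a [NullspaceBasis-class] for `model`.
#' @param model the matching [NetworkModel-class].
#' @param relTol relative tolerance for ratio equality on normalised rows.
#' @param includeReversible logical; if `TRUE`, reversible reactions are
#'   also eligible for pairing (off by default: the condition is defined
#'   over irreversible reactions).
#' @return data.frame with columns `i`, `j` (reaction indices, i < j) and
#'   `ratio` (the common flux ratio v_i / v_j).
#' @export
#' @examples
#' net <- fixtureNetwork("net-c")$model
#' findCoupled(computeNullBasis(net), net)
findCoupled <- function(basis, model, relTol = 1e-6,
                        includeReversible = FALSE) {
  stopifnot(is(basis, "NullspaceBasis"), is(model, "NetworkModel"))
  B <- basis@basis
  n <- nrow(B)
  if (n != ncol(model@S)) {
    stop("basis and model disagree on the number of reactions")
  }
  empty <- data.frame(i = integer(0), j = integer(0), ratio = numeric(0))
  if (ncol(B) == 0L) return(empty)
  zeroTol <- basisZeroTol(basis)
  eligible <- if (includeReversible) seq_len(n) else which(!model@reversible)
  eligible <- setdiff(eligible, findBasisZeroRows(basis, zeroTol))
  if (length(eligible) < 2L) return(empty)

  # zero-thresholded copies of the candidate rows
  Z <- B
  Z[abs(Z) <= zeroTol] <- 0

  # bucket by zero pattern, then cluster within buckets.  Rows are compared
  # after normalising by a reference column fixed per cluster (the largest
  # entry of the cluster's first member), so proportional rows always land
  # together regardless of how ties in magnitude would break per row.
  pattern <- vapply(eligible, function(i) {
    paste(which(Z[i, ] != 0), collapse = ",")
  }, character(1))
  groups <- list()
  refCols <- integer(0)
  for (bucket in split(eligible, pattern)) {
    reps <- integer(0)
    repCol <- integer(0)
    members <- list()
    for (i in bucket) {
      placed <- FALSE
      for (g in seq_along(reps)) {
        k <- repCol[g]
        ref <- Z[reps[g], ] / Z[reps[g], k]
        u <- Z[i, ] / Z[i, k]
        if (max(abs(u - ref)) <= relTol * max(1, max(abs(ref)))) {
          members[[g]] <- c(members[[g]], i)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        reps <- c(reps, i)
        repCol <- c(repCol, which.max(abs(Z[i, ])))
        members[[length(reps)]] <- i
      }
    }
    keep <- lengths(members) >= 2L
    groups <- c(groups, members[keep])
    refCols <- c(refCols, repCol[keep])
  }
  if (!length(groups)) return(empty)

  out <- do.call(rbind, lapply(seq_along(groups), function(gi) {
    g <- sort(groups[[gi]])
    pairs <- utils::combn(g, 2L)
    k <- refCols[gi]  # reference column shared by the whole cluster
    data.frame(i = pairs[1, ], j = pairs[2, ],
               ratio = B[pairs[1, ], k] / B[pairs[2, ], k])
  }))
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reversibly coupled reaction pairs (RCR)
#'
#' The subset of coupled pairs whose flux ratio is negative: the two
#' irreversible reactions can only run in lockstep with opposite net signs,
#' which no steady state with nonnegative fluxes can realise unless both
#' are zero.  Always a subset of the coupled set.
#'
#' @param pairs a data.frame produced by [findCoupled()].
#' @return the rows of `pairs` with `ratio < 0`.
#' @export
findReversiblyCoupled <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("i", "j", "ratio") %in% names(pairs)))
  out <- pairs[pairs$ratio < 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}
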