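# ---------------------------------------------------------------------------
# Dense two-phase primal simplex for box-constrained linear programs
#
#   optimise c'x  subject to  A x = b,  0 <= x <= u
#
# written in standard form with one slack per upper bound and one artificial
# per equality row.  Bland's smallest-index rule is used throughout, so the
# method cannot cycle and always terminates.  Problem sizes here are those
# of consistency checking (hundreds of variables), where a dense tableau is
# perfectly adequate and, unlike off-the-shelf teaching implementations,
# handles degenerate and redundant equality systems reliably.
# ---------------------------------------------------------------------------

# One simplex phase on the tableau.  Tab is rows x (cols+1) with the RHS in
# the last column; obj is the current reduced-cost row (length cols+1,
# objective value, negated, in the last entry); basis[i] is the variable
# occupying row i.  allowed marks columns eligible to enter.
simplexPhase <- function(Tab, obj, basis, allowed, tol = 1e-9) {
  nc <- ncol(Tab) - 1L
  repeat {
    enter <- 0L
    for (j in seq_len(nc)) {            # Bland: first improving column
      if (allowed[j] && obj[j] < -tol) {
        enter <- j
        break
      }
    }
    if (enter == 0L) break
    col <- Tab[, enter]
    rows <- which(col > tol)
    if (!length(rows)) {
      return(list(Tab = Tab, obj = obj, basis = basis,
                  status = "unbounded"))
    }
    ratios <- Tab[rows, nc + 1L] / col[rows]
    best <- min(ratios)
    cand <- rows[ratios <= best + tol]
    leave <- cand[which.min(basis[cand])]  # Bland tie-break
    piv <- Tab[leave, enter]
    Tab[leave, ] <- Tab[leave, ] / piv
    for (r in seq_len(nrow(Tab))) {
      if (r != leave && abs(Tab[r, enter]) > 0) {
        Tab[r, ] <- Tab[r, ] - Tab[r, enter] * Tab[leave, ]
      }
    }
    obj <- obj - obj[enter] * Tab[leave, ]
    basis[leave] <- enter
  }
  list(Tab = Tab, obj = obj, basis = basis, status = "optimal")
}

# Solve: optimise c'x subject to A x = b, 0 <= x <= u.
# Returns list(status, value, x).
simplexBoxLP <- function(A, b, u, cvec, maximise = FALSE, tol = 1e-9) {
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(b) == m, length(u) == n, length(cvec) == n)
  # flip rows so every right-hand side is nonnegative
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
  }
  rows <- m + n
  nx <- n            # structural variables
  ns <- n            # bound slacks
  na <- m            # artificials on the equality rows
  nc <- nx + ns + na
  Tab <- matrix(0, rows, nc + 1L)
  Tab[seq_len(m), seq_len(nx)] <- A
  Tab[seq_len(m), nx + ns + seq_len(na)] <- diag(na)[, , drop = FALSE]
  Tab[m + seq_len(n), seq_len(n)] <- diag(n)
  Tab[m + seq_len(n), nx + seq_len(ns)] <- diag(n)
  Tab[, nc + 1L] <- c(b, u)
  basis <- c(nx + ns + seq_len(na), nx + seq_len(ns))

  # phase 1: minimise the artificial sum
  obj1 <- numeric(nc + 1L)
  obj1[nx + ns + seq_len(na)] <- 1
  for (r in seq_len(m)) obj1 <- obj1 - Tab[r, ]   # price out the basis
  allowed <- rep(TRUE, nc)
  ph1 <- simplexPhase(Tab, obj1, basis, allowed, tol)
  if (ph1$status != "optimal" || -ph1$obj[nc + 1L] > 1e-7) {
    return(list(status = "infeasible", value = NA_real_, x = NULL))
  }
  Tab <- ph1$Tab
  basis <- ph1$basis

  # drive leftover artificials out of the basis or drop redundant rows
  dropRows <- integer(0)
  for (r in seq_len(rows)) {
    if (basis[r] > nx + ns) {
      piv <- which(abs(Tab[r, seq_len(nx + ns)]) > tol)
      if (length(piv)) {
        jcol <- piv[1L]
        p <- Tab[r, jcol]
        Tab[r, ] <- Tab[r, ] / p
        for (rr in seq_len(rows)) {
          if (rr != r && abs(Tab[rr, jcol]) > 0) {
            Tab[rr, ] <- Tab[rr, ] - Tab[rr, jcol] * Tab[r, ]
          }
        }
        basis[r] <- jcol
      } else {
        dropRows <- c(dropRows, r)   # redundant equality row
      }
    }
  }
  if (length(dropRows)) {
    Tab <- Tab[-dropRows, , drop = FALSE]
    basis <- basis[-dropRows]
  }

  # phase 2 on the original objective (as a minimisation)
  sign <- if (maximise) -1 else 1
  obj2 <- numeric(nc + 1L)
  obj2[seq_len(nx)] <- sign * cvec
  for (r in seq_along(basis)) {        # price out the current basis
    bj <- basis[r]
    if (obj2[bj] != 0) obj2 <- obj2 - obj2[bj] * Tab[r, ]
  }
  allowed <- c(rep(TRUE, nx + ns), rep(FALSE, na))
  ph2 <- simplexPhase(Tab, obj2, basis, allowed, tol)
  if (ph2$status != "optimal") {
    return(list(status = ph2$status, value = NA_real_, x = NULL))
  }
  x <- numeric(nx)
  inX <- ph2$basis <= nx
  x[ph2$basis[inX]] <- ph2$Tab[inX, nc + 1L]
  value <- -sign * ph2$obj[nc + 1L]
  list(status = "optimal", value = value, x = x)
}
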