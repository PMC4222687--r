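test_that("kernel bases match hand-solved examples", {
  b1 <- computeNullBasis(matrix(c(1, -1), 1, 2))
  expect_equal(kernelDim(b1), 1L)
  v <- basisMatrix(b1)[, 1]
  expect_equal(abs(v[1] / v[2]), 1, tolerance = 1e-12)
  expect_gt(v[1] / v[2], 0)  # spans (1, 1)

  netc <- fixtureNetwork("net-c")$model
  b2 <- computeNullBasis(netc)
  expect_equal(kernelDim(b2), 1L)
  w <- basisMatrix(b2)[, 1]
  expect_equal(w / w[1], c(1, 1, -1, -1), tolerance = 1e-9)

  expect_equal(kernelDim(computeNullBasis(diag(3))), 0L)
})

test_that("basis columns are orthonormal and annihilated by S", {
  for (net in plantedBatch(1:8)) {
    S <- stoichiometry(net$model)
    basis <- computeNullBasis(net$model)
    B <- basisMatrix(basis)
    p <- ncol(B)
    expect_equal(p, ncol(S) - qr(S)$rank)
    if (p > 0) {
      expect_equal(crossprod(B), diag(p), tolerance = 1e-9,
                   ignore_attr = TRUE)
      resid <- max(abs(S %*% B))
      expect_lte(resid, 1e-8 * max(abs(S)) * max(abs(B)))
    }
  }
})

test_that("basis zero rows flag reactions with no steady-state flux", {
  netb <- fixtureNetwork("net-b")$model
  expect_equal(rxnIdSet(netb, findBasisZeroRows(computeNullBasis(netb))),
               "R3")
  neta <- fixtureNetwork("net-a")$model
  expect_equal(findBasisZeroRows(computeNullBasis(neta)), integer(0))
  # directionality-blocked reactions are invisible to the basis
  netc <- fixtureNetwork("net-c")$model
  expect_equal(findBasisZeroRows(computeNullBasis(netc)), integer(0))
  # empty kernel: every reaction is zero in every steady state
  expect_equal(findBasisZeroRows(computeNullBasis(diag(3))), 1:3)
})

test_that("coupled pairs reproduce the fixture ratios", {
  neta <- fixtureNetwork("net-a")$model
  pa <- findCoupled(computeNullBasis(neta), neta)
  expect_equal(pa, data.frame(i = 1L, j = 2L, ratio = 1))

  netc <- fixtureNetwork("net-c")$model
  pc <- findCoupled(computeNullBasis(netc), netc)
  expect_equal(nrow(pc), 6L)
  ratios <- setNames(pc$ratio, paste(pc$i, pc$j))
  expect_equal(ratios[["1 2"]], 1, tolerance = 1e-9)
  expect_equal(ratios[["3 4"]], 1, tolerance = 1e-9)
  for (k in c("1 3", "1 4", "2 3", "2 4")) {
    expect_equal(ratios[[k]], -1, tolerance = 1e-9)
  }
  rcr <- findReversiblyCoupled(pc)
  expect_equal(nrow(rcr), 4L)
  expect_true(all(rcr$ratio < 0))
})

test_that("reversible reactions are excluded from coupling by default", {
  netd <- fixtureNetwork("net-d")$model
  basis <- computeNullBasis(netd)
  pairs <- findCoupled(basis, netd)
  expect_equal(paste(pairs$i, pairs$j), "1 3")  # R2 (reversible) excluded
  withRev <- findCoupled(basis, netd, includeReversible = TRUE)
  expect_equal(nrow(withRev), 3L)
})

test_that("non-unit stoichiometry yields non-unit coupling ratios", {
  # R1 makes two units of A, R2 consumes one: v1/v2 = 1/2 at steady state
  model <- NetworkModel(matrix(c(2, -1), 1, 2),
                        reversible = c(FALSE, FALSE))
  pairs <- findCoupled(computeNullBasis(model), model)
  expect_equal(pairs$ratio, 0.5, tolerance = 1e-9)
})

test_that("reversibly coupled pairs are a subset of coupled pairs", {
  for (net in plantedBatch(1:10)) {
    basis <- computeNullBasis(net$model)
    cr <- findCoupled(basis, net$model)
    rcr <- findReversiblyCoupled(cr)
    expect_true(all(pairKeys(rcr) %in% pairKeys(cr)))
  }
})

test_that("coupling is invariant under the choice of kernel basis", {
  for (s in 1:6) {
    net <- plantedBatch(s)[[1]]
    basis <- computeNullBasis(net$model)
    p <- kernelDim(basis)
    if (p < 2) next
    rotated <- new("NullspaceBasis",
                   basis = basisMatrix(basis) %*% randomOrthogonal(p, s),
                   rankTolerance = basis@rankTolerance,
                   reactionIds = reactionIds(basis))
    a <- findCoupled(basis, net$model)
    b <- findCoupled(rotated, net$model)
    expect_equal(pairKeys(a), pairKeys(b))
    expect_equal(pairKeys(findReversiblyCoupled(a)),
                 pairKeys(findReversiblyCoupled(b)))
    ord <- function(x) x[order(x$i, x$j), ]
    expect_equal(ord(a)$ratio, ord(b)$ratio, tolerance = 1e-6)
  }
})

test_that("coupling is symmetric-transitive within a proportionality class", {
  for (net in plantedBatch(c(2, 3, 6, 7))) {
    pairs <- findCoupled(computeNullBasis(net$model), net$model)
    if (nrow(pairs) == 0L) next
    key <- paste(pairs$i, pairs$j)
    for (a in seq_len(nrow(pairs))) {
      for (b in seq_len(nrow(pairs))) {
        if (pairs$j[a] == pairs$i[b]) {
          expect_true(paste(pairs$i[a], pairs$j[b]) %in% key)
        }
      }
    }
  }
})
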