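test_that("FVA reproduces the hand-solved flux ranges", {
  netd <- fixtureNetwork("net-d")$model
  fva <- runFVA(netd)
  expect_equal(unname(fluxMin(fva)["R2"]), 0, tolerance = 1e-9)
  expect_equal(unname(fluxMax(fva)["R2"]), 1000, tolerance = 1e-9)

  netb <- fixtureNetwork("net-b")$model
  fvb <- runFVA(netb)
  expect_equal(unname(fluxMin(fvb)["R3"]), 0, tolerance = 1e-9)
  expect_equal(unname(fluxMax(fvb)["R3"]), 0, tolerance = 1e-9)

  netc <- fixtureNetwork("net-c")$model
  fvc <- runFVA(netc)
  expect_equal(unname(fluxMin(fvc)), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(fluxMax(fvc)), rep(0, 4), tolerance = 1e-9)
})

test_that("FVA intervals satisfy the result invariants", {
  for (net in plantedBatch(1:10)) {
    fva <- runFVA(net$model)
    expect_true(all(fluxMin(fva) <= fluxMax(fva) + 1e-9))
    irrev <- !isReversible(net$model)
    expect_true(all(fluxMin(fva)[irrev] >= -1e-9))
    expect_true(all(fva@lowerUsed <= fva@upperUsed))
  }
})

test_that("zero-flux detection matches the fixtures", {
  netb <- fixtureNetwork("net-b")$model
  expect_equal(rxnIdSet(netb, findZeroFlux(runFVA(netb))), "R3")
  neta <- fixtureNetwork("net-a")$model
  expect_equal(findZeroFlux(runFVA(neta)), integer(0))
  netc <- fixtureNetwork("net-c")$model
  expect_equal(findZeroFlux(runFVA(netc)), 1:4)
})

test_that("unsatisfied reversibility is annotated with its direction", {
  netd <- fixtureNetwork("net-d")$model
  fva <- runFVA(netd)
  ur <- findUnsatisfiedReversibility(fva, netd)
  expect_equal(as.integer(ur), 2L)
  expect_equal(attr(ur, "direction"), "only-forward")

  # mirrored chain: the reversible step can only run backwards
  S <- rbind(c(-1, -1, 0), c(0, 1, 1))
  mirror <- NetworkModel(S, reversible = c(FALSE, TRUE, FALSE),
                         exchange = c(1L, 3L),
                         metaboliteIds = c("A", "B"))
  urM <- findUnsatisfiedReversibility(runFVA(mirror), mirror)
  expect_equal(attr(urM, "direction"), "only-backward")

  # irreversible-only models can never trip the condition
  netc <- fixtureNetwork("net-c")$model
  expect_length(findUnsatisfiedReversibility(runFVA(netc), netc), 0L)

  # a blocked reversible reaction is annotated "zero"
  S2 <- rbind(c(1, -1, -1), c(0, 0, 1))
  blockedRev <- NetworkModel(S2, reversible = c(FALSE, FALSE, TRUE),
                             exchange = c(1L, 2L))
  fv2 <- runFVA(blockedRev)
  ur2 <- findUnsatisfiedReversibility(fv2, blockedRev)
  expect_equal(attr(ur2, "direction"), "zero")
})

test_that("blocked reversible reactions are always unsatisfied", {
  for (net in plantedBatch(1:10)) {
    fva <- runFVA(net$model)
    zfr <- findZeroFlux(fva)
    ur <- findUnsatisfiedReversibility(fva, net$model)
    revZfr <- intersect(which(isReversible(net$model)), zfr)
    expect_true(all(revZfr %in% as.integer(ur)))
  }
})

test_that("basis-detected zero rows are a subset of FVA-detected ones", {
  nets <- c(lapply(c("net-a", "net-b", "net-c", "net-d", "net-combined"),
                   function(nm) fixtureNetwork(nm)),
            plantedBatch(1:10))
  for (net in nets) {
    model <- net$model
    bz <- findBasisZeroRows(computeNullBasis(model))
    zf <- findZeroFlux(runFVA(model))
    expect_true(all(bz %in% zf))
  }
})

test_that("irreversible reactions at a dead end are blocked", {
  for (net in plantedBatch(1:6)) {
    model <- net$model
    S <- stoichiometry(model)
    dem <- findDeadEnd(model)
    zfr <- findZeroFlux(runFVA(model))
    for (i in dem) {
      touching <- which(abs(S[i, ]) > 1e-12)
      if (all(!isReversible(model)[touching])) {
        expect_true(all(touching %in% zfr))
      }
    }
  }
})

test_that("scaling all bounds by a positive constant changes no result set", {
  for (net in plantedBatch(c(3, 5, 7))) {
    model <- net$model
    fva1 <- runFVA(model)
    scaled <- cbind(fva1@lowerUsed, fva1@upperUsed) * 4
    fva2 <- runFVA(model, bounds = scaled)
    expect_equal(findZeroFlux(fva1), findZeroFlux(fva2))
    ur1 <- findUnsatisfiedReversibility(fva1, model)
    ur2 <- findUnsatisfiedReversibility(fva2, model)
    expect_equal(as.integer(ur1), as.integer(ur2))
  }
})

test_that("user bounds are honoured; exchange widening only fills defaults", {
  netd <- fixtureNetwork("net-d")
  S <- stoichiometry(netd$model)
  capped <- NetworkModel(S, reversible = isReversible(netd$model),
                         exchange = exchangeReactions(netd$model),
                         lowerBounds = c(0, -1000, 0),
                         upperBounds = c(5, 1000, 1000))
  fva <- runFVA(capped)
  # the whole chain is throttled by the user cap on the uptake reaction
  expect_equal(unname(fluxMax(fva)), c(5, 5, 5), tolerance = 1e-9)

  # without user bounds the exchange bounds are the wide defaults
  fvaWide <- runFVA(netd$model)
  expect_equal(unname(fluxMax(fvaWide)), c(1000, 1000, 1000),
               tolerance = 1e-9)
})

test_that("each LP is solved independently and deterministically", {
  model <- fixtureNetwork("net-combined")$model
  a <- runFVA(model)
  b <- runFVA(model)
  expect_identical(fluxMin(a), fluxMin(b))
  expect_identical(fluxMax(a), fluxMax(b))
})
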