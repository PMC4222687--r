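test_that("smallest legal tabular grid parses with reversibility row", {
  grid <- rbind(c(1, -1), c(1, 0))  # one metabolite; last row = flags
  model <- readTabularModel(grid, exchange = c(1, 2))
  expect_s4_class(model, "NetworkModel")
  expect_equal(nMetabolites(model), 1L)
  expect_equal(nReactions(model), 2L)
  expect_equal(isReversible(model), c(TRUE, FALSE))
  expect_equal(exchangeReactions(model), c(1L, 2L))
})

test_that("net-b grid parses to the hand-counted shape", {
  fx <- fixtureNetwork("net-b")
  stoich <- tempfile(fileext = ".tsv")
  exch <- tempfile()
  exportTabular(fx$model, stoich, exchangeFile = exch)
  model <- readTabularModel(stoich, exchange = exch)
  expect_equal(nMetabolites(model), 2L)
  expect_equal(nReactions(model), 3L)
  expect_equal(exchangeReactions(model), c(1L, 2L))
  expect_equal(stoichiometry(model), stoichiometry(fx$model))
  expect_equal(isReversible(model), isReversible(fx$model))
})

test_that("external rows are stripped without touching reactions", {
  grid <- rbind(c(1, -1, 0),
                c(0, 1, -1),
                c(0, 0, 1),
                c(0, 0, 0))   # reversibility row
  full <- readTabularModel(grid, exchange = 1)
  stripped <- readTabularModel(grid, exchange = 1, external = 2)
  expect_equal(nMetabolites(stripped), nMetabolites(full) - 1L)
  expect_equal(nReactions(stripped), nReactions(full))
  expect_equal(stoichiometry(stripped)[, 2], c(M1 = -1, M3 = 0))

  # stripping k rows always reduces m by exactly k
  both <- suppressWarnings(
    readTabularModel(grid, exchange = 1, external = c(1, 3)))
  expect_equal(nMetabolites(both), 1L)
})

test_that("identifier row/column are detected by non-numeric content", {
  grid <- rbind(c("ID", "up", "conv"),
                c("glc", "1", "-1"),
                c("REVERSIBLE", "0", "1"))
  model <- readTabularModel(grid, exchange = 1)
  expect_equal(metaboliteIds(model), "glc")
  expect_equal(reactionIds(model), c("up", "conv"))
  expect_equal(isReversible(model), c(FALSE, TRUE))
})

test_that("malformed tabular input fails with a located error", {
  bad <- rbind(c("1", "x"), c("0", "0"))
  expect_error(readTabularModel(bad, exchange = 1),
               "row 1, column 2")
  grid <- rbind(c(1, -1), c(0, 0))
  expect_error(readTabularModel(grid, exchange = 5), "1\\.\\.2")
  expect_error(readTabularModel(grid, exchange = 1, external = 9),
               "external")
  expect_error(readTabularModel(grid, exchange = 1,
                                bounds = matrix(0, 3, 2)),
               "one row per reaction")
  expect_error(readTabularModel(matrix(1, 1, 2), exchange = 1),
               "reversibility row")
  expect_error(readTabularModel(rbind(c(1, -1), c(2, 0)), exchange = 1),
               "0/1")
})

test_that("default bounds follow reversibility elementwise", {
  mk <- function(rev) {
    NetworkModel(matrix(rnorm(length(rev)), 1), reversible = rev)
  }
  expect_equal(defaultBounds(mk(TRUE)), list(lower = -1000, upper = 1000))
  expect_equal(defaultBounds(mk(FALSE)), list(lower = 0, upper = 1000))
  db <- defaultBounds(mk(c(FALSE, TRUE, FALSE)))
  expect_equal(db$lower, c(0, -1000, 0))
  expect_equal(db$upper, rep(1000, 3))
  # defaults always satisfy the model bound invariants
  expect_true(all(db$lower <= db$upper))
})

test_that("user bounds override defaults and are marked as user-supplied", {
  model <- NetworkModel(matrix(c(1, -1), 1, 2),
                        reversible = c(FALSE, FALSE),
                        exchange = c(1L, 2L),
                        lowerBounds = c(0, 0), upperBounds = c(5, 7))
  expect_equal(upperBounds(model), c(5, 7))
  expect_error(
    NetworkModel(matrix(c(1, -1), 1, 2), reversible = c(FALSE, FALSE),
                 lowerBounds = c(-1, 0), upperBounds = c(5, 7)),
    "irreversible")
})

test_that("model statistics count the four report quantities", {
  st <- modelStatistics(fixtureNetwork("net-c")$model)
  expect_equal(st, list(nReactions = 4L, nReversible = 0L,
                        nExchange = 2L, nMetabolites = 3L))
  noExch <- NetworkModel(matrix(c(1, -1), 1, 2),
                         reversible = c(TRUE, FALSE))
  expect_equal(modelStatistics(noExch)$nExchange, 0L)
})

test_that("SBML and tabular readers agree on the same network", {
  for (name in c("net-a", "net-c", "net-d")) {
    fx <- fixtureNetwork(name)
    sbml <- tempfile(fileext = ".xml")
    stoich <- tempfile(fileext = ".tsv")
    exch <- tempfile()
    exportSBML(fx$model, sbml)
    exportTabular(fx$model, stoich, exchangeFile = exch)
    fromSbml <- readSBMLModel(sbml,
      exchangeIds = reactionIds(fx$model)[exchangeReactions(fx$model)])
    fromTab <- readTabularModel(stoich, exchange = exch)
    expect_equal(stoichiometry(fromSbml), stoichiometry(fromTab))
    expect_equal(isReversible(fromSbml), isReversible(fromTab))
    expect_equal(exchangeReactions(fromSbml), exchangeReactions(fromTab))
  }
})

sbmlDoc <- function(species, reactions) {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" ',
    'level="2" version="4"><model id="m">',
    '<listOfSpecies>', species, '</listOfSpecies>',
    '<listOfReactions>', reactions, '</listOfReactions>',
    '</model></sbml>')
}

test_that("boundary-condition species are stripped from SBML models", {
  doc <- sbmlDoc(
    paste0('<species id="A" compartment="c"/>',
           '<species id="Aext" compartment="c" boundaryCondition="true"/>'),
    paste0('<reaction id="R1" reversible="false">',
           '<listOfReactants>',
           '<speciesReference species="Aext"/>',
           '</listOfReactants><listOfProducts>',
           '<speciesReference species="A" stoichiometry="2"/>',
           '</listOfProducts></reaction>'))
  path <- tempfile(fileext = ".xml")
  writeLines(doc, path)
  model <- readSBMLModel(path)
  expect_equal(metaboliteIds(model), "A")
  expect_equal(unname(stoichiometry(model)[1, 1]), 2)
  # the reaction touched a boundary species, so it is auto-exchange
  expect_equal(exchangeReactions(model), 1L)
})

test_that("an all-boundary SBML document is rejected", {
  doc <- sbmlDoc(
    '<species id="A" boundaryCondition="true"/>',
    paste0('<reaction id="R1"><listOfProducts>',
           '<speciesReference species="A"/>',
           '</listOfProducts></reaction>'))
  path <- tempfile(fileext = ".xml")
  writeLines(doc, path)
  expect_error(readSBMLModel(path), "no internal metabolites")
})

test_that("duplicate species references are summed; missing reversible attr means reversible", {
  doc <- sbmlDoc(
    paste0('<species id="A"/>', '<species id="B"/>'),
    paste0('<reaction id="R1">',
           '<listOfReactants>',
           '<speciesReference species="A"/>',
           '<speciesReference species="A" stoichiometry="2"/>',
           '</listOfReactants><listOfProducts>',
           '<speciesReference species="B"/>',
           '</listOfProducts></reaction>'))
  path <- tempfile(fileext = ".xml")
  writeLines(doc, path)
  model <- readSBMLModel(path)
  expect_equal(stoichiometry(model)["A", "R1"], -3)
  expect_true(isReversible(model))  # SBML Level 2 default
})

test_that("unknown identifiers in SBML lists fail rather than being skipped", {
  fx <- fixtureNetwork("net-a")
  path <- tempfile(fileext = ".xml")
  exportSBML(fx$model, path)
  expect_error(readSBMLModel(path, externalIds = "nope"), "unknown external")
  expect_error(readSBMLModel(path, exchangeIds = "nope"), "unknown exchange")
  bad <- tempfile(fileext = ".xml")
  writeLines("<sbml><unclosed", bad)
  expect_error(readSBMLModel(bad), "cannot parse")
})
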