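# ---------------------------------------------------------------------------
# Synthetic networks with planted inconsistencies and ground-truth labels.
#
# The canonical fixtures are minimal hand-checkable networks exhibiting one
# issue each; randomPlanted() grafts the same motifs onto a feasible
# backbone so detection can be validated against known truth at scale.
# ---------------------------------------------------------------------------

emptyTruth <- function() {
  list(scm = character(0), dem = character(0),
       zfr = character(0), ur = character(0),
       urDirection = character(0),
       cr = data.frame(idI = character(0), idJ = character(0),
                       ratio = numeric(0)),
       rcr = data.frame(idI = character(0), idJ = character(0),
                        ratio = numeric(0)))
}

truthPairs <- function(idI, idJ, ratio) {
  data.frame(idI = idI, idJ = idJ, ratio = ratio)
}

#' Canonical fixture networks
#'
#' Small networks, each planted with a known set of issues:
#' \describe{
#'   \item{net-a}{in -> A -> out, two irreversible exchange reactions.  No
#'     issues; R1 and R2 are coupled with ratio +1.}
#'   \item{net-b}{net-a plus a branch A -> C with C internal: C is singly
#'     connected and a dead end, and the branch reaction is blocked.}
#'   \item{net-c}{two irreversible chains in -> A -> D and in -> B -> D
#'     meeting at dead-end D: every reaction is blocked by FVA even though
#'     no basis row is zero; the four cross pairs are reversibly coupled
#'     (ratio -1).}
#'   \item{net-d}{in -> A <-> B -> out with the middle step reversible: its
#'     feasible range is [0, 1000], so its reversibility is unsatisfied
#'     (only-forward).}
#'   \item{net-combined}{the net-c and net-d patterns side by side in one
#'     model, exercising the coexistence of DEM, ZFR, UR and RCR.}
#' }
#'
#' @param name one of `"net-a"`, `"net-b"`, `"net-c"`, `"net-d"`,
#'   `"net-combined"`.
#' @return list with components `model` (a [NetworkModel-class]) and
#'   `truth` (planted ground-truth sets, by identifier: `scm`, `dem`,
#'   `zfr`, `ur`, `urDirection`, and pair data frames `cr`, `rcr`).
#' @export
#' @examples
#' fixtureNetwork("net-c")$truth$rcr
fixtureNetwork <- function(name = c("net-a", "net-b", "net-c", "net-d",
                                    "net-combined")) {
  name <- match.arg(name)
  truth <- emptyTruth()
  if (name == "net-a") {
    S <- matrix(c(1, -1), 1, 2)
    model <- NetworkModel(S, reversible = c(FALSE, FALSE),
                          exchange = c(1L, 2L),
                          metaboliteIds = "A",
                          reactionIds = c("R1", "R2"),
                          metadata = list(source = name))
    truth$cr <- truthPairs("R1", "R2", 1)
  } else if (name == "net-b") {
    S <- rbind(c(1, -1, -1),
               c(0, 0, 1))
    model <- NetworkModel(S, reversible = rep(FALSE, 3),
                          exchange = c(1L, 2L),
                          metaboliteIds = c("A", "C"),
                          reactionIds = c("R1", "R2", "R3"),
                          metadata = list(source = name))
    truth$scm <- "C"
    truth$dem <- "C"
    truth$zfr <- "R3"
    truth$cr <- truthPairs("R1", "R2", 1)
  } else if (name == "net-c") {
    S <- rbind(c(1, -1, 0, 0),
               c(0, 0, 1, -1),
               c(0, 1, 0, 1))
    model <- NetworkModel(S, reversible = rep(FALSE, 4),
                          exchange = c(1L, 3L),
                          metaboliteIds = c("A", "B", "D"),
                          reactionIds = c("R1", "R2", "R3", "R4"),
                          metadata = list(source = name))
    truth$dem <- "D"
    truth$zfr <- c("R1", "R2", "R3", "R4")
    truth$cr <- truthPairs(
      c("R1", "R1", "R1", "R2", "R2", "R3"),
      c("R2", "R3", "R4", "R3", "R4", "R4"),
      c(1, -1, -1, -1, -1, 1))
    truth$rcr <- truth$cr[truth$cr$ratio < 0, ]
    rownames(truth$rcr) <- NULL
  } else if (name == "net-d") {
    S <- rbind(c(1, -1, 0),
               c(0, 1, -1))
    model <- NetworkModel(S, reversible = c(FALSE, TRUE, FALSE),
                          exchange = c(1L, 3L),
                          metaboliteIds = c("A", "B"),
                          reactionIds = c("R1", "R2", "R3"),
                          metadata = list(source = name))
    truth$ur <- "R2"
    truth$urDirection <- c(R2 = "only-forward")
    truth$cr <- truthPairs("R1", "R3", 1)
  } else { # net-combined
    #        R1   R2   R3   R4   R5   R6   R7
    S <- rbind(
      c(1, -1, 0, 0, 0, 0, 0),   # A1
      c(0, 0, 1, -1, 0, 0, 0),   # B1
      c(0, 1, 0, 1, 0, 0, 0),   # D1  (dead end)
      c(0, 0, 0, 0, 1, -1, 0),   # A2
      c(0, 0, 0, 0, 0, 1, -1))   # B2
    model <- NetworkModel(S,
      reversible = c(rep(FALSE, 5), TRUE, FALSE),
      exchange = c(1L, 3L, 5L, 7L),
      metaboliteIds = c("A1", "B1", "D1", "A2", "B2"),
      reactionIds = paste0("R", 1:7),
      metadata = list(source = name))
    truth$dem <- "D1"
    truth$zfr <- c("R1", "R2", "R3", "R4")
    truth$ur <- "R6"
    truth$urDirection <- c(R6 = "only-forward")
    truth$cr <- rbind(
      truthPairs(
        c("R1", "R1", "R1", "R2", "R2", "R3"),
        c("R2", "R3", "R4", "R3", "R4", "R4"),
        c(1, -1, -1, -1, -1, 1)),
      truthPairs("R5", "R7", 1))
    truth$rcr <- truth$cr[truth$cr$ratio < 0, ]
    rownames(truth$rcr) <- NULL
  }
  truth$name <- name
  list(model = model, truth = truth)
}

# run body with a private RNG stream seeded by `seed`
withLocalSeed <- function(seed, body) {
  hadSeed <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  body()
}

#' Random network with planted inconsistencies
#'
#' Builds a feasible backbone — an uptake exchange, a chain of `nCore`
#' metabolites, and a secretion exchange, all irreversible, every reaction
#' able to carry flux (verified internally by FVA) — and grafts the
#' requested number of issue motifs onto distinct backbone metabolites,
#' using fresh metabolite identifiers so the planted truths compose
#' without interference:
#' \describe{
#'   \item{dead-end branch (`nDem`)}{a single reaction into a fresh
#'     metabolite: plants one SCM, one DEM and one blocked reaction.}
#'   \item{blocked pair (`nZfr`)}{two irreversible two-step arms meeting
#'     at a fresh dead-end metabolite: plants one DEM, four blocked
#'     reactions, six coupled pairs of which four are reversibly
#'     coupled.}
#'   \item{one-way reversible cycle (`nUr`)}{a reversible step to a fresh
#'     metabolite and an irreversible step back: the reversible reaction
#'     can only run forward (unsatisfied reversibility) and nothing is
#'     blocked.}
#' }
#' Stoichiometric coefficients of the grafted motifs are drawn from
#' \{1, 2\} so coupling ratios other than ±1 occur.  Output is
#' deterministic for a fixed seed.
#'
#' @param nCore number of backbone metabolites (>= 2); also the number of
#'   attachment sites, so `nDem + nZfr + nUr <= nCore`.
#' @param nDem,nZfr,nUr number of motifs of each kind to plant.
#' @param seed integer seed; the generator uses a private RNG stream.
#' @return list with components `model` and `truth` as in
#'   [fixtureNetwork()], plus `truth$seed` and `truth$params`.
#' @export
#' @examples
#' net <- randomPlanted(5, nDem = 2, nZfr = 1, nUr = 1, seed = 7)
#' net$truth$dem
randomPlanted <- function(nCore, nDem = 0, nZfr = 0, nUr = 0, seed = 1) {
  stopifnot(nCore >= 2, nDem >= 0, nZfr >= 0, nUr >= 0)
  nMotifs <- nDem + nZfr + nUr
  if (nMotifs > nCore) {
    stop("more motifs requested (", nMotifs, ") than attachable backbone ",
         "sites (", nCore, ")")
  }
  withLocalSeed(seed, function() {
    mets <- paste0("C", seq_len(nCore))
    entries <- list()  # (met, rxn, coef)
    addEntry <- function(met, rxn, coef) {
      entries[[length(entries) + 1L]] <<- list(met = met, rxn = rxn,
                                               coef = coef)
    }
    rxns <- character(0)
    revFlags <- logical(0)
    addRxn <- function(id, reversible) {
      rxns <<- c(rxns, id)
      revFlags <<- c(revFlags, reversible)
    }

    # backbone: EX_in -> C1 -> ... -> CnCore -> EX_out
    addRxn("EX_in", FALSE); addEntry(mets[1], "EX_in", 1)
    for (i in seq_len(nCore - 1L)) {
      id <- paste0("B", i)
      addRxn(id, FALSE)
      addEntry(mets[i], id, -1)
      addEntry(mets[i + 1L], id, 1)
    }
    addRxn("EX_out", FALSE); addEntry(mets[nCore], "EX_out", -1)
    exchangeIds <- c("EX_in", "EX_out")

    truth <- emptyTruth()
    sites <- sample(nCore, nMotifs)
    kinds <- rep(c("dem", "zfr", "ur"), times = c(nDem, nZfr, nUr))
    coef <- function() sample(c(1, 2), 1L)

    for (k in seq_along(kinds)) {
      site <- mets[sites[k]]
      if (kinds[k] == "dem") {
        x <- paste0("Xdem", k)
        rid <- paste0("Rdem", k)
        mets <- c(mets, x)
        addRxn(rid, FALSE)
        addEntry(site, rid, -1)
        addEntry(x, rid, coef())
        truth$scm <- c(truth$scm, x)
        truth$dem <- c(truth$dem, x)
        truth$zfr <- c(truth$zfr, rid)
      } else if (kinds[k] == "zfr") {
        y1 <- paste0("Yzfr", k, "a"); y2 <- paste0("Yzfr", k, "b")
        w <- paste0("Wzfr", k)
        mets <- c(mets, y1, y2, w)
        ra <- paste0("Rzfr", k, "a"); rb <- paste0("Rzfr", k, "b")
        rc <- paste0("Rzfr", k, "c"); rd <- paste0("Rzfr", k, "d")
        cA <- coef(); cB1 <- coef(); cB2 <- coef()
        cC <- coef(); cD1 <- coef(); cD2 <- coef()
        addRxn(ra, FALSE); addEntry(site, ra, -1); addEntry(y1, ra, cA)
        addRxn(rb, FALSE); addEntry(y1, rb, -cB1); addEntry(w, rb, cB2)
        addRxn(rc, FALSE); addEntry(site, rc, -1); addEntry(y2, rc, cC)
        addRxn(rd, FALSE); addEntry(y2, rd, -cD1); addEntry(w, rd, cD2)
        truth$dem <- c(truth$dem, w)
        truth$zfr <- c(truth$zfr, ra, rb, rc, rd)
        # kernel direction: vd = t, vb = -(cD2/cB2) t,
        # va = (cB1/cA) vb, vc = (cD1/cC) t
        va <- -(cB1 / cA) * (cD2 / cB2)
        vb <- -(cD2 / cB2)
        vc <- cD1 / cC
        vd <- 1
        v <- c(va, vb, vc, vd)
        ids <- c(ra, rb, rc, rd)
        pr <- utils::combn(4L, 2L)
        motifPairs <- truthPairs(ids[pr[1, ]], ids[pr[2, ]],
                                 v[pr[1, ]] / v[pr[2, ]])
        truth$cr <- rbind(truth$cr, motifPairs)
      } else { # ur
        y <- paste0("Yur", k)
        mets <- c(mets, y)
        rrev <- paste0("Rur", k, "fwd")
        rret <- paste0("Rur", k, "ret")
        addRxn(rrev, TRUE)
        addEntry(site, rrev, -1); addEntry(y, rrev, 1)
        addRxn(rret, FALSE)
        addEntry(y, rret, -1); addEntry(site, rret, 1)
        truth$ur <- c(truth$ur, rrev)
        dir <- stats::setNames("only-forward", rrev)
        truth$urDirection <- c(truth$urDirection, dir)
      }
    }

    S <- matrix(0, length(mets), length(rxns),
                dimnames = list(mets, rxns))
    for (e in entries) S[e$met, e$rxn] <- S[e$met, e$rxn] + e$coef
    model <- NetworkModel(S, reversible = revFlags,
                          exchange = match(exchangeIds, rxns),
                          metaboliteIds = mets, reactionIds = rxns,
                          metadata = list(source = "randomPlanted",
                                          seed = seed))

    # the backbone alone must be able to carry flux everywhere
    backboneCols <- which(!(rxns %in% c(truth$zfr, truth$ur)) &
                            !grepl("^Rur", rxns))
    backbone <- NetworkModel(
      S[seq_len(nCore), backboneCols, drop = FALSE],
      reversible = revFlags[backboneCols],
      exchange = match(exchangeIds, rxns[backboneCols]),
      metaboliteIds = mets[seq_len(nCore)],
      reactionIds = rxns[backboneCols])
    fva <- runFVA(backbone)
    if (any(fva@vMax <= 1e-9)) {
      stop("internal error: backbone is not fully feasible")
    }

    truth$rcr <- truth$cr[truth$cr$ratio < 0, , drop = FALSE]
    rownames(truth$rcr) <- NULL
    truth$seed <- seed
    truth$params <- list(nCore = nCore, nDem = nDem, nZfr = nZfr,
                         nUr = nUr)
    truth$name <- "random-planted"
    list(model = model, truth = truth)
  })
}

# ---------------------------------------------------------------------------
# fixture export (feeds the tabular/SBML round-trip tests)
# ---------------------------------------------------------------------------

#' Write a model in the tabular layout
#'
#' Writes the stoichiometry grid (identifier header row and column, one
#' row per metabolite, trailing 0/1 reversibility row labelled
#' `REVERSIBLE`) and, optionally, the single-column exchange index list
#' and the two-column bounds table.  Files are TSV unless the path ends
#' in `.csv`.
#'
#' @param model a [NetworkModel-class].
#' @param stoichFile path for the stoichiometry grid.
#' @param exchangeFile optional path for the exchange list (1-based
#'   reaction indices, one per line).
#' @param boundsFile optional path for the n x 2 bounds table.
#' @return invisibly, the stoichiometry file path.
#' @export
exportTabular <- function(model, stoichFile, exchangeFile = NULL,
                          boundsFile = NULL) {
  stopifnot(is(model, "NetworkModel"))
  sep <- if (grepl("\\.csv$", stoichFile, ignore.case = TRUE)) "," else "\t"
  grid <- rbind(model@S, as.numeric(model@reversible))
  grid <- cbind(c(model@metaboliteIds, "REVERSIBLE"),
                format(grid, trim = TRUE, scientific = FALSE, digits = 15))
  grid <- rbind(c("ID", model@reactionIds), grid)
  utils::write.table(grid, stoichFile, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(exchangeFile)) {
    writeLines(as.character(model@exchange), exchangeFile)
  }
  if (!is.null(boundsFile)) {
    utils::write.table(cbind(model@lowerBounds, model@upperBounds),
                       boundsFile, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(stoichFile)
}

xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write a model as a minimal SBML Level 3 document
#'
#' Serialises species, reactions, stoichiometries and reversibility flags
#' — the subset [readSBMLModel()] consumes.  All species are written as
#' internal (the model is already stripped); `boundarySpecies` adds extra
#' species flagged `boundaryCondition="true"` for testing the stripping
#' path.
#'
#' @param model a [NetworkModel-class].
#' @param file output path.
#' @param boundarySpecies optional character vector of extra species ids
#'   written with a true boundary condition (referenced by no reaction).
#' @return invisibly, `file`.
#' @export
exportSBML <- function(model, file, boundarySpecies = character(0)) {
  stopifnot(is(model, "NetworkModel"))
  sp <- vapply(model@metaboliteIds, function(id) {
    sprintf(paste0('      <species id="%s" compartment="c" ',
                   'boundaryCondition="false" hasOnlySubstanceUnits="false"',
                   ' constant="false"/>'), xmlEscape(id))
  }, character(1))
  spB <- vapply(boundarySpecies, function(id) {
    sprintf(paste0('      <species id="%s" compartment="c" ',
                   'boundaryCondition="true" hasOnlySubstanceUnits="false"',
                   ' constant="false"/>'), xmlEscape(id))
  }, character(1))
  rx <- vapply(seq_len(ncol(model@S)), function(j) {
    col <- model@S[, j]
    ref <- function(i, coef) {
      sprintf(paste0('          <speciesReference species="%s" ',
                     'stoichiometry="%s" constant="true"/>'),
              xmlEscape(model@metaboliteIds[i]),
              format(coef, scientific = FALSE))
    }
    reactants <- which(col < 0)
    products <- which(col > 0)
    body <- character(0)
    if (length(reactants)) {
      body <- c(body, "        <listOfReactants>",
                vapply(reactants, function(i) ref(i, -col[i]), character(1)),
                "        </listOfReactants>")
    }
    if (length(products)) {
      body <- c(body, "        <listOfProducts>",
                vapply(products, function(i) ref(i, col[i]), character(1)),
                "        </listOfProducts>")
    }
    paste(c(sprintf('      <reaction id="%s" reversible="%s" fast="false">',
                    xmlEscape(model@reactionIds[j]),
                    if (model@reversible[j]) "true" else "false"),
            body, "      </reaction>"), collapse = "\n")
  }, character(1))
  doc <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'level="3" version="1">'),
    '  <model id="model">',
    '    <listOfCompartments>',
    '      <compartment id="c" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>',
    sp, spB,
    '    </listOfSpecies>',
    '    <listOfReactions>',
    rx,
    '    </listOfReactions>',
    '  </model>',
    '</sbml>')
  writeLines(doc, file)
  invisible(file)
}
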