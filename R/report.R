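#' Run a full consistency check on a model
#'
#' Orchestrates the condition checks.  Connectivity checks (singly
#' connected and dead-end metabolites) always run; `checkType` selects
#' the rest: 0 runs only the null-space-basis checks (coupled and
#' reversibly coupled reactions), 1 runs only the FVA checks (zero-flux
#' reactions and unsatisfied reversibility), 2 runs both.
#'
#' @param model a [NetworkModel-class].
#' @param checkType integer 0, 1 or 2 (see above).
#' @param bounds optional n x 2 matrix overriding all flux bounds for FVA.
#' @param tolFlux zero tolerance on FVA optima.
#' @param tolRatio relative tolerance for coupling-ratio equality.
#' @return a [CheckReport-class].
#' @export
#' @examples
#' checkModel(fixtureNetwork("net-c")$model, checkType = 2)
checkModel <- function(model, checkType = 2, bounds = NULL,
                       tolFlux = 1e-9, tolRatio = 1e-6) {
  stopifnot(is(model, "NetworkModel"))
  if (length(checkType) != 1L || !checkType %in% 0:2) {
    stop("checkType must be 0 (basis checks), 1 (FVA checks) or 2 (both)")
  }
  checkType <- as.integer(checkType)
  doBasis <- checkType %in% c(0L, 2L)
  doFva <- checkType %in% c(1L, 2L)

  scm <- findSinglyConnected(model)
  dem <- findDeadEnd(model)
  orphans <- findOrphanMetabolites(model)

  emptyPairs <- data.frame(i = integer(0), j = integer(0),
                           ratio = numeric(0))
  basisZero <- integer(0)
  crPairs <- rcrPairs <- emptyPairs
  if (doBasis) {
    basis <- computeNullBasis(model)
    basisZero <- findBasisZeroRows(basis)
    crPairs <- findCoupled(basis, model, relTol = tolRatio)
    rcrPairs <- findReversiblyCoupled(crPairs)
  }

  zfr <- ur <- integer(0)
  urDirection <- character(0)
  fva <- NULL
  if (doFva) {
    fva <- runFVA(model, bounds = bounds, eps = tolFlux)
    zfr <- findZeroFlux(fva, tol = tolFlux)
    ur <- findUnsatisfiedReversibility(fva, model, tol = tolFlux)
    urDirection <- attr(ur, "direction")
    if (is.null(urDirection)) urDirection <- character(0)
    ur <- as.integer(ur)
  }

  new("CheckReport",
    statistics = modelStatistics(model),
    scm = as.integer(scm),
    dem = as.integer(dem),
    orphans = as.integer(orphans),
    basisZero = as.integer(basisZero),
    zfr = as.integer(zfr),
    ur = ur,
    urDirection = urDirection,
    crPairs = crPairs,
    rcrPairs = rcrPairs,
    checkType = checkType,
    enabled = c(connectivity = TRUE, basis = doBasis, fva = doFva),
    fva = fva,
    metaboliteIds = model@metaboliteIds,
    reactionIds = model@reactionIds,
    tolerances = list(tolFlux = tolFlux, tolRatio = tolRatio)
  )
}

# reactions participating in >=1 coupled pair
coupledReactionCount <- function(pairs) {
  length(unique(c(pairs$i, pairs$j)))
}

#' Render the four-section text report
#'
#' Produces the human-readable summary: a statistics section, the
#' connectivity checks, the basis-based checks, and the FVA-based checks.
#' Coupling lines count the number of reactions participating in at least
#' one coupled pair.  Sections disabled by the check type are replaced by
#' a one-line note.  The output is a pure function of the report object
#' (byte-identical across runs).
#'
#' @param report a [CheckReport-class].
#' @return a single character string (ends with a newline).
#' @export
#' @examples
#' cat(renderReport(checkModel(fixtureNetwork("net-b")$model)))
renderReport <- function(report) {
  stopifnot(is(report, "CheckReport"))
  st <- report@statistics
  lines <- c(
    "Statistics:",
    paste(st$nReactions, "reactions"),
    paste(st$nReversible, "reversible reactions"),
    paste(st$nExchange, "exchange reactions"),
    paste(st$nMetabolites, "metabolites"),
    "",
    "Connectivity Checks:",
    paste(length(report@scm), "Singly connected metabolites (SCM)"),
    paste(length(report@dem), "dead-end metabolites (DEM)"),
    "",
    "Basis-based checks:"
  )
  if (report@enabled[["basis"]]) {
    lines <- c(lines,
      paste(coupledReactionCount(report@crPairs), "coupled reactions (CR)"),
      paste(coupledReactionCount(report@rcrPairs),
            "reversibly coupled reactions (RCR)"))
  } else {
    lines <- c(lines, "skipped (not requested for this check type)")
  }
  lines <- c(lines, "", "FVA-based checks:")
  if (report@enabled[["fva"]]) {
    lines <- c(lines,
      paste(length(report@zfr), "zero-flux reactions (ZFR)"),
      paste(length(report@ur), "unsatisfied reversibility (UR)"))
  } else {
    lines <- c(lines, "skipped (not requested for this check type)")
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

# union-find over pair lists -> list of coupled groups (identifier vectors)
pairsToGroups <- function(pairs, ids) {
  if (nrow(pairs) == 0L) return(list())
  parent <- seq_along(ids)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (k in seq_len(nrow(pairs))) {
    ri <- find(pairs$i[k])
    rj <- find(pairs$j[k])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_along(ids), find, integer(1))
  members <- split(seq_along(ids), roots)
  members <- members[lengths(members) >= 2L]
  unname(lapply(members, function(g) ids[g]))
}

#' Serialise a check report to JSON
#'
#' Lossless machine-readable rendering: identifiers and 1-based indices
#' for every condition set, direction annotations for unsatisfied
#' reversibility, coupled pairs with ratios plus the derived coupled
#' groups, the bounds FVA ran under, and tool/version metadata.
#'
#' @param report a [CheckReport-class].
#' @param model the [NetworkModel-class] the report was computed from.
#' @param pretty passed to [jsonlite::toJSON()].
#' @return a JSON character string.
#' @export
#' @examples
#' renderJSON(checkModel(fixtureNetwork("net-b")$model),
#'            fixtureNetwork("net-b")$model)
renderJSON <- function(report, model, pretty = TRUE) {
  stopifnot(is(report, "CheckReport"), is(model, "NetworkModel"))
  if (!identical(report@reactionIds, model@reactionIds)) {
    stop("report and model disagree on reaction identifiers")
  }
  rids <- model@reactionIds
  mids <- model@metaboliteIds
  idxIds <- function(idx, ids) {
    list(indices = as.integer(idx), ids = ids[idx])
  }
  pairsOut <- function(pairs) {
    data.frame(i = as.integer(pairs$i), j = as.integer(pairs$j),
               idI = rids[pairs$i], idJ = rids[pairs$j],
               ratio = pairs$ratio)
  }
  out <- list(
    tool = list(name = "fluxcheck",
                version = as.character(utils::packageVersion("fluxcheck"))),
    checkType = report@checkType,
    enabled = as.list(report@enabled),
    statistics = report@statistics,
    scm = idxIds(report@scm, mids),
    dem = idxIds(report@dem, mids),
    orphans = idxIds(report@orphans, mids),
    basisZero = idxIds(report@basisZero, rids),
    zfr = idxIds(report@zfr, rids),
    ur = c(idxIds(report@ur, rids),
           list(direction = report@urDirection)),
    cr = list(
      nReactions = coupledReactionCount(report@crPairs),
      nPairs = nrow(report@crPairs),
      pairs = pairsOut(report@crPairs),
      groups = pairsToGroups(report@crPairs, rids)
    ),
    rcr = list(
      nReactions = coupledReactionCount(report@rcrPairs),
      nPairs = nrow(report@rcrPairs),
      pairs = pairsOut(report@rcrPairs)
    ),
    tolerances = report@tolerances
  )
  if (!is.null(report@fva)) {
    out$fva <- list(
      vMin = report@fva@vMin,
      vMax = report@fva@vMax,
      lowerBounds = report@fva@lowerUsed,
      upperBounds = report@fva@upperUsed
    )
  }
  jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = pretty)
}
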