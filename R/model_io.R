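#' Construct a NetworkModel
#'
#' Low-level constructor.  Most users will read models with
#' [readTabularModel()] or [readSBMLModel()] instead.  Bounds left `NULL`
#' are filled with the defaults: `[-1000, 1000]` for reversible reactions
#' and `[0, 1000]` for irreversible ones.
#'
#' @param S numeric m x n matrix; rows internal metabolites, columns
#'   reactions; negative entries reactants, positive products.
#' @param reversible logical vector of length n.
#' @param exchange integer vector of exchange reaction indices (1-based)
#'   or character vector of reaction identifiers.
#' @param metaboliteIds,reactionIds identifier vectors; defaults `M1..Mm` /
#'   `R1..Rn`.
#' @param lowerBounds,upperBounds optional numeric vectors of length n.
#'   Entries given here are treated as user-supplied and are not widened
#'   for exchange reactions during FVA.
#' @param metadata list of provenance information.
#' @return a validated [NetworkModel-class].
#' @export
#' @examples
#' # A -> is consumed by one reaction and produced by another
#' NetworkModel(matrix(c(1, -1), 1, 2), reversible = c(FALSE, FALSE),
#'              exchange = c(1L, 2L))
NetworkModel <- function(S, reversible, exchange = integer(0),
                         metaboliteIds = NULL, reactionIds = NULL,
                         lowerBounds = NULL, upperBounds = NULL,
                         metadata = list()) {
  S <- as.matrix(S)
  storage.mode(S) <- "double"
  m <- nrow(S)
  n <- ncol(S)
  if (is.null(metaboliteIds)) {
    metaboliteIds <- if (!is.null(rownames(S))) rownames(S) else
      paste0("M", seq_len(m))
  }
  if (is.null(reactionIds)) {
    reactionIds <- if (!is.null(colnames(S))) colnames(S) else
      paste0("R", seq_len(n))
  }
  dimnames(S) <- NULL
  if (is.character(exchange)) {
    idx <- match(exchange, reactionIds)
    if (anyNA(idx)) {
      stop("unknown exchange reaction identifier(s): ",
           paste(exchange[is.na(idx)], collapse = ", "))
    }
    exchange <- idx
  }
  exchange <- sort(unique(as.integer(exchange)))
  reversible <- as.logical(reversible)
  userBounds <- rep(!is.null(lowerBounds) || !is.null(upperBounds), n)
  defs <- defaultBoundsForReversibility(reversible)
  if (is.null(lowerBounds)) lowerBounds <- defs$lower
  if (is.null(upperBounds)) upperBounds <- defs$upper
  obj <- new("NetworkModel",
    metaboliteIds = as.character(metaboliteIds),
    reactionIds = as.character(reactionIds),
    S = S,
    reversible = reversible,
    exchange = exchange,
    lowerBounds = as.numeric(lowerBounds),
    upperBounds = as.numeric(upperBounds),
    userBounds = userBounds,
    metadata = metadata
  )
  warnOrphanRows(obj)
  obj
}

# default bounds as a function of reversibility alone
defaultBoundsForReversibility <- function(reversible) {
  list(lower = ifelse(reversible, -1000, 0),
       upper = rep(1000, length(reversible)))
}

# all-zero rows (metabolites in no reaction) are kept but flagged
warnOrphanRows <- function(model, tol = 1e-12) {
  orphans <- which(rowSums(abs(model@S) > tol) == 0L)
  if (length(orphans)) {
    warning("model has ", length(orphans),
            " orphan metabolite(s) participating in no reaction: ",
            paste(model@metaboliteIds[orphans], collapse = ", "),
            call. = FALSE)
  }
  invisible(orphans)
}

#' Default flux bounds for a model
#'
#' Returns the conventional constraint-based-modeling defaults:
#' lower bound -1000 for reversible reactions and 0 for irreversible ones,
#' upper bound 1000 for all reactions.
#'
#' @param model a [NetworkModel-class].
#' @return list with numeric components `lower` and `upper` of length n.
#' @export
#' @examples
#' defaultBounds(fixtureNetwork("net-d")$model)
defaultBounds <- function(model) {
  stopifnot(is(model, "NetworkModel"))
  defaultBoundsForReversibility(model@reversible)
}

#' Model statistics
#'
#' Pure counting over a model: number of reactions, reversible reactions,
#' exchange reactions, and internal metabolites.  These are the figures the
#' report's "Statistics:" section prints.
#'
#' @param model a [NetworkModel-class].
#' @return list with integer components `nReactions`, `nReversible`,
#'   `nExchange`, `nMetabolites`.
#' @export
#' @examples
#' modelStatistics(fixtureNetwork("net-c")$model)
modelStatistics <- function(model) {
  stopifnot(is(model, "NetworkModel"))
  list(
    nReactions = ncol(model@S),
    nReversible = sum(model@reversible),
    nExchange = length(model@exchange),
    nMetabolites = nrow(model@S)
  )
}

# ---------------------------------------------------------------------------
# tabular layout
# ---------------------------------------------------------------------------

# Read a delimited text file into a character matrix; separator by extension
# (.csv -> comma, else tab), no header handling here.
readGridFile <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  as.matrix(utils::read.table(path, sep = sep, header = FALSE,
                              colClasses = "character",
                              stringsAsFactors = FALSE,
                              strip.white = TRUE))
}

# Single-column index/identifier list: one entry per line, blanks ignored.
readColumnFile <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x)]
}

# Coerce a character grid to numeric, failing with the offending cell named.
gridToNumeric <- function(grid, what) {
  out <- suppressWarnings(array(as.numeric(grid), dim = dim(grid)))
  bad <- which(is.na(out) & !is.na(grid), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(what, ": non-numeric cell at row ", bad[1, 1],
         ", column ", bad[1, 2], " ('", grid[bad[1, 1], bad[1, 2]], "')")
  }
  if (anyNA(out)) {
    bad <- which(is.na(out), arr.ind = TRUE)
    stop(what, ": empty cell at row ", bad[1, 1], ", column ", bad[1, 2])
  }
  out
}

isNumericLike <- function(x) !is.na(suppressWarnings(as.numeric(x)))

#' Read a model in the tabular layout
#'
#' The stoichiometry grid has one row per metabolite and one column per
#' reaction, plus a trailing row of 0/1 reversibility flags (1 =
#' reversible).  Every data cell must be numeric.  An optional leading
#' identifier row and/or column is detected by non-numeric content.
#' Exchange reactions and external metabolites are given as single-column
#' lists of 1-based indices (reaction columns and metabolite rows,
#' respectively); rows listed as external are stripped from the matrix
#' before analysis.  Bounds, if supplied, are an n x 2 grid (lower, upper)
#' with one row per reaction; reactions not covered keep the defaults.
#'
#' @param stoich a file path (TSV or CSV) or a matrix/data.frame holding the
#'   grid described above.
#' @param exchange a file path or vector of 1-based reaction indices.
#' @param external optional file path or vector of 1-based metabolite row
#'   indices (numbered before stripping); `NULL` or empty for none.
#' @param bounds optional file path or n x 2 numeric matrix.
#' @return a [NetworkModel-class].
#' @export
#' @examples
#' grid <- rbind(c(1, -1), c(0, 0))   # one metabolite + reversibility row
#' readTabularModel(grid, exchange = c(1, 2))
readTabularModel <- function(stoich, exchange = integer(0), external = NULL,
                             bounds = NULL) {
  src <- if (is.character(stoich) && length(stoich) == 1L) stoich else "in-memory"
  if (is.character(stoich) && length(stoich) == 1L) {
    stoich <- readGridFile(stoich)
  }
  grid <- as.matrix(stoich)
  if (is.numeric(grid)) storage.mode(grid) <- "character"
  if (nrow(grid) < 2L) {
    stop("stoichiometry grid needs at least one metabolite row plus the ",
         "reversibility row")
  }

  metIds <- NULL
  rxnIds <- NULL
  # optional identifier row/column: recognised only when entirely
  # non-numeric, so a stray bad cell in a data row still errors below
  if (!any(isNumericLike(grid[1, -1])) && nrow(grid) > 2L) {
    rxnIds <- as.character(grid[1, ])
    grid <- grid[-1, , drop = FALSE]
  }
  if (!any(isNumericLike(grid[, 1]))) {
    metIds <- as.character(grid[-nrow(grid), 1])
    if (!is.null(rxnIds)) rxnIds <- rxnIds[-1]
    grid <- grid[, -1, drop = FALSE]
  }
  num <- gridToNumeric(grid, "stoichiometry grid")
  revRow <- num[nrow(num), ]
  if (!all(revRow %in% c(0, 1))) {
    stop("last row of the stoichiometry grid must contain only 0/1 ",
         "reversibility flags")
  }
  S <- num[-nrow(num), , drop = FALSE]
  m <- nrow(S)
  n <- ncol(S)
  if (is.null(metIds)) metIds <- paste0("M", seq_len(m))
  if (is.null(rxnIds)) rxnIds <- paste0("R", seq_len(n))

  if (is.character(exchange) && length(exchange) == 1L &&
      file.exists(exchange)) {
    exchange <- readColumnFile(exchange)
  }
  exchange <- as.numeric(exchange)
  if (length(exchange) && (any(exchange < 1) || any(exchange > n) ||
                           any(exchange != round(exchange)))) {
    stop("exchange list: indices must be integers in 1..", n)
  }

  if (!is.null(external) && is.character(external) &&
      length(external) == 1L && file.exists(external)) {
    external <- readColumnFile(external)
  }
  external <- if (is.null(external)) numeric(0) else as.numeric(external)
  if (length(external) && (any(external < 1) || any(external > m) ||
                           any(external != round(external)))) {
    stop("external-metabolite list: indices must be integers in 1..", m)
  }
  if (length(external)) {
    keep <- setdiff(seq_len(m), as.integer(external))
    S <- S[keep, , drop = FALSE]
    metIds <- metIds[keep]
  }

  boundsGiven <- !is.null(bounds) && (!is.matrix(bounds) || nrow(bounds) > 0)
  lb <- ub <- NULL
  if (boundsGiven) {
    if (is.character(bounds) && length(bounds) == 1L) {
      bounds <- readGridFile(bounds)
    }
    bounds <- as.matrix(bounds)
    if (is.character(bounds)) bounds <- gridToNumeric(bounds, "bounds grid")
    if (ncol(bounds) != 2L || nrow(bounds) != n) {
      stop("bounds grid must have one row per reaction and two columns ",
           "(lower, upper); got ", nrow(bounds), " x ", ncol(bounds),
           " for ", n, " reactions")
    }
    lb <- bounds[, 1]
    ub <- bounds[, 2]
  }

  NetworkModel(S,
    reversible = revRow == 1,
    exchange = as.integer(exchange),
    metaboliteIds = metIds,
    reactionIds = rxnIds,
    lowerBounds = lb,
    upperBounds = ub,
    metadata = list(source = src, format = "tabular")
  )
}

# ---------------------------------------------------------------------------
# SBML (Level 2/3, read-only subset: species / reactions / stoichiometry)
# ---------------------------------------------------------------------------

#' Read a model from an SBML file
#'
#' Parses the subset of SBML Level 2/3 the checks consume: species become
#' matrix rows, reactions become columns, reactant stoichiometries are
#' negative and product stoichiometries positive.  Species flagged with
#' `boundaryCondition="true"` in the file, plus any listed in
#' `externalIds`, are treated as external metabolites and stripped.
#' Reversibility comes from each reaction's `reversible` attribute
#' (missing means reversible, the SBML Level 2 default).  Duplicate species
#' references within one reaction are summed into a single coefficient.
#'
#' @param path SBML file path.
#' @param exchangeIds optional character vector of reaction identifiers to
#'   mark as exchange reactions.  When `NULL`, exchange reactions are
#'   auto-detected: a reaction is exchange iff, after stripping, its column
#'   is all-nonnegative or all-nonpositive, or it referenced a boundary or
#'   external species.
#' @param externalIds optional character vector of species identifiers to
#'   strip in addition to boundary-condition species.  Unknown identifiers
#'   are an error, not silently skipped.
#' @param bounds optional n x 2 numeric matrix (lower, upper) in reaction
#'   column order.
#' @return a [NetworkModel-class].
#' @export
readSBMLModel <- function(path, exchangeIds = NULL, externalIds = NULL,
                          bounds = NULL) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("cannot parse SBML document '", path, "': ", conditionMessage(e))
  })
  xml2::xml_ns_strip(doc)
  speciesNodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  reactionNodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (length(reactionNodes) == 0L) {
    stop("SBML document contains no reactions")
  }
  spIds <- xml2::xml_attr(speciesNodes, "id")
  boundary <- xml2::xml_attr(speciesNodes, "boundaryCondition")
  boundary <- !is.na(boundary) & tolower(boundary) == "true"

  if (!is.null(externalIds) && length(externalIds)) {
    unknown <- setdiff(externalIds, spIds)
    if (length(unknown)) {
      stop("unknown external metabolite identifier(s): ",
           paste(unknown, collapse = ", "))
    }
    boundary <- boundary | spIds %in% externalIds
  }

  rxnIds <- xml2::xml_attr(reactionNodes, "id")
  revAttr <- xml2::xml_attr(reactionNodes, "reversible")
  reversible <- is.na(revAttr) | tolower(revAttr) == "true"

  m0 <- length(spIds)
  n <- length(rxnIds)
  S0 <- matrix(0, m0, n)
  touchesBoundary <- logical(n)
  rowOf <- stats::setNames(seq_len(m0), spIds)
  for (j in seq_len(n)) {
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(reactionNodes[[j]],
                                 paste0("./", side, "/speciesReference"))
      if (!length(refs)) next
      sp <- xml2::xml_attr(refs, "species")
      st <- xml2::xml_attr(refs, "stoichiometry")
      st <- ifelse(is.na(st), 1, as.numeric(st))
      if (anyNA(st)) {
        stop("reaction '", rxnIds[j], "': non-numeric stoichiometry")
      }
      if (side == "listOfReactants") st <- -st
      rows <- rowOf[sp]
      if (anyNA(rows)) {
        stop("reaction '", rxnIds[j], "' references unknown species: ",
             paste(sp[is.na(rows)], collapse = ", "))
      }
      for (k in seq_along(rows)) {
        S0[rows[k], j] <- S0[rows[k], j] + st[k]  # duplicates summed
      }
      touchesBoundary[j] <- touchesBoundary[j] || any(boundary[rows])
    }
  }

  keep <- which(!boundary)
  if (!length(keep)) {
    stop("no internal metabolites: every species is flagged as external/",
         "boundary")
  }
  S <- S0[keep, , drop = FALSE]
  metIds <- spIds[keep]

  if (!is.null(exchangeIds)) {
    unknown <- setdiff(exchangeIds, rxnIds)
    if (length(unknown)) {
      stop("unknown exchange reaction identifier(s): ",
           paste(unknown, collapse = ", "))
    }
    exchange <- which(rxnIds %in% exchangeIds)
  } else {
    oneSided <- vapply(seq_len(n), function(j) {
      col <- S[, j]
      all(col >= 0) || all(col <= 0)
    }, logical(1))
    exchange <- which(oneSided | touchesBoundary)
  }

  lb <- ub <- NULL
  if (!is.null(bounds)) {
    bounds <- as.matrix(bounds)
    if (ncol(bounds) != 2L || nrow(bounds) != n) {
      stop("bounds must have one row per reaction and two columns")
    }
    lb <- bounds[, 1]
    ub <- bounds[, 2]
  }

  NetworkModel(S,
    reversible = reversible,
    exchange = as.integer(exchange),
    metaboliteIds = metIds,
    reactionIds = rxnIds,
    lowerBounds = lb,
    upperBounds = ub,
    metadata = list(source = if (is.character(path)) path else "connection",
                    format = "sbml")
  )
}
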