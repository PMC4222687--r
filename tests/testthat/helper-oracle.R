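# Test helpers: identifier-set comparisons, a brute-force extreme-ray
# enumerator (double description) used as an independent oracle for the
# blocked-reaction set, and a generator of tiny random networks.

metIdSet <- function(model, idx) sort(metaboliteIds(model)[idx])
rxnIdSet <- function(model, idx) sort(reactionIds(model)[idx])

# canonical "i|j" keys for pair data frames indexed by reaction id
pairKeys <- function(pairs, rids = NULL) {
  if (nrow(pairs) == 0L) return(character(0))
  if (!is.null(rids)) {
    a <- rids[pairs$i]
    b <- rids[pairs$j]
  } else {
    a <- pairs$idI
    b <- pairs$idJ
  }
  sort(paste(pmin(a, b), pmax(a, b), sep = "|"))
}

# Extreme rays of the cone {z : A z = 0, z >= 0} by double description:
# start from the nonnegative orthant's rays, intersect with one hyperplane
# at a time, keep support-minimal rays.  Rays are rows of the result.
enumerateExtremeRays <- function(A, tol = 1e-10) {
  n <- ncol(A)
  rays <- diag(n)
  for (r in seq_len(nrow(A))) {
    vals <- as.vector(rays %*% A[r, ])
    zero <- abs(vals) <= tol
    keep <- rays[zero, , drop = FALSE]
    pos <- which(!zero & vals > 0)
    neg <- which(!zero & vals < 0)
    if (length(pos) && length(neg)) {
      combos <- expand.grid(p = pos, q = neg)
      newRays <- t(apply(combos, 1L, function(pq) {
        w <- vals[pq[["p"]]] * rays[pq[["q"]], ] -
          vals[pq[["q"]]] * rays[pq[["p"]], ]
        w / max(abs(w))
      }))
      rays <- rbind(keep, newRays)
    } else {
      rays <- keep
    }
    if (nrow(rays) > 1L) {
      supports <- lapply(seq_len(nrow(rays)),
                         function(i) which(rays[i, ] > tol))
      keepIdx <- rep(TRUE, nrow(rays))
      for (i in seq_len(nrow(rays))) {
        if (!keepIdx[i]) next
        for (j in seq_len(nrow(rays))) {
          if (i == j || !keepIdx[i]) next
          si <- supports[[i]]
          sj <- supports[[j]]
          if (length(sj) < length(si) && all(sj %in% si)) {
            keepIdx[i] <- FALSE            # i is not support-minimal
          } else if (j < i && length(sj) == length(si) &&
                     all(sj %in% si)) {
            keepIdx[i] <- FALSE            # duplicate ray, keep first
          }
        }
      }
      rays <- rays[keepIdx, , drop = FALSE]
    }
    if (nrow(rays) == 0L) break
  }
  rays
}

# Oracle blocked set: split reversible columns into forward/backward parts,
# enumerate the extreme rays of the split flux cone, project each ray back
# to net fluxes (forward minus backward), and report the reactions whose
# net flux is zero in every ray.  The projection matters: the split cone
# contains futile forward+backward rays whose net flux is zero.
oracleBlockedSet <- function(model, tol = 1e-8) {
  S <- stoichiometry(model)
  rev <- isReversible(model)
  n <- ncol(S)
  A <- cbind(S, -S[, rev, drop = FALSE])
  rays <- enumerateExtremeRays(unname(A))
  if (nrow(rays) == 0L) return(seq_len(n))
  net <- rays[, seq_len(n), drop = FALSE]
  bwd <- which(rev)
  for (k in seq_along(bwd)) {
    net[, bwd[k]] <- net[, bwd[k]] - rays[, n + k]
  }
  which(apply(abs(net) <= tol, 2L, all))
}

# Tiny random network: m metabolites, n reactions, sparse signed entries,
# a sprinkle of reversible columns.  Only used at n <= 8 where the oracle
# is exhaustive.
randomTinyModel <- function(seed) {
  set.seed(seed)
  m <- sample(2:4, 1L)
  n <- sample(3:8, 1L)
  S <- matrix(0, m, n)
  for (j in seq_len(n)) {
    k <- sample(1:min(3, m), 1L)
    rows <- sample(m, k)
    S[rows, j] <- sample(c(-2, -1, 1, 2), k, replace = TRUE)
  }
  reversible <- stats::runif(n) < 0.3
  oneSided <- vapply(seq_len(n), function(j) {
    all(S[, j] >= 0) || all(S[, j] <= 0)
  }, logical(1))
  suppressWarnings(
    NetworkModel(S, reversible = reversible, exchange = which(oneSided))
  )
}

# a batch of seeded planted networks with parameters varied by seed
plantedBatch <- function(seeds) {
  lapply(seeds, function(s) {
    nCore <- 3L + (s %% 4L)
    counts <- c((s %% 2L), ((s %/% 2L) %% 2L), ((s %/% 4L) %% 2L))
    if (sum(counts) == 0L) counts[1L + (s %% 3L)] <- 1L
    randomPlanted(nCore, nDem = counts[1], nZfr = counts[2],
                  nUr = counts[3], seed = s)
  })
}

# random orthogonal p x p matrix (QR of a Gaussian matrix)
randomOrthogonal <- function(p, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(stats::rnorm(p * p), p, p)))
}
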