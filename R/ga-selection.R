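# Genetic-algorithm selection of the LR subset whose CCI scores best
# correlate (in absolute Spearman value) with intercellular distances.

# Precompute everything the objective needs so that whole populations can be
# scored with two matrix products per generation. For the strict upper
# triangle of the T x T matrices (autocrine diagonal excluded):
#   E[p, k]   = activity of pair p for the k-th unordered type pair
#               (both directed halves)
#   mol[p, t] = ligand + receptor entries pair p contributes to type t
.objectivePrecompute <- function(presence, db, dist,
                                 method = "bray_curtis", expr = NULL) {
  if (method == "icellnet") {
    if (is.null(expr)) stop("icellnet objective requires the TPM matrix 'expr'")
    pm <- .productMatrices(validateExpression(expr), db)
  } else {
    stopifnot(is(presence, "PresenceMatrix"))
    pm <- .pairMatrices(presence, db, warn = FALSE)
  }
  types <- pm$types
  if (is.null(rownames(dist))) stop("distance matrix must have cell-type dimnames")
  miss <- setdiff(types, rownames(dist))
  if (length(miss)) {
    stop("cell type(s) missing from distance matrix: ",
         paste(miss, collapse = ", "))
  }
  dist <- dist[types, types]
  ut <- which(upper.tri(dist), arr.ind = TRUE)
  Ai <- ut[, 1L]
  Bi <- ut[, 2L]
  E <- pm$L[, Ai, drop = FALSE] * pm$R[, Bi, drop = FALSE] +
    pm$L[, Bi, drop = FALSE] * pm$R[, Ai, drop = FALSE]
  list(
    method = method, types = types, Ai = Ai, Bi = Bi,
    E = E, mol = pm$L + pm$R,
    distRank = rank(dist[upper.tri(dist)])
  )
}

# Score K masks at once. W is a K x P numeric 0/1 matrix; returns signed
# Spearman rho per mask (0 for constant CCI vectors or empty masks).
.evalMasks <- function(W, pre) {
  C <- W %*% pre$E
  if (pre$method == "bray_curtis") {
    S <- W %*% pre$mol
    den <- S[, pre$Ai, drop = FALSE] + S[, pre$Bi, drop = FALSE]
    val <- 2 * C / den
    val[den == 0] <- 0
  } else {
    val <- C
  }
  Rk <- t(apply(val, 1L, rank))
  Rc <- Rk - rowMeans(Rk)
  dc <- pre$distRank - mean(pre$distRank)
  num <- as.vector(Rc %*% dc)
  den2 <- sqrt(rowSums(Rc^2) * sum(dc^2))
  rho <- ifelse(den2 == 0, 0, num / den2)
  rho
}

#' Spearman objective of an LR subset against intercellular distances
#'
#' Computes the CCI matrix restricted to the masked LR pairs, then the
#' Spearman rank correlation between the vectorized strict upper triangles
#' of the CCI matrix and the distance matrix (the autocrine diagonal is
#' excluded). The objective is the absolute correlation; the signed value
#' is returned alongside (a negative rho means the selected pairs are
#' preferentially used by proximal cells). A constant CCI vector (or an
#' empty mask, with a warning) yields objective 0.
#'
#' @param mask logical vector of length \code{length(db)} selecting LR
#'   pairs.
#' @param presence a [PresenceMatrix-class].
#' @param db an [LRDatabase-class].
#' @param dist symmetric cell-type distance matrix covering the presence
#'   cell types (see [distanceMatrix()]).
#' @param method CCI method (\code{"bray_curtis"}, \code{"lr_count"} or
#'   \code{"icellnet"}).
#' @param expr TPM matrix (required for \code{"icellnet"}).
#' @return list with \code{objective} (= |rho|) and \code{rho} (signed).
#' @export
gaObjective <- function(mask, presence, db, dist, method = "bray_curtis",
                        expr = NULL) {
  if (length(mask) != length(db)) {
    stop("mask length must equal the number of LR pairs")
  }
  if (!any(mask)) {
    warning("empty LR mask: objective set to 0", call. = FALSE)
    return(list(objective = 0, rho = 0))
  }
  pre <- .objectivePrecompute(presence, db, dist, method = method, expr = expr)
  rho <- .evalMasks(matrix(as.numeric(mask), nrow = 1L), pre)
  list(objective = abs(rho), rho = rho)
}

# Fitness ranking with parsimony tie-break: higher objective wins; exact
# ties go to the mask selecting fewer pairs.
.fitnessRank <- function(obj, size) {
  rnk <- integer(length(obj))
  rnk[order(-obj, size)] <- seq_along(obj)
  rnk
}

#' One genetic-algorithm run
#'
#' Evolves a population of length-P bit masks over the LR database,
#' maximizing the absolute Spearman correlation of [gaObjective()].
#' Operators: tournament selection (size 3), uniform crossover, per-bit
#' flip mutation, 1-elite preservation. Objective ties are broken toward
#' fewer selected pairs. With a fixed \code{seed} the run is fully
#' reproducible.
#'
#' @inheritParams gaObjective
#' @param popSize population size (default 100).
#' @param generations number of generations (default 200).
#' @param pCrossover per-couple crossover probability (default 0.7).
#' @param pMutation per-bit mutation probability (default \code{1/P}).
#' @param tournamentSize tournament size (default 3).
#' @param pInit initial per-pair inclusion probability (default 0.5).
#' @param seed RNG seed for this run.
#' @return object of class \code{gaRun}: list with \code{mask} (named
#'   logical), \code{objective}, \code{rho}, \code{trace} (best-ever
#'   objective per generation, non-decreasing), \code{seed} and
#'   \code{config}.
#' @export
runGA <- function(presence, db, dist, method = "bray_curtis", expr = NULL,
                  popSize = 100, generations = 200, pCrossover = 0.7,
                  pMutation = NULL, tournamentSize = 3, pInit = 0.5,
                  seed = NULL) {
  P <- length(db)
  if (P < 1L) stop("LR database is empty")
  if (popSize < 2L) stop("population size must be at least 2")
  if (is.null(pMutation)) pMutation <- 1 / P
  stopifnot(pCrossover >= 0, pCrossover <= 1, pMutation >= 0, pMutation <= 1,
            pInit >= 0, pInit <= 1)
  if (!is.null(seed)) set.seed(seed)
  pre <- .objectivePrecompute(presence, db, dist, method = method, expr = expr)

  repairEmpty <- function(W) {
    empty <- rowSums(W) == 0
    if (any(empty)) {
      W[cbind(which(empty), sample.int(P, sum(empty), replace = TRUE))] <- 1
    }
    W
  }
  W <- matrix(as.numeric(stats::runif(popSize * P) < pInit), popSize, P)
  W <- repairEmpty(W)
  rho <- .evalMasks(W, pre)
  obj <- abs(rho)
  size <- rowSums(W)

  bestIdx <- .fitnessRank(obj, size) == 1L
  best <- list(mask = W[which(bestIdx)[1L], ], objective = obj[bestIdx][1L],
               rho = rho[bestIdx][1L])
  trace <- numeric(generations + 1L)
  trace[1L] <- best$objective

  for (g in seq_len(generations)) {
    rnk <- .fitnessRank(obj, size)
    # tournament selection of popSize parents
    cand <- matrix(sample.int(popSize, popSize * tournamentSize, replace = TRUE),
                   nrow = tournamentSize)
    winners <- cand[cbind(apply(matrix(rnk[cand], nrow = tournamentSize), 2L,
                                which.min), seq_len(popSize))]
    off <- W[winners, , drop = FALSE]
    # uniform crossover on consecutive couples
    for (i in seq(1L, popSize - 1L, by = 2L)) {
      if (stats::runif(1) < pCrossover) {
        swap <- stats::runif(P) < 0.5
        tmp <- off[i, swap]
        off[i, swap] <- off[i + 1L, swap]
        off[i + 1L, swap] <- tmp
      }
    }
    # per-bit flip mutation
    flips <- matrix(stats::runif(popSize * P) < pMutation, popSize, P)
    off[flips] <- 1 - off[flips]
    # elitism: best-ever individual survives unchanged
    off[1L, ] <- best$mask
    W <- repairEmpty(off)
    rho <- .evalMasks(W, pre)
    obj <- abs(rho)
    size <- rowSums(W)
    topIdx <- which(.fitnessRank(obj, size) == 1L)[1L]
    if (obj[topIdx] > best$objective ||
        (obj[topIdx] == best$objective && size[topIdx] < sum(best$mask))) {
      best <- list(mask = W[topIdx, ], objective = obj[topIdx],
                   rho = rho[topIdx])
    }
    trace[g + 1L] <- best$objective
  }

  mask <- as.logical(best$mask)
  names(mask) <- pairLabels(db)
  structure(
    list(
      mask = mask, objective = best$objective, rho = best$rho,
      trace = trace, seed = seed,
      config = list(
        method = method, popSize = popSize, generations = generations,
        pCrossover = pCrossover, pMutation = pMutation,
        tournamentSize = tournamentSize, pInit = pInit
      )
    ),
    class = "gaRun"
  )
}

#' @export
print.gaRun <- function(x, ...) {
  cat(sprintf(
    "gaRun: |rho| = %.4f (rho = %.4f), %d/%d LR pairs selected, %d generation(s)\n",
    x$objective, x$rho, sum(x$mask), length(x$mask), length(x$trace) - 1L
  ))
  invisible(x)
}

#' Multiple independent GA runs
#'
#' Runs [runGA()] \code{nRuns} times with seeds \code{seed + 0:(nRuns-1)},
#' mirroring the repeated-maximization design (100 independent runs by
#' default).
#'
#' @inheritParams runGA
#' @param nRuns number of independent runs (default 100).
#' @param seed base seed; run i uses \code{seed + i - 1}.
#' @return list of \code{gaRun} objects.
#' @export
runGAEnsemble <- function(presence, db, dist, nRuns = 100, seed = 1,
                          method = "bray_curtis", expr = NULL, ...) {
  lapply(seq_len(nRuns), function(i) {
    runGA(presence, db, dist, method = method, expr = expr,
          seed = seed + i - 1L, ...)
  })
}

#' Consensus LR subset across GA runs
#'
#' The selection frequency of each LR pair is its fraction of runs whose
#' best mask includes it; the consensus mask keeps pairs with frequency at
#' or above the threshold ("presence in most of the runs"). The consensus
#' correlation is recomputed from the consensus mask alone.
#'
#' @param runs list of \code{gaRun} objects.
#' @param presence,db,dist,method,expr as in [gaObjective()].
#' @param threshold minimum selection frequency (default 0.5).
#' @return object of class \code{gaConsensus}: list with \code{frequency}
#'   (named numeric), \code{mask}, \code{threshold}, \code{objective},
#'   \code{rho}, \code{nRuns}.
#' @export
gaConsensus <- function(runs, presence, db, dist, threshold = 0.5,
                        method = "bray_curtis", expr = NULL) {
  if (!length(runs)) stop("need at least one GA run")
  M <- do.call(rbind, lapply(runs, function(r) r$mask))
  freq <- colMeans(M)
  mask <- freq >= threshold
  if (!any(mask)) {
    warning("no LR pair reaches the consensus threshold", call. = FALSE)
    res <- list(objective = 0, rho = 0)
  } else {
    res <- gaObjective(mask, presence, db, dist, method = method, expr = expr)
  }
  structure(
    list(
      frequency = freq, mask = mask, threshold = threshold,
      objective = res$objective, rho = res$rho, nRuns = length(runs)
    ),
    class = "gaConsensus"
  )
}

#' @export
print.gaConsensus <- function(x, ...) {
  cat(sprintf(
    "gaConsensus over %d run(s): %d/%d pairs at frequency >= %.2f; |rho| = %.4f (rho = %.4f)\n",
    x$nRuns, sum(x$mask), length(x$mask), x$threshold, x$objective, x$rho
  ))
  invisible(x)
}

# Objective for an arbitrary (possibly duplicated) ligand/receptor gene
# pairing, used by the permutation null models.
.objectiveFromGenes <- function(lig, rec, presence, dist,
                                method = "bray_curtis", expr = NULL) {
  if (method == "icellnet") {
    L <- log2(.tpmRows(expr, lig) + 1)
    R <- log2(.tpmRows(expr, rec) + 1)
    types <- colnames(expr)
  } else {
    L <- .presenceRows(presence, lig, warn = FALSE) * 1
    R <- .presenceRows(presence, rec, warn = FALSE) * 1
    types <- colnames(presence@presence)
  }
  dist <- dist[types, types]
  m <- switch(method,
    bray_curtis = .brayCurtisMatrix(L, R),
    lr_count = .lrCountMatrix(L, R),
    icellnet = .icellnetMatrix(L, R),
    stop("unsupported method: ", method)
  )
  v <- m[upper.tri(m)]
  d <- dist[upper.tri(dist)]
  if (length(unique(v)) < 2L) return(0)
  abs(stats::cor(v, d, method = "spearman"))
}

#' Permutation significance of a selected LR subset
#'
#' Builds a null distribution of the absolute Spearman objective under one
#' of three scenarios applied to the selected list: \code{"repair_columns"}
#' shuffles the receptor column against the ligand column;
#' \code{"relabel"} independently permutes the ligand identities and the
#' receptor identities; \code{"subsample"} draws random same-size subsets
#' from the full database. The p-value uses add-one smoothing:
#' \code{p = (1 + #(null >= observed)) / (1 + nPerm)}.
#'
#' @param mask logical consensus mask over \code{db}.
#' @param presence,db,dist,method,expr as in [gaObjective()].
#' @param scenario one of \code{"repair_columns"}, \code{"relabel"},
#'   \code{"subsample"}.
#' @param nPerm number of permutations (default 9999).
#' @param seed optional RNG seed.
#' @return list with \code{p}, \code{observed}, \code{null} (numeric vector
#'   of length \code{nPerm}), \code{scenario}, \code{nPerm}.
#' @export
permutationSignificance <- function(mask, presence, db, dist,
                                    scenario = c("repair_columns", "relabel",
                                                 "subsample"),
                                    nPerm = 9999, seed = NULL,
                                    method = "bray_curtis", expr = NULL) {
  scenario <- match.arg(scenario)
  if (nPerm <= 0) stop("nPerm must be positive")
  if (!is.null(seed)) set.seed(seed)
  observed <- gaObjective(mask, presence, db, dist,
                          method = method, expr = expr)$objective
  lig <- db@pairs$ligand[mask]
  rec <- db@pairs$receptor[mask]
  k <- sum(mask)
  P <- length(db)
  null <- vapply(seq_len(nPerm), function(i) {
    switch(scenario,
      repair_columns = .objectiveFromGenes(
        lig, sample(rec), presence, dist, method = method, expr = expr
      ),
      relabel = {
        uL <- unique(lig); uR <- unique(rec)
        mapL <- stats::setNames(sample(uL), uL)
        mapR <- stats::setNames(sample(uR), uR)
        .objectiveFromGenes(
          unname(mapL[lig]), unname(mapR[rec]), presence, dist,
          method = method, expr = expr
        )
      },
      subsample = {
        sub <- logical(P)
        sub[sample.int(P, k)] <- TRUE
        suppressWarnings(
          gaObjective(sub, presence, db, dist,
                      method = method, expr = expr)$objective
        )
      }
    )
  }, numeric(1))
  p <- (1 + sum(null >= observed)) / (1 + nPerm)
  list(p = p, observed = observed, null = null,
       scenario = scenario, nPerm = nPerm)
}
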