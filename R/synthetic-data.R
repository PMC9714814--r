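# Synthetic study generator: a virtual elongated animal with cell types
# laid out along an anteroposterior (AP) axis, an LR database with a
# planted spatially informative subset, and a TPM expression matrix in
# which planted LR pairs are complementary with probability exp(-d/lambda)
# (decaying with the true cell-type distance d) while background pairs
# activate at a distance-independent rate q.

#' Configuration for the synthetic spatial-code generator
#'
#' @param nTypes number of cell types (default 20).
#' @param nucleiPerType nuclei sampled per type (default 5).
#' @param nPairs number of LR pairs in the database (default 200).
#' @param plantedSize size of the planted spatially informative subset
#'   (default 30).
#' @param lambda decay length of proximity-dependent complementarity, in
#'   atlas length units (default 30).
#' @param q background activation probability per direction for
#'   non-planted pairs (default 0.15).
#' @param threshold TPM presence threshold the generated data are designed
#'   around (default 10).
#' @param typeSpacing AP-axis spacing between consecutive cell-type
#'   centroids (default 60; with the default \code{lambda} of 30 this
#'   places adjacent types two decay lengths apart, the regime in which
#'   planted-pair complementarity is most strongly distance-graded).
#' @param jitterSD isotropic 3D jitter SD around each centroid (default 2).
#' @param expressedMeanlog,expressedSdlog log-normal parameters for
#'   expressed TPM values (median 100, well above the threshold).
#' @param silentMax upper bound of the uniform silent-TPM distribution
#'   (default 5, safely below the threshold).
#' @param annotationBias probability that a planted pair carries the
#'   spatially associated annotation label (default 0.9).
#' @param locationBias probability that a planted pair is membrane-bound
#'   (default 0.7); background pairs draw location types uniformly.
#' @param seed RNG seed for the whole generation.
#' @return list of class \code{syntheticConfig}.
#' @export
syntheticConfig <- function(nTypes = 20, nucleiPerType = 5, nPairs = 200,
                            plantedSize = 30, lambda = 30, q = 0.15,
                            threshold = 10, typeSpacing = 60, jitterSD = 2,
                            expressedMeanlog = log(100), expressedSdlog = 0.5,
                            silentMax = 5, annotationBias = 0.9,
                            locationBias = 0.7, seed = 1) {
  stopifnot(plantedSize > 0, plantedSize <= nPairs, q >= 0, q <= 1,
            lambda > 0, nTypes >= 3, nucleiPerType >= 1)
  structure(
    list(
      nTypes = nTypes, nucleiPerType = nucleiPerType, nPairs = nPairs,
      plantedSize = plantedSize, lambda = lambda, q = q,
      threshold = threshold, typeSpacing = typeSpacing, jitterSD = jitterSD,
      expressedMeanlog = expressedMeanlog, expressedSdlog = expressedSdlog,
      silentMax = silentMax, annotationBias = annotationBias,
      locationBias = locationBias, seed = seed
    ),
    class = "syntheticConfig"
  )
}

.syntheticTypeNames <- function(nTypes) {
  nm <- sprintf("T%02d", seq_len(nTypes))
  nm[ceiling(nTypes / 2)] <- "intestine"
  nm
}

#' Generate a synthetic 3D nucleus atlas
#'
#' Cell-type centroids are placed along a virtual AP axis (x) at regular
#' spacing with isotropic 3D jitter per nucleus. The middle type is an
#' "intestine"-like type whose nuclei span the central third of the body,
#' so body-section assignment has a well-defined mid-body.
#'
#' @param config a [syntheticConfig()].
#' @return list with \code{atlas} (a [CellAtlas-class]) and
#'   \code{distances} (the true minimum inter-nucleus distance matrix).
#' @export
makeAtlas <- function(config) {
  set.seed(config$seed)
  n <- config$nTypes
  k <- config$nucleiPerType
  types <- .syntheticTypeNames(n)
  centroids <- (seq_len(n) - 1L) * config$typeSpacing
  span <- centroids[n]
  rows <- list()
  for (i in seq_len(n)) {
    if (types[i] == "intestine") {
      x <- stats::runif(k, span / 3, 2 * span / 3)
    } else {
      x <- centroids[i] + stats::rnorm(k, sd = config$jitterSD)
    }
    rows[[i]] <- data.frame(
      nucleus_id = sprintf("%s_n%02d", types[i], seq_len(k)),
      x = x,
      y = stats::rnorm(k, sd = config$jitterSD),
      z = stats::rnorm(k, sd = config$jitterSD),
      cell_type = types[i],
      stringsAsFactors = FALSE
    )
  }
  atlas <- CellAtlas(do.call(rbind, rows))
  list(atlas = atlas, distances = distanceMatrix(atlas, types = types))
}

#' Generate a synthetic LR database with a planted subset
#'
#' Gene names are \code{L001...}/\code{R001...}. Functional annotations are
#' drawn from a small label set with a planted-vs-background bias (planted
#' pairs preferentially carry the "cell positioning" label, giving the
#' abundance-shift statistics a signal); location types are biased toward
#' membrane-bound for planted pairs.
#'
#' @param config a [syntheticConfig()].
#' @return list with \code{db} (an [LRDatabase-class]) and
#'   \code{plantedMask} (logical of length \code{nPairs}).
#' @export
makeLRTable <- function(config) {
  set.seed(config$seed + 1L)
  P <- config$nPairs
  planted <- logical(P)
  planted[sample.int(P, config$plantedSize)] <- TRUE
  labels <- c("cell positioning", "Wnt signaling", "Notch signaling",
              "FGF signaling", "cell adhesion", "TGF-beta signaling")
  ann <- character(P)
  for (p in seq_len(P)) {
    if (planted[p] && stats::runif(1) < config$annotationBias) {
      ann[p] <- labels[1L]
    } else {
      ann[p] <- sample(labels[-1L], 1L)
    }
  }
  loc <- character(P)
  for (p in seq_len(P)) {
    if (planted[p] && stats::runif(1) < config$locationBias) {
      loc[p] <- "membrane-bound"
    } else {
      loc[p] <- sample(.LOCATION_TYPES, 1L)
    }
  }
  db <- LRDatabase(
    ligand = sprintf("L%03d", seq_len(P)),
    receptor = sprintf("R%03d", seq_len(P)),
    functionAnnotation = ann,
    location = loc
  )
  list(db = db, plantedMask = planted)
}

#' Generate a synthetic TPM expression matrix with a planted spatial code
#'
#' For each planted LR pair p and each unordered cell-type pair (i, j),
#' with probability \code{exp(-d_ij / lambda)} the ligand of p is made
#' expressed in i and the receptor of p in j (and symmetrically with an
#' independent draw), so planted-pair complementarity decays with the true
#' cell-type distance. Non-planted pairs activate with the
#' distance-independent probability \code{q}. Expressed TPM values are
#' log-normal (median far above the threshold); all remaining values are
#' uniform below the threshold, so the >threshold binarization is
#' unambiguous.
#'
#' @param config a [syntheticConfig()].
#' @param atlasResult output of [makeAtlas()].
#' @param lrResult output of [makeLRTable()].
#' @return list with \code{expression} (genes x cell-types TPM matrix) and
#'   \code{truth} (list: plantedMask, distances, the per-pair activation
#'   probability matrix used).
#' @export
makeExpression <- function(config, atlasResult, lrResult) {
  set.seed(config$seed + 2L)
  d <- atlasResult$distances
  types <- rownames(d)
  Tn <- length(types)
  P <- config$nPairs
  planted <- lrResult$plantedMask
  probNear <- exp(-d / config$lambda)
  L <- matrix(FALSE, P, Tn, dimnames = list(NULL, types))
  R <- matrix(FALSE, P, Tn, dimnames = list(NULL, types))
  for (p in seq_len(P)) {
    for (i in seq_len(Tn - 1L)) {
      for (j in seq((i + 1L), Tn)) {
        pr <- if (planted[p]) probNear[i, j] else config$q
        if (stats::runif(1) < pr) { L[p, i] <- TRUE; R[p, j] <- TRUE }
        if (stats::runif(1) < pr) { L[p, j] <- TRUE; R[p, i] <- TRUE }
      }
    }
  }
  genes <- c(lrPairs(lrResult$db)$ligand, lrPairs(lrResult$db)$receptor)
  expressed <- rbind(L, R)
  tpm <- matrix(stats::runif(length(genes) * Tn, 0, config$silentMax),
                nrow = length(genes),
                dimnames = list(genes, types))
  nOn <- sum(expressed)
  tpm[expressed] <- stats::rlnorm(nOn, meanlog = config$expressedMeanlog,
                                  sdlog = config$expressedSdlog)
  list(
    expression = validateExpression(tpm),
    truth = list(
      plantedMask = planted,
      distances = d,
      activationProb = probNear
    )
  )
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper chaining [makeAtlas()], [makeLRTable()] and
#' [makeExpression()] under one seed.
#'
#' @param config a [syntheticConfig()] (default: all defaults).
#' @return list with \code{expression}, \code{db}, \code{atlas},
#'   \code{distances}, \code{truth} and \code{config}.
#' @export
simulateSpatialCode <- function(config = syntheticConfig()) {
  at <- makeAtlas(config)
  lr <- makeLRTable(config)
  ex <- makeExpression(config, at, lr)
  list(
    expression = ex$expression, db = lr$db, atlas = at$atlas,
    distances = at$distances, truth = ex$truth, config = config
  )
}
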