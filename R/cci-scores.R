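#' Paired interaction vectors for two cell types
#'
#' Builds the two aligned length-2P binary vectors underlying the modified
#' Bray-Curtis CCI score. For cell types A and B, position k < P of vec_A
#' holds "ligand of pair k present in A" and position P+k holds "receptor of
#' pair k present in A"; vec_B holds the cognate molecules in the same
#' positions (receptors first, then ligands), so position k pairs
#' ligand_k(A) with receptor_k(B) and position P+k pairs receptor_k(A) with
#' ligand_k(B). Both directed halves are present, which makes the aggregate
#' score undirected.
#'
#' @param presence a [PresenceMatrix-class].
#' @param db an [LRDatabase-class].
#' @param A,B cell-type labels.
#' @return list with integer (0/1) vectors \code{vecA} and \code{vecB},
#'   each of length \code{2 * length(db)}.
#' @export
interactionVectors <- function(presence, db, A, B) {
  stopifnot(is(presence, "PresenceMatrix"), is(db, "LRDatabase"))
  types <- colnames(presence@presence)
  if (!A %in% types) stop("unknown cell type: ", A)
  if (!B %in% types) stop("unknown cell type: ", B)
  L <- .presenceRows(presence, db@pairs$ligand, warn = FALSE)
  R <- .presenceRows(presence, db@pairs$receptor, warn = FALSE)
  list(
    vecA = as.integer(c(L[, A], R[, A])),
    vecB = as.integer(c(R[, B], L[, B]))
  )
}

#' Modified Bray-Curtis CCI score of two aligned interaction vectors
#'
#' \code{2 * sum(pmin(vecA, vecB)) / (sum(vecA) + sum(vecB))}: twice the
#' number of matched active entries (active LR pairs, counting both directed
#' halves) over the total number of ligand and receptor entries each cell
#' expresses independently. Ranges over [0, 1]; a pair of cells interacting
#' through all their ligands and receptors scores 1, one using none of them
#' scores 0 (including the degenerate case of no expressed molecules at
#' all). Symmetric in (A, B) by construction.
#'
#' @param vecA,vecB aligned binary vectors of equal length (typically from
#'   [interactionVectors()]).
#' @return score in [0, 1].
#' @examples
#' brayCurtisScore(c(1, 1, 0, 0), c(1, 0, 0, 0)) # 2*1 / (2+1)
#' @export
brayCurtisScore <- function(vecA, vecB) {
  if (length(vecA) != length(vecB)) {
    stop("interaction vectors must have equal length")
  }
  denom <- sum(vecA) + sum(vecB)
  if (denom == 0) return(0)
  2 * sum(pmin(vecA, vecB)) / denom
}

#' LR-count CCI score
#'
#' Number of active LR pairs between two cell types in an undirected
#' manner. In \code{"sum"} mode (default, following the two-directed-halves
#' vector construction) both directions are added; in \code{"union"} mode an
#' LR pair active in both directions counts once. Autocrine pairs (A == B)
#' are counted once since the two directions coincide.
#'
#' @param tensor a binary [CommunicationTensor-class].
#' @param A,B cell-type labels.
#' @param countMode \code{"sum"} or \code{"union"}.
#' @return non-negative integer count.
#' @export
lrCountScore <- function(tensor, A, B, countMode = c("sum", "union")) {
  countMode <- match.arg(countMode)
  stopifnot(is(tensor, "CommunicationTensor"))
  if (tensor@mode != "binary") stop("lrCountScore requires a binary tensor")
  ab <- tensor@scores[, A, B]
  ba <- tensor@scores[, B, A]
  if (identical(A, B)) return(sum(ab))
  if (countMode == "sum") sum(ab) + sum(ba) else sum(ab | ba)
}

#' ICELLNET-style CCI score
#'
#' Sum over LR pairs of the log2(TPM+1) expression products, totalled over
#' both directions of interaction to make the score undirected.
#'
#' @param tensor a product-mode [CommunicationTensor-class].
#' @param A,B cell-type labels.
#' @return non-negative real score.
#' @export
icellnetScore <- function(tensor, A, B) {
  stopifnot(is(tensor, "CommunicationTensor"))
  if (tensor@mode != "product") stop("icellnetScore requires a product tensor")
  sum(tensor@scores[, A, B]) + sum(tensor@scores[, B, A])
}

#' Smillie-style permutation CCI score
#'
#' -log10 of the probability that a label-shuffled null reproduces at least
#' the observed interaction strength (the number of active LR pairs between
#' A and B, both directions). Cell-type labels are shuffled only within bins
#' of similar total expressed ligand+receptor entry count (bin width
#' \code{binSize}), preserving the number of expressed molecules per bin.
#' The p-value uses add-one smoothing:
#' \code{p = (1 + #(null >= observed)) / (1 + nPerm)}.
#'
#' @param presence a [PresenceMatrix-class].
#' @param db an [LRDatabase-class].
#' @param A,B cell-type labels.
#' @param nPerm number of label shuffles (default 10000).
#' @param binSize bin width on the expressed-entry totals (default 10).
#' @param seed optional RNG seed for reproducible shuffles.
#' @return \code{-log10(p)}; 0 when every shuffle reaches the observed
#'   strength.
#' @export
smillieScore <- function(presence, db, A, B, nPerm = 10000, binSize = 10,
                         seed = NULL) {
  pm <- .pairMatrices(presence, db, warn = FALSE)
  m <- .smillieMatrix(pm$L, pm$R, nPerm = nPerm, binSize = binSize, seed = seed)
  m[A, B]
}

#' Overall CCI score matrix for all cell-type pairs
#'
#' Computes the symmetric T x T matrix of undirected CCI scores with the
#' requested aggregation method. The diagonal (autocrine scores) is computed
#' but flagged in the metadata; downstream correlation and enrichment
#' exclude it.
#'
#' @param method one of \code{"bray_curtis"}, \code{"lr_count"},
#'   \code{"icellnet"}, \code{"smillie"}.
#' @param presence a [PresenceMatrix-class] (binary methods).
#' @param db an [LRDatabase-class].
#' @param expr genes x cell-types TPM matrix (required for
#'   \code{"icellnet"}).
#' @param countMode LR-count mode, see [lrCountScore()].
#' @param nPerm,binSize,seed Smillie parameters, see [smillieScore()].
#' @return a [CCIMatrix-class].
#' @examples
#' db <- LRDatabase("L1", "R1")
#' m <- matrix(c(100, 0, 0, 100), 2, 2,
#'             dimnames = list(c("L1", "R1"), c("A", "B")))
#' scores(cciMatrix("bray_curtis", binarizeExpression(m), db))
#' @export
cciMatrix <- function(method = c("bray_curtis", "lr_count", "icellnet", "smillie"),
                      presence = NULL, db = NULL, expr = NULL,
                      countMode = c("sum", "union"),
                      nPerm = 10000, binSize = 10, seed = NULL) {
  method <- match.arg(method)
  countMode <- match.arg(countMode)
  stopifnot(is(db, "LRDatabase"))
  meta <- list(autocrineDiagonal = TRUE)
  if (method == "icellnet") {
    if (is.null(expr)) stop("icellnet scoring requires the TPM matrix 'expr'")
    pm <- .productMatrices(validateExpression(expr), db)
    m <- .icellnetMatrix(pm$L, pm$R)
  } else {
    stopifnot(is(presence, "PresenceMatrix"))
    pm <- .pairMatrices(presence, db, warn = FALSE)
    m <- switch(method,
      bray_curtis = .brayCurtisMatrix(pm$L, pm$R),
      lr_count = {
        if (countMode == "union") {
          cr <- crossprod(pm$L, pm$R)
          u <- matrix(0, ncol(pm$L), ncol(pm$L), dimnames = dimnames(cr))
          Lb <- pm$L > 0; Rb <- pm$R > 0
          for (a in seq_len(ncol(u))) for (b in seq_len(ncol(u))) {
            u[a, b] <- sum((Lb[, a] & Rb[, b]) | (Lb[, b] & Rb[, a]))
          }
          u
        } else {
          .lrCountMatrix(pm$L, pm$R)
        }
      },
      smillie = {
        meta <- c(meta, list(nPerm = nPerm, binSize = binSize, seed = seed))
        .smillieMatrix(pm$L, pm$R, nPerm = nPerm, binSize = binSize, seed = seed)
      }
    )
  }
  new("CCIMatrix", scores = m, method = method, metadata = meta)
}

#' Complement dissimilarity of a CCI matrix
#'
#' \code{1 - score} off the diagonal, 0 on the diagonal (autocrine
#' interactions are disregarded). Scores must lie in [0, 1] (native for
#' Bray-Curtis); other methods must be min-max rescaled first with
#' \code{rescale = TRUE}. The result is suitable as input to average-linkage
#' agglomerative clustering, see [clusterCellTypes()].
#'
#' @param cci a [CCIMatrix-class].
#' @param rescale min-max rescale scores to [0, 1] first (off-diagonal
#'   entries define the range).
#' @return symmetric numeric matrix of 1 - score with zero diagonal.
#' @export
cciDissimilarity <- function(cci, rescale = FALSE) {
  stopifnot(is(cci, "CCIMatrix"))
  m <- cci@scores
  if (rescale) {
    off <- m[row(m) != col(m)]
    rng <- range(off)
    m <- if (diff(rng) == 0) (m * 0) else (m - rng[1L]) / diff(rng)
  }
  if (any(m < -1e-9) || any(m > 1 + 1e-9)) {
    stop("scores outside [0, 1]; use rescale = TRUE for non-Bray-Curtis methods")
  }
  d <- 1 - pmin(pmax(m, 0), 1)
  diag(d) <- 0
  d
}

#' Hierarchical clustering of cell types on CCI dissimilarity
#'
#' Average-linkage (configurable) agglomerative clustering on the
#' complement (1 - score) dissimilarity.
#'
#' @param cci a [CCIMatrix-class].
#' @param linkage linkage method passed to [stats::hclust()] (default
#'   \code{"average"}).
#' @param rescale see [cciDissimilarity()].
#' @return an object of class \code{hclust}.
#' @export
clusterCellTypes <- function(cci, linkage = "average", rescale = FALSE) {
  d <- cciDissimilarity(cci, rescale = rescale)
  stats::hclust(stats::as.dist(d), method = linkage)
}
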