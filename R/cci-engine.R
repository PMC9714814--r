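# Internal matrix engine for CCI scores.
#
# All overall scores reduce to operations on two P x T matrices:
#   L[p, t] = ligand of pair p present (or log2(TPM+1)) in type t
#   R[p, t] = receptor of pair p present (or log2(TPM+1)) in type t
# With cross = t(L) %*% R (entry [A, B] = sum over pairs of
# ligand_A * receptor_B):
#   matches(A, B)  = cross[A, B] + cross[B, A]      (both directed halves)
#   molecules(t)   = colSums(L) + colSums(R)        (Fig-1 vector totals)
#   Bray-Curtis    = 2 * matches / (molecules(A) + molecules(B)), 0/0 -> 0
#   LR count       = matches, with the diagonal counted once
#   ICELLNET       = matches on product-mode L, R

.pairMatrices <- function(presence, db, warn = TRUE) {
  L <- .presenceRows(presence, db@pairs$ligand, warn = warn) * 1
  R <- .presenceRows(presence, db@pairs$receptor, warn = FALSE) * 1
  list(L = L, R = R, types = colnames(presence@presence))
}

.productMatrices <- function(expr, db) {
  list(
    L = log2(.tpmRows(expr, db@pairs$ligand) + 1),
    R = log2(.tpmRows(expr, db@pairs$receptor) + 1),
    types = colnames(expr)
  )
}

.brayCurtisMatrix <- function(L, R) {
  cross <- crossprod(L, R)
  C <- cross + t(cross)
  mol <- colSums(L) + colSums(R)
  den <- outer(mol, mol, "+")
  out <- 2 * C / den
  out[den == 0] <- 0
  out
}

.lrCountMatrix <- function(L, R) {
  cross <- crossprod(L, R)
  out <- cross + t(cross)
  diag(out) <- diag(cross) # autocrine: the two directions coincide
  out
}

.icellnetMatrix <- function(L, R) {
  cross <- crossprod(L, R)
  cross + t(cross)
}

# Smillie-style permutation score matrix: -log10 of the add-one-smoothed
# probability that a bin-preserving label shuffle yields an interaction
# strength (active LR count, both directions) >= the observed one.
.smillieMatrix <- function(L, R, nPerm = 10000, binSize = 10, seed = NULL) {
  if (nPerm <= 0) stop("nPerm must be positive")
  if (binSize <= 0) stop("binSize must be positive")
  if (!is.null(seed)) set.seed(seed)
  obs <- .lrCountMatrix(L, R)
  totals <- colSums(L) + colSums(R) # expressed ligand+receptor entries per type
  bins <- floor(totals / binSize)
  Tn <- ncol(L)
  exceed <- matrix(0, Tn, Tn)
  binMembers <- split(seq_len(Tn), bins)
  for (i in seq_len(nPerm)) {
    idx <- seq_len(Tn)
    for (members in binMembers) {
      if (length(members) > 1L) idx[members] <- members[sample.int(length(members))]
    }
    s <- .lrCountMatrix(L[, idx, drop = FALSE], R[, idx, drop = FALSE])
    exceed <- exceed + (s >= obs)
  }
  p <- (1 + exceed) / (1 + nPerm)
  out <- -log10(p)
  dimnames(out) <- dimnames(obs)
  # numerical symmetrization (strength and shuffles are symmetric already)
  (out + t(out)) / 2
}
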