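# Independent brute-force oracles. Every oracle is a plain double/triple
# loop (or closed-form enumeration) deliberately avoiding the package's
# matrix engine, so that implementation and oracle can only agree by
# computing the same quantity.

# Interaction vectors by explicit per-pair loop over a logical genes x types
# presence matrix and a pairs data.frame (ligand, receptor).
oracleVectors <- function(presMat, pairsDF, A, B) {
  P <- nrow(pairsDF)
  vecA <- integer(2 * P)
  vecB <- integer(2 * P)
  has <- function(gene, ty) {
    gene %in% rownames(presMat) && isTRUE(presMat[gene, ty])
  }
  for (k in seq_len(P)) {
    vecA[k] <- as.integer(has(pairsDF$ligand[k], A))
    vecA[P + k] <- as.integer(has(pairsDF$receptor[k], A))
    vecB[k] <- as.integer(has(pairsDF$receptor[k], B))
    vecB[P + k] <- as.integer(has(pairsDF$ligand[k], B))
  }
  list(vecA = vecA, vecB = vecB)
}

oracleBrayCurtis <- function(presMat, pairsDF, A, B) {
  v <- oracleVectors(presMat, pairsDF, A, B)
  num <- 0
  den <- 0
  for (k in seq_along(v$vecA)) {
    num <- num + min(v$vecA[k], v$vecB[k])
    den <- den + v$vecA[k] + v$vecB[k]
  }
  if (den == 0) 0 else 2 * num / den
}

oracleLRCount <- function(presMat, pairsDF, A, B) {
  has <- function(gene, ty) {
    gene %in% rownames(presMat) && isTRUE(presMat[gene, ty])
  }
  n <- 0
  for (k in seq_len(nrow(pairsDF))) {
    ab <- has(pairsDF$ligand[k], A) && has(pairsDF$receptor[k], B)
    ba <- has(pairsDF$ligand[k], B) && has(pairsDF$receptor[k], A)
    if (identical(A, B)) {
      n <- n + as.integer(ab)
    } else {
      n <- n + as.integer(ab) + as.integer(ba)
    }
  }
  n
}

oracleICELLNET <- function(expr, pairsDF, A, B) {
  tpm <- function(gene, ty) {
    if (gene %in% rownames(expr)) expr[gene, ty] else 0
  }
  s <- 0
  for (k in seq_len(nrow(pairsDF))) {
    s <- s + log2(tpm(pairsDF$ligand[k], A) + 1) *
      log2(tpm(pairsDF$receptor[k], B) + 1)
    s <- s + log2(tpm(pairsDF$ligand[k], B) + 1) *
      log2(tpm(pairsDF$receptor[k], A) + 1)
  }
  s
}

# Hand-rolled Spearman: mid-ranks computed by counting, then the Pearson
# product-moment formula written out.
oracleRanks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    below <- sum(x < x[i])
    ties <- sum(x == x[i])
    r[i] <- below + (ties + 1) / 2
  }
  r
}

oracleSpearman <- function(x, y) {
  rx <- oracleRanks(x)
  ry <- oracleRanks(y)
  mx <- mean(rx)
  my <- mean(ry)
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  if (den == 0) return(NA_real_)
  num / den
}

# One-sided hypergeometric tail probabilities for the 2x2 table
# (a, b; c, d) with fixed margins, via direct enumeration over the support
# (log-binomials for numeric stability; independent of stats::fisher.test
# and of d*hyper).
oracleFisherGreater <- function(a, b, cc, d) {
  m <- a + b
  n <- cc + d
  k <- a + cc
  support <- max(0, k - n):min(m, k)
  pr <- exp(lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k))
  sum(pr[support >= a])
}

oracleFisherLess <- function(a, b, cc, d) {
  m <- a + b
  n <- cc + d
  k <- a + cc
  support <- max(0, k - n):min(m, k)
  pr <- exp(lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k))
  sum(pr[support <= a])
}

# Random binary scoring instance: an LR database of P pairs with distinct
# gene symbols and a random presence pattern over the given cell types.
randomInstance <- function(P, types, pPresent = 0.5) {
  pairsDF <- data.frame(
    ligand = sprintf("ol%03d", seq_len(P)),
    receptor = sprintf("or%03d", seq_len(P)),
    stringsAsFactors = FALSE
  )
  genes <- c(pairsDF$ligand, pairsDF$receptor)
  tpm <- matrix(
    ifelse(stats::runif(length(genes) * length(types)) < pPresent, 100, 0),
    nrow = length(genes), dimnames = list(genes, types)
  )
  db <- LRDatabase(pairsDF$ligand, pairsDF$receptor)
  list(pairsDF = pairsDF, expr = tpm, db = db,
       presence = binarizeExpression(tpm))
}

# Line atlas: one nucleus per type at the given x positions.
lineAtlas <- function(x, types = sprintf("T%02d", seq_along(x))) {
  CellAtlas(data.frame(
    nucleus_id = paste0("n", seq_along(x)), x = x, y = 0, z = 0,
    cell_type = types, stringsAsFactors = FALSE
  ))
}

# The criterion-9 style dominant-signal toy: 4 types on a line, 15
# informative LR pairs whose activity counts per type pair are exactly
# (5, 4, 3, 2, 1, 0) from the closest to the farthest pair, plus 15 noise
# pairs whose genes are never expressed. The LR-count CCI of the
# informative mask is perfectly anti-monotone in distance (|rho| = 1), and
# every other same-size subset breaks the strict count ordering.
dominantSignalToy <- function() {
  types <- c("A", "B", "C", "D")
  atlas <- lineAtlas(c(0, 1, 3, 7), types)
  d <- distanceMatrix(atlas, types = types)
  ut <- which(upper.tri(d), arr.ind = TRUE)
  counts <- 6 - rank(d[upper.tri(d)])
  lig <- character(0)
  rec <- character(0)
  on <- list()
  g <- 0
  for (k in seq_len(nrow(ut))) {
    if (counts[k] > 0) {
      for (j in seq_len(counts[k])) {
        g <- g + 1
        lig <- c(lig, sprintf("Lg%03d", g))
        rec <- c(rec, sprintf("Rc%03d", g))
        on[[g]] <- c(sprintf("Lg%03d", g), types[ut[k, 1]],
                     sprintf("Rc%03d", g), types[ut[k, 2]])
      }
    }
  }
  nInf <- length(lig)
  lig <- c(lig, sprintf("Nl%03d", seq_len(15)))
  rec <- c(rec, sprintf("Nr%03d", seq_len(15)))
  db <- LRDatabase(lig, rec)
  genes <- unique(c(lig, rec))
  expr <- matrix(0, length(genes), 4, dimnames = list(genes, types))
  for (e in on) {
    expr[e[1], e[2]] <- 100
    expr[e[3], e[4]] <- 100
  }
  list(
    atlas = atlas, dist = d, db = db, expr = expr,
    presence = binarizeExpression(expr),
    mask = c(rep(TRUE, nInf), rep(FALSE, 15))
  )
}
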