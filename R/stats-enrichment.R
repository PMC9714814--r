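#' Fisher exact test on a 2x2 table
#'
#' Conditional (hypergeometric) exact p-value via [stats::fisher.test()],
#' with the sample odds ratio \code{ad/bc} (reported as \code{Inf} when
#' \code{bc == 0} and \code{ad > 0}, \code{NaN} when both products are 0)
#' rather than the conditional MLE.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param side \code{"greater"} (enrichment), \code{"less"} (depletion) or
#'   \code{"two-sided"}.
#' @return list with \code{oddsRatio} and \code{p}.
#' @export
fisherExact <- function(table, side = c("greater", "less", "two-sided")) {
  side <- match.arg(side)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  alt <- if (side == "two-sided") "two.sided" else side
  p <- stats::fisher.test(table, alternative = alt)$p.value
  ad <- table[1L, 1L] * table[2L, 2L]
  bc <- table[1L, 2L] * table[2L, 1L]
  or <- if (bc == 0) { if (ad > 0) Inf else NaN } else ad / bc
  list(oddsRatio = or, p = min(p, 1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement, preserving input order.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bhAdjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

# Usage matrix over unordered cell pairs: U[p, k] = 1 iff LR pair p is
# active in either direction between the k-th pair of types.
.usageMatrix <- function(tensor, typeA, typeB) {
  stopifnot(is(tensor, "CommunicationTensor"))
  if (tensor@mode != "binary") stop("enrichment requires a binary tensor")
  arr <- tensor@scores
  U <- vapply(seq_along(typeA), function(k) {
    as.numeric(arr[, typeA[k], typeB[k]] | arr[, typeB[k], typeA[k]])
  }, numeric(dim(arr)[1L]))
  if (is.null(dim(U))) U <- matrix(U, nrow = dim(arr)[1L])
  rownames(U) <- dimnames(arr)[[1L]]
  U
}

# Shared core: one Fisher enrichment/depletion scan of LR-pair usage across
# strata of cell pairs. strata: factor per cell-pair instance; the universe
# is the sum of instances over strata.
.lrStratumEnrichment <- function(U, strata, db, fdr) {
  strata <- as.factor(strata)
  lev <- levels(strata)
  tot <- rowSums(U)
  N <- ncol(U)
  out <- list()
  for (s in lev) {
    inS <- strata == s
    nS <- sum(inS)
    if (nS == 0L) {
      warning("empty stratum '", s, "' skipped", call. = FALSE)
      next
    }
    a <- rowSums(U[, inS, drop = FALSE])
    cc <- tot - a
    for (p in seq_len(nrow(U))) {
      tab <- matrix(c(a[p], nS - a[p], cc[p], (N - nS) - cc[p]), 2L, 2L)
      fe <- fisherExact(tab, "greater")
      fd <- fisherExact(tab, "less")
      f2 <- fisherExact(tab, "two-sided")
      out[[length(out) + 1L]] <- data.frame(
        unit = rownames(U)[p], stratum = s,
        a = a[p], stratumSize = nS,
        oddsRatio = fe$oddsRatio,
        pEnrich = fe$p, pDeplete = fd$p, pTwoSided = f2$p,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) stop("no testable strata")
  res <- do.call(rbind, out)
  res$pEnrichAdj <- bhAdjust(res$pEnrich)
  res$pDepleteAdj <- bhAdjust(res$pDeplete)
  res$verdict <- ifelse(res$pEnrichAdj < fdr, "enriched",
                        ifelse(res$pDepleteAdj < fdr, "depleted", "none"))
  rownames(res) <- NULL
  res
}

#' LR-pair enrichment/depletion by body section
#'
#' For every LR pair and body section: the cell pairs co-occurring in the
#' section (both types present) form the stratum; usage of a pair by a cell
#' pair means the pair is active in either direction. The universe is the
#' sum of cell pairs over all sections (a cell pair spanning several
#' sections contributes once per section). One-sided Fisher tests are
#' computed for enrichment and depletion; BH adjustment is joint across all
#' (pair, section) tests per side.
#'
#' @param tensor a binary [CommunicationTensor-class].
#' @param sections a [BodySections-class].
#' @param db an [LRDatabase-class] (for labels).
#' @param fdr verdict threshold on adjusted p-values (default 0.01).
#' @return data.frame with columns unit, stratum, a, stratumSize,
#'   oddsRatio, pEnrich, pDeplete, pTwoSided, pEnrichAdj, pDepleteAdj,
#'   verdict.
#' @export
lrSectionEnrichment <- function(tensor, sections, db, fdr = 0.01) {
  sp <- sectionCellPairs(sections)
  nonEmpty <- vapply(sp, nrow, integer(1)) > 0L
  if (sum(nonEmpty) < 2L) stop("need at least two non-empty sections")
  typeA <- unlist(lapply(sp, function(d) d$typeA), use.names = FALSE)
  typeB <- unlist(lapply(sp, function(d) d$typeB), use.names = FALSE)
  strata <- factor(
    rep(names(sp), vapply(sp, nrow, integer(1))), levels = .SECTION_LEVELS
  )
  avail <- cellTypes(tensor)
  keep <- typeA %in% avail & typeB %in% avail
  U <- .usageMatrix(tensor, typeA[keep], typeB[keep])
  .lrStratumEnrichment(U, droplevels(strata[keep]), db, fdr)
}

#' LR-pair enrichment/depletion by distance range
#'
#' Strata are the short/mid/long ranges over unordered non-autocrine cell
#' pairs; usage of an LR pair by a cell pair means active in either
#' direction. Same testing and adjustment scheme as
#' [lrSectionEnrichment()].
#'
#' @param tensor a binary [CommunicationTensor-class].
#' @param ranges a [DistanceRanges-class].
#' @param db an [LRDatabase-class].
#' @param fdr verdict threshold (default 0.01).
#' @return data.frame as in [lrSectionEnrichment()].
#' @export
lrRangeEnrichment <- function(tensor, ranges, db, fdr = 0.01) {
  rp <- ranges@pairs
  if (length(unique(rp$range)) < 2L) {
    warning("only one distance range present; no contrast to test",
            call. = FALSE)
    return(data.frame())
  }
  avail <- cellTypes(tensor)
  keep <- rp$typeA %in% avail & rp$typeB %in% avail
  U <- .usageMatrix(tensor, rp$typeA[keep], rp$typeB[keep])
  .lrStratumEnrichment(U, droplevels(rp$range[keep]), db, fdr)
}

#' Ligand location-type enrichment by distance range
#'
#' The counting unit is an active LR-pair occurrence: one (LR pair, cell
#' pair) event with the pair active in either direction. For each location
#' type and distance range the 2x2 table splits occurrences by "is of this
#' location type" x "is in this distance range".
#'
#' @param tensor a binary [CommunicationTensor-class].
#' @param ranges a [DistanceRanges-class].
#' @param db an [LRDatabase-class] carrying location annotations.
#' @param fdr verdict threshold (default 0.01).
#' @return data.frame with one row per (location type, range) and the same
#'   statistic columns as [lrSectionEnrichment()].
#' @export
locationTypeEnrichment <- function(tensor, ranges, db, fdr = 0.01) {
  loc <- db@pairs$location
  if (all(is.na(loc))) stop("no location annotations in the LR database")
  rp <- ranges@pairs
  avail <- cellTypes(tensor)
  keep <- rp$typeA %in% avail & rp$typeB %in% avail
  rp <- rp[keep, , drop = FALSE]
  U <- .usageMatrix(tensor, rp$typeA, rp$typeB)
  occ <- which(U == 1, arr.ind = TRUE)
  if (!nrow(occ)) {
    warning("no active LR-pair occurrences; nothing to test", call. = FALSE)
    return(data.frame())
  }
  occLoc <- loc[occ[, 1L]]
  occRange <- rp$range[occ[, 2L]]
  ok <- !is.na(occLoc)
  occLoc <- occLoc[ok]
  occRange <- occRange[ok]
  out <- list()
  for (ty in intersect(.LOCATION_TYPES, unique(occLoc))) {
    for (rg in levels(droplevels(occRange))) {
      a <- sum(occLoc == ty & occRange == rg)
      b <- sum(occLoc == ty & occRange != rg)
      cc <- sum(occLoc != ty & occRange == rg)
      d <- sum(occLoc != ty & occRange != rg)
      fe <- fisherExact(matrix(c(a, cc, b, d), 2L), "greater")
      fd <- fisherExact(matrix(c(a, cc, b, d), 2L), "less")
      f2 <- fisherExact(matrix(c(a, cc, b, d), 2L), "two-sided")
      out[[length(out) + 1L]] <- data.frame(
        unit = ty, stratum = rg, a = a, stratumSize = a + cc,
        oddsRatio = fe$oddsRatio,
        pEnrich = fe$p, pDeplete = fd$p, pTwoSided = f2$p,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  res$pEnrichAdj <- bhAdjust(res$pEnrich)
  res$pDepleteAdj <- bhAdjust(res$pDeplete)
  res$verdict <- ifelse(res$pEnrichAdj < fdr, "enriched",
                        ifelse(res$pDepleteAdj < fdr, "depleted", "none"))
  rownames(res) <- NULL
  res
}

#' Functional-annotation abundance shifts across GA runs
#'
#' For each functional annotation, the relative abundance in each run's
#' selected mask (pairs carrying the annotation / mask size; a pair with
#' several annotations votes once per annotation by default) is compared to
#' the expected relative abundance in the full database with a one-sample
#' two-tailed Wilcoxon signed-rank test. Fold changes per run are reported
#' together with the \code{log10(FC + 1)} transform of their median.
#'
#' @param masks list of logical masks over \code{db} (e.g. \code{$mask} of
#'   GA runs).
#' @param db an [LRDatabase-class] carrying function annotations.
#' @param mode \code{"per-annotation"} (default; a multi-annotated pair
#'   counts once under each annotation) or \code{"per-pair"} (the full
#'   annotation string is a single label).
#' @param minRuns minimum number of runs required (default 6; the
#'   signed-rank test needs some nonzero differences).
#' @return data.frame with one row per annotation: expected and median
#'   observed abundance, median fold change, \code{log10(FC + 1)},
#'   Wilcoxon \code{p} and BH-adjusted p. Per-run fold changes are in the
#'   attribute \code{"foldChanges"}.
#' @export
functionAbundanceShift <- function(masks, db,
                                   mode = c("per-annotation", "per-pair"),
                                   minRuns = 6) {
  mode <- match.arg(mode)
  if (length(masks) < minRuns) {
    stop("need at least ", minRuns, " GA runs for the signed-rank test")
  }
  annots <- if (mode == "per-annotation") annotationList(db) else
    lapply(db@pairs$functionAnnotation,
           function(a) if (is.na(a)) character(0) else a)
  allAnn <- sort(unique(unlist(annots)))
  if (!length(allAnn)) stop("no function annotations in the LR database")
  P <- length(db)
  hasAnn <- function(ann) vapply(annots, function(v) ann %in% v, logical(1))
  expected <- vapply(allAnn, function(ann) sum(hasAnn(ann)) / P, numeric(1))
  rows <- list()
  fcs <- list()
  for (i in seq_along(allAnn)) {
    ann <- allAnn[i]
    flag <- hasAnn(ann)
    abund <- vapply(masks, function(m) {
      if (!sum(m)) return(0)
      sum(flag & m) / sum(m)
    }, numeric(1))
    diffs <- abund - expected[i]
    if (all(diffs == 0)) {
      p <- 1 # degenerate signed-rank: no evidence of a shift
    } else {
      p <- suppressWarnings(
        stats::wilcox.test(abund, mu = expected[i], alternative = "two.sided",
                           exact = FALSE)$p.value
      )
    }
    fc <- abund / expected[i]
    fcs[[ann]] <- fc
    rows[[i]] <- data.frame(
      annotation = ann, expected = expected[i],
      medianAbundance = stats::median(abund),
      medianFC = stats::median(fc),
      log10FCp1 = log10(stats::median(fc) + 1),
      p = p, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, rows)
  res$pAdj <- bhAdjust(res$p)
  rownames(res) <- NULL
  attr(res, "foldChanges") <- fcs
  res
}

#' Gene-set Fisher enrichment against a declared background
#'
#' Standard 2x2 gene-set test: sample vs rest of background, annotated vs
#' not.
#'
#' @param sample character vector of genes (must be a subset of
#'   \code{background}).
#' @param background character vector of background genes.
#' @param annotated character vector of genes carrying the annotation.
#' @return list with \code{oddsRatio}, \code{p} (enrichment side) and
#'   \code{table}; \code{NULL} (with a warning) when the annotated set does
#'   not intersect the background.
#' @export
genesetFisher <- function(sample, background, annotated) {
  sample <- unique(sample)
  background <- unique(background)
  annotated <- unique(annotated)
  if (!all(sample %in% background)) {
    stop("sample genes must be a subset of the background")
  }
  annBg <- intersect(annotated, background)
  if (!length(annBg)) {
    warning("annotated set does not intersect the background; no test",
            call. = FALSE)
    return(NULL)
  }
  a <- length(intersect(sample, annBg))
  b <- length(setdiff(sample, annBg))
  cc <- length(setdiff(annBg, sample))
  d <- length(background) - a - b - cc
  tab <- matrix(c(a, cc, b, d), 2L)
  fe <- fisherExact(tab, "greater")
  list(oddsRatio = fe$oddsRatio, p = fe$p, table = tab)
}

#' Similarity between directed cell pairs from their active LR profiles
#'
#' For directed cell pairs u = (s, r) and v = (s', r') with active LR sets
#' S_u, S_v: Jaccard = |intersection| / |union| (1 when both sets are
#' empty); Rand = (both active + both inactive) / P_total. The complement
#' (1 - similarity) is a distance suitable for embedding or clustering.
#'
#' @param tensor a binary [CommunicationTensor-class].
#' @param metric \code{"jaccard"} or \code{"rand"}.
#' @param includeAutocrine include directed pairs with sender == receiver
#'   (default FALSE).
#' @return symmetric similarity matrix over directed cell pairs, labeled
#'   \code{"sender->receiver"}.
#' @export
pairSimilarity <- function(tensor, metric = c("jaccard", "rand"),
                           includeAutocrine = FALSE) {
  metric <- match.arg(metric)
  stopifnot(is(tensor, "CommunicationTensor"))
  if (tensor@mode != "binary") stop("pairSimilarity requires a binary tensor")
  types <- cellTypes(tensor)
  grid <- expand.grid(receiver = types, sender = types,
                      stringsAsFactors = FALSE)[, c("sender", "receiver")]
  if (!includeAutocrine) grid <- grid[grid$sender != grid$receiver, ]
  P <- nPairs(tensor)
  X <- t(vapply(seq_len(nrow(grid)), function(i) {
    tensor@scores[, grid$sender[i], grid$receiver[i]]
  }, numeric(P)))
  rownames(X) <- paste0(grid$sender, "->", grid$receiver)
  inter <- tcrossprod(X)
  sizes <- rowSums(X)
  if (metric == "jaccard") {
    un <- outer(sizes, sizes, "+") - inter
    sim <- inter / un
    sim[un == 0] <- 1
  } else {
    bothZero <- tcrossprod(1 - X)
    sim <- (inter + bothZero) / P
  }
  sim
}
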