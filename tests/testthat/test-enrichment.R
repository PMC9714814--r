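test_that("Fisher exact p-values equal the hypergeometric tail enumeration", {
  expect_equal(fisherExact(matrix(c(8, 2, 2, 8), 2), "greater")$p,
               oracleFisherGreater(8, 2, 2, 8))
  expect_equal(fisherExact(matrix(c(8, 2, 2, 8), 2), "greater")$oddsRatio, 16)
  set.seed(71)
  for (rep in 1:50) {
    tab <- matrix(rpois(4, 6), 2)
    expect_equal(fisherExact(tab, "greater")$p,
                 oracleFisherGreater(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
    expect_equal(fisherExact(tab, "less")$p,
                 oracleFisherLess(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
  }
})

test_that("balanced and degenerate tables follow the odds-ratio conventions", {
  bal <- fisherExact(matrix(c(5, 5, 5, 5), 2), "two-sided")
  expect_equal(bal$oddsRatio, 1)
  expect_equal(bal$p, 1)
  anti <- fisherExact(matrix(c(0, 10, 10, 0), 2), "greater")
  expect_equal(anti$oddsRatio, 0)
  expect_equal(anti$p, 1)
  expect_equal(fisherExact(matrix(c(5, 0, 0, 5), 2), "greater")$oddsRatio, Inf)
  expect_true(is.nan(fisherExact(matrix(c(3, 0, 5, 0), 2), "greater")$oddsRatio))
  expect_error(fisherExact(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("one-sided minimum never exceeds the two-sided Fisher p", {
  set.seed(72)
  for (rep in 1:40) {
    tab <- matrix(rpois(4, 5), 2)
    pe <- fisherExact(tab, "greater")$p
    pd <- fisherExact(tab, "less")$p
    p2 <- fisherExact(tab, "two-sided")$p
    expect_lte(min(pe, pd), p2 + 1e-12)
    expect_lte(p2, 1)
  }
})

test_that("BH adjustment is order-preserving, monotone and >= raw p", {
  expect_equal(bhAdjust(0.04), 0.04)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(73)
  p <- runif(30)
  adj <- bhAdjust(p)
  expect_true(all(adj >= p))
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= -1e-12))
  expect_error(bhAdjust(c(0.5, 0)), "0, 1")
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

# A deterministic toy with three body sections and location-annotated pairs:
# pair hl^hr is used by every head cell pair and never elsewhere.
sectionToy <- function() {
  headTypes <- paste0("h", 1:5)
  midTypes <- c("gut", paste0("m", 1:3))
  tailTypes <- paste0("t", 1:4)
  atlas <- CellAtlas(data.frame(
    nucleus_id = paste0("n", 1:15),
    x = c(0, 2, 4, 6, 8, 40, 60, 45, 50, 55, 80, 85, 90, 95, 82),
    y = 0, z = 0,
    cell_type = c(headTypes, "gut", "gut", paste0("m", 1:3), tailTypes, "t1")
  ))
  db <- LRDatabase(c("hl", "ul"), c("hr", "ur"),
                   location = c("membrane-bound", "secreted"))
  types <- c(headTypes, midTypes, tailTypes)
  expr <- matrix(0, 4, length(types),
                 dimnames = list(c("hl", "hr", "ul", "ur"), types))
  expr[c("hl", "hr"), headTypes] <- 100 # active in the head only
  expr[c("ul", "ur"), ] <- 100          # active everywhere
  list(atlas = atlas, db = db,
       tensor = binaryCommunication(binarizeExpression(expr), db),
       sections = assignBodySections(atlas, "gut", apAxis = "x"))
}

test_that("a head-exclusive LR pair is enriched in the head and depleted elsewhere", {
  toy <- sectionToy()
  res <- lrSectionEnrichment(toy$tensor, toy$sections, toy$db, fdr = 0.05)
  head1 <- res[res$unit == "hl^hr" & res$stratum == "head", ]
  expect_identical(head1$verdict, "enriched")
  expect_gt(head1$oddsRatio, 1)
  other <- res[res$unit == "hl^hr" & res$stratum != "head", ]
  expect_true(all(other$oddsRatio < 1 | other$a == 0))
  # a pair used by every cell pair in every section has OR 1 and no call
  ubi <- res[res$unit == "ul^ur", ]
  expect_true(all(ubi$verdict == "none"))
})

test_that("range enrichment flags a short-range-only pair and warns on one range", {
  set.seed(74)
  # 8 types alternating on two well-separated body ends
  types <- sprintf("t%d", 1:8)
  x <- c(0, 1, 2, 3, 200, 201, 202, 203)
  atlas <- lineAtlas(x, types)
  d <- distanceMatrix(atlas, types = types)
  df <- data.frame(
    typeA = rownames(d)[which(upper.tri(d), arr.ind = TRUE)[, 1]],
    typeB = colnames(d)[which(upper.tri(d), arr.ind = TRUE)[, 2]],
    distance = d[upper.tri(d)]
  )
  # deterministic two-level ranges lifted to the three-level factor
  df$range <- factor(ifelse(df$distance < 100, "short", "long"),
                     levels = c("short", "mid", "long"))
  ranges <- new("DistanceRanges", pairs = df,
                mixture = list(means = c(2, 100, 200), variances = c(1, 1, 1),
                               weights = c(0.4, 0.2, 0.4)))
  db <- LRDatabase(c("sl", "ul"), c("sr", "ur"))
  expr <- matrix(0, 4, 8, dimnames = list(c("sl", "sr", "ul", "ur"), types))
  expr[c("sl", "sr"), c("t1", "t2", "t3", "t4")] <- 100 # co-present when close
  expr[c("ul", "ur"), ] <- 100
  tensor <- binaryCommunication(binarizeExpression(expr), db)
  res <- lrRangeEnrichment(tensor, ranges, db, fdr = 0.05)
  short1 <- res[res$unit == "sl^sr" & res$stratum == "short", ]
  expect_identical(short1$verdict, "enriched")
  # a uniformly active pair carries no contrast between ranges
  resU <- res[res$unit == "ul^ur", ]
  expect_true(all(resU$oddsRatio %in% c(1, NaN) | resU$pEnrich == 1))
  oneRange <- ranges
  oneRange@pairs$range <- factor("short", levels = c("short", "mid", "long"))
  expect_warning(empty <- lrRangeEnrichment(tensor, oneRange, db), "one")
  expect_identical(nrow(empty), 0L)
})

test_that("location-type occurrences concentrate where their pairs are active", {
  toy <- sectionToy()
  d <- distanceMatrix(toy$atlas)
  types <- rownames(d)
  ut <- which(upper.tri(d), arr.ind = TRUE)
  df <- data.frame(
    typeA = types[ut[, 1]], typeB = types[ut[, 2]],
    distance = d[upper.tri(d)],
    range = factor(ifelse(d[upper.tri(d)] < 10, "short", "long"),
                   levels = c("short", "mid", "long"))
  )
  ranges <- new("DistanceRanges", pairs = df,
                mixture = list(means = c(2, 40, 80), variances = c(1, 1, 1),
                               weights = c(1, 1, 1) / 3))
  res <- locationTypeEnrichment(toy$tensor, ranges, toy$db, fdr = 0.05)
  # membrane-bound usage comes only from the head-exclusive pair (all short)
  mbShort <- res[res$unit == "membrane-bound" & res$stratum == "short", ]
  expect_gt(mbShort$oddsRatio, 1)
  noLoc <- LRDatabase("a", "b")
  expect_error(locationTypeEnrichment(toy$tensor, ranges, noLoc), "location")
})

test_that("function-abundance shifts detect a systematic enrichment across runs", {
  db <- LRDatabase(paste0("l", 1:10), paste0("r", 1:10),
                   functionAnnotation = c(rep("positioning", 4),
                                          rep("other", 6)))
  # expected abundance of "positioning" = 0.4; every run doubles it to 0.8
  masks <- lapply(1:8, function(i) {
    m <- logical(10)
    m[c(1:4, 4 + i %% 6 + 1)] <- TRUE
    m
  })
  res <- functionAbundanceShift(masks, db)
  pos <- res[res$annotation == "positioning", ]
  expect_equal(pos$expected, 0.4)
  expect_equal(pos$medianFC, 2)
  expect_equal(pos$log10FCp1, log10(3))
  expect_lt(pos$pAdj, 0.05)
  fcs <- attr(res, "foldChanges")
  expect_equal(unname(fcs[["positioning"]]), rep(2, 8))
})

test_that("runs at exactly the expected abundance give the degenerate p = 1", {
  db <- LRDatabase(paste0("l", 1:4), paste0("r", 1:4),
                   functionAnnotation = c("f", "f", "g", "g"))
  masks <- lapply(1:6, function(i) c(TRUE, FALSE, TRUE, FALSE))
  res <- functionAbundanceShift(masks, db)
  expect_true(all(res$p == 1))
  expect_error(functionAbundanceShift(masks[1:3], db), "at least")
})

test_that("multi-annotation pairs vote once per annotation by default", {
  db <- LRDatabase(c("l1", "l2"), c("r1", "r2"),
                   functionAnnotation = c("a; b", "b"))
  masks <- lapply(1:6, function(i) c(TRUE, TRUE))
  res <- functionAbundanceShift(masks, db)
  expect_setequal(res$annotation, c("a", "b"))
  expect_equal(res$expected[res$annotation == "b"], 1)
  perPair <- functionAbundanceShift(masks, db, mode = "per-pair")
  expect_setequal(perPair$annotation, c("a; b", "b"))
})

test_that("gene-set Fisher enforces the declared background", {
  bg <- paste0("g", 1:20)
  ann <- paste0("g", 1:5)
  res <- genesetFisher(paste0("g", 1:4), bg, ann)
  expect_gt(res$oddsRatio, 1)
  expect_lt(res$p, 0.05)
  expect_error(genesetFisher(c("g1", "zz"), bg, ann), "subset")
  expect_warning(none <- genesetFisher("g1", bg, c("h1", "h2")), "intersect")
  expect_null(none)
})

test_that("Jaccard and Rand similarities follow their set formulas", {
  # S_u = {a, b, c}, S_v = {b, c, d} over P = 6 pairs -> Jaccard 0.5,
  # Rand = (2 + 2) / 6
  types <- c("A", "B", "C")
  db <- LRDatabase(paste0("l", 1:6), paste0("r", 1:6))
  expr <- matrix(0, 12, 3,
                 dimnames = list(c(paste0("l", 1:6), paste0("r", 1:6)), types))
  expr[c("l1", "l2", "l3"), "A"] <- 100
  expr[c("l2", "l3", "l4"), "B"] <- 100
  expr[paste0("r", 1:6), "C"] <- 100
  tensor <- binaryCommunication(binarizeExpression(expr), db)
  sim <- pairSimilarity(tensor, "jaccard")
  expect_equal(sim["A->C", "B->C"], 0.5)
  rand <- pairSimilarity(tensor, "rand")
  expect_equal(rand["A->C", "B->C"], 4 / 6)
  expect_equal(sim["A->C", "A->C"], 1)
  # empty-profile convention: Jaccard of two inactive pairs is 1
  expect_equal(sim["C->A", "C->B"], 1)
})

test_that("Rand similarity dominates Jaccard on random binary profiles", {
  set.seed(75)
  for (rep in 1:10) {
    inst <- randomInstance(10, c("A", "B", "C", "D"))
    tensor <- binaryCommunication(inst$presence, inst$db)
    j <- pairSimilarity(tensor, "jaccard")
    r <- pairSimilarity(tensor, "rand")
    expect_true(all(r - j >= -1e-12))
  }
})
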