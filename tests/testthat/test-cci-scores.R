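test_that("interaction vectors implement the paired two-half construction", {
  # DB = {(L1,R1),(L2,R2)}; A expresses both ligands, no receptors;
  # B expresses R1 only: 2 + 1 molecules, 1 match -> 2/3.
  m <- matrix(c(100, 100, 0, 0,
                0, 0, 100, 0), 4, 2,
              dimnames = list(c("L1", "L2", "R1", "R2"), c("A", "B")))
  db <- LRDatabase(c("L1", "L2"), c("R1", "R2"))
  pres <- binarizeExpression(m)
  v <- interactionVectors(pres, db, "A", "B")
  expect_identical(v$vecA, c(1L, 1L, 0L, 0L)) # ligands of A, receptors of A
  expect_identical(v$vecB, c(1L, 0L, 0L, 0L)) # receptors of B, ligands of B
  expect_equal(brayCurtisScore(v$vecA, v$vecB), 2 / 3)
})

test_that("Bray-Curtis, LR-count and ICELLNET match brute-force oracles on random instances", {
  set.seed(41)
  types <- c("A", "B")
  for (rep in 1:60) {
    P <- sample(2:20, 1)
    inst <- randomInstance(P, types)
    presMat <- scores(inst$presence)
    tpm <- inst$expr * runif(length(inst$expr), 0.5, 2)
    tensor <- binaryCommunication(inst$presence, inst$db)
    ptensor <- productCommunication(tpm, inst$db)
    for (A in types) for (B in types) {
      v <- interactionVectors(inst$presence, inst$db, A, B)
      expect_equal(brayCurtisScore(v$vecA, v$vecB),
                   oracleBrayCurtis(presMat, inst$pairsDF, A, B))
      expect_equal(lrCountScore(tensor, A, B),
                   oracleLRCount(presMat, inst$pairsDF, A, B))
      expect_equal(icellnetScore(ptensor, A, B),
                   oracleICELLNET(tpm, inst$pairsDF, A, B))
    }
  }
})

test_that("every CCI method is symmetric in the two cell types", {
  set.seed(42)
  for (rep in 1:20) {
    inst <- randomInstance(sample(2:15, 1), c("A", "B", "C"))
    for (method in c("bray_curtis", "lr_count")) {
      m <- scores(cciMatrix(method, inst$presence, inst$db))
      expect_equal(m, t(m))
    }
    mi <- scores(cciMatrix("icellnet", presence = inst$presence,
                           db = inst$db, expr = inst$expr))
    expect_equal(mi, t(mi))
  }
})

test_that("Bray-Curtis matches contribute to both molecule sums (2C <= S)", {
  set.seed(43)
  for (rep in 1:30) {
    inst <- randomInstance(sample(2:20, 1), c("A", "B"))
    v <- interactionVectors(inst$presence, inst$db, "A", "B")
    expect_lte(2 * sum(pmin(v$vecA, v$vecB)), sum(v$vecA) + sum(v$vecB))
    s <- brayCurtisScore(v$vecA, v$vecB)
    expect_gte(s, 0)
    expect_lte(s, 1)
  }
})

test_that("Bray-Curtis is 1 exactly for fully matched vectors and 0 for no molecules", {
  expect_equal(brayCurtisScore(rep(1L, 8), rep(1L, 8)), 1)
  expect_equal(brayCurtisScore(rep(0L, 8), rep(0L, 8)), 0)
  # equals 1 iff vectors coincide with no unmatched active entry
  expect_lt(brayCurtisScore(c(1L, 1L), c(1L, 0L)), 1)
})

test_that("appending LR pairs moves the Bray-Curtis score in the provable direction", {
  set.seed(44)
  for (rep in 1:20) {
    inst <- randomInstance(sample(2:12, 1), c("A", "B"))
    base <- scores(cciMatrix("bray_curtis", inst$presence, inst$db))["A", "B"]
    extend <- function(tpmA, tpmB) {
      expr2 <- rbind(inst$expr,
                     matrix(c(tpmA, tpmB), 2, 2, byrow = TRUE,
                            dimnames = list(c("xlig", "xrec"),
                                            colnames(inst$expr))))
      db2 <- LRDatabase(c(inst$pairsDF$ligand, "xlig"),
                        c(inst$pairsDF$receptor, "xrec"))
      scores(cciMatrix("bray_curtis", binarizeExpression(expr2), db2))["A", "B"]
    }
    # fully complementary in both directions: never decreases
    expect_gte(extend(c(100, 100), c(100, 100)), base)
    # expressed in neither cell: unchanged
    expect_equal(extend(c(0, 0), c(0, 0)), base)
    # one-sided (ligand in A only, inactive B -> A): never increases
    expect_lte(extend(c(100, 0), c(0, 0)), base)
  }
})

test_that("LR count sums both directions but counts autocrine pairs once", {
  m <- matrix(c(100, 100, 100, 100), 2, 2,
              dimnames = list(c("lig", "rec"), c("A", "B")))
  db <- LRDatabase("lig", "rec")
  tensor <- binaryCommunication(binarizeExpression(m), db)
  expect_identical(lrCountScore(tensor, "A", "B"), 2)
  expect_identical(lrCountScore(tensor, "A", "B", countMode = "union"), 1L)
  expect_identical(lrCountScore(tensor, "A", "A"), 1)
  cm <- scores(cciMatrix("lr_count", binarizeExpression(m), db))
  expect_identical(unname(diag(cm)), c(1, 1))
  expect_identical(cm["A", "B"], 2)
})

test_that("Smillie score is 0 when every shuffle reproduces the observed strength", {
  # all cell types share one presence row: any label shuffle is a no-op
  m <- matrix(100, 2, 4,
              dimnames = list(c("lig", "rec"), c("A", "B", "C", "D")))
  db <- LRDatabase("lig", "rec")
  s <- smillieScore(binarizeExpression(m), db, "A", "B",
                    nPerm = 200, seed = 1)
  expect_equal(s, 0)
})

test_that("Smillie p-values respect the add-one floor", {
  set.seed(45)
  inst <- randomInstance(8, c("A", "B", "C", "D"))
  nPerm <- 10
  s <- smillieScore(inst$presence, inst$db, "A", "B",
                    nPerm = nPerm, seed = 2)
  p <- 10^(-s)
  expect_gte(p, 1 / (nPerm + 1) - 1e-12)
  expect_lte(p, 1 + 1e-12)
})

test_that("cciMatrix agrees with the per-pair scores and handles edge databases", {
  inst <- randomInstance(6, c("A", "B"))
  m <- scores(cciMatrix("bray_curtis", inst$presence, inst$db))
  v <- interactionVectors(inst$presence, inst$db, "A", "B")
  expect_equal(m["A", "B"], brayCurtisScore(v$vecA, v$vecB))
  # identical expression for all types -> constant off-diagonal
  eq <- inst$expr
  eq[, 2] <- eq[, 1]
  meq <- scores(cciMatrix("bray_curtis", binarizeExpression(eq), inst$db))
  expect_equal(meq["A", "B"], meq["B", "A"])
  # empty database -> all-zero matrix
  m0 <- scores(cciMatrix("bray_curtis", inst$presence,
                         inst$db[rep(FALSE, 6)]))
  expect_true(all(m0 == 0))
  expect_error(cciMatrix("bogus", inst$presence, inst$db), "arg")
})

test_that("dissimilarity is the complement with a zero diagonal", {
  inst <- randomInstance(8, c("A", "B", "C"))
  cci <- cciMatrix("bray_curtis", inst$presence, inst$db)
  d <- cciDissimilarity(cci)
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(d["A", "B"], 1 - scores(cci)["A", "B"])
  ones <- new("CCIMatrix",
              scores = matrix(1, 2, 2, dimnames = list(c("A", "B"), c("A", "B"))),
              method = "bray_curtis", metadata = list())
  expect_true(all(cciDissimilarity(ones) == 0))
})

test_that("dissimilarity refuses out-of-range scores unless rescaled", {
  counts <- new("CCIMatrix",
                scores = matrix(c(0, 5, 5, 0), 2, 2,
                                dimnames = list(c("A", "B"), c("A", "B"))),
                method = "lr_count", metadata = list())
  expect_error(cciDissimilarity(counts), "rescale")
  d <- cciDissimilarity(counts, rescale = TRUE)
  expect_equal(unname(diag(d)), c(0, 0))
})

test_that("cell types cluster on the complement dissimilarity", {
  inst <- randomInstance(10, c("A", "B", "C", "D"))
  hc <- clusterCellTypes(cciMatrix("bray_curtis", inst$presence, inst$db))
  expect_s3_class(hc, "hclust")
  expect_identical(hc$method, "average")
  expect_setequal(hc$labels, c("A", "B", "C", "D"))
})
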