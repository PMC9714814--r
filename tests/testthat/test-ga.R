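test_that("the Spearman objective matches the hand-rolled rank oracle", {
  set.seed(61)
  types <- sprintf("t%d", 1:6)
  atlas <- lineAtlas(cumsum(runif(6, 1, 10)), types)
  d <- distanceMatrix(atlas, types = types)
  for (rep in 1:15) {
    inst <- randomInstance(10, types)
    mask <- runif(10) < 0.6
    if (!any(mask)) mask[1] <- TRUE
    got <- gaObjective(mask, inst$presence, inst$db, d)
    cci <- scores(cciMatrix("bray_curtis", inst$presence, inst$db[mask]))
    cci <- cci[types, types]
    rho <- oracleSpearman(cci[upper.tri(cci)], d[upper.tri(d)])
    if (is.na(rho)) rho <- 0 # constant CCI convention
    expect_equal(got$rho, rho)
    expect_equal(got$objective, abs(rho))
  }
})

test_that("an empty mask warns and yields objective zero", {
  inst <- randomInstance(5, c("A", "B", "C"))
  d <- distanceMatrix(lineAtlas(c(0, 3, 9), c("A", "B", "C")))
  expect_warning(res <- gaObjective(rep(FALSE, 5), inst$presence, inst$db, d),
                 "empty")
  expect_equal(res$objective, 0)
  expect_error(gaObjective(TRUE, inst$presence, inst$db, d), "length")
})

test_that("a perfectly anti-monotone CCI gives rho -1 and objective 1", {
  toy <- dominantSignalToy()
  res <- gaObjective(toy$mask, toy$presence, toy$db, toy$dist,
                     method = "lr_count")
  expect_equal(res$rho, -1)
  expect_equal(res$objective, 1)
})

test_that("GA runs are reproducible and their best-ever trace never decreases", {
  set.seed(62)
  types <- sprintf("t%d", 1:5)
  inst <- randomInstance(12, types)
  d <- distanceMatrix(lineAtlas(c(0, 2, 5, 11, 17), types))
  r1 <- runGA(inst$presence, inst$db, d, popSize = 20, generations = 30,
              seed = 99)
  r2 <- runGA(inst$presence, inst$db, d, popSize = 20, generations = 30,
              seed = 99)
  expect_identical(r1, r2)
  expect_true(all(diff(r1$trace) >= 0))
  expect_length(r1$trace, 31)
  expect_gte(sum(r1$mask), 1)
  # after enough generations the best objective reaches at least the
  # full-database mask (always within the GA's reach)
  full <- gaObjective(rep(TRUE, 12), inst$presence, inst$db, d)$objective
  r3 <- runGA(inst$presence, inst$db, d, popSize = 40, generations = 60,
              seed = 3)
  expect_gte(r3$objective, full)
})

test_that("ensemble runs use consecutive seeds and feed the consensus", {
  set.seed(63)
  types <- sprintf("t%d", 1:5)
  inst <- randomInstance(10, types)
  d <- distanceMatrix(lineAtlas(c(0, 4, 9, 15, 22), types))
  runs <- runGAEnsemble(inst$presence, inst$db, d, nRuns = 4, seed = 10,
                        popSize = 15, generations = 10)
  expect_equal(vapply(runs, `[[`, numeric(1), "seed"), 10:13,
               ignore_attr = TRUE)
  single <- runGA(inst$presence, inst$db, d, popSize = 15, generations = 10,
                  seed = 12)
  expect_identical(runs[[3]]$mask, single$mask)
  cons <- gaConsensus(runs, inst$presence, inst$db, d)
  expect_equal(cons$frequency,
               colMeans(do.call(rbind, lapply(runs, `[[`, "mask"))))
  expect_identical(unname(cons$mask), unname(cons$frequency >= 0.5))
})

test_that("consensus frequency boundary includes >= threshold and excludes below", {
  mk <- function(m) structure(list(mask = m), class = "gaRun")
  runs <- c(
    lapply(1:5, function(i) mk(c(a = TRUE, b = TRUE, c = FALSE))),
    lapply(1:5, function(i) mk(c(a = TRUE, b = FALSE, c = FALSE)))
  )
  inst <- randomInstance(3, c("A", "B", "C"))
  d <- distanceMatrix(lineAtlas(c(0, 2, 7), c("A", "B", "C")))
  cons <- suppressWarnings(
    gaConsensus(runs, inst$presence, inst$db, d, threshold = 0.5)
  )
  expect_identical(unname(cons$mask), c(TRUE, TRUE, FALSE)) # 1.0, 0.5, 0.0
})

test_that("consensus rho is recomputable from the mask alone", {
  set.seed(64)
  types <- sprintf("t%d", 1:5)
  inst <- randomInstance(10, types)
  d <- distanceMatrix(lineAtlas(c(0, 3, 7, 12, 20), types))
  runs <- runGAEnsemble(inst$presence, inst$db, d, nRuns = 3, seed = 5,
                        popSize = 15, generations = 10)
  cons <- gaConsensus(runs, inst$presence, inst$db, d)
  redo <- gaObjective(cons$mask, inst$presence, inst$db, d)
  expect_equal(cons$rho, redo$rho)
  expect_equal(cons$objective, redo$objective)
})

test_that("an all-below-threshold consensus warns and returns objective zero", {
  mk <- function(m) structure(list(mask = m), class = "gaRun")
  runs <- list(mk(c(TRUE, FALSE)), mk(c(FALSE, TRUE)),
               mk(c(FALSE, FALSE)))
  inst <- randomInstance(2, c("A", "B", "C"))
  d <- distanceMatrix(lineAtlas(c(0, 2, 7), c("A", "B", "C")))
  expect_warning(cons <- gaConsensus(runs, inst$presence, inst$db, d,
                                     threshold = 0.9),
                 "threshold")
  expect_false(any(cons$mask))
  expect_equal(cons$objective, 0)
})

test_that("permutation p-values stay within the add-one bounds in all scenarios", {
  set.seed(65)
  types <- sprintf("t%d", 1:5)
  inst <- randomInstance(12, types)
  d <- distanceMatrix(lineAtlas(c(0, 3, 8, 14, 21), types))
  mask <- c(rep(TRUE, 6), rep(FALSE, 6))
  for (sc in c("repair_columns", "relabel", "subsample")) {
    res <- permutationSignificance(mask, inst$presence, inst$db, d,
                                   scenario = sc, nPerm = 49, seed = 6)
    expect_gte(res$p, 1 / 50)
    expect_lte(res$p, 1)
    expect_length(res$null, 49)
  }
  expect_error(
    permutationSignificance(mask, inst$presence, inst$db, d, nPerm = 0),
    "positive"
  )
})

test_that("a zero observed objective gives permutation p = 1", {
  # no gene expressed: every subset scores 0, all null >= observed
  types <- c("A", "B", "C")
  expr <- matrix(0, 4, 3,
                 dimnames = list(c("l1", "l2", "r1", "r2"), types))
  db <- LRDatabase(c("l1", "l2"), c("r1", "r2"))
  d <- distanceMatrix(lineAtlas(c(0, 2, 7), types))
  res <- permutationSignificance(c(TRUE, FALSE), binarizeExpression(expr),
                                 db, d, scenario = "subsample", nPerm = 19,
                                 seed = 1)
  expect_equal(res$observed, 0)
  expect_equal(res$p, 1)
})
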