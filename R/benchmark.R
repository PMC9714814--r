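#' Distance-range classification benchmark of a CCI score
#'
#' Quantifies how well an overall CCI score separates the short/mid/long
#' distance ranges. Samples are the unordered non-autocrine cell-type
#' pairs, the single feature is the CCI score, and the labels are the
#' distance ranges. A random-forest classifier with \code{nTrees} trees is
#' trained under stratified \code{nFolds}-fold cross-validation; per split,
#' class probabilities on the held-out pairs give a one-vs-rest ROC and AUC
#' per class. Per-class means and SDs are taken across splits and the grand
#' mean is the macro average over classes.
#'
#' @param cci a [CCIMatrix-class].
#' @param ranges a [DistanceRanges-class] over the same cell types.
#' @param nFolds number of CV folds (default 3).
#' @param nTrees number of random-forest trees (default 10).
#' @param seed RNG seed controlling fold assignment and forest fitting.
#' @return list with \code{perClass} (data.frame: class, meanAUC, sdAUC),
#'   \code{meanAUC} (grand mean), \code{sdAUC}, \code{aucByFold}
#'   (folds x classes matrix), \code{roc} (list of per-fold, per-class
#'   FPR/TPR tables) and \code{config}.
#' @export
scoreRangeAUC <- function(cci, ranges, nFolds = 3, nTrees = 10, seed = NULL) {
  stopifnot(is(cci, "CCIMatrix"), is(ranges, "DistanceRanges"))
  rp <- ranges@pairs
  avail <- cellTypes(cci)
  keep <- rp$typeA %in% avail & rp$typeB %in% avail
  rp <- rp[keep, , drop = FALSE]
  y <- droplevels(rp$range)
  x <- scores(cci)[cbind(rp$typeA, rp$typeB)]
  classCounts <- table(y)
  if (any(classCounts < nFolds)) {
    stop(
      "class(es) with fewer members than folds: ",
      paste(names(classCounts)[classCounts < nFolds], collapse = ", "),
      "; reduce nFolds"
    )
  }
  if (!is.null(seed)) set.seed(seed)
  # stratified folds: shuffle within class, deal round-robin
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  classes <- levels(y)
  aucByFold <- matrix(NA_real_, nFolds, length(classes),
                      dimnames = list(NULL, classes))
  rocs <- vector("list", nFolds)
  for (f in seq_len(nFolds)) {
    train <- fold != f
    fit <- randomForest::randomForest(
      x = data.frame(score = x[train]), y = droplevels(y[train]),
      ntree = nTrees
    )
    prob <- stats::predict(fit, data.frame(score = x[!train]), type = "prob")
    rocs[[f]] <- list()
    for (cl in classes) {
      resp <- factor(y[!train] == cl, levels = c(FALSE, TRUE))
      r <- pROC::roc(resp, prob[, cl], quiet = TRUE,
                     levels = c(FALSE, TRUE), direction = "<")
      aucByFold[f, cl] <- as.numeric(pROC::auc(r))
      rocs[[f]][[cl]] <- data.frame(
        fpr = rev(1 - r$specificities), tpr = rev(r$sensitivities)
      )
    }
  }
  perClass <- data.frame(
    class = classes,
    meanAUC = colMeans(aucByFold),
    sdAUC = apply(aucByFold, 2L, stats::sd),
    row.names = NULL
  )
  list(
    perClass = perClass,
    meanAUC = mean(aucByFold),
    sdAUC = stats::sd(rowMeans(aucByFold)),
    aucByFold = aucByFold,
    roc = rocs,
    config = list(nFolds = nFolds, nTrees = nTrees, seed = seed,
                  n = length(y), method = cci@method)
  )
}
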