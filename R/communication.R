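#' Binary communication tensor
#'
#' For every LR pair p and directed cell-type pair (sender s, receiver r), a
#' communication score of 1 is assigned iff the ligand of p is present
#' (> threshold TPM) in s and the receptor of p is present in r; otherwise 0.
#' Pairs whose ligand or receptor gene is missing from the expression matrix
#' score 0 everywhere (with a warning naming the genes). Autocrine entries
#' (s == r) are computed; exclusion happens downstream.
#'
#' @param presence a [PresenceMatrix-class].
#' @param db an [LRDatabase-class].
#' @return a binary [CommunicationTensor-class] of shape P x T x T.
#' @export
binaryCommunication <- function(presence, db) {
  stopifnot(is(presence, "PresenceMatrix"), is(db, "LRDatabase"))
  L <- .presenceRows(presence, db@pairs$ligand)
  R <- .presenceRows(presence, db@pairs$receptor, warn = FALSE)
  # one combined warning for receptor genes not covered by the ligand lookup
  missR <- setdiff(
    db@pairs$receptor[!db@pairs$receptor %in% rownames(presence@presence)],
    db@pairs$ligand[!db@pairs$ligand %in% rownames(presence@presence)]
  )
  if (length(missR)) {
    warning(
      "gene(s) absent from expression matrix, treated as not expressed: ",
      paste(unique(missR), collapse = ", "),
      call. = FALSE
    )
  }
  types <- colnames(presence@presence)
  P <- nrow(db@pairs)
  Tn <- length(types)
  arr <- array(0, dim = c(P, Tn, Tn),
               dimnames = list(pairLabels(db), types, types))
  # scores[p, s, r] = L[p, s] * R[p, r]
  Ln <- L * 1
  Rn <- R * 1
  for (r in seq_len(Tn)) arr[, , r] <- Ln * Rn[, r]
  new("CommunicationTensor", scores = arr, mode = "binary")
}

#' Expression-product communication tensor
#'
#' Continuous communication scores: for LR pair p, sender s and receiver r,
#' the score is \code{log2(TPM_ligand(s) + 1) * log2(TPM_receptor(r) + 1)}
#' on raw (unthresholded) TPM values. Genes missing from the matrix
#' contribute 0 TPM.
#'
#' @param expr genes x cell-types TPM matrix.
#' @param db an [LRDatabase-class].
#' @param presenceFilter optional [PresenceMatrix-class]; when supplied,
#'   entries failing the binary communication filter are zeroed (off by
#'   default).
#' @return a product-mode [CommunicationTensor-class].
#' @export
productCommunication <- function(expr, db, presenceFilter = NULL) {
  expr <- validateExpression(expr)
  stopifnot(is(db, "LRDatabase"))
  L <- log2(.tpmRows(expr, db@pairs$ligand) + 1)
  R <- log2(.tpmRows(expr, db@pairs$receptor) + 1)
  types <- colnames(expr)
  P <- nrow(db@pairs)
  Tn <- length(types)
  arr <- array(0, dim = c(P, Tn, Tn),
               dimnames = list(pairLabels(db), types, types))
  for (r in seq_len(Tn)) arr[, , r] <- L * R[, r]
  if (!is.null(presenceFilter)) {
    gate <- binaryCommunication(presenceFilter, db)
    arr <- arr * gate@scores
  }
  new("CommunicationTensor", scores = arr, mode = "product")
}

#' Active LR pairs of a directed cell-type pair
#'
#' @param tensor a binary [CommunicationTensor-class].
#' @param sender,receiver cell-type labels.
#' @return integer vector of LR pair positions p with
#'   \code{scores[p, sender, receiver] == 1} (possibly empty).
#' @export
directedProfile <- function(tensor, sender, receiver) {
  stopifnot(is(tensor, "CommunicationTensor"))
  if (tensor@mode != "binary") {
    stop("directedProfile requires a binary-mode tensor")
  }
  types <- cellTypes(tensor)
  if (!sender %in% types) stop("unknown sender cell type: ", sender)
  if (!receiver %in% types) stop("unknown receiver cell type: ", receiver)
  which(tensor@scores[, sender, receiver] == 1)
}

#' Export a communication tensor as a long-format table
#'
#' One row per (LR pair, sender, receiver) with the communication score;
#' by default zero-score rows are dropped.
#'
#' @param tensor a [CommunicationTensor-class].
#' @param keepZero keep zero-score rows (default FALSE).
#' @return data.frame with columns lr_pair, sender, receiver, score.
#' @export
communicationTable <- function(tensor, keepZero = FALSE) {
  stopifnot(is(tensor, "CommunicationTensor"))
  dn <- dimnames(tensor@scores)
  out <- expand.grid(
    lr_pair = dn[[1L]], sender = dn[[2L]], receiver = dn[[3L]],
    stringsAsFactors = FALSE
  )
  out$score <- as.vector(tensor@scores)
  if (!keepZero) out <- out[out$score != 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}
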