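#' Read a cell-type expression matrix (TPM)
#'
#' Reads a rectangular numeric table with labeled rows and columns and
#' returns it in the canonical genes x cell-types orientation. No silent
#' imputation is performed: any non-numeric or missing cell is an error.
#'
#' @param path path to a TSV/CSV file; first column holds the row labels.
#' @param orientation \code{"genes-in-rows"} (default) or
#'   \code{"genes-in-columns"} for transposed files.
#' @param delim field separator; inferred from extension when NULL.
#' @return numeric matrix, genes in rows, cell types in columns, validated
#'   by [validateExpression()].
#' @export
readExpression <- function(path,
                           orientation = c("genes-in-rows", "genes-in-columns"),
                           delim = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delim)) delim <- .delimFromPath(path)
  tab <- utils::read.table(path,
    header = TRUE, sep = delim, quote = "\"", row.names = 1L,
    stringsAsFactors = FALSE, check.names = FALSE, comment.char = "",
    colClasses = NA
  )
  m <- as.matrix(tab)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) &
                   !is.na(m), arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf(
        "non-numeric value at row '%s', column '%s'",
        rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]
      ))
    }
    stop("expression table is not numeric")
  }
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop(sprintf(
      "missing value (NA) at row '%s', column '%s'; no silent imputation",
      rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]
    ))
  }
  if (orientation == "genes-in-columns") m <- t(m)
  validateExpression(m)
}

#' Validate an expression matrix
#'
#' Checks that the matrix is numeric, finite and non-negative with unique
#' gene rownames and unique cell-type colnames.
#'
#' @param m numeric matrix, genes in rows, cell types in columns.
#' @return \code{m}, invisibly usable (returned unchanged).
#' @export
validateExpression <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expression must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression must have gene rownames and cell-type colnames")
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate gene label(s): ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(m))) stop("duplicate cell-type label(s)")
  if (anyNA(m) || any(!is.finite(m))) stop("expression values must be finite")
  if (any(m < 0)) stop("expression values must be non-negative (TPM)")
  m
}

#' Write an expression matrix to TSV/CSV
#'
#' @param m genes x cell-types numeric matrix.
#' @param path output path; extension picks the separator.
#' @param delim field separator; inferred from extension when NULL.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(m, path, delim = NULL) {
  if (is.null(delim)) delim <- .delimFromPath(path)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Binarize expression at a strict TPM threshold
#'
#' A gene is called present in a cell type iff its TPM strictly exceeds the
#' threshold (a value exactly at the threshold is absent). The default of
#' 10 TPM is the presence filter used for all binary communication scores.
#'
#' @param expr genes x cell-types numeric matrix (TPM).
#' @param threshold non-negative TPM cutoff (default 10).
#' @return a [PresenceMatrix-class].
#' @examples
#' m <- matrix(c(10, 10.5, 0, 20), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("A", "B")))
#' scores(binarizeExpression(m))
#' @export
binarizeExpression <- function(expr, threshold = 10) {
  expr <- validateExpression(expr)
  if (length(threshold) != 1L || is.na(threshold) || threshold < 0) {
    stop("threshold must be a single non-negative number")
  }
  new("PresenceMatrix", presence = expr > threshold, threshold = threshold)
}

# Presence rows for an arbitrary gene vector: genes absent from the matrix
# are treated as never expressed (all-FALSE rows); a warning lists them once.
.presenceRows <- function(presence, genes, warn = TRUE) {
  m <- presence@presence
  out <- matrix(FALSE, length(genes), ncol(m),
                dimnames = list(NULL, colnames(m)))
  hit <- genes %in% rownames(m)
  if (any(hit)) out[hit, ] <- m[genes[hit], , drop = FALSE]
  if (warn && any(!hit)) {
    warning(
      "gene(s) absent from expression matrix, treated as not expressed: ",
      paste(unique(genes[!hit]), collapse = ", "),
      call. = FALSE
    )
  }
  out
}

# Same lookup on a raw TPM matrix (absent -> 0 TPM).
.tpmRows <- function(expr, genes) {
  out <- matrix(0, length(genes), ncol(expr),
                dimnames = list(NULL, colnames(expr)))
  hit <- genes %in% rownames(expr)
  if (any(hit)) out[hit, ] <- expr[genes[hit], , drop = FALSE]
  out
}
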