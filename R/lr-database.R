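#' Construct an LRDatabase from vectors
#'
#' Gene symbols are whitespace-trimmed and matched case-sensitively; a pair
#' is identified by its (ligand, receptor) combination, which must be unique.
#'
#' @param ligand,receptor character vectors of gene symbols (equal length).
#' @param functionAnnotation optional character vector of free-text
#'   annotations; several annotations per pair may be given as a delimited
#'   list (see \code{annotationDelim}).
#' @param location optional character vector of ligand location types, each
#'   one of \code{"ECM-component"}, \code{"membrane-bound"}, \code{"secreted"}
#'   or \code{NA}.
#' @param annotationDelim delimiter for multi-annotation cells (default ";").
#' @return an [LRDatabase-class].
#' @examples
#' db <- LRDatabase(c("lin-44", "egl-17"), c("lin-17", "egl-15"),
#'                  location = c("secreted", "secreted"))
#' length(db)
#' @export
LRDatabase <- function(ligand, receptor, functionAnnotation = NULL,
                       location = NULL, annotationDelim = ";") {
  ligand <- trimws(as.character(ligand))
  receptor <- trimws(as.character(receptor))
  if (length(ligand) != length(receptor)) {
    stop("ligand and receptor must have the same length")
  }
  n <- length(ligand)
  fa <- if (is.null(functionAnnotation)) rep(NA_character_, n) else
    trimws(as.character(functionAnnotation))
  loc <- if (is.null(location)) rep(NA_character_, n) else
    trimws(as.character(location))
  fa[!is.na(fa) & !nzchar(fa)] <- NA_character_
  loc[!is.na(loc) & !nzchar(loc)] <- NA_character_
  new("LRDatabase",
    pairs = data.frame(
      ligand = ligand, receptor = receptor,
      functionAnnotation = fa, location = loc,
      stringsAsFactors = FALSE, row.names = NULL
    ),
    annotationDelim = annotationDelim
  )
}

.delimFromPath <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a ligand-receptor database from CSV/TSV
#'
#' The file must contain a ligand and a receptor column; function and
#' location columns are optional. Column names are configurable to
#' accommodate external tables. Rows are kept in file order and duplicate
#' (ligand, receptor) rows are rejected.
#'
#' @param path path to a CSV (default) or TSV file with a header row.
#' @param ligandCol,receptorCol,functionCol,locationCol column names in the
#'   file mapping onto the database fields.
#' @param annotationDelim delimiter for multi-annotation cells (default ";").
#' @param delim field separator; inferred from the file extension when NULL.
#' @return an [LRDatabase-class] preserving file row order.
#' @seealso [writeLRDatabase()]
#' @export
readLRDatabase <- function(path, ligandCol = "ligand",
                           receptorCol = "receptor",
                           functionCol = "function",
                           locationCol = "location",
                           annotationDelim = ";", delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delim)) delim <- .delimFromPath(path)
  tab <- utils::read.table(path,
    header = TRUE, sep = delim, quote = "\"",
    stringsAsFactors = FALSE, check.names = FALSE, comment.char = ""
  )
  for (col in c(ligandCol, receptorCol)) {
    if (!col %in% colnames(tab)) {
      stop("missing mandatory column '", col, "' in ", path)
    }
  }
  LRDatabase(
    ligand = tab[[ligandCol]],
    receptor = tab[[receptorCol]],
    functionAnnotation = if (functionCol %in% colnames(tab)) tab[[functionCol]],
    location = if (locationCol %in% colnames(tab)) tab[[locationCol]],
    annotationDelim = annotationDelim
  )
}

#' Write a ligand-receptor database to CSV/TSV
#'
#' Emits the default dialect (header \code{ligand,receptor,function,location})
#' so that \code{readLRDatabase(writeLRDatabase(db, f))} round-trips.
#'
#' @param db an [LRDatabase-class].
#' @param path output path; extension picks the separator.
#' @param delim field separator; inferred from extension when NULL.
#' @return \code{path}, invisibly.
#' @export
writeLRDatabase <- function(db, path, delim = NULL) {
  stopifnot(is(db, "LRDatabase"))
  if (is.null(delim)) delim <- .delimFromPath(path)
  out <- db@pairs
  colnames(out) <- c("ligand", "receptor", "function", "location")
  utils::write.table(out, path,
    sep = delim, quote = TRUE,
    row.names = FALSE, na = ""
  )
  invisible(path)
}

#' @describeIn LRDatabase subset by logical mask or integer index,
#'   preserving the original relative order of pairs.
#' @param x an LRDatabase.
#' @param i logical mask of length \code{length(x)} or integer positions.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "LRDatabase", function(x, i, j, ..., drop = FALSE) {
  if (is.logical(i)) {
    if (length(i) != nrow(x@pairs)) {
      stop(sprintf(
        "mask length (%d) must equal the number of pairs (%d)",
        length(i), nrow(x@pairs)
      ))
    }
    i <- which(i)
  }
  initialize(x, pairs = x@pairs[i, , drop = FALSE])
})

#' Unique ligand and receptor gene sets of a database
#'
#' A gene may appear in both sets (some molecules serve as ligand in one
#' pair and receptor in another).
#'
#' @param db an [LRDatabase-class].
#' @return list with character vectors \code{ligands} and \code{receptors}
#'   (deduplicated, in order of first appearance).
#' @export
uniqueMolecules <- function(db) {
  stopifnot(is(db, "LRDatabase"))
  list(
    ligands = unique(db@pairs$ligand),
    receptors = unique(db@pairs$receptor)
  )
}

#' LR pair table accessor
#'
#' @param db an [LRDatabase-class].
#' @return the underlying data.frame (ligand, receptor, functionAnnotation,
#'   location), one row per pair in stable order.
#' @export
lrPairs <- function(db) {
  stopifnot(is(db, "LRDatabase"))
  db@pairs
}

#' Split multi-annotation cells into per-pair annotation lists
#'
#' @param db an [LRDatabase-class].
#' @return list (length = number of pairs) of character vectors; pairs
#'   without annotation yield \code{character(0)}.
#' @export
annotationList <- function(db) {
  stopifnot(is(db, "LRDatabase"))
  lapply(db@pairs$functionAnnotation, function(a) {
    if (is.na(a)) character(0) else trimws(strsplit(a, db@annotationDelim, fixed = TRUE)[[1L]])
  })
}

#' Stable labels for LR pairs ("ligand^receptor")
#' @param db an [LRDatabase-class].
#' @return character vector of pair labels.
#' @export
pairLabels <- function(db) {
  stopifnot(is(db, "LRDatabase"))
  paste(db@pairs$ligand, db@pairs$receptor, sep = "^")
}
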