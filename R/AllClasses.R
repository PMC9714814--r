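#' @import methods
NULL

.LOCATION_TYPES <- c("ECM-component", "membrane-bound", "secreted")
.CCI_METHODS <- c("bray_curtis", "lr_count", "icellnet", "smillie")
.RANGE_LEVELS <- c("short", "mid", "long")
.SECTION_LEVELS <- c("head", "mid-body", "tail")

#' LRDatabase: an ordered table of ligand-receptor pairs
#'
#' Holds the curated ligand-receptor (LR) interaction pairs that every
#' downstream computation indexes. Each row is one LR pair with an optional
#' free-text functional annotation (possibly a delimited list) and an optional
#' ligand location type (\code{"ECM-component"}, \code{"membrane-bound"} or
#' \code{"secreted"}). Row order is preserved through subsetting so that
#' boolean masks (as used by the genetic algorithm) always refer to stable
#' positions.
#'
#' @slot pairs data.frame with columns \code{ligand}, \code{receptor},
#'   \code{functionAnnotation} (character, \code{NA} allowed) and
#'   \code{location} (character, \code{NA} allowed).
#' @slot annotationDelim delimiter separating multiple functional annotations
#'   within one cell (default \code{";"}).
#'
#' @seealso [readLRDatabase()], [uniqueMolecules()]
#' @export
setClass("LRDatabase",
  representation(pairs = "data.frame", annotationDelim = "character"),
  prototype(
    pairs = data.frame(
      ligand = character(), receptor = character(),
      functionAnnotation = character(), location = character(),
      stringsAsFactors = FALSE
    ),
    annotationDelim = ";"
  )
)

setValidity("LRDatabase", function(object) {
  p <- object@pairs
  req <- c("ligand", "receptor", "functionAnnotation", "location")
  if (!all(req %in% colnames(p))) {
    return(paste("pairs must have columns:", paste(req, collapse = ", ")))
  }
  if (nrow(p) == 0L) return(TRUE)
  if (any(is.na(p$ligand)) || any(!nzchar(p$ligand))) {
    return("ligand symbols must be non-empty strings")
  }
  if (any(is.na(p$receptor)) || any(!nzchar(p$receptor))) {
    return("receptor symbols must be non-empty strings")
  }
  key <- paste(p$ligand, p$receptor, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    return(sprintf(
      "duplicate (ligand, receptor) pair at row %d: (%s, %s)",
      i, p$ligand[i], p$receptor[i]
    ))
  }
  loc <- p$location[!is.na(p$location)]
  if (length(loc) && !all(loc %in% .LOCATION_TYPES)) {
    bad <- setdiff(unique(loc), .LOCATION_TYPES)
    return(sprintf(
      "invalid location type(s): %s (allowed: %s)",
      paste(bad, collapse = ", "), paste(.LOCATION_TYPES, collapse = ", ")
    ))
  }
  TRUE
})

#' PresenceMatrix: binarized ligand/receptor expression
#'
#' Binary presence/absence calls per gene and cell type, obtained by strict
#' thresholding of a TPM expression matrix (an entry is present iff
#' TPM > threshold).
#'
#' @slot presence logical matrix, genes in rows, cell types in columns.
#' @slot threshold numeric TPM threshold used for the strict comparison.
#'
#' @seealso [binarizeExpression()]
#' @export
setClass("PresenceMatrix",
  representation(presence = "matrix", threshold = "numeric")
)

setValidity("PresenceMatrix", function(object) {
  m <- object@presence
  if (!is.logical(m)) return("presence must be a logical matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    return("presence must have gene rownames and cell-type colnames")
  }
  if (anyDuplicated(rownames(m))) return("duplicate gene symbols")
  if (anyDuplicated(colnames(m))) return("duplicate cell-type labels")
  if (anyNA(m)) return("presence entries must not be NA")
  if (length(object@threshold) != 1L || is.na(object@threshold) ||
      object@threshold < 0) {
    return("threshold must be a single non-negative number")
  }
  TRUE
})

#' CommunicationTensor: per-LR-pair communication scores for directed
#' cell-type pairs
#'
#' A dense P x T x T array of communication scores: for LR pair p, sender
#' cell type s and receiver cell type r, \code{scores[p, s, r]} is 1/0 in
#' \code{"binary"} mode (1 iff the ligand of p is present in s and the
#' receptor of p is present in r) or
#' \code{log2(TPM_ligand + 1) * log2(TPM_receptor + 1)} in \code{"product"}
#' mode. Autocrine entries (s == r) are computed; their exclusion happens
#' downstream.
#'
#' @slot scores numeric array \code{[P, T, T]} with dimnames
#'   (pair label, sender, receiver).
#' @slot mode \code{"binary"} or \code{"product"}.
#'
#' @seealso [binaryCommunication()], [productCommunication()],
#'   [directedProfile()]
#' @export
setClass("CommunicationTensor",
  representation(scores = "array", mode = "character")
)

setValidity("CommunicationTensor", function(object) {
  a <- object@scores
  if (length(dim(a)) != 3L) return("scores must be a 3-dimensional array")
  if (dim(a)[2L] != dim(a)[3L]) {
    return("sender and receiver dimensions must match")
  }
  if (!object@mode %in% c("binary", "product")) {
    return("mode must be 'binary' or 'product'")
  }
  if (anyNA(a)) return("scores must not contain NA")
  if (object@mode == "binary" && !all(a %in% c(0, 1))) {
    return("binary-mode scores must be 0/1")
  }
  if (any(a < 0)) return("scores must be non-negative")
  TRUE
})

#' CCIMatrix: symmetric cell-cell interaction score matrix
#'
#' A T x T symmetric matrix of undirected overall interaction scores between
#' cell types, tagged with the aggregation method that produced it. The
#' diagonal holds autocrine scores; downstream analyses (correlation with
#' distance, enrichment) exclude it.
#'
#' @slot scores numeric T x T matrix with cell-type dimnames.
#' @slot method one of \code{"bray_curtis"}, \code{"lr_count"},
#'   \code{"icellnet"}, \code{"smillie"}.
#' @slot metadata list of method parameters (e.g. permutation settings).
#'
#' @seealso [cciMatrix()], [cciDissimilarity()]
#' @export
setClass("CCIMatrix",
  representation(scores = "matrix", method = "character", metadata = "list"),
  prototype(metadata = list())
)

setValidity("CCIMatrix", function(object) {
  m <- object@scores
  if (nrow(m) != ncol(m)) return("scores must be square")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m))) {
    return("scores must have identical row and column cell-type names")
  }
  if (anyNA(m)) return("scores must not contain NA")
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    return("scores must be symmetric")
  }
  if (!object@method %in% .CCI_METHODS) {
    return(paste("method must be one of:", paste(.CCI_METHODS, collapse = ", ")))
  }
  if (object@method == "bray_curtis" && (any(m < 0) || any(m > 1))) {
    return("Bray-Curtis scores must lie in [0, 1]")
  }
  TRUE
})

#' CellAtlas: a labeled 3D nucleus atlas
#'
#' Nucleus coordinates with cell-type labels. Only labeled nuclei are
#' retained; unlabeled rows are dropped at read time.
#'
#' @slot nuclei data.frame with columns \code{nucleus_id}, \code{x},
#'   \code{y}, \code{z}, \code{cell_type}.
#'
#' @seealso [readAtlas()], [distanceMatrix()]
#' @export
setClass("CellAtlas", representation(nuclei = "data.frame"))

setValidity("CellAtlas", function(object) {
  n <- object@nuclei
  req <- c("nucleus_id", "x", "y", "z", "cell_type")
  if (!all(req %in% colnames(n))) {
    return(paste("nuclei must have columns:", paste(req, collapse = ", ")))
  }
  if (nrow(n) == 0L) return(TRUE)
  xyz <- as.matrix(n[, c("x", "y", "z")])
  if (!is.numeric(xyz) || any(!is.finite(xyz))) {
    return("coordinates must be finite numbers")
  }
  if (any(is.na(n$cell_type)) || any(!nzchar(n$cell_type))) {
    return("every retained nucleus must carry a non-empty cell-type label")
  }
  if (anyDuplicated(n$nucleus_id)) return("duplicate nucleus_id")
  TRUE
})

#' DistanceRanges: short/mid/long classification of cell-type distances
#'
#' Per unordered cell-type pair, the distance-range label assigned by a
#' 3-component 1-D Gaussian mixture fitted on the minimum inter-nucleus
#' distances, with components relabeled short/mid/long by ascending mean.
#'
#' @slot pairs data.frame with columns \code{typeA}, \code{typeB},
#'   \code{distance}, \code{range} (factor short/mid/long).
#' @slot mixture list with \code{means}, \code{variances}, \code{weights}
#'   (each length-3, ordered short/mid/long).
#'
#' @seealso [fitDistanceRanges()]
#' @export
setClass("DistanceRanges",
  representation(pairs = "data.frame", mixture = "list")
)

setValidity("DistanceRanges", function(object) {
  p <- object@pairs
  req <- c("typeA", "typeB", "distance", "range")
  if (!all(req %in% colnames(p))) {
    return(paste("pairs must have columns:", paste(req, collapse = ", ")))
  }
  if (!all(levels(p$range) == .RANGE_LEVELS)) {
    return("range must be a factor with levels short, mid, long")
  }
  mx <- object@mixture
  if (!all(c("means", "variances", "weights") %in% names(mx))) {
    return("mixture must contain means, variances, weights")
  }
  if (is.unsorted(mx$means)) {
    return("mixture means must be ascending (short < mid < long)")
  }
  TRUE
})

#' BodySections: head / mid-body / tail partition of an atlas
#'
#' Assigns every nucleus to one of three sections along the anteroposterior
#' (AP) axis. The mid-body is the closed interval spanned by the intestine
#' nuclei on that axis; head and tail are the two complementary sides.
#'
#' @slot nuclei data.frame with columns \code{nucleus_id}, \code{cell_type},
#'   \code{axisPos}, \code{section} (factor head/mid-body/tail).
#' @slot axis the coordinate used as AP axis (\code{"x"}, \code{"y"} or
#'   \code{"z"}).
#' @slot span numeric length-2, the intestine interval on the AP axis.
#' @slot intestineLabel the cell-type label that defines the mid-body.
#'
#' @seealso [assignBodySections()], [sectionCellPairs()]
#' @export
setClass("BodySections",
  representation(
    nuclei = "data.frame", axis = "character",
    span = "numeric", intestineLabel = "character"
  )
)

setValidity("BodySections", function(object) {
  n <- object@nuclei
  req <- c("nucleus_id", "cell_type", "axisPos", "section")
  if (!all(req %in% colnames(n))) {
    return(paste("nuclei must have columns:", paste(req, collapse = ", ")))
  }
  if (!all(levels(n$section) == .SECTION_LEVELS)) {
    return("section must be a factor with levels head, mid-body, tail")
  }
  if (length(object@span) != 2L || object@span[1L] > object@span[2L]) {
    return("span must be an ordered length-2 interval")
  }
  if (!object@axis %in% c("x", "y", "z")) return("axis must be x, y or z")
  TRUE
})

## ---- show methods ----

setMethod("show", "LRDatabase", function(object) {
  p <- object@pairs
  cat(sprintf(
    "LRDatabase with %d pair(s): %d unique ligand(s), %d unique receptor(s)\n",
    nrow(p), length(unique(p$ligand)), length(unique(p$receptor))
  ))
  nloc <- sum(!is.na(p$location))
  nfun <- sum(!is.na(p$functionAnnotation))
  cat(sprintf(
    "  annotated: %d with function, %d with location type\n", nfun, nloc
  ))
  if (nrow(p)) {
    shown <- utils::head(p, 4L)
    cat(paste0(
      "  ", shown$ligand, " -> ", shown$receptor,
      ifelse(is.na(shown$location), "", paste0(" [", shown$location, "]")),
      collapse = "\n"
    ), "\n")
    if (nrow(p) > 4L) cat(sprintf("  ... and %d more\n", nrow(p) - 4L))
  }
  invisible(NULL)
})

setMethod("show", "PresenceMatrix", function(object) {
  m <- object@presence
  cat(sprintf(
    "PresenceMatrix: %d gene(s) x %d cell type(s), threshold > %g TPM, %.1f%% present\n",
    nrow(m), ncol(m), object@threshold, 100 * mean(m)
  ))
  invisible(NULL)
})

setMethod("show", "CommunicationTensor", function(object) {
  d <- dim(object@scores)
  cat(sprintf(
    "CommunicationTensor (%s mode): %d LR pair(s) x %d sender(s) x %d receiver(s)\n",
    object@mode, d[1L], d[2L], d[3L]
  ))
  if (object@mode == "binary") {
    cat(sprintf("  active entries: %d (%.1f%%)\n",
                sum(object@scores), 100 * mean(object@scores)))
  }
  invisible(NULL)
})

setMethod("show", "CCIMatrix", function(object) {
  m <- object@scores
  off <- m[upper.tri(m)]
  cat(sprintf(
    "CCIMatrix (%s): %d cell type(s); off-diagonal scores in [%.3g, %.3g]\n",
    object@method, nrow(m),
    if (length(off)) min(off) else NA, if (length(off)) max(off) else NA
  ))
  invisible(NULL)
})

setMethod("show", "CellAtlas", function(object) {
  n <- object@nuclei
  cat(sprintf(
    "CellAtlas: %d labeled nucleus/nuclei across %d cell type(s)\n",
    nrow(n), length(unique(n$cell_type))
  ))
  invisible(NULL)
})

setMethod("show", "DistanceRanges", function(object) {
  p <- object@pairs
  tab <- table(p$range)
  cat(sprintf(
    "DistanceRanges: %d cell-type pair(s); short=%d, mid=%d, long=%d\n",
    nrow(p), tab[["short"]], tab[["mid"]], tab[["long"]]
  ))
  cat(sprintf(
    "  mixture means: %.3g / %.3g / %.3g\n",
    object@mixture$means[1L], object@mixture$means[2L], object@mixture$means[3L]
  ))
  invisible(NULL)
})

setMethod("show", "BodySections", function(object) {
  tab <- table(object@nuclei$section)
  cat(sprintf(
    "BodySections along %s (intestine '%s' spans [%.3g, %.3g]): head=%d, mid-body=%d, tail=%d nuclei\n",
    object@axis, object@intestineLabel, object@span[1L], object@span[2L],
    tab[["head"]], tab[["mid-body"]], tab[["tail"]]
  ))
  invisible(NULL)
})
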