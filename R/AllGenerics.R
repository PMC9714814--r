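#' Cell-type labels of an object
#'
#' @param x an object carrying cell-type labels (a [PresenceMatrix-class],
#'   [CommunicationTensor-class], [CCIMatrix-class] or [CellAtlas-class]).
#' @return character vector of cell-type labels.
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' Number of ligand-receptor pairs
#'
#' @param x an [LRDatabase-class] or [CommunicationTensor-class].
#' @return integer count of LR pairs.
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' Score matrix / table extractor
#'
#' @param x an object holding scores ([CCIMatrix-class],
#'   [CommunicationTensor-class], [PresenceMatrix-class]).
#' @return the underlying matrix or array.
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

setMethod("cellTypes", "PresenceMatrix", function(x) colnames(x@presence))
setMethod("cellTypes", "CommunicationTensor", function(x) dimnames(x@scores)[[2L]])
setMethod("cellTypes", "CCIMatrix", function(x) rownames(x@scores))
setMethod("cellTypes", "CellAtlas", function(x) sort(unique(x@nuclei$cell_type)))

setMethod("nPairs", "LRDatabase", function(x) nrow(x@pairs))
setMethod("nPairs", "CommunicationTensor", function(x) dim(x@scores)[1L])

setMethod("scores", "CCIMatrix", function(x) x@scores)
setMethod("scores", "CommunicationTensor", function(x) x@scores)
setMethod("scores", "PresenceMatrix", function(x) x@presence)

#' @describeIn LRDatabase number of LR pairs.
#' @param x an LRDatabase.
#' @export
setMethod("length", "LRDatabase", function(x) nrow(x@pairs))
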