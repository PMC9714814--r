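#' Construct a CellAtlas
#'
#' @param nuclei data.frame with columns \code{nucleus_id}, \code{x},
#'   \code{y}, \code{z}, \code{cell_type}. Rows with a missing or empty
#'   label are dropped (only labeled nuclei are retained), with a message.
#' @return a [CellAtlas-class].
#' @export
CellAtlas <- function(nuclei) {
  nuclei <- as.data.frame(nuclei, stringsAsFactors = FALSE)
  lab <- nuclei$cell_type
  keep <- !is.na(lab) & nzchar(trimws(as.character(lab)))
  if (any(!keep)) {
    message(sum(!keep), " unlabeled nucleus/nuclei dropped from atlas")
    nuclei <- nuclei[keep, , drop = FALSE]
  }
  nuclei$cell_type <- trimws(as.character(nuclei$cell_type))
  nuclei$nucleus_id <- as.character(nuclei$nucleus_id)
  rownames(nuclei) <- NULL
  new("CellAtlas", nuclei = nuclei)
}

#' Read a 3D nucleus atlas from CSV/TSV
#'
#' Expected columns: \code{nucleus_id,x,y,z,cell_type}. Unlabeled nuclei
#' are dropped.
#'
#' @param path path to the atlas table.
#' @param delim field separator; inferred from extension when NULL.
#' @return a [CellAtlas-class].
#' @export
readAtlas <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delim)) delim <- .delimFromPath(path)
  tab <- utils::read.table(path,
    header = TRUE, sep = delim, quote = "\"",
    stringsAsFactors = FALSE, check.names = FALSE, comment.char = ""
  )
  req <- c("nucleus_id", "x", "y", "z", "cell_type")
  miss <- setdiff(req, colnames(tab))
  if (length(miss)) stop("atlas is missing column(s): ", paste(miss, collapse = ", "))
  CellAtlas(tab[, req])
}

#' Write an atlas to CSV/TSV
#' @param atlas a [CellAtlas-class].
#' @param path output path.
#' @param delim field separator; inferred from extension when NULL.
#' @return \code{path}, invisibly.
#' @export
writeAtlas <- function(atlas, path, delim = NULL) {
  stopifnot(is(atlas, "CellAtlas"))
  if (is.null(delim)) delim <- .delimFromPath(path)
  utils::write.table(atlas@nuclei, path, sep = delim, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Atlas nuclei accessor
#' @param atlas a [CellAtlas-class].
#' @return the nucleus data.frame.
#' @export
atlasNuclei <- function(atlas) {
  stopifnot(is(atlas, "CellAtlas"))
  atlas@nuclei
}

#' Minimum inter-nucleus distance between two cell types
#'
#' All nuclei of each type are compared pairwise and the minimal Euclidean
#' distance is used as the distance between the two cell types. The
#' distance of a type to itself is 0 by convention (autocrine pairs are
#' excluded from every downstream analysis).
#'
#' @param atlas a [CellAtlas-class].
#' @param A,B cell-type labels present in the atlas.
#' @return non-negative distance in atlas length units.
#' @export
cellTypeDistance <- function(atlas, A, B) {
  stopifnot(is(atlas, "CellAtlas"))
  n <- atlas@nuclei
  for (ty in unique(c(A, B))) {
    if (!ty %in% n$cell_type) stop("cell type absent from atlas: ", ty)
  }
  if (identical(A, B)) return(0)
  xa <- as.matrix(n[n$cell_type == A, c("x", "y", "z")])
  xb <- as.matrix(n[n$cell_type == B, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  sqrt(max(0, min(d2)))
}

#' Cell-type distance matrix from an atlas
#'
#' Symmetric matrix of minimum inter-nucleus Euclidean distances for every
#' pair of labeled cell types; zero diagonal.
#'
#' @param atlas a [CellAtlas-class].
#' @param types optional character vector restricting/ordering the cell
#'   types (default: all atlas types, sorted).
#' @return T x T numeric matrix with cell-type dimnames.
#' @export
distanceMatrix <- function(atlas, types = NULL) {
  stopifnot(is(atlas, "CellAtlas"))
  n <- atlas@nuclei
  if (is.null(types)) types <- sort(unique(n$cell_type))
  miss <- setdiff(types, n$cell_type)
  if (length(miss)) stop("cell type(s) absent from atlas: ",
                         paste(miss, collapse = ", "))
  xyz <- as.matrix(n[, c("x", "y", "z")])
  dAll <- as.matrix(stats::dist(xyz))
  out <- matrix(0, length(types), length(types),
                dimnames = list(types, types))
  idx <- split(seq_len(nrow(n)), n$cell_type)
  for (a in seq_along(types)) {
    for (b in seq_len(a - 1L)) {
      m <- min(dAll[idx[[types[a]]], idx[[types[b]]]])
      out[a, b] <- out[b, a] <- m
    }
  }
  out
}

#' Classify cell-type distances into short/mid/long ranges
#'
#' Fits a 3-component 1-D Gaussian mixture (unconstrained variances) to the
#' pairwise distances and assigns each unordered cell-type pair to its
#' maximum-posterior component; components are relabeled short/mid/long by
#' ascending mean. Posterior ties break toward the smaller-mean component.
#'
#' @param distances a symmetric distance matrix from [distanceMatrix()]
#'   (strict upper triangle is used) or a named list/data.frame with
#'   \code{typeA}, \code{typeB}, \code{distance} columns.
#' @param nComponents number of mixture components (default 3).
#' @param seed optional RNG seed (the mixture fit itself is deterministic
#'   given the data; the seed guards auxiliary randomness).
#' @return a [DistanceRanges-class].
#' @export
fitDistanceRanges <- function(distances, nComponents = 3, seed = NULL) {
  if (is.matrix(distances)) {
    ut <- which(upper.tri(distances), arr.ind = TRUE)
    df <- data.frame(
      typeA = rownames(distances)[ut[, 1L]],
      typeB = colnames(distances)[ut[, 2L]],
      distance = distances[ut],
      stringsAsFactors = FALSE
    )
  } else {
    df <- as.data.frame(distances, stringsAsFactors = FALSE)
    stopifnot(all(c("typeA", "typeB", "distance") %in% colnames(df)))
  }
  x <- df$distance
  if (length(unique(x)) < nComponents) {
    stop("need at least ", nComponents, " distinct distance values")
  }
  if (!is.null(seed)) set.seed(seed)
  # Mclust() re-evaluates mclustBIC() in the caller's frame, so bind it
  # locally to stay namespace-safe without attaching mclust.
  mclustBIC <- mclust::mclustBIC
  fit <- mclust::Mclust(x, G = nComponents, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) stop("Gaussian mixture fit failed (degenerate distances?)")
  means <- fit$parameters$mean
  ord <- order(means)
  post <- fit$z[, ord, drop = FALSE]
  # max-posterior assignment; ties toward the smaller-mean component
  cls <- apply(post, 1L, function(p) which(p >= max(p) - 1e-12)[1L])
  lev <- .RANGE_LEVELS[seq_len(nComponents)]
  df$range <- factor(lev[cls], levels = .RANGE_LEVELS)
  vars <- fit$parameters$variance$sigmasq
  if (length(vars) == 1L) vars <- rep(vars, nComponents)
  new("DistanceRanges",
    pairs = df,
    mixture = list(
      means = unname(means[ord]),
      variances = unname(vars[ord]),
      weights = unname(fit$parameters$pro[ord])
    )
  )
}

#' Distance-range pair table accessor
#' @param ranges a [DistanceRanges-class].
#' @return data.frame (typeA, typeB, distance, range).
#' @export
rangePairs <- function(ranges) {
  stopifnot(is(ranges, "DistanceRanges"))
  ranges@pairs
}

#' Partition the body into head / mid-body / tail sections
#'
#' The anteroposterior (AP) axis is either a declared coordinate or, with
#' \code{apAxis = "auto"}, the coordinate of maximal variance across nuclei.
#' The mid-body is the closed interval [min, max] spanned by the intestine
#' nuclei on that axis; nuclei strictly below are on the head side and
#' strictly above on the tail side (orientation configurable).
#'
#' @param atlas a [CellAtlas-class].
#' @param intestineLabel cell-type label whose nuclei define the mid-body.
#' @param apAxis \code{"auto"} (default), \code{"x"}, \code{"y"} or
#'   \code{"z"}.
#' @param headSide \code{"low"} (default: lower coordinates are the head)
#'   or \code{"high"}.
#' @return a [BodySections-class].
#' @export
assignBodySections <- function(atlas, intestineLabel,
                               apAxis = c("auto", "x", "y", "z"),
                               headSide = c("low", "high")) {
  stopifnot(is(atlas, "CellAtlas"))
  apAxis <- match.arg(apAxis)
  headSide <- match.arg(headSide)
  n <- atlas@nuclei
  if (!intestineLabel %in% n$cell_type) {
    stop("intestine label absent from atlas: ", intestineLabel)
  }
  if (apAxis == "auto") {
    v <- vapply(c("x", "y", "z"), function(a) stats::var(n[[a]]), numeric(1))
    apAxis <- names(v)[which.max(v)]
  }
  pos <- n[[apAxis]]
  span <- range(pos[n$cell_type == intestineLabel])
  below <- pos < span[1L]
  above <- pos > span[2L]
  section <- rep("mid-body", nrow(n))
  if (headSide == "low") {
    section[below] <- "head"; section[above] <- "tail"
  } else {
    section[below] <- "tail"; section[above] <- "head"
  }
  new("BodySections",
    nuclei = data.frame(
      nucleus_id = n$nucleus_id, cell_type = n$cell_type,
      axisPos = pos, section = factor(section, levels = .SECTION_LEVELS),
      stringsAsFactors = FALSE
    ),
    axis = apAxis, span = span, intestineLabel = intestineLabel
  )
}

#' Unordered cell-type pairs co-occurring in each body section
#'
#' A cell type belongs to a section if at least one of its nuclei lies
#' there; a pair belongs to every section containing both types. Autocrine
#' pairs are excluded.
#'
#' @param sections a [BodySections-class].
#' @return named list (head, mid-body, tail) of data.frames with columns
#'   \code{typeA}, \code{typeB} (typeA < typeB).
#' @export
sectionCellPairs <- function(sections) {
  stopifnot(is(sections, "BodySections"))
  n <- sections@nuclei
  out <- lapply(.SECTION_LEVELS, function(s) {
    types <- sort(unique(n$cell_type[n$section == s]))
    if (length(types) < 2L) {
      return(data.frame(typeA = character(), typeB = character(),
                        stringsAsFactors = FALSE))
    }
    cmb <- utils::combn(types, 2L)
    data.frame(typeA = cmb[1L, ], typeB = cmb[2L, ], stringsAsFactors = FALSE)
  })
  names(out) <- .SECTION_LEVELS
  out
}
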