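#' @import methods
NULL

.check2col <- function(m, what) {
  if (!is.matrix(m) || !is.numeric(m) || ncol(m) != 2L)
    return(sprintf("'%s' must be a numeric matrix with 2 columns", what))
  if (!all(is.finite(m)))
    return(sprintf("'%s' contains non-finite coordinates", what))
  NULL
}

#' Grid aggregation settings for velocity arrows
#'
#' Controls how per-cell velocity displacements are aggregated into grid
#' arrows: the number of grid rectangles per axis, the minimum number of
#' cells a rectangle must hold to emit an arrow, the fractional expansion of
#' the bounding box, a multiplier on the mean displacement, and whether an
#' arrow starts at the rectangle centre or at the mean position of its member
#' cells.
#'
#' @slot nGrid integer(1), grid rectangles per axis (>= 2).
#' @slot minCells integer(1), minimum cells per occupied rectangle (>= 1).
#' @slot marginFrac numeric(1), bounding-box expansion fraction (>= 0).
#' @slot arrowScale numeric(1), multiplier on the mean displacement (> 0).
#' @slot startAt character(1), \code{"center"} (grid-rectangle centre) or
#'   \code{"mean"} (mean member position).
#' @seealso [gridConfig()], [buildGridArrows()]
#' @exportClass GridConfig
setClass("GridConfig",
  representation(nGrid = "integer", minCells = "integer",
                 marginFrac = "numeric", arrowScale = "numeric",
                 startAt = "character"),
  prototype(nGrid = 30L, minCells = 2L, marginFrac = 0.02,
            arrowScale = 1.0, startAt = "center"))

setValidity("GridConfig", function(object) {
  msg <- character()
  if (length(object@nGrid) != 1L || is.na(object@nGrid) || object@nGrid < 2L)
    msg <- c(msg, "nGrid must be a single integer >= 2")
  if (length(object@minCells) != 1L || is.na(object@minCells) ||
      object@minCells < 1L)
    msg <- c(msg, "minCells must be a single integer >= 1")
  if (length(object@marginFrac) != 1L || !is.finite(object@marginFrac) ||
      object@marginFrac < 0)
    msg <- c(msg, "marginFrac must be a single finite number >= 0")
  if (length(object@arrowScale) != 1L || !is.finite(object@arrowScale) ||
      object@arrowScale <= 0)
    msg <- c(msg, "arrowScale must be a single finite number > 0")
  if (length(object@startAt) != 1L || !object@startAt %in% c("center", "mean"))
    msg <- c(msg, "startAt must be \"center\" or \"mean\"")
  if (length(msg)) msg else TRUE
})

#' Construct a GridConfig
#'
#' @param nGrid Grid rectangles per axis (default 30).
#' @param minCells Minimum cells per occupied rectangle (default 2).
#' @param marginFrac Bounding-box expansion fraction (default 0.02).
#' @param arrowScale Multiplier on the mean displacement (default 1).
#' @param startAt Arrow start rule, \code{"center"} or \code{"mean"}.
#' @return A [GridConfig-class] object.
#' @examples
#' gridConfig(nGrid = 20, minCells = 3)
#' @export
gridConfig <- function(nGrid = 30L, minCells = 2L, marginFrac = 0.02,
                       arrowScale = 1.0, startAt = c("center", "mean")) {
  startAt <- match.arg(startAt)
  new("GridConfig", nGrid = as.integer(nGrid), minCells = as.integer(minCells),
      marginFrac = as.numeric(marginFrac), arrowScale = as.numeric(arrowScale),
      startAt = startAt)
}

#' Grid-aggregated velocity arrows in one 2D view
#'
#' Each arrow summarizes the cells of one occupied grid rectangle: it starts
#' at \code{start[i, ]}, ends at \code{end[i, ]}, carries the majority-vote
#' cluster label of its member cells as its starting cluster, and records how
#' many cells it aggregates.
#'
#' @slot viewId character(1) identifier of the 2D perspective.
#' @slot start n x 2 numeric matrix of arrow start coordinates.
#' @slot end n x 2 numeric matrix of arrow end coordinates.
#' @slot startCluster character vector of starting-cluster labels.
#' @slot nCells integer vector of member-cell counts (all >= 1).
#' @seealso [buildGridArrows()], [scoreArrows()]
#' @exportClass VelocityArrows
setClass("VelocityArrows",
  representation(viewId = "character", start = "matrix", end = "matrix",
                 startCluster = "character", nCells = "integer"))

setValidity("VelocityArrows", function(object) {
  msg <- character()
  msg <- c(msg, .check2col(object@start, "start"), .check2col(object@end, "end"))
  n <- nrow(object@start)
  if (nrow(object@end) != n || length(object@startCluster) != n ||
      length(object@nCells) != n)
    msg <- c(msg, "start, end, startCluster and nCells must have equal length")
  if (length(object@nCells) && any(object@nCells < 1L))
    msg <- c(msg, "all nCells must be >= 1")
  if (length(object@viewId) != 1L)
    msg <- c(msg, "viewId must be a single string")
  if (length(msg)) msg else TRUE
})

#' Per-cluster centroids in one 2D view
#'
#' Holds one representative 2D coordinate per cluster label (the arithmetic
#' mean of the member-cell positions in the view plane).
#'
#' @slot viewId character(1) identifier of the 2D perspective.
#' @slot coords K x 2 numeric matrix, rownames = cluster labels.
#' @seealso [computeCentroids()], [distanceWeights()]
#' @exportClass CentroidSet
setClass("CentroidSet",
  representation(viewId = "character", coords = "matrix"))

setValidity("CentroidSet", function(object) {
  msg <- c(.check2col(object@coords, "coords"))
  labs <- rownames(object@coords)
  if (is.null(labs) || anyDuplicated(labs) || any(labs == ""))
    msg <- c(msg, "coords must have unique, non-empty cluster-label rownames")
  if (length(object@viewId) != 1L)
    msg <- c(msg, "viewId must be a single string")
  if (length(msg)) msg else TRUE
})

#' Composite transition score matrix
#'
#' The K x K directed composite transition scores between clusters
#' (rows = source, columns = destination), together with the unweighted raw
#' score totals, the per-view distance weights, and a log of arrow/pair skips
#' caused by degenerate geometry.
#'
#' @slot cts K x K numeric matrix of composite transition scores (diagonal 0).
#' @slot raw K x K numeric matrix of unweighted summed alignment scores.
#' @slot clusters character vector giving the row/column cluster order.
#' @slot views list of per-view detail lists (view axes, weight matrix,
#'   number of arrows).
#' @slot skips data.frame with columns \code{view}, \code{reason}, \code{n}
#'   accounting for pairs dropped due to degenerate geometry.
#' @seealso [composeCTS()], [multiviewCTS()], [ctsScores()], [rawTotals()]
#' @exportClass CTSMatrix
setClass("CTSMatrix",
  representation(cts = "matrix", raw = "matrix", clusters = "character",
                 views = "list", skips = "data.frame"))

setValidity("CTSMatrix", function(object) {
  msg <- character()
  K <- length(object@clusters)
  for (nm in c("cts", "raw")) {
    m <- slot(object, nm)
    if (!is.numeric(m) || nrow(m) != K || ncol(m) != K) {
      msg <- c(msg, sprintf("'%s' must be a %d x %d numeric matrix", nm, K, K))
      next
    }
    if (any(m < 0)) msg <- c(msg, sprintf("'%s' entries must be >= 0", nm))
    if (K && any(diag(m) != 0))
      msg <- c(msg, sprintf("'%s' diagonal must be exactly 0", nm))
  }
  if (anyDuplicated(object@clusters))
    msg <- c(msg, "cluster labels must be unique")
  if (length(msg)) msg else TRUE
})

#' Ground-truth scenario for synthetic velocity flow fields
#'
#' Describes Gaussian cell clusters in a D-dimensional embedding together
#' with a directed transition graph: cells of a source cluster receive
#' displacement vectors pointing at the destination cluster's centre
#' parameter, scaled by the edge speed, plus isotropic Gaussian noise.
#' Clusters without an outgoing edge are terminal and receive pure noise.
#'
#' @slot centers K x D numeric matrix of cluster centre parameters,
#'   rownames = cluster labels.
#' @slot nCells integer vector, cells per cluster (named as centers).
#' @slot spread numeric(1), isotropic Gaussian s.d. of cell positions around
#'   their centre (embedding units, > 0).
#' @slot edges data.frame with columns \code{from}, \code{to}, \code{speed}
#'   (embedding units per step, > 0).
#' @slot noiseSd numeric(1), s.d. of isotropic displacement noise (>= 0).
#' @slot seed integer(1), RNG seed making the scenario reproducible.
#' @seealso [flowScenario()], [chainScenario()], [simulateDataset()]
#' @exportClass FlowScenario
setClass("FlowScenario",
  representation(centers = "matrix", nCells = "integer", spread = "numeric",
                 edges = "data.frame", noiseSd = "numeric", seed = "integer"))

setValidity("FlowScenario", function(object) {
  msg <- character()
  cen <- object@centers
  if (!is.matrix(cen) || !is.numeric(cen) || !all(is.finite(cen)) ||
      !ncol(cen) %in% c(2L, 3L))
    msg <- c(msg, "centers must be a finite numeric matrix with 2 or 3 columns")
  labs <- rownames(cen)
  if (is.null(labs) || anyDuplicated(labs))
    msg <- c(msg, "centers must have unique cluster-label rownames")
  if (length(object@nCells) != nrow(cen) || any(object@nCells < 1L))
    msg <- c(msg, "nCells must give a count >= 1 for every cluster")
  if (length(object@spread) != 1L || !is.finite(object@spread) ||
      object@spread <= 0)
    msg <- c(msg, "spread must be a single finite number > 0")
  e <- object@edges
  if (!all(c("from", "to", "speed") %in% names(e))) {
    msg <- c(msg, "edges needs columns from, to, speed")
  } else if (nrow(e)) {
    if (!all(c(e$from, e$to) %in% labs))
      msg <- c(msg, "edge endpoints must be known cluster labels")
    if (any(e$speed <= 0)) msg <- c(msg, "edge speeds must be > 0")
    if (anyDuplicated(e$from) && anyDuplicated(paste(e$from, e$to)))
      msg <- c(msg, "duplicate edges are not allowed")
  }
  if (length(object@noiseSd) != 1L || !is.finite(object@noiseSd) ||
      object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be a single finite number >= 0")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

#' A simulated dataset with its generating scenario
#'
#' Aligned embedding coordinates, velocity displacement vectors and cluster
#' labels drawn from a [FlowScenario-class], reproducible from the scenario's
#' seed.
#'
#' @slot embedding n x D numeric matrix, rownames = cell barcodes.
#' @slot velocity n x D numeric matrix of displacement vectors, same
#'   rownames and order as \code{embedding}.
#' @slot clusters named character vector of per-cell cluster labels.
#' @slot scenario the generating [FlowScenario-class].
#' @seealso [simulateDataset()]
#' @exportClass SyntheticDataset
setClass("SyntheticDataset",
  representation(embedding = "matrix", velocity = "matrix",
                 clusters = "character", scenario = "FlowScenario"))

setValidity("SyntheticDataset", function(object) {
  msg <- character()
  n <- nrow(object@embedding)
  if (nrow(object@velocity) != n || length(object@clusters) != n)
    msg <- c(msg, "embedding, velocity and clusters must be aligned")
  if (!identical(rownames(object@embedding), rownames(object@velocity)) ||
      !identical(rownames(object@embedding), names(object@clusters)))
    msg <- c(msg, "barcodes must agree across embedding, velocity and clusters")
  if (length(msg)) msg else TRUE
})
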