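#' Cluster labels of an object
#'
#' @param x A [CentroidSet-class], [CTSMatrix-class] or [FlowScenario-class].
#' @return Character vector of cluster labels.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' Composite transition scores
#'
#' @param x A [CTSMatrix-class].
#' @return K x K numeric matrix (rows = source cluster, columns =
#'   destination cluster).
#' @export
setGeneric("ctsScores", function(x) standardGeneric("ctsScores"))

#' Unweighted raw score totals
#'
#' @param x A [CTSMatrix-class].
#' @return K x K numeric matrix of summed per-arrow alignment scores.
#' @export
setGeneric("rawTotals", function(x) standardGeneric("rawTotals"))

#' Per-view distance weights and arrow counts
#'
#' @param x A [CTSMatrix-class].
#' @return List with one element per view: axes, weight matrix, arrow count.
#' @export
setGeneric("viewDetails", function(x) standardGeneric("viewDetails"))

#' Degenerate-geometry skip log
#'
#' Arrows or (arrow, destination) pairs dropped because a side of the
#' alignment triangle had zero length are counted per view and reason so that
#' silent data loss is detectable.
#'
#' @param x A [CTSMatrix-class] or [VelocityArrows-class]-derived score set.
#' @return data.frame with columns \code{view}, \code{reason}, \code{n}.
#' @export
setGeneric("skipLog", function(x) standardGeneric("skipLog"))

#' Centroid coordinates
#'
#' @param x A [CentroidSet-class].
#' @return K x 2 numeric matrix with cluster-label rownames.
#' @export
setGeneric("centroidCoords", function(x) standardGeneric("centroidCoords"))

setMethod("clusterLabels", "CentroidSet", function(x) rownames(x@coords))
setMethod("clusterLabels", "CTSMatrix", function(x) x@clusters)
setMethod("clusterLabels", "FlowScenario", function(x) rownames(x@centers))

setMethod("ctsScores", "CTSMatrix", function(x) x@cts)
setMethod("rawTotals", "CTSMatrix", function(x) x@raw)
setMethod("viewDetails", "CTSMatrix", function(x) x@views)
setMethod("skipLog", "CTSMatrix", function(x) x@skips)
setMethod("centroidCoords", "CentroidSet", function(x) x@coords)

#' @describeIn VelocityArrows-class number of arrows
#' @param x A \code{VelocityArrows} object.
#' @export
setMethod("length", "VelocityArrows", function(x) nrow(x@start))

#' Arrows as a data.frame
#'
#' @param x A [VelocityArrows-class].
#' @param row.names,optional,... Passed over for S3 compatibility; unused.
#' @return data.frame with columns \code{view}, \code{x0}, \code{y0},
#'   \code{x1}, \code{y1}, \code{startCluster}, \code{nCells}.
#' @export
as.data.frame.VelocityArrows <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(view = rep(x@viewId, length(x)),
             x0 = x@start[, 1], y0 = x@start[, 2],
             x1 = x@end[, 1], y1 = x@end[, 2],
             startCluster = x@startCluster, nCells = x@nCells,
             stringsAsFactors = FALSE)
}

setMethod("show", "VelocityArrows", function(object) {
  cat(sprintf("VelocityArrows: %d arrows in view '%s'\n",
              length(object), object@viewId))
  tab <- table(object@startCluster)
  cat("  starting clusters:",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  cat(sprintf("  cells aggregated: %d\n", sum(object@nCells)))
})

setMethod("show", "CentroidSet", function(object) {
  cat(sprintf("CentroidSet: %d clusters in view '%s'\n",
              nrow(object@coords), object@viewId))
  print(round(object@coords, 3))
})

setMethod("show", "CTSMatrix", function(object) {
  K <- length(object@clusters)
  cat(sprintf("CTSMatrix: %d clusters, %d view(s)\n", K, length(object@views)))
  cat("  composite transition scores (rows = source, cols = destination):\n")
  print(signif(object@cts, 4))
  nsk <- if (nrow(object@skips)) sum(object@skips$n) else 0L
  cat(sprintf("  skipped degenerate pairs/arrows: %d\n", nsk))
})

setMethod("show", "FlowScenario", function(object) {
  cat(sprintf("FlowScenario: %d clusters in %dD, %d cells, seed %d\n",
              nrow(object@centers), ncol(object@centers),
              sum(object@nCells), object@seed))
  if (nrow(object@edges)) {
    cat("  transitions:",
        paste(sprintf("%s->%s (speed %g)", object@edges$from,
                      object@edges$to, object@edges$speed), collapse = ", "),
        "\n")
  } else cat("  transitions: none (all clusters terminal)\n")
  cat(sprintf("  spread %g, noiseSd %g\n", object@spread, object@noiseSd))
})

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf("SyntheticDataset: %d cells in %dD, %d clusters\n",
              nrow(object@embedding), ncol(object@embedding),
              nrow(object@scenario@centers)))
})

#' Embedding coordinates of a synthetic dataset
#' @param x A [SyntheticDataset-class].
#' @return n x D numeric matrix with barcode rownames.
#' @export
setGeneric("embeddingCoords", function(x) standardGeneric("embeddingCoords"))

#' Velocity displacement vectors of a synthetic dataset
#' @param x A [SyntheticDataset-class].
#' @return n x D numeric matrix with barcode rownames.
#' @export
setGeneric("velocityVectors", function(x) standardGeneric("velocityVectors"))

#' Per-cell cluster assignment of a synthetic dataset
#' @param x A [SyntheticDataset-class].
#' @return Named character vector (names = barcodes).
#' @export
setGeneric("cellClusters", function(x) standardGeneric("cellClusters"))

#' Generating scenario of a synthetic dataset
#' @param x A [SyntheticDataset-class].
#' @return The [FlowScenario-class] used to generate the data.
#' @export
setGeneric("flowTruth", function(x) standardGeneric("flowTruth"))

setMethod("embeddingCoords", "SyntheticDataset", function(x) x@embedding)
setMethod("velocityVectors", "SyntheticDataset", function(x) x@velocity)
setMethod("cellClusters", "SyntheticDataset", function(x) x@clusters)
setMethod("flowTruth", "SyntheticDataset", function(x) x@scenario)
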