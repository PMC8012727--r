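## From per-cell embeddings + velocity displacements + cluster labels to
## grid-aggregated arrows and the multi-perspective CTS matrix.

.checkAligned <- function(embedding, velocity, clusters) {
  if (!is.matrix(embedding) || !is.numeric(embedding) ||
      !all(is.finite(embedding)))
    stop("embedding must be a finite numeric matrix (cells x dimensions)",
         call. = FALSE)
  if (!is.matrix(velocity) || !identical(dim(velocity), dim(embedding)) ||
      !all(is.finite(velocity)))
    stop("velocity must be a finite numeric matrix matching the embedding",
         call. = FALSE)
  if (length(clusters) != nrow(embedding))
    stop("clusters must assign one label per cell", call. = FALSE)
  eb <- rownames(embedding)
  if (!is.null(eb)) {
    for (pair in list(c("velocity", "embedding"), c("clusters", "embedding"))) {
      other <- if (pair[1] == "velocity") rownames(velocity)
               else names(clusters)
      if (is.null(other)) next
      miss <- setdiff(eb, other); extra <- setdiff(other, eb)
      if (length(miss) || length(extra))
        stop(sprintf(
          "cell sets differ between %s and %s: %d missing (e.g. %s), %d extra (e.g. %s)",
          pair[1], pair[2], length(miss),
          paste(utils::head(miss, 3), collapse = ", "),
          length(extra), paste(utils::head(extra, 3), collapse = ", ")),
          call. = FALSE)
      if (!identical(other, eb))
        stop(pair[1], " rows are ordered differently from the embedding; ",
             "reorder them to match", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Project a D-dimensional embedding and velocity field onto a 2D view
#'
#' Selects two axes (1-based) from the embedding and displacement tables,
#' preserving cell order. For a 3D UMAP, the two default perspectives are
#' axes (1, 3) and (2, 3) — UMAP1 vs UMAP3 and UMAP2 vs UMAP3.
#'
#' @param embedding n x D numeric matrix of cell coordinates (D = 2 or 3),
#'   rownames = cell barcodes.
#' @param velocity n x D numeric matrix of displacement vectors, aligned with
#'   \code{embedding}.
#' @param view Integer vector of 2 distinct 1-based axis indices.
#' @return List with \code{pos} and \code{disp}, both n x 2 matrices, and
#'   \code{viewId} (e.g. \code{"axes 1,3"}).
#' @examples
#' e <- matrix(1:6, 2, 3); v <- e / 10
#' projectView(e, v, c(1, 3))$pos
#' @export
projectView <- function(embedding, velocity, view) {
  view <- as.integer(view)
  D <- ncol(embedding)
  if (length(view) != 2L || anyDuplicated(view) || any(view < 1L) ||
      any(view > D))
    stop(sprintf("view must be 2 distinct axis indices in 1..%d", D),
         call. = FALSE)
  list(pos = embedding[, view, drop = FALSE],
       disp = velocity[, view, drop = FALSE],
       viewId = paste0("axes ", paste(view, collapse = ",")))
}

#' Majority vote over cluster labels
#'
#' Returns the most frequent label; ties are broken by the lexicographically
#' smallest label so the result is deterministic and independent of input
#' order.
#'
#' @param labels Non-empty character vector (the labels of the cells in one
#'   grid rectangle).
#' @return A single label.
#' @examples
#' majorityVote(c("A", "A", "B"))  # "A"
#' majorityVote(c("B", "A"))       # "A" (tie-break)
#' @export
majorityVote <- function(labels) {
  if (length(labels) == 0L)
    stop("majority vote over an empty label set", call. = FALSE)
  tab <- table(as.character(labels))
  winners <- names(tab)[tab == max(tab)]
  min(winners)
}

#' Aggregate per-cell displacements into grid arrows
#'
#' Lays a regular \code{nGrid} x \code{nGrid} grid over the (margin-expanded)
#' bounding box of the 2D positions. Every rectangle holding at least
#' \code{minCells} cells emits one arrow: its start is the rectangle centre
#' (or the mean member position if \code{startAt = "mean"}), its end is the
#' start plus \code{arrowScale} times the mean member displacement, its
#' starting cluster is the majority vote of member labels, and it records the
#' member count. Sparser rectangles emit nothing.
#'
#' @param pos n x 2 numeric matrix of cell positions in the view plane.
#' @param disp n x 2 numeric matrix of displacement vectors, aligned with
#'   \code{pos}.
#' @param clusters Character vector of per-cell labels (length n).
#' @param config A [GridConfig-class]; see [gridConfig()].
#' @param viewId Identifier stored on the arrows (default \code{"view"}).
#' @return A [VelocityArrows-class]; zero-length for an empty input.
#' @export
buildGridArrows <- function(pos, disp, clusters, config = gridConfig(),
                            viewId = "view") {
  stopifnot(is(config, "GridConfig"))
  clusters <- as.character(clusters)
  if (!is.matrix(pos) || ncol(pos) != 2L ||
      !identical(dim(disp), dim(pos)) || length(clusters) != nrow(pos))
    stop("pos, disp and clusters must be aligned (n x 2, n x 2, n)",
         call. = FALSE)
  n <- nrow(pos)
  mk <- function() {
    m0 <- matrix(numeric(), 0, 2)
    new("VelocityArrows", viewId = viewId, start = m0, end = m0,
        startCluster = character(), nCells = integer())
  }
  if (n == 0L) return(mk())
  G <- config@nGrid
  lo <- apply(pos, 2, min); hi <- apply(pos, 2, max)
  width <- hi - lo
  width[width == 0] <- 1  # degenerate axis: give it unit extent
  lo <- lo - config@marginFrac * width
  hi <- hi + config@marginFrac * width
  stepx <- (hi[1] - lo[1]) / G; stepy <- (hi[2] - lo[2]) / G
  bx <- pmin(G, pmax(1L, ceiling((pos[, 1] - lo[1]) / stepx)))
  by <- pmin(G, pmax(1L, ceiling((pos[, 2] - lo[2]) / stepy)))
  cellOf <- (bx - 1L) * G + by
  groups <- split(seq_len(n), cellOf)
  groups <- groups[lengths(groups) >= config@minCells]
  if (!length(groups)) return(mk())
  ## deterministic order: by grid index
  groups <- groups[order(as.integer(names(groups)))]
  gid <- as.integer(names(groups))
  gx <- (gid - 1L) %/% G + 1L
  gy <- (gid - 1L) %% G + 1L
  centers <- cbind(lo[1] + (gx - 0.5) * stepx, lo[2] + (gy - 0.5) * stepy)
  meanDisp <- t(vapply(groups, function(ix)
    colMeans(disp[ix, , drop = FALSE]), numeric(2)))
  starts <- if (config@startAt == "center") centers
            else t(vapply(groups, function(ix)
              colMeans(pos[ix, , drop = FALSE]), numeric(2)))
  labs <- vapply(groups, function(ix) majorityVote(clusters[ix]), character(1))
  dimnames(starts) <- NULL; dimnames(meanDisp) <- NULL
  new("VelocityArrows", viewId = viewId,
      start = starts, end = starts + config@arrowScale * meanDisp,
      startCluster = unname(labs), nCells = unname(lengths(groups)))
}

#' Cluster centroids in the view plane
#'
#' The centroid of a cluster is the arithmetic mean of its member-cell 2D
#' coordinates, computed in the plane where arrow alignment and distance
#' weighting are measured.
#'
#' @param pos n x 2 numeric matrix of cell positions.
#' @param clusters Character vector of per-cell labels (length n).
#' @param viewId Identifier stored on the centroid set.
#' @return A [CentroidSet-class].
#' @examples
#' computeCentroids(rbind(c(0, 0), c(2, 0)), c("A", "A"))
#' @export
computeCentroids <- function(pos, clusters, viewId = "view") {
  clusters <- as.character(clusters)
  if (!is.matrix(pos) || ncol(pos) != 2L || nrow(pos) != length(clusters))
    stop("pos must be an n x 2 matrix aligned with clusters", call. = FALSE)
  if (nrow(pos) == 0L)
    stop("cannot compute centroids from zero cells", call. = FALSE)
  f <- factor(clusters)
  co <- rowsum(pos, f) / as.vector(table(f))
  co <- co[order(rownames(co)), , drop = FALSE]
  new("CentroidSet", viewId = viewId, coords = unname(co) |>
        `rownames<-`(sort(levels(f))))
}

.defaultViews <- function(D) {
  if (D == 2L) list(c(1L, 2L))
  else if (D == 3L) list(c(1L, 3L), c(2L, 3L))
  else stop("embedding must have 2 or 3 dimensions", call. = FALSE)
}

#' Multi-perspective composite transition score
#'
#' Runs the full pipeline for each 2D perspective of the embedding —
#' projection, grid-arrow aggregation, centroid computation, per-pair
#' alignment scoring, per-transition summation, distance weighting and
#' composition — and sums the per-view CTS matrices element-wise into the
#' final matrix. Weights are computed from each view's own centroid geometry
#' (centroid distances are only defined within a view's plane). For a 3D
#' embedding the default perspectives are axes (1, 3) and (2, 3); a 2D
#' embedding uses its single plane.
#'
#' @param embedding n x D numeric matrix (D = 2 or 3), rownames = barcodes.
#' @param velocity n x D numeric matrix of displacements, aligned.
#' @param clusters Character vector (optionally named by barcode) of per-cell
#'   labels; at least 2 distinct labels required.
#' @param views List of integer pairs of 1-based axis indices, or \code{NULL}
#'   for the dimension-appropriate defaults.
#' @param config A [GridConfig-class].
#' @param convention Alignment convention, \code{"endpoint"} or
#'   \code{"origin"}; see [alignmentCosine()].
#' @return A [CTSMatrix-class]; \code{viewDetails()} exposes each view's
#'   weight matrix and arrow count, \code{skipLog()} the aggregated skip
#'   counts.
#' @examples
#' sc <- chainScenario(D = 2, nPerCluster = 60, seed = 7)
#' ds <- simulateDataset(sc)
#' cts <- multiviewCTS(embeddingCoords(ds), velocityVectors(ds),
#'                     cellClusters(ds))
#' ctsScores(cts)
#' @export
multiviewCTS <- function(embedding, velocity, clusters, views = NULL,
                         config = gridConfig(),
                         convention = c("endpoint", "origin")) {
  convention <- match.arg(convention)
  clusters <- stats::setNames(as.character(clusters), names(clusters))
  .checkAligned(embedding, velocity, clusters)
  labs <- sort(unique(clusters))
  if (length(labs) < 2L)
    stop("no transitions definable: fewer than 2 clusters", call. = FALSE)
  if (is.null(views)) views <- .defaultViews(ncol(embedding))
  if (!length(views)) stop("at least one view is required", call. = FALSE)
  K <- length(labs)
  ctsSum <- rawSum <- matrix(0, K, K, dimnames = list(labs, labs))
  details <- list()
  skips <- data.frame(view = character(), reason = character(),
                      n = integer(), stringsAsFactors = FALSE)
  for (v in views) {
    pv <- projectView(embedding, velocity, v)
    arrows <- buildGridArrows(pv$pos, pv$disp, clusters, config,
                              viewId = pv$viewId)
    cen <- computeCentroids(pv$pos, clusters, viewId = pv$viewId)
    ps <- scoreArrows(arrows, cen, convention)
    raw <- sumByTransition(ps, labs)
    w <- distanceWeights(cen)
    ctsV <- raw * w
    diag(ctsV) <- 0
    ctsSum <- ctsSum + ctsV
    rawSum <- rawSum + raw
    skips <- rbind(skips, attr(ps, "skips"))
    details[[pv$viewId]] <- list(axes = as.integer(v), weights = w,
                                 nArrows = length(arrows))
  }
  new("CTSMatrix", cts = ctsSum, raw = rawSum, clusters = labs,
      views = details, skips = skips)
}
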