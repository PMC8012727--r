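## Core geometry of the composite transition score.
##
## Each grid arrow runs from X (start) to Y (end); Z is a destination-cluster
## centroid. Alignment is the cosine of the triangle angle, computed by the
## law of cosines, under one of two conventions:
##   endpoint: angle at the arrow tip Y, between Y->X and Y->Z;
##             perfect alignment (Z ahead of the arrow) gives cos = -1 and
##             the score uses (1 - cos).
##   origin:   angle at the arrow origin X, between X->Y and X->Z;
##             perfect alignment gives cos = +1 and the score uses (1 + cos).
## Both conventions are maximal when the arrow points at the centroid and
## zero when it points directly away.

.sqlen <- function(v) rowSums(v * v)

## Vectorized law-of-cosines over n (X, Y, Z) triples given as n x 2
## matrices. Returns cos (clamped to [-1, 1]) and a degeneracy reason
## (zero-length triangle side in the active convention); degenerate entries
## carry NA cosine.
.lawCosine <- function(X, Y, Z, convention) {
  d2xy <- .sqlen(Y - X)
  d2xz <- .sqlen(Z - X)
  d2yz <- .sqlen(Z - Y)
  if (convention == "endpoint") {
    num <- d2xy + d2yz - d2xz
    den <- 2 * sqrt(d2xy * d2yz)
    bad <- ifelse(d2xy == 0, "zero-length arrow",
                  ifelse(d2yz == 0, "arrow end at centroid", NA_character_))
  } else {
    num <- d2xy + d2xz - d2yz
    den <- 2 * sqrt(d2xy * d2xz)
    bad <- ifelse(d2xy == 0, "zero-length arrow",
                  ifelse(d2xz == 0, "arrow start at centroid", NA_character_))
  }
  cosv <- ifelse(is.na(bad), pmin(1, pmax(-1, num / den)), NA_real_)
  list(cos = cosv, reason = bad,
       lenXY = sqrt(d2xy), lenXZ = sqrt(d2xz))
}

.asPoint <- function(p, what) {
  if (!is.numeric(p) || length(p) != 2L || !all(is.finite(p)))
    stop(sprintf("'%s' must be a finite numeric vector of length 2", what),
         call. = FALSE)
  matrix(p, nrow = 1L)
}

.degenerateStop <- function(reason) {
  stop(errorCondition(paste("degenerate geometry:", reason),
                      class = c("velocts_degenerate_geometry", "error")))
}

#' Alignment cosine between a velocity arrow and a destination centroid
#'
#' Computes, by the law of cosines on the triangle (X = arrow start,
#' Y = arrow end, Z = destination centroid), the cosine of the alignment
#' angle. Under the \code{"endpoint"} convention this is the angle at the
#' arrow tip Y (between Y\eqn{\to}X and Y\eqn{\to}Z); under the
#' \code{"origin"} convention the angle at the arrow start X (between
#' X\eqn{\to}Y and X\eqn{\to}Z), so that a perfectly aligned collinear arrow
#' yields cosine 1. Results are clamped to \eqn{[-1, 1]} to absorb
#' floating-point overshoot on near-collinear triangles.
#'
#' @param start,end Numeric length-2 vectors: arrow start X and end Y.
#' @param centroid Numeric length-2 vector: destination centroid Z.
#' @param convention \code{"endpoint"} (default) or \code{"origin"}.
#' @return A single cosine in \eqn{[-1, 1]}.
#' @section Errors:
#' A zero-length side of the active convention (zero-length arrow, or the
#' relevant endpoint coinciding with the centroid) raises a condition of
#' class \code{velocts_degenerate_geometry}; bulk scoring skips and counts
#' such pairs.
#' @examples
#' alignmentCosine(c(0, 0), c(1, 0), c(2, 0), convention = "origin")  # 1
#' alignmentCosine(c(0, 0), c(1, 0), c(2, 0))                         # -1
#' @export
alignmentCosine <- function(start, end, centroid,
                            convention = c("endpoint", "origin")) {
  convention <- match.arg(convention)
  g <- .lawCosine(.asPoint(start, "start"), .asPoint(end, "end"),
                  .asPoint(centroid, "centroid"), convention)
  if (!is.na(g$reason)) .degenerateStop(g$reason)
  g$cos
}

#' Alignment score of one arrow towards one destination centroid
#'
#' The per-pair transition score combines the alignment cosine with the
#' arrow length |XY| (velocity strength, rewarding) and the start-to-centroid
#' distance |XZ| (penalizing):
#' \deqn{S = (1 - \cos\theta_Y) \, |XY| / |XZ|}{S = (1 - cos) * |XY| / |XZ|}
#' under the endpoint convention, and \eqn{S = (1 + \cos\theta_X)\,|XY|/|XZ|}
#' under the origin convention. Either form is non-negative, grows as the
#' arrow aligns with the direction towards the centroid, and is zero at
#' perfect anti-alignment.
#'
#' @inheritParams alignmentCosine
#' @return A single non-negative score.
#' @examples
#' arrowScore(c(0, 0), c(1, 0), c(2, 0))  # 1: aligned, |XY|/|XZ| = 1/2
#' arrowScore(c(0, 0), c(-1, 0), c(2, 0)) # 0: points directly away
#' @export
arrowScore <- function(start, end, centroid,
                       convention = c("endpoint", "origin")) {
  convention <- match.arg(convention)
  X <- .asPoint(start, "start"); Y <- .asPoint(end, "end")
  Z <- .asPoint(centroid, "centroid")
  g <- .lawCosine(X, Y, Z, convention)
  if (!is.na(g$reason)) .degenerateStop(g$reason)
  if (g$lenXZ == 0) .degenerateStop("arrow start at centroid")
  sgn <- if (convention == "endpoint") 1 - g$cos else 1 + g$cos
  sgn * g$lenXY / g$lenXZ
}

#' Score every arrow against every non-self destination cluster
#'
#' Evaluates [arrowScore()] for each (arrow, destination cluster) pair,
#' excluding the arrow's own starting cluster (self-transitions carry no
#' information and would otherwise dominate). Pairs with degenerate geometry
#' (e.g. zero-length arrows) are skipped and accounted for in the
#' \code{"skips"} attribute of the result.
#'
#' @param arrows A [VelocityArrows-class] object.
#' @param centroids A [CentroidSet-class] sharing the arrows' \code{viewId}.
#' @param convention \code{"endpoint"} (default) or \code{"origin"}.
#' @return data.frame with columns \code{arrow} (index), \code{source},
#'   \code{destination}, \code{cosTheta}, \code{score}; attribute
#'   \code{"skips"} is a data.frame (\code{view}, \code{reason}, \code{n}).
#' @examples
#' arr <- buildGridArrows(matrix(c(0, 0, 1, 1), 2), matrix(c(1, 1, 0, 0), 2),
#'                        c(a = "A", b = "B"), gridConfig(nGrid = 2,
#'                        minCells = 1))
#' cen <- new("CentroidSet", viewId = "v",
#'            coords = matrix(c(0, 4, 0, 0), 2,
#'                            dimnames = list(c("A", "B"), NULL)))
#' @export
scoreArrows <- function(arrows, centroids,
                        convention = c("endpoint", "origin")) {
  convention <- match.arg(convention)
  stopifnot(is(arrows, "VelocityArrows"), is(centroids, "CentroidSet"))
  if (arrows@viewId != centroids@viewId)
    stop("arrows and centroids come from different views: ",
         arrows@viewId, " vs ", centroids@viewId, call. = FALSE)
  labs <- clusterLabels(centroids)
  unknown <- setdiff(unique(arrows@startCluster), labs)
  if (length(unknown))
    stop("arrow starting cluster(s) not in centroid set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  n <- length(arrows)
  empty <- data.frame(arrow = integer(), source = character(),
                      destination = character(), cosTheta = numeric(),
                      score = numeric(), stringsAsFactors = FALSE)
  skips0 <- data.frame(view = character(), reason = character(),
                       n = integer(), stringsAsFactors = FALSE)
  if (n == 0L) {
    attr(empty, "skips") <- skips0
    return(empty)
  }
  ## expand all (arrow, destination != source) pairs
  K <- length(labs)
  ai <- rep(seq_len(n), each = K)
  dj <- rep(labs, times = n)
  keep <- dj != arrows@startCluster[ai]
  ai <- ai[keep]; dj <- dj[keep]
  X <- arrows@start[ai, , drop = FALSE]
  Y <- arrows@end[ai, , drop = FALSE]
  Z <- centroids@coords[dj, , drop = FALSE]
  g <- .lawCosine(X, Y, Z, convention)
  reason <- g$reason
  reason[is.na(reason) & g$lenXZ == 0] <- "arrow start at centroid"
  ok <- is.na(reason)
  sgn <- if (convention == "endpoint") 1 - g$cos else 1 + g$cos
  out <- data.frame(arrow = ai[ok], source = arrows@startCluster[ai[ok]],
                    destination = dj[ok], cosTheta = g$cos[ok],
                    score = (sgn * g$lenXY / g$lenXZ)[ok],
                    stringsAsFactors = FALSE)
  if (any(!ok)) {
    tab <- table(reason[!ok])
    skips0 <- data.frame(view = arrows@viewId, reason = names(tab),
                         n = as.integer(tab), stringsAsFactors = FALSE)
  }
  attr(out, "skips") <- skips0
  out
}

#' Sum per-pair scores into a raw source-by-destination matrix
#'
#' Classifies every scored pair by the arrow's starting cluster and sums the
#' scores per (source, destination) transition. The diagonal is zero by
#' construction (self-pairs are never scored).
#'
#' @param pairScores data.frame as returned by [scoreArrows()].
#' @param clusterOrder Character vector fixing the row/column order.
#' @return K x K numeric matrix of summed scores.
#' @export
sumByTransition <- function(pairScores, clusterOrder) {
  stopifnot(is.data.frame(pairScores),
            all(c("source", "destination", "score") %in% names(pairScores)))
  if (anyDuplicated(clusterOrder))
    stop("clusterOrder contains duplicate labels", call. = FALSE)
  bad <- setdiff(unique(c(pairScores$source, pairScores$destination)),
                 clusterOrder)
  if (length(bad))
    stop("pair scores reference unknown cluster(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  K <- length(clusterOrder)
  m <- matrix(0, K, K, dimnames = list(clusterOrder, clusterOrder))
  if (nrow(pairScores)) {
    agg <- tapply(pairScores$score,
                  list(factor(pairScores$source, clusterOrder),
                       factor(pairScores$destination, clusterOrder)),
                  sum)
    agg[is.na(agg)] <- 0
    m[] <- agg
  }
  m
}

#' Distance-based weights between cluster centroids
#'
#' For every destination cluster, the Euclidean distances z from all other
#' cluster centroids are rescaled to a weight
#' \deqn{w = 1 - (z - \min z) / (\max z - \min z)}{w = 1 - (z - min z)/(max z - min z)}
#' so the nearest source cluster receives weight 1 and the farthest weight 0:
#' transitions between nearby clusters are up-weighted. Self-distances are
#' excluded from each destination's distance set (otherwise the zero
#' self-distance would pin \eqn{\min z = 0} and no source could reach weight
#' 1). When all candidate distances towards a destination are equal —
#' including the two-cluster case — every weight is set to 1, as no relative
#' penalty is definable from a single distance value.
#'
#' @param centroids A [CentroidSet-class] with at least 2 clusters.
#' @return K x K numeric matrix of weights in \eqn{[0, 1]} (rows = source,
#'   columns = destination) with \code{NA} on the diagonal.
#' @examples
#' cen <- new("CentroidSet", viewId = "v",
#'            coords = matrix(c(0, 1, 3, 0, 0, 0), 3,
#'                            dimnames = list(c("A", "B", "C"), NULL)))
#' distanceWeights(cen)["B", "A"]  # 1: B is the nearest source to A
#' distanceWeights(cen)["C", "A"]  # 0: C is the farthest
#' @export
distanceWeights <- function(centroids) {
  stopifnot(is(centroids, "CentroidSet"))
  co <- centroids@coords
  K <- nrow(co)
  if (K < 2L)
    stop("no transitions definable: fewer than 2 clusters", call. = FALSE)
  d <- as.matrix(stats::dist(co))
  labs <- rownames(co)
  w <- matrix(NA_real_, K, K, dimnames = list(labs, labs))
  for (j2 in seq_len(K)) {
    src <- setdiff(seq_len(K), j2)
    z <- d[src, j2]
    rng <- max(z) - min(z)
    w[src, j2] <- if (rng == 0) 1 else 1 - (z - min(z)) / rng
  }
  w
}

#' Compose the weighted CTS matrix
#'
#' Multiplies, entry-wise, the raw summed scores by the centroid-distance
#' weights, yielding the composite transition score
#' \eqn{CTS_{j_1,j_2} = w_{j_1,j_2} \times \sum S_{i,j_2}}. The raw totals
#' are stored alongside.
#'
#' @param rawTotals K x K numeric matrix from [sumByTransition()].
#' @param weights K x K weight matrix from [distanceWeights()].
#' @param clusterOrder Character vector of cluster labels (row/column order
#'   of both matrices).
#' @param views Optional list of per-view detail records.
#' @param skips Optional skip-log data.frame.
#' @return A [CTSMatrix-class].
#' @export
composeCTS <- function(rawTotals, weights, clusterOrder,
                       views = list(), skips = NULL) {
  K <- length(clusterOrder)
  if (!identical(dim(rawTotals), c(K, K)) || !identical(dim(weights), c(K, K)))
    stop("rawTotals and weights must both be ", K, " x ", K, " matrices",
         call. = FALSE)
  offdiag <- row(weights) != col(weights)
  if (any(is.na(weights[offdiag])))
    stop("weights must cover all off-diagonal cluster pairs", call. = FALSE)
  cts <- rawTotals * weights
  diag(cts) <- 0
  dimnames(cts) <- list(clusterOrder, clusterOrder)
  if (is.null(skips))
    skips <- data.frame(view = character(), reason = character(),
                        n = integer(), stringsAsFactors = FALSE)
  new("CTSMatrix", cts = cts, raw = rawTotals, clusters = clusterOrder,
      views = views, skips = skips)
}

#' Log2 display transform of a CTS matrix
#'
#' Returns \code{log2(CTS)} entry-wise to dampen extreme signals when
#' plotting. Zero entries (no measured flow) are masked as \code{NA} rather
#' than pseudo-counted: zero flow is qualitatively different from small flow,
#' and a pseudo-count would fabricate an ordering among zeros. The transform
#' is monotone on the positive entries.
#'
#' @param cts A [CTSMatrix-class] or a non-negative numeric matrix.
#' @return Numeric matrix of the same shape; \code{NA} where the input is 0.
#' @examples
#' m <- matrix(c(0, 8, 1, 0), 2, dimnames = list(c("A","B"), c("A","B")))
#' log2Display(m)
#' @export
log2Display <- function(cts) {
  m <- if (is(cts, "CTSMatrix")) ctsScores(cts) else cts
  stopifnot(is.numeric(m), all(m >= 0))
  out <- m
  out[m == 0] <- NA_real_
  out[m > 0] <- log2(m[m > 0])
  out
}
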