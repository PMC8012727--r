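# Shared fixture builders for the suite. All randomness is seeded locally.

# independent oracle: cosine of the convention's angle via normalized dot
# product of the direction vectors (endpoint: Y->X with Y->Z; origin:
# X->Y with X->Z)
dotCosine <- function(X, Y, Z, convention) {
  if (convention == "endpoint") { u <- X - Y; v <- Z - Y }
  else { u <- Y - X; v <- Z - X }
  sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
}

randomTriangle <- function() {
  repeat {
    pts <- matrix(stats::runif(6, -10, 10), 3, 2)
    d <- as.matrix(stats::dist(pts))
    if (min(d[upper.tri(d)]) > 1e-3) return(pts)
  }
}

makeCentroidSet <- function(coords, labels, viewId = "view") {
  rownames(coords) <- labels
  new("CentroidSet", viewId = viewId, coords = coords)
}

makeArrows <- function(start, end, startCluster, viewId = "view") {
  new("VelocityArrows", viewId = viewId,
      start = start, end = end, startCluster = startCluster,
      nCells = rep(1L, nrow(start)))
}

# geometry-level random instance: arrows with labels + centroid set
randomInstance <- function(nArrows = 12, K = 4) {
  labs <- LETTERS[seq_len(K)]
  cen <- matrix(stats::runif(K * 2, -5, 5), K, 2)
  start <- matrix(stats::runif(nArrows * 2, -5, 5), nArrows, 2)
  end <- start + matrix(stats::rnorm(nArrows * 2, sd = 0.5), nArrows, 2)
  list(arrows = makeArrows(start, end, sample(labs, nArrows, replace = TRUE)),
       centroids = makeCentroidSet(cen, labs))
}

toyCountsPath <- function(file) {
  system.file("extdata", "toy_counts", file, package = "velocts",
              mustWork = TRUE)
}

# 10 cells with total counts 1..10, one distinct gene each, no forbidden
# markers: isolates the top-percentile stage
totalsLadderCounts <- function() {
  m <- matrix(0L, 2, 10,
              dimnames = list(c("G1", "G2"), paste0("cell", 1:10)))
  m["G1", ] <- 1:10
  m
}
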