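test_that("view projection selects the named axes and preserves order", {
  e <- rbind(c(1, 2, 3), c(4, 5, 6))
  v <- rbind(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))
  pv <- projectView(e, v, c(1, 3))
  expect_equal(pv$pos, e[, c(1, 3)])
  expect_equal(pv$disp[1, ], c(0.1, 0.3))
  pv2 <- projectView(e, v, c(2, 3))
  expect_equal(pv2$disp[2, ], c(0.5, 0.6))
  # identity on 2D input
  e2 <- e[, 1:2]; v2 <- v[, 1:2]
  pv3 <- projectView(e2, v2, c(1, 2))
  expect_identical(pv3$pos, e2)
  expect_identical(pv3$disp, v2)
  expect_error(projectView(e2, v2, c(1, 3)), "axis indices")
})

test_that("majority vote picks the mode and breaks ties lexicographically", {
  expect_equal(majorityVote(c("A", "A", "B")), "A")
  expect_equal(majorityVote(c("B", "A")), "A")
  expect_equal(majorityVote("C"), "C")
  # order independence under ties
  expect_equal(majorityVote(c("b", "a", "b", "a")), "a")
  expect_error(majorityVote(character()), "empty")
})

test_that("grid arrows aggregate member displacements from rectangle centres", {
  pos <- rbind(c(0.4, 0.4), c(0.6, 0.6), c(0.5, 0.4), c(0.5, 0.6),
               c(3.5, 3.4), c(3.6, 3.6))
  disp <- rbind(c(1, 0), c(1, 0), c(1, 0), c(1, 0),
                c(0, -1), c(0, -1))
  labs <- c("A", "A", "B", "A", "B", "B")
  cfg <- gridConfig(nGrid = 2, minCells = 2, marginFrac = 0)
  arr <- buildGridArrows(pos, disp, labs, cfg)
  expect_equal(length(arr), 2L)
  df <- as.data.frame(arr)
  # bbox [0.4, 3.6]^2, step 1.6: rectangle centres (1.2, 1.2) and (2.8, 2.8)
  lower <- df[df$x0 < 2, ]
  expect_equal(c(lower$x0, lower$y0), c(1.2, 1.2))
  expect_equal(c(lower$x1, lower$y1), c(2.2, 1.2))  # +mean disp (1, 0)
  expect_equal(lower$startCluster, "A")              # 3 A vs 1 B
  expect_equal(lower$nCells, 4L)
  upper <- df[df$x0 > 2, ]
  expect_equal(c(upper$x1, upper$y1), c(2.8, 1.8))
  expect_equal(upper$startCluster, "B")
})

test_that("rectangles below the cell threshold emit no arrow", {
  pos <- rbind(c(0, 0), c(0.1, 0.1), c(5, 5))
  disp <- matrix(0.1, 3, 2)
  arr <- buildGridArrows(pos, disp, c("A", "A", "B"),
                         gridConfig(nGrid = 2, minCells = 2))
  expect_equal(length(arr), 1L)
  expect_equal(arr@startCluster, "A")
  # empty input is valid
  expect_equal(length(buildGridArrows(matrix(numeric(), 0, 2),
                                      matrix(numeric(), 0, 2), character(),
                                      gridConfig())), 0L)
})

test_that("grid aggregation is cell-order invariant and monotone in minCells", {
  set.seed(31)
  n <- 300
  pos <- matrix(runif(2 * n, 0, 10), n, 2)
  disp <- matrix(rnorm(2 * n, sd = 0.3), n, 2)
  labs <- sample(c("A", "B", "C"), n, replace = TRUE)
  cfg <- gridConfig(nGrid = 8, minCells = 2)
  a1 <- buildGridArrows(pos, disp, labs, cfg)
  perm <- sample(n)
  a2 <- buildGridArrows(pos[perm, ], disp[perm, ], labs[perm], cfg)
  expect_equal(as.data.frame(a1), as.data.frame(a2))
  # arrow count bounded by grid size and never grows with minCells
  prev <- Inf
  for (mc in c(1, 2, 4, 8)) {
    nArr <- length(buildGridArrows(pos, disp, labs,
                                   gridConfig(nGrid = 8, minCells = mc)))
    expect_lte(nArr, 64)
    expect_lte(nArr, prev)
    prev <- nArr
  }
  expect_lte(sum(a1@nCells), n)
})

test_that("centroids are per-cluster coordinate means", {
  cen <- computeCentroids(rbind(c(0, 0), c(2, 0)), c("A", "A"))
  expect_equal(unname(centroidCoords(cen)["A", ]), c(1, 0))
  cen2 <- computeCentroids(rbind(c(5, 5)), "B")
  expect_equal(unname(centroidCoords(cen2)["B", ]), c(5, 5))
  set.seed(37)
  pos <- matrix(runif(40), 20, 2)
  labs <- sample(c("A", "B"), 20, replace = TRUE)
  cen3 <- centroidCoords(computeCentroids(pos, labs))
  for (l in c("A", "B"))
    expect_equal(unname(cen3[l, ]), colMeans(pos[labs == l, , drop = FALSE]))
})

test_that("single-view multiviewCTS equals the composed geometry pipeline", {
  ds <- simulateDataset(chainScenario(D = 2, nPerCluster = 80, seed = 5))
  emb <- embeddingCoords(ds); vel <- velocityVectors(ds)
  cl <- cellClusters(ds)
  cfg <- gridConfig(nGrid = 12)
  got <- multiviewCTS(emb, vel, cl, config = cfg)

  pv <- projectView(emb, vel, c(1, 2))
  arr <- buildGridArrows(pv$pos, pv$disp, cl, cfg, viewId = pv$viewId)
  cen <- computeCentroids(pv$pos, cl, viewId = pv$viewId)
  labs <- sort(unique(cl))
  want <- composeCTS(sumByTransition(scoreArrows(arr, cen), labs),
                     distanceWeights(cen), labs)
  expect_equal(ctsScores(got), ctsScores(want))
  expect_equal(rawTotals(got), rawTotals(want))
})

test_that("duplicated views double the CTS exactly", {
  ds <- simulateDataset(chainScenario(D = 2, nPerCluster = 60, seed = 9))
  one <- multiviewCTS(embeddingCoords(ds), velocityVectors(ds),
                      cellClusters(ds), views = list(c(1, 2)))
  two <- multiviewCTS(embeddingCoords(ds), velocityVectors(ds),
                      cellClusters(ds), views = list(c(1, 2), c(1, 2)))
  expect_equal(ctsScores(two), 2 * ctsScores(one))
  expect_equal(rawTotals(two), 2 * rawTotals(one))
})

test_that("noise-free flow towards destination centres is recovered at modest grids", {
  sc <- chainScenario(D = 3, nPerCluster = 150, noiseSd = 0, seed = 21)
  ds <- simulateDataset(sc)
  for (g in c(4, 10, 30)) {
    cts <- multiviewCTS(embeddingCoords(ds), velocityVectors(ds),
                        cellClusters(ds), config = gridConfig(nGrid = g))
    expect_equal(evaluateRecovery(cts, sc), 1.0)
  }
})

test_that("multiviewCTS validates alignment and cluster count", {
  ds <- simulateDataset(chainScenario(D = 2, nPerCluster = 30, seed = 2))
  emb <- embeddingCoords(ds)
  vel <- velocityVectors(ds)
  badVel <- vel
  rownames(badVel)[1] <- "intruder"
  expect_error(multiviewCTS(emb, badVel, cellClusters(ds)), "intruder")
  oneCluster <- setNames(rep("A", nrow(emb)), rownames(emb))
  expect_error(multiviewCTS(emb, vel, oneCluster), "no transitions definable")
})
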