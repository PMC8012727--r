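test_that("alignment cosine matches analytic anchors in both conventions", {
  X <- c(0, 0); Y <- c(1, 0); Z <- c(2, 0)
  # collinear arrow pointing at the centroid
  expect_equal(alignmentCosine(X, Y, Z, convention = "origin"), 1)
  expect_equal(alignmentCosine(X, Y, Z, convention = "endpoint"), -1)
  # right-angle-ish case frozen from the dot-product oracle: Y->X = (0,-1),
  # Y->Z = (2,-1), cos = 1/sqrt(5)
  expect_equal(alignmentCosine(c(0, 0), c(0, 1), c(2, 0)), 1 / sqrt(5))
})

test_that("law-of-cosines cosine equals the dot-product oracle on random triangles", {
  set.seed(42)
  for (i in 1:1000) {
    p <- randomTriangle()
    for (conv in c("endpoint", "origin")) {
      expect_equal(alignmentCosine(p[1, ], p[2, ], p[3, ], conv),
                   dotCosine(p[1, ], p[2, ], p[3, ], conv),
                   tolerance = 1e-9)
    }
  }
})

test_that("degenerate triangle sides raise the degenerate-geometry condition", {
  expect_error(alignmentCosine(c(0, 0), c(0, 0), c(1, 1)),
               class = "velocts_degenerate_geometry")
  # arrow end coincides with centroid: degenerate for endpoint only
  expect_error(alignmentCosine(c(0, 0), c(1, 0), c(1, 0), "endpoint"),
               class = "velocts_degenerate_geometry")
  expect_equal(alignmentCosine(c(0, 0), c(1, 0), c(1, 0), "origin"), 1)
  # arrow start at centroid: degenerate for origin and for the score
  expect_error(alignmentCosine(c(0, 0), c(1, 0), c(0, 0), "origin"),
               class = "velocts_degenerate_geometry")
  expect_error(arrowScore(c(0, 0), c(1, 0), c(0, 0), "endpoint"),
               class = "velocts_degenerate_geometry")
})

test_that("arrow score anchors and non-negativity hold", {
  # aligned collinear arrow halfway to the centroid scores 1 either way
  expect_equal(arrowScore(c(0, 0), c(1, 0), c(2, 0), "endpoint"), 1)
  expect_equal(arrowScore(c(0, 0), c(1, 0), c(2, 0), "origin"), 1)
  # arrow pointing directly away scores exactly 0
  expect_equal(arrowScore(c(0, 0), c(-1, 0), c(2, 0), "endpoint"), 0)
  expect_equal(arrowScore(c(0, 0), c(-1, 0), c(2, 0), "origin"), 0)
  set.seed(7)
  for (i in 1:200) {
    p <- randomTriangle()
    for (conv in c("endpoint", "origin"))
      expect_gte(arrowScore(p[1, ], p[2, ], p[3, ], conv), 0)
  }
})

test_that("score grows with arrow length and shrinks with centroid distance", {
  Z <- c(10, 0)
  short <- arrowScore(c(0, 0), c(1, 0), Z)
  long <- arrowScore(c(0, 0), c(2, 0), Z)
  expect_gt(long, short)
  near <- arrowScore(c(5, 0), c(6, 0), Z)
  expect_gt(near, short)
})

test_that("scoreArrows excludes self, matches pairwise scoring, and counts skips", {
  cen <- makeCentroidSet(rbind(c(0, 0), c(4, 0), c(0, 4)), c("A", "B", "C"))
  one <- makeArrows(rbind(c(0.5, 0.5)), rbind(c(1, 0.5)), "A")
  ps <- scoreArrows(one, cen)
  expect_equal(nrow(ps), 2L)           # destinations B and C only
  expect_false("A" %in% ps$destination)

  none <- makeArrows(matrix(numeric(), 0, 2), matrix(numeric(), 0, 2),
                     character())
  expect_equal(nrow(scoreArrows(none, cen)), 0L)

  two <- makeArrows(rbind(c(0, 0.5), c(3, 1)), rbind(c(1, 0.6), c(3.5, 0.5)),
                    c("A", "B"))
  ps2 <- scoreArrows(two, cen, "endpoint")
  for (r in seq_len(nrow(ps2))) {
    i <- ps2$arrow[r]
    expect_equal(ps2$score[r],
                 arrowScore(two@start[i, ], two@end[i, ],
                            centroidCoords(cen)[ps2$destination[r], ],
                            "endpoint"))
  }

  # zero-length arrow: both its pairs skipped and accounted for
  degen <- makeArrows(rbind(c(1, 1), c(0, 0.5)), rbind(c(1, 1), c(1, 0.6)),
                      c("A", "A"))
  psd <- scoreArrows(degen, cen)
  expect_equal(nrow(psd), 2L)
  sk <- attr(psd, "skips")
  expect_equal(sum(sk$n), 2L)
  expect_match(sk$reason, "zero-length")
})

test_that("scoreArrows validates view identity and cluster labels", {
  cen <- makeCentroidSet(rbind(c(0, 0), c(4, 0)), c("A", "B"))
  arr <- makeArrows(rbind(c(0, 0.5)), rbind(c(1, 0.5)), "Z")
  expect_error(scoreArrows(arr, cen), "not in centroid set")
  cen2 <- makeCentroidSet(rbind(c(0, 0), c(4, 0)), c("A", "Z"),
                          viewId = "other")
  expect_error(scoreArrows(arr, cen2), "different views")
})

test_that("per-transition sums are additive and match a brute-force double loop", {
  ps <- data.frame(arrow = 1:2, source = c("A", "A"),
                   destination = c("B", "B"), cosTheta = 0,
                   score = c(0.5, 0.25))
  m <- sumByTransition(ps, c("A", "B", "C"))
  expect_equal(m["A", "B"], 0.75)
  expect_true(all(diag(m) == 0))
  expect_equal(sum(m), sum(ps$score))

  empty <- ps[0, ]
  expect_true(all(sumByTransition(empty, c("A", "B")) == 0))

  set.seed(11)
  inst <- randomInstance(nArrows = 15, K = 4)
  labs <- clusterLabels(inst$centroids)
  ps2 <- scoreArrows(inst$arrows, inst$centroids)
  got <- sumByTransition(ps2, labs)
  want <- matrix(0, 4, 4, dimnames = list(labs, labs))
  for (r in seq_len(nrow(ps2)))
    want[ps2$source[r], ps2$destination[r]] <-
      want[ps2$source[r], ps2$destination[r]] + ps2$score[r]
  expect_equal(got, want)
})

test_that("distance weights rescale to [0, 1] with nearest source at 1", {
  cen <- makeCentroidSet(rbind(c(0, 0), c(1, 0), c(3, 0)), c("A", "B", "C"))
  w <- distanceWeights(cen)
  expect_equal(w["B", "A"], 1)   # nearest source to destination A
  expect_equal(w["C", "A"], 0)   # farthest
  expect_true(all(is.na(diag(w))))

  # K = 2: single candidate distance, no relative penalty definable
  w2 <- distanceWeights(makeCentroidSet(rbind(c(0, 0), c(5, 5)),
                                        c("A", "B")))
  expect_equal(w2["A", "B"], 1)
  expect_equal(w2["B", "A"], 1)

  expect_error(distanceWeights(makeCentroidSet(rbind(c(0, 0)), "A")),
               "no transitions definable")
})

test_that("distance weights match an independent pairwise-distance recomputation", {
  set.seed(13)
  co <- matrix(runif(10, -5, 5), 5, 2)
  labs <- LETTERS[1:5]
  w <- distanceWeights(makeCentroidSet(co, labs))
  for (j2 in 1:5) {
    z <- sapply(setdiff(1:5, j2), function(j1)
      sqrt(sum((co[j1, ] - co[j2, ])^2)))
    want <- 1 - (z - min(z)) / (max(z) - min(z))
    expect_equal(unname(w[setdiff(1:5, j2), j2]), want)
    expect_equal(max(w[, j2], na.rm = TRUE), 1)
    expect_equal(min(w[, j2], na.rm = TRUE), 0)
  }
})

test_that("CTS composition multiplies raw totals by weights entry-wise", {
  labs <- c("A", "B")
  raw <- matrix(c(0, 0.2, 0.75, 0), 2, dimnames = list(labs, labs))
  w <- matrix(c(NA, 0.4, 0.5, NA), 2, dimnames = list(labs, labs))
  cts <- composeCTS(raw, w, labs)
  expect_equal(ctsScores(cts)["A", "B"], 0.375)
  expect_equal(ctsScores(cts)["B", "A"], 0.08)
  expect_equal(rawTotals(cts), raw)

  zero <- composeCTS(raw * 0, w, labs)
  expect_true(all(ctsScores(zero) == 0))

  set.seed(17)
  labs4 <- LETTERS[1:4]
  raw4 <- matrix(runif(16), 4, dimnames = list(labs4, labs4))
  diag(raw4) <- 0
  w4 <- distanceWeights(makeCentroidSet(matrix(runif(8), 4, 2), labs4))
  cts4 <- ctsScores(composeCTS(raw4, w4, labs4))
  for (i in 1:4) for (j in setdiff(1:4, i))
    expect_equal(cts4[i, j], raw4[i, j] * w4[i, j])

  expect_error(composeCTS(raw, w[1, , drop = FALSE], labs), "2 x 2")
})

test_that("log2 display transforms positives and masks zeros", {
  labs <- c("A", "B")
  raw <- matrix(c(0, 1, 8, 0), 2, dimnames = list(labs, labs))
  w <- matrix(c(NA, 1, 1, NA), 2, dimnames = list(labs, labs))
  d <- log2Display(composeCTS(raw, w, labs))
  expect_equal(d["A", "B"], 3)
  expect_equal(d["B", "A"], 0)
  expect_true(is.na(d["A", "A"]))
  # monotone on positive entries
  vals <- c(0.25, 2, 16, 1024)
  expect_equal(order(log2Display(matrix(vals, 1))), order(vals))
})

test_that("CTS is invariant to rigid motion and uniform scaling of the plane", {
  set.seed(23)
  inst <- randomInstance(nArrows = 20, K = 4)
  labs <- clusterLabels(inst$centroids)
  base <- ctsScores(composeCTS(
    sumByTransition(scoreArrows(inst$arrows, inst$centroids), labs),
    distanceWeights(inst$centroids), labs))
  for (rep in 1:10) {
    th <- runif(1, 0, 2 * pi); s <- runif(1, 0.2, 5)
    R <- s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    tr <- runif(2, -20, 20)
    f <- function(m) sweep(m %*% t(R), 2, tr, `+`)
    arrT <- makeArrows(f(inst$arrows@start), f(inst$arrows@end),
                       inst$arrows@startCluster)
    cenT <- makeCentroidSet(f(centroidCoords(inst$centroids)), labs)
    got <- ctsScores(composeCTS(
      sumByTransition(scoreArrows(arrT, cenT), labs),
      distanceWeights(cenT), labs))
    expect_equal(got, base, tolerance = 1e-6)
  }
})
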