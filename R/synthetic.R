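## Synthetic Gaussian-cluster embeddings with a ground-truth directed
## transition graph, for validating the CTS pipeline end-to-end.

#' Construct a FlowScenario
#'
#' @param centers K x D numeric matrix of cluster centre parameters
#'   (D = 2 or 3), rownames = cluster labels.
#' @param nCells Integer, cells per cluster; recycled to K if length 1.
#' @param spread Isotropic s.d. of cell positions around their centre.
#' @param edges data.frame(from, to, speed): directed transitions; cells of
#'   \code{from} drift towards the centre of \code{to} at \code{speed}
#'   embedding units per step. Clusters without an outgoing edge are
#'   terminal.
#' @param noiseSd S.d. of isotropic Gaussian noise added to every
#'   displacement.
#' @param seed Integer RNG seed.
#' @return A [FlowScenario-class].
#' @export
flowScenario <- function(centers, nCells, spread, edges, noiseSd, seed = 1L) {
  if (length(nCells) == 1L) nCells <- rep(nCells, nrow(centers))
  new("FlowScenario", centers = centers,
      nCells = stats::setNames(as.integer(nCells), rownames(centers)),
      spread = as.numeric(spread),
      edges = as.data.frame(edges, stringsAsFactors = FALSE),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

#' Default four-cluster chain scenario
#'
#' A bent chain A -> B -> C -> D of well-separated Gaussian clusters (D is
#' terminal). Centre spacing is about 7 embedding units; the default spread
#' (1.2) is below 0.2 of the minimum centre distance, the drift speed is 1
#' unit per step, and the displacement noise s.d. is 0.1 of the speed —
#' i.e. clearly separated clusters with a velocity field dominated by the
#' true flow. The 3D centres are chosen so that both default perspectives
#' (axes 1,3 and 2,3) separate all four clusters.
#'
#' @param D Embedding dimension, 2 or 3.
#' @param nPerCluster Cells per cluster (default 200).
#' @param spread Positional s.d. (default 1.2).
#' @param speed Drift speed on every edge (default 1).
#' @param noiseSd Displacement noise s.d. (default \code{0.1 * speed}).
#' @param seed Integer RNG seed.
#' @return A [FlowScenario-class].
#' @examples
#' chainScenario(D = 2, nPerCluster = 50, seed = 3)
#' @export
chainScenario <- function(D = 3L, nPerCluster = 200L, spread = 1.2,
                          speed = 1.0, noiseSd = 0.1 * speed, seed = 1L) {
  D <- as.integer(D)
  centers <- if (D == 2L) {
    rbind(A = c(0, 0), B = c(6, 3), C = c(12, 0), D = c(18, 3))
  } else if (D == 3L) {
    rbind(A = c(0, 0, 0), B = c(6, 2, 4), C = c(12, -2, 8),
          D = c(18, 1, 12))
  } else stop("D must be 2 or 3", call. = FALSE)
  edges <- data.frame(from = c("A", "B", "C"), to = c("B", "C", "D"),
                      speed = speed, stringsAsFactors = FALSE)
  flowScenario(centers, nPerCluster, spread, edges, noiseSd, seed)
}

.scenarioBarcodes <- function(scenario) {
  sprintf("cell_%05d", seq_len(sum(scenario@nCells)))
}

#' Simulate cell positions and cluster labels from a scenario
#'
#' Draws each cell from an isotropic Gaussian centred at its cluster's
#' centre parameter with the scenario's spread. Deterministic given the
#' scenario seed.
#'
#' @param scenario A [FlowScenario-class].
#' @return List with \code{embedding} (n x D matrix, barcode rownames) and
#'   \code{clusters} (named character vector).
#' @export
simulateEmbedding <- function(scenario) {
  stopifnot(is(scenario, "FlowScenario"))
  set.seed(scenario@seed)
  labs <- rownames(scenario@centers)
  D <- ncol(scenario@centers)
  clusters <- rep(labs, times = scenario@nCells)
  n <- length(clusters)
  pos <- scenario@centers[clusters, , drop = FALSE] +
    matrix(stats::rnorm(n * D, sd = scenario@spread), n, D)
  bc <- .scenarioBarcodes(scenario)
  dimnames(pos) <- list(bc, NULL)
  list(embedding = pos, clusters = stats::setNames(clusters, bc))
}

#' Simulate velocity displacement vectors from a scenario
#'
#' A cell in a source cluster with an outgoing edge receives a displacement
#' of length \code{speed} pointing from the cell's position towards the
#' destination cluster's centre parameter (not its empirical centroid, so
#' the ground truth is independent of sampling noise), plus isotropic
#' Gaussian noise with s.d. \code{noiseSd}. Cells in terminal clusters
#' receive pure noise. Deterministic given the scenario seed.
#'
#' @param embedding n x D matrix of cell positions.
#' @param clusters Per-cell labels aligned with \code{embedding}.
#' @param scenario A [FlowScenario-class].
#' @return n x D displacement matrix with the embedding's rownames.
#' @export
simulateVelocity <- function(embedding, clusters, scenario) {
  stopifnot(is(scenario, "FlowScenario"))
  if (!all(clusters %in% rownames(scenario@centers)))
    stop("clusters contain labels unknown to the scenario", call. = FALSE)
  set.seed(scenario@seed + 1L)
  n <- nrow(embedding); D <- ncol(embedding)
  disp <- matrix(0, n, D, dimnames = dimnames(embedding))
  e <- scenario@edges
  for (k in seq_len(nrow(e))) {
    ix <- which(clusters == e$from[k])
    if (!length(ix)) next
    tow <- matrix(scenario@centers[e$to[k], ], length(ix), D, byrow = TRUE) -
      embedding[ix, , drop = FALSE]
    len <- sqrt(rowSums(tow^2))
    atTarget <- len < 1e-12  # cell exactly at the target centre: no drift
    len[atTarget] <- 1
    tow[atTarget, ] <- 0
    disp[ix, ] <- disp[ix, , drop = FALSE] + e$speed[k] * tow / len
  }
  if (scenario@noiseSd > 0)
    disp <- disp + matrix(stats::rnorm(n * D, sd = scenario@noiseSd), n, D)
  disp
}

#' Simulate an aligned embedding + velocity + labels dataset
#'
#' Convenience wrapper drawing positions with [simulateEmbedding()] and
#' displacements with [simulateVelocity()] from one scenario.
#'
#' @param scenario A [FlowScenario-class].
#' @return A [SyntheticDataset-class].
#' @examples
#' ds <- simulateDataset(chainScenario(D = 2, nPerCluster = 40, seed = 2))
#' ds
#' @export
simulateDataset <- function(scenario) {
  emb <- simulateEmbedding(scenario)
  vel <- simulateVelocity(emb$embedding, emb$clusters, scenario)
  new("SyntheticDataset", embedding = emb$embedding, velocity = vel,
      clusters = emb$clusters, scenario = scenario)
}

#' Default gene panel for simulated count matrices
#'
#' A small panel mixing forbidden lineage markers, clonotype-specific Ig/TCR
#' symbols and ordinary B-cell genes, so simulated matrices exercise both
#' the QC filters and the pruning rules.
#'
#' @return data.frame with columns \code{gene}, \code{rate} (Poisson mean
#'   per cell) and \code{role} (\code{forbidden}, \code{clonotype} or
#'   \code{ordinary}).
#' @export
defaultGenePanel <- function() {
  data.frame(
    gene = c(qcForbiddenGenes(),
             "IGHV1-69", "IGKC", "IGLL5", "TRBV7-2", "IGHM",
             "CD19", "MS4A1", "CD79A", "CD79B", "TCL1A", "CD27", "CD38",
             "HLA-DRA", "CD74", "ACTB"),
    rate = c(rep(0, 8), rep(1.5, 5), rep(2.5, 10)),
    role = c(rep("forbidden", 8), rep("clonotype", 5), rep("ordinary", 10)),
    stringsAsFactors = FALSE)
}

#' Simulate a toy genes x cells count matrix
#'
#' Counts are Poisson with per-gene rates; a configurable fraction of cells
#' is "contaminated" with guaranteed nonzero counts in one randomly chosen
#' forbidden gene (simulating non-B cells or doublets), so stage-1 QC
#' removals are exercised deterministically. Reproducible given the seed.
#'
#' @param nCells Number of cells (>= 1).
#' @param panel Gene panel data.frame as from [defaultGenePanel()].
#' @param forbiddenFraction Fraction of cells given forbidden-gene counts
#'   (default 0.05).
#' @param seed Integer RNG seed.
#' @return Sparse \code{dgCMatrix}, genes x cells, with symbol rownames and
#'   barcode colnames.
#' @export
simulateCounts <- function(nCells, panel = defaultGenePanel(),
                           forbiddenFraction = 0.05, seed = 1L) {
  stopifnot(nCells >= 1L, forbiddenFraction >= 0, forbiddenFraction <= 1)
  set.seed(as.integer(seed))
  G <- nrow(panel)
  m <- matrix(stats::rpois(G * nCells, lambda = panel$rate), G, nCells)
  forb <- which(panel$role == "forbidden")
  nBad <- round(forbiddenFraction * nCells)
  if (nBad > 0 && length(forb)) {
    bad <- sample.int(nCells, nBad)
    hitGene <- sample(forb, nBad, replace = TRUE)
    m[cbind(hitGene, bad)] <- stats::rpois(nBad, 2) + 1L
  }
  dimnames(m) <- list(panel$gene, sprintf("bc_%05d", seq_len(nCells)))
  Matrix::Matrix(m, sparse = TRUE)
}

#' Fraction of true transitions recovered by a CTS matrix
#'
#' For every non-terminal source cluster of the scenario, checks whether the
#' destination with the (strictly) largest CTS from that source matches a
#' true edge destination; ties for the maximum count as failures. Returns
#' the fraction of sources recovered.
#'
#' @param cts A [CTSMatrix-class] whose clusters include the scenario's.
#' @param scenario The generating [FlowScenario-class].
#' @return A fraction in \eqn{[0, 1]} (NaN if the scenario has no edges).
#' @export
evaluateRecovery <- function(cts, scenario) {
  stopifnot(is(cts, "CTSMatrix"), is(scenario, "FlowScenario"))
  labs <- clusterLabels(cts)
  if (!all(rownames(scenario@centers) %in% labs))
    stop("CTS matrix lacks scenario cluster(s)", call. = FALSE)
  e <- scenario@edges
  sources <- unique(e$from)
  if (!length(sources)) return(NaN)
  m <- ctsScores(cts)
  hit <- vapply(sources, function(s) {
    row <- m[s, setdiff(labs, s)]
    mx <- max(row)
    winners <- names(row)[row == mx]
    length(winners) == 1L && winners %in% e$to[e$from == s]
  }, logical(1))
  mean(hit)
}
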