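## Single-cell QC filters and immunoglobulin/TCR variable-gene pruning.
## Counts are genes x cells sparse (dgCMatrix) or dense integer matrices
## with gene-symbol rownames and barcode colnames.

#' Default forbidden lineage-marker genes for B-cell QC
#'
#' Non-B lineage markers whose expression disqualifies a cell: T cell
#' (CD3E, CD8A), NK (GNLY, FCGR3A), monocyte/DC (CD14, LYZ, FCER1A,
#' FCGR3A) and platelet (PPBP) markers. \code{strict = TRUE} substitutes the
#' non-standard symbol GCGR3A for FCGR3A, reproducing a symbol misprint that
#' circulates in some published marker lists; FCGR3A (CD16) is the intended
#' NK/monocyte marker and is the default.
#'
#' @param strict Logical; use the verbatim misprinted symbol GCGR3A instead
#'   of FCGR3A.
#' @return Character vector of gene symbols.
#' @export
qcForbiddenGenes <- function(strict = FALSE) {
  c("CD3E", "GNLY", "CD14", "FCER1A", if (strict) "GCGR3A" else "FCGR3A",
    "LYZ", "PPBP", "CD8A")
}

#' Immunoglobulin constant-region genes removed from variable-feature lists
#'
#' The Ig heavy/light constant-region symbols plus AC233755.1 (which encodes
#' IGHV4-38-2) that are pruned so clonotype- or isotype-specific usage does
#' not drive clustering.
#'
#' @return Character vector of gene symbols.
#' @export
igConstantGenes <- function() {
  c("IGHM", "IGHD", "IGHE", "IGHA1", "IGHA2",
    paste0("IGHG", 1:4), "IGKC", paste0("IGLC", 1:7), "AC233755.1")
}

#' Default pruning patterns for clonotype-specific genes
#'
#' Prefix-anchored regular expressions covering Ig V/D/J segments
#' (\code{IG[HKL][VDJ]}), T-cell-receptor constant/variable segments
#' (\code{TR[ABGD][CV]}) and the IGLL surrogate-light-chain family. Patterns
#' match from the first character of the symbol: \code{IG[HKL][VDJ]} must
#' catch IGHV1-69 and its kin without removing unrelated symbols that merely
#' contain the substring.
#'
#' @return Character vector of anchored regular expressions.
#' @export
pruningPatterns <- function() {
  c("^IG[HKL][VDJ]", "^TR[ABGD][CV]", "^IGLL")
}

.totalsPerCell <- function(counts) {
  if (methods::is(counts, "sparseMatrix")) Matrix::colSums(counts)
  else colSums(counts)
}

.genesPerCell <- function(counts) {
  if (methods::is(counts, "sparseMatrix")) Matrix::colSums(counts >= 1)
  else colSums(counts >= 1)
}

#' Nearest-rank quantile
#'
#' The q-quantile of \code{x} defined as the \code{ceiling(q * n)}-th order
#' statistic (type-1 quantile), the definition used by the top-percentile
#' transcript-count filter.
#'
#' @param x Numeric vector (non-empty).
#' @param q Quantile in (0, 1].
#' @return The nearest-rank quantile of \code{x}.
#' @examples
#' nearestRankQuantile(1:10, 0.8)  # 8
#' @export
nearestRankQuantile <- function(x, q) {
  stopifnot(length(x) >= 1L, q > 0, q <= 1)
  unname(sort(x)[ceiling(q * length(x))])
}

#' Select cells by lineage-marker, gene-count and transcript-count criteria
#'
#' Three ordered stages: (1) remove any cell with a nonzero count in a
#' forbidden lineage-marker gene (non-B cells); (2) remove cells expressing
#' fewer than \code{minGenes} distinct genes; (3) compute the
#' \code{1 - topCountPercentile} nearest-rank quantile of total transcript
#' counts over the survivors of stages 1–2 and remove cells whose total is
#' strictly greater — the top-percentile cells, which tend to be doublets or
#' cell clumps sharing a barcode. Forbidden genes absent from the matrix are
#' treated as all-zero (and reported).
#'
#' @param counts Genes x cells matrix (sparse \code{dgCMatrix} or dense),
#'   with unique gene-symbol rownames and unique barcode colnames;
#'   non-negative integer counts.
#' @param forbiddenGenes Character vector of disqualifying marker symbols
#'   (default [qcForbiddenGenes()]).
#' @param minGenes Minimum number of distinct genes with count >= 1
#'   (default 200).
#' @param topCountPercentile Fraction of top total-count cells to remove
#'   (default 0.01; 0 disables stage 3).
#' @return List with \code{barcodes} (survivors, input order), \code{report}
#'   (data.frame \code{stage}, \code{criterion}, \code{nRemoved}),
#'   \code{threshold} (the stage-3 total-count cutoff, or \code{NA}), and
#'   \code{missingForbidden} (forbidden symbols absent from the matrix).
#' @examples
#' m <- matrix(rpois(60, 2), 6, 10,
#'             dimnames = list(c("CD3E", paste0("G", 1:5)),
#'                             paste0("c", 1:10)))
#' filterCells(m, minGenes = 1)$report
#' @export
filterCells <- function(counts, forbiddenGenes = qcForbiddenGenes(),
                        minGenes = 200L, topCountPercentile = 0.01) {
  stopifnot(minGenes >= 1L, topCountPercentile >= 0, topCountPercentile < 1)
  bc <- colnames(counts)
  report <- data.frame(stage = integer(), criterion = character(),
                       nRemoved = integer(), stringsAsFactors = FALSE)
  if (ncol(counts) == 0L) {
    warning("empty count matrix: no cells to filter")
    return(list(barcodes = character(), report = report,
                threshold = NA_real_, missingForbidden = character()))
  }
  if (is.null(rownames(counts)) || is.null(bc))
    stop("counts must carry gene-symbol rownames and barcode colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(counts)) || anyDuplicated(bc))
    stop("gene symbols and barcodes must be unique", call. = FALSE)
  missing <- setdiff(forbiddenGenes, rownames(counts))
  present <- intersect(forbiddenGenes, rownames(counts))
  ## stage 1: any forbidden-marker expression
  if (length(present)) {
    sub <- counts[present, , drop = FALSE]
    hit <- if (methods::is(counts, "sparseMatrix"))
      Matrix::colSums(sub > 0) > 0 else colSums(sub > 0) > 0
  } else hit <- rep(FALSE, ncol(counts))
  keep1 <- !hit
  report <- rbind(report, data.frame(
    stage = 1L, criterion = "forbidden lineage marker expressed",
    nRemoved = sum(!keep1), stringsAsFactors = FALSE))
  ## stage 2: distinct-gene minimum
  ngenes <- .genesPerCell(counts)
  keep2 <- keep1 & ngenes >= minGenes
  report <- rbind(report, data.frame(
    stage = 2L, criterion = sprintf("fewer than %d distinct genes", minGenes),
    nRemoved = sum(keep1) - sum(keep2), stringsAsFactors = FALSE))
  ## stage 3: top total-count percentile over stage-1/2 survivors
  threshold <- NA_real_
  keep3 <- keep2
  if (topCountPercentile > 0 && any(keep2)) {
    totals <- .totalsPerCell(counts)[keep2]
    threshold <- nearestRankQuantile(totals, 1 - topCountPercentile)
    keep3[keep2] <- totals <= threshold
  }
  report <- rbind(report, data.frame(
    stage = 3L,
    criterion = sprintf("total count above the %.4g%% top percentile",
                        100 * topCountPercentile),
    nRemoved = sum(keep2) - sum(keep3), stringsAsFactors = FALSE))
  if (!any(keep3)) warning("all cells removed by QC filtering")
  list(barcodes = bc[keep3], report = report, threshold = threshold,
       missingForbidden = missing)
}

#' Prune clonotype-specific genes from a variable-feature list
#'
#' Removes from an ordered gene list every symbol matching a prefix-anchored
#' pruning pattern (Ig V/D/J, TCR, IGLL families) or contained in the
#' explicit constant-region list, preserving the order of survivors. The
#' operation is idempotent.
#'
#' @param genes Ordered character vector of gene symbols (e.g. the top
#'   variable features from upstream feature selection).
#' @param patterns Anchored regular expressions (default
#'   [pruningPatterns()]).
#' @param constantGenes Explicit removal list (default [igConstantGenes()]).
#' @return The pruned ordered character vector.
#' @examples
#' pruneVariableGenes(c("IGHV1-69", "IGKC", "IGLL5", "TRBV7-2",
#'                      "CD19", "MS4A1", "AC233755.1"))
#' @export
pruneVariableGenes <- function(genes, patterns = pruningPatterns(),
                               constantGenes = igConstantGenes()) {
  genes <- as.character(genes)
  if (!length(genes)) return(genes)
  drop <- genes %in% constantGenes
  for (p in patterns) drop <- drop | grepl(p, genes)
  genes[!drop]
}

.openMaybeGz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

.readSidecar <- function(path, what) {
  con <- .openMaybeGz(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (!length(lines))
    stop(sprintf("%s file '%s' is empty", what, path), call. = FALSE)
  strsplit(lines, "\t", fixed = TRUE)
}

#' Read a 10x-style MatrixMarket count triplet
#'
#' Loads a genes x cells count matrix from a MatrixMarket coordinate file
#' with features and barcodes sidecar files (plain or gzip-compressed).
#' Features files may carry one column (symbol) or the 10x three-column
#' layout (id, symbol, type); the symbol column is used. Duplicate symbols
#' are made unique with [make.unique()] (with a warning); duplicate barcodes
#' are an error.
#'
#' @param mtxPath Path to the \code{.mtx(.gz)} coordinate file.
#' @param featuresPath Path to \code{features.tsv(.gz)}.
#' @param barcodesPath Path to \code{barcodes.tsv(.gz)}.
#' @return A sparse \code{dgCMatrix}, genes x cells, integer-valued.
#' @export
readCounts <- function(mtxPath, featuresPath, barcodesPath) {
  for (p in c(mtxPath, featuresPath, barcodesPath))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  mtxCon <- .openMaybeGz(mtxPath)
  on.exit(try(close(mtxCon), silent = TRUE))
  m <- tryCatch(Matrix::readMM(mtxCon), error = function(e)
    stop(sprintf("malformed MatrixMarket file '%s': %s", mtxPath,
                 conditionMessage(e)), call. = FALSE))
  feats <- .readSidecar(featuresPath, "features")
  bcs <- .readSidecar(barcodesPath, "barcodes")
  if (length(feats) != nrow(m))
    stop(sprintf(
      "dimension mismatch: '%s' declares %d genes but '%s' has %d rows",
      mtxPath, nrow(m), featuresPath, length(feats)), call. = FALSE)
  if (length(bcs) != ncol(m))
    stop(sprintf(
      "dimension mismatch: '%s' declares %d cells but '%s' has %d rows",
      mtxPath, ncol(m), barcodesPath, length(bcs)), call. = FALSE)
  x <- if (methods::is(m, "sparseMatrix")) m@x else as.vector(m)
  if (any(x != round(x)) || any(x < 0))
    stop(sprintf("'%s' contains negative or non-integer counts", mtxPath),
         call. = FALSE)
  symbols <- vapply(feats, function(f) f[[min(2L, length(f))]], character(1))
  if (anyDuplicated(symbols)) {
    warning("duplicate gene symbols made unique with make.unique()")
    symbols <- make.unique(symbols)
  }
  barcodes <- vapply(bcs, `[[`, character(1), 1L)
  if (anyDuplicated(barcodes))
    stop(sprintf("'%s' contains duplicate barcodes", barcodesPath),
         call. = FALSE)
  m <- methods::as(methods::as(m, "CsparseMatrix"), "dMatrix")
  dimnames(m) <- list(symbols, barcodes)
  m
}

#' Write a count matrix as a 10x-style MatrixMarket triplet
#'
#' Writes \code{matrix.mtx}, \code{features.tsv} and \code{barcodes.tsv}
#' into a directory, round-trippable by [readCounts()].
#'
#' @param counts Genes x cells matrix with dimnames.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
writeCounts <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "generalMatrix"), paths[1])
  writeLines(rownames(counts), paths[2])
  writeLines(colnames(counts), paths[3])
  invisible(paths)
}
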