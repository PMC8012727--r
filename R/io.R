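## Readers/writers for the tabular interchange formats: headered TSV/CSV
## with the cell barcode in the first column.

.sepFor <- function(path) if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"

.readIdTable <- function(path, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = .sepFor(path),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (ncol(df) < 2L)
    stop(sprintf("%s file '%s' needs an id column plus data columns",
                 what, path), call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop(sprintf("%s file '%s' contains duplicate cell identifiers",
                 what, path), call. = FALSE)
  list(ids = ids, data = df[-1])
}

#' Read an embedding or velocity table
#'
#' Headered TSV (or CSV, by extension) with the cell identifier in the first
#' column and one numeric column per embedding axis.
#'
#' @param path File path.
#' @return n x D numeric matrix with barcode rownames.
#' @export
readEmbeddingTable <- function(path) {
  t <- .readIdTable(path, "embedding/velocity")
  m <- as.matrix(t$data)
  if (!is.numeric(m) || !all(is.finite(m)))
    stop(sprintf("'%s' contains non-numeric or non-finite coordinates", path),
         call. = FALSE)
  rownames(m) <- t$ids
  m
}

#' Read a cell-to-cluster assignment table
#'
#' Headered TSV/CSV: first column cell identifier, second column cluster
#' label.
#'
#' @param path File path.
#' @return Named character vector (names = barcodes).
#' @export
readClusterTable <- function(path) {
  t <- .readIdTable(path, "cluster-label")
  stats::setNames(as.character(t$data[[1]]), t$ids)
}

.writeIdTable <- function(m, path, idName = "cell", colNames = NULL) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(idName, colNames %||% colnames(m) %||%
                   paste0("V", seq_len(ncol(m))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a CTS matrix (and its raw totals) as TSV
#'
#' Writes the composite transition scores with a header row of destination
#' labels and the source label in the first column; row/column order is the
#' sorted cluster order, so output is deterministic. The unweighted raw
#' totals go to a sibling file when requested.
#'
#' @param cts A [CTSMatrix-class].
#' @param file Output path for the CTS matrix.
#' @param rawFile Optional output path for the raw totals.
#' @return Invisibly, the path(s) written.
#' @export
writeCTSMatrix <- function(cts, file, rawFile = NULL) {
  stopifnot(is(cts, "CTSMatrix"))
  ord <- sort(clusterLabels(cts))
  .writeIdTable(ctsScores(cts)[ord, ord, drop = FALSE], file,
                idName = "source", colNames = ord)
  if (!is.null(rawFile))
    .writeIdTable(rawTotals(cts)[ord, ord, drop = FALSE], rawFile,
                  idName = "source", colNames = ord)
  invisible(c(file, rawFile))
}

#' Read aligned embedding, velocity and cluster tables
#'
#' Reads the three tables and validates that they describe the same cell
#' set; the velocity and cluster tables are reordered to the embedding's
#' cell order. On a mismatch the error names example missing/extra
#' barcodes.
#'
#' @param embeddingPath,velocityPath,labelsPath File paths.
#' @return List with \code{embedding}, \code{velocity} (matrices) and
#'   \code{clusters} (named character).
#' @export
readVelocityInputs <- function(embeddingPath, velocityPath, labelsPath) {
  emb <- readEmbeddingTable(embeddingPath)
  vel <- readEmbeddingTable(velocityPath)
  cl <- readClusterTable(labelsPath)
  for (x in list(list(rownames(vel), "velocity"), list(names(cl), "labels"))) {
    miss <- setdiff(rownames(emb), x[[1]])
    extra <- setdiff(x[[1]], rownames(emb))
    if (length(miss) || length(extra))
      stop(sprintf(
        "cell sets differ between embedding and %s: %d missing (e.g. %s), %d extra (e.g. %s)",
        x[[2]], length(miss), paste(utils::head(miss, 3), collapse = ", "),
        length(extra), paste(utils::head(extra, 3), collapse = ", ")),
        call. = FALSE)
  }
  if (!identical(dim(vel), dim(emb)))
    stop("velocity table dimension differs from the embedding", call. = FALSE)
  list(embedding = emb, velocity = vel[rownames(emb), , drop = FALSE],
       clusters = cl[rownames(emb)])
}
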