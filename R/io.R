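#' Read a gene x sample count matrix
#'
#' Accepts a dense TSV (first column gene ids, header row of sample ids) or
#' a MatrixMarket triplet (`.mtx` plus row- and column-name files, one id
#' per line).
#'
#' @param path TSV path, or the `.mtx` path when `rowsPath`/`colsPath` are
#'   given.
#' @param rowsPath,colsPath Row/column id files for the MTX form.
#' @return Integer matrix, genes x samples.
#' @export
readCounts <- function(path, rowsPath = NULL, colsPath = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (!is.null(rowsPath)) {
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(rowsPath)
    colnames(m) <- readLines(colsPath)
    storage.mode(m) <- "integer"
    return(m)
  }
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!is.finite(m) | m != suppressWarnings(as.integer(m)),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("non-integer count at row %d, column '%s'",
          bad[1, 1], colnames(m)[bad[1, 2]])
  }
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

# generic schema-checked delimited reader
.readTable <- function(path, required, sep = "\t") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  missing <- setdiff(required, colnames(df))
  if (length(missing)) {
    stopf("%s: missing required column '%s'", basename(path), missing[1])
  }
  df
}

#' Schema-validated readers for the pipeline's tables
#'
#' `readMetadata()` expects biopsy_id, patient, activity (and keeps any
#' further columns); `readCells()` expects cell_id, biopsy_id, cluster;
#' `readContigs()` reads the 10x-style CSV with barcode, biopsy_id, chain,
#' cdr3_nt, umis, productive; `readZotus()` reads a TSV whose first column
#' is the zOTU id and last column the taxonomy string, returning the count
#' matrix with a `taxonomy` attribute.
#'
#' @param path File path.
#' @return A data.frame (metadata/cells/contigs) or matrix (zOTUs).
#' @name table-readers
#' @export
readMetadata <- function(path) {
  df <- .readTable(path, c("biopsy_id", "patient", "activity"))
  rownames(df) <- df$biopsy_id
  df
}

#' @rdname table-readers
#' @export
readCells <- function(path) {
  .readTable(path, c("cell_id", "biopsy_id", "cluster"))
}

#' @rdname table-readers
#' @export
readContigs <- function(path) {
  df <- .readTable(path, c("barcode", "chain", "cdr3_nt", "umis",
                           "productive"), sep = ",")
  df$productive <- as.logical(df$productive)
  df
}

#' @rdname table-readers
#' @export
readZotus <- function(path) {
  df <- .readTable(path, character())
  tax <- setNames(df[[ncol(df)]], df[[1]])
  m <- as.matrix(df[, -c(1, ncol(df)), drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  attr(m, "taxonomy") <- tax
  m
}
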