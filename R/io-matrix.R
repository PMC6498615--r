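#' Write a labeled matrix to TSV
#'
#' Layout: header row of column labels (first cell empty), one row per row
#' label. Values are written with 12 significant digits so that
#' write/read round-trips are exact at that precision.
#'
#' @param matrix a numeric matrix with complete `dimnames`.
#' @param path output path.
#' @param symmetric declare the matrix symmetric; validated before writing.
#' @export
write_matrix_tsv <- function(matrix, path, symmetric = FALSE) {
  if (!is.matrix(matrix) || nrow(matrix) == 0L || ncol(matrix) == 0L)
    stopf("cannot write an empty or non-matrix object")
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stopf("matrix must have row and column labels")
  if (symmetric) {
    if (nrow(matrix) != ncol(matrix) ||
        !identical(rownames(matrix), colnames(matrix)) ||
        !isTRUE(all.equal(matrix, t(matrix), check.attributes = FALSE)))
      stopf("matrix flagged symmetric is not symmetric")
  }
  fmt <- function(v) {
    out <- sprintf("%.12g", v)
    out[is.na(v)] <- "NA"
    out
  }
  lines <- c(paste(c("", colnames(matrix)), collapse = "\t"),
             vapply(seq_len(nrow(matrix)), function(i)
               paste(c(rownames(matrix)[i], fmt(matrix[i, ])), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a labeled matrix from TSV
#'
#' @param path path to a file written by [write_matrix_tsv()].
#' @param symmetric validate symmetry after reading.
#' @return a numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path, symmetric = FALSE) {
  if (!file.exists(path)) stopf("matrix file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stopf("matrix file %s has no data rows", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(cells[[1]])
  if (any(lengths(cells) != width))
    stopf("ragged rows in matrix file %s (expected %d fields, row %d has %d)",
          path, width, which(lengths(cells) != width)[1],
          lengths(cells)[lengths(cells) != width][1])
  col_labels <- cells[[1]][-1]
  row_labels <- vapply(cells[-1], `[`, character(1), 1L)
  vals <- do.call(rbind, lapply(cells[-1], function(r) {
    v <- suppressWarnings(as.numeric(r[-1]))
    if (any(is.na(v) & r[-1] != "NA"))
      stopf("non-numeric cell '%s' in matrix file %s",
            r[-1][is.na(v) & r[-1] != "NA"][1], path)
    v
  }))
  dimnames(vals) <- list(row_labels, col_labels)
  if (symmetric) {
    if (!identical(row_labels, col_labels) ||
        !isTRUE(all.equal(vals, t(vals), check.attributes = FALSE)))
      stopf("matrix in %s is not symmetric", path)
  }
  vals
}
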