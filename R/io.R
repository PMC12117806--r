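#' Write a matrix as tab-delimited text with id header row and id column
#'
#' @param m matrix with dimnames.
#' @param path output path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by \code{\link{write_matrix_tsv}}
#'
#' @param path input path.
#' @param integer coerce values to integer (for count matrices).
#' @return matrix with dimnames.
#' @export
read_matrix_tsv <- function(path, integer = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (integer) storage.mode(m) <- "integer"
  m
}
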