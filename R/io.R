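#' Read a Q-matrix from CSV
#'
#' Expects a header row of attribute names and one row of 0/1 entries per
#' item. Malformed entries are reported with their file line number (header
#' is line 1).
#'
#' @param path path to a CSV file.
#' @return A validated integer Q-matrix with the header as column names.
#' @export
read_qmatrix <- function(path) {
  Q <- .read_binary_csv(path, what = "Q-matrix")
  zero <- which(rowSums(Q) == 0)
  if (length(zero))
    stop(path, ": Q-matrix rows must require at least one attribute (line",
         if (length(zero) > 1) "s" else "", " ",
         paste(zero + 1L, collapse = ", "), ")")
  validate_qmatrix(Q)
}

#' Read a response matrix from CSV
#'
#' Expects a header row of item identifiers and one row of 0/1 responses per
#' examinee.
#'
#' @param path path to a CSV file.
#' @param Q optional Q-matrix to check the item count against.
#' @return A validated integer response matrix.
#' @export
read_responses <- function(path, Q = NULL) {
  Y <- .read_binary_csv(path, what = "response matrix")
  validate_responses(Y, Q)
}

.read_binary_csv <- function(path, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  if (nrow(df) == 0) stop(path, ": ", what, " has no data rows")
  M <- suppressWarnings(as.matrix(df))
  storage.mode(M) <- "double"
  bad <- which(!(M == 0 | M == 1) | is.na(M), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(path, ": ", what, " entries must be 0 or 1; first bad value at line ",
         bad[1, 1] + 1L, ", column ", bad[1, 2])
  }
  storage.mode(M) <- "integer"
  M
}

#' Write a Q-matrix or response matrix to CSV
#'
#' @param x binary matrix to write.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_binary_csv <- function(x, path) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
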