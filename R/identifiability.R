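#' Check Q-matrix completeness
#'
#' A Q-matrix is complete for the DINA model when it contains, up to row
#' permutation, the K x K identity: for every attribute there is an item
#' requiring that attribute and nothing else. Completeness is the first of
#' the two conditions that are jointly sufficient and necessary for
#' identifiability of all DINA parameters.
#'
#' @param Q binary Q-matrix.
#' @return A list with `complete` (logical) and `identity_rows` (for each
#'   attribute, the lowest item index whose row is the corresponding unit
#'   vector, or `NA` when none exists).
#' @export
check_completeness <- function(Q) {
  Q <- validate_qmatrix(Q)
  K <- ncol(Q)
  unit <- rowSums(Q) == 1
  rows <- vapply(seq_len(K), function(k) {
    idx <- which(unit & Q[, k] == 1)
    if (length(idx)) idx[1] else NA_integer_
  }, integer(1))
  list(complete = !anyNA(rows), identity_rows = rows)
}

#' Check per-attribute item counts
#'
#' Each attribute must be required by at least three items.
#'
#' @param Q binary Q-matrix.
#' @return A list with `ok` (logical) and `counts` (column sums of Q).
#' @export
check_attribute_counts <- function(Q) {
  Q <- validate_qmatrix(Q)
  counts <- colSums(Q)
  list(ok = all(counts >= 3), counts = as.integer(counts))
}

#' Check distinctness of the residual submatrix columns
#'
#' With one identity row per attribute removed, any two columns of the
#' remaining submatrix must differ.
#'
#' @param Q binary Q-matrix.
#' @param identity_rows item indices forming the embedded identity, as
#'   returned by [check_completeness()]; must contain one valid index per
#'   attribute.
#' @return Logical: `TRUE` iff all column pairs of the submatrix are distinct
#'   (vacuously `TRUE` for a single attribute).
#' @export
check_distinct_columns <- function(Q, identity_rows) {
  Q <- validate_qmatrix(Q)
  K <- ncol(Q)
  if (length(identity_rows) != K || anyNA(identity_rows) ||
      any(identity_rows < 1 | identity_rows > nrow(Q)))
    stop("identity_rows must give one valid item index per attribute")
  Qstar <- Q[-identity_rows, , drop = FALSE]
  if (K < 2) return(TRUE)
  keys <- apply(Qstar, 2, paste, collapse = "")
  !any(duplicated(keys))
}

#' Identifiability report for a Q-matrix
#'
#' Combines the three checks — completeness (an embedded identity),
#' attribute counts (each attribute in at least three items), and distinct
#' residual-submatrix columns — whose conjunction is sufficient and
#' necessary for identifiability of all DINA model parameters.
#'
#' @param Q binary Q-matrix.
#' @return An object of class `dina_qcheck`: a list with fields `complete`,
#'   `identity_rows`, `attribute_counts`, `min_count_ok`,
#'   `distinct_columns_ok` and `identifiable`.
#' @examples
#' check_identifiability(sim_qmatrix())
#' @export
check_identifiability <- function(Q) {
  Q <- validate_qmatrix(Q)
  comp <- check_completeness(Q)
  cnt <- check_attribute_counts(Q)
  distinct <- if (comp$complete) check_distinct_columns(Q, comp$identity_rows) else FALSE
  out <- list(
    complete = comp$complete,
    identity_rows = comp$identity_rows,
    attribute_counts = cnt$counts,
    min_count_ok = cnt$ok,
    distinct_columns_ok = distinct,
    identifiable = comp$complete && cnt$ok && distinct
  )
  class(out) <- "dina_qcheck"
  out
}

#' @export
print.dina_qcheck <- function(x, ...) {
  cat("Q-matrix identifiability report\n")
  cat("  complete (embedded identity): ", x$complete, "\n", sep = "")
  if (x$complete)
    cat("  identity rows: ", paste(x$identity_rows, collapse = ", "), "\n", sep = "")
  cat("  attribute counts: ", paste(x$attribute_counts, collapse = ", "),
      " (all >= 3: ", x$min_count_ok, ")\n", sep = "")
  cat("  distinct residual columns: ", x$distinct_columns_ok, "\n", sep = "")
  cat("  identifiable: ", x$identifiable, "\n", sep = "")
  invisible(x)
}
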