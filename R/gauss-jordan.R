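#' Exact sparse Gauss-Jordan elimination
#'
#' Reduces a [rational_matrix()] to reduced row-echelon form in exact
#' rational arithmetic, recording every elementary row operation so that the
#' reduction can be replayed on other matrices (for example on extra columns
#' appended to a stoichiometric matrix).
#'
#' The pivot rule is a Markowitz-style sparsity heuristic: among admissible
#' nonzero entries the pivot minimising
#' `(nonzeros in its row - 1) * (nonzeros in its column - 1)` is chosen,
#' with ties broken by smallest column then smallest row index. Columns
#' listed in `preferred_dependent` are tried first, in the given order.
#' Columns in `forbidden_pivot_cols` (requested independent fluxes) are used
#' as pivots only when the remaining columns cannot complete the reduction;
#' any such forced move is reported in `moved_to_dependent`, mirroring how a
#' researcher-selected independent set that is not linearly independent gets
#' partially overridden.
#'
#' @param matrix A [rational_matrix()] with at least one row and column.
#' @param preferred_dependent Integer vector of column indices preferred as
#'   pivot (dependent) columns, in preference order.
#' @param forbidden_pivot_cols Integer vector of column indices requested to
#'   stay independent (non-pivot). Must be disjoint from
#'   `preferred_dependent`.
#' @return An object of class `elimination_result` with components
#'   `echelon` (the reduced row-echelon [rational_matrix()], pivot rows
#'   first in pivot-column order), `pivot_columns`, `free_columns`, `rank`,
#'   `row_ops` (a data frame logging every operation), `moved_to_dependent`
#'   and `max_bits` (the largest numerator/denominator bit length seen
#'   during the reduction, a coefficient-growth diagnostic).
#' @examples
#' n <- as_rational_matrix(matrix(c(1, -1, -1, 1), 2, 2))
#' e <- gauss_jordan_eliminate(n)
#' e$rank
#' e$free_columns
#' @export
gauss_jordan_eliminate <- function(matrix, preferred_dependent = integer(),
                                   forbidden_pivot_cols = integer()) {
  if (!inherits(matrix, "rational_matrix"))
    fk_stop("fk_input_error", "expected a rational_matrix")
  if (matrix$nrow < 1L || matrix$ncol < 1L)
    fk_stop("fk_input_error", "matrix must have at least one row and one column")
  preferred_dependent <- as.integer(preferred_dependent)
  forbidden_pivot_cols <- as.integer(forbidden_pivot_cols)
  if (length(intersect(preferred_dependent, forbidden_pivot_cols)))
    fk_stop("fk_input_error",
            "preferred_dependent and forbidden_pivot_cols must be disjoint")
  bad <- setdiff(c(preferred_dependent, forbidden_pivot_cols), seq_len(matrix$ncol))
  if (length(bad))
    fk_stop("fk_input_error", "column indices out of range: %s",
            paste(bad, collapse = ", "))
  res <- cpp_gje(matrix$nrow, matrix$ncol, matrix$i, matrix$j, matrix$val,
                 preferred_dependent, forbidden_pivot_cols)
  ech <- res$echelon
  structure(
    list(
      echelon = rational_matrix(ech$nrow, ech$ncol, ech$i, ech$j, ech$val),
      pivot_columns = res$pivot_columns,
      free_columns = res$free_columns,
      rank = res$rank,
      row_ops = data.frame(
        kind = c("swap", "scale", "add_multiple")[res$ops_kind + 1L],
        target_row = res$ops_target,
        source_row = res$ops_source,
        factor = res$ops_factor,
        stringsAsFactors = FALSE
      ),
      moved_to_dependent = res$moved_to_dependent,
      max_bits = res$max_bits,
      n_rows = matrix$nrow,
      n_cols = matrix$ncol
    ),
    class = "elimination_result"
  )
}

#' @export
print.elimination_result <- function(x, ...) {
  cat(sprintf("<elimination_result: %d x %d, rank %d, %d free column(s), %d row op(s)>\n",
              x$n_rows, x$n_cols, x$rank, length(x$free_columns), nrow(x$row_ops)))
  if (length(x$moved_to_dependent))
    cat("  moved to dependent (requested independent, infeasible):",
        paste(x$moved_to_dependent, collapse = ", "), "\n")
  invisible(x)
}

#' Replay a recorded row-operation log
#'
#' Applies the elementary row operations recorded by
#' [gauss_jordan_eliminate()] to another matrix with the same number of
#' rows. Replaying the log on the original input reproduces the echelon
#' form bit-exactly; replaying it on an identity matrix yields the
#' transformation matrix `T` with `T %*% A = echelon(A)`.
#'
#' @param row_ops The `row_ops` data frame of an `elimination_result` (or
#'   the whole result object).
#' @param matrix A [rational_matrix()] with the row count the log was
#'   recorded against.
#' @return The transformed [rational_matrix()].
#' @export
replay_row_ops <- function(row_ops, matrix) {
  if (inherits(row_ops, "elimination_result")) row_ops <- row_ops$row_ops
  if (!inherits(matrix, "rational_matrix"))
    fk_stop("fk_input_error", "expected a rational_matrix")
  if (nrow(row_ops)) {
    mx <- max(row_ops$target_row, row_ops$source_row, na.rm = TRUE)
    if (mx > matrix$nrow)
      fk_stop("fk_input_error",
              "row-operation log was recorded against %d rows, matrix has %d",
              mx, matrix$nrow)
  }
  kind <- match(row_ops$kind, c("swap", "scale", "add_multiple")) - 1L
  if (anyNA(kind)) fk_stop("fk_input_error", "unknown row-operation kind")
  res <- cpp_replay(kind, row_ops$target_row, row_ops$source_row,
                    row_ops$factor, matrix$nrow, matrix$ncol,
                    matrix$i, matrix$j, matrix$val)
  rational_matrix(res$nrow, res$ncol, res$i, res$j, res$val)
}

#' Serialise an elimination result to JSON
#'
#' Round-trips the echelon form (as triplets), the pivot/free column
#' partition and the full row-operation log, so a reduction can be archived
#' and replayed later without recomputing it.
#'
#' @param result An `elimination_result`.
#' @param path Output JSON file.
#' @return `path` invisibly, or for the reader the restored
#'   `elimination_result`.
#' @export
write_elimination_json <- function(result, path) {
  ech <- result$echelon
  obj <- list(
    schema = "fluxkernel/elimination/v1",
    n_rows = result$n_rows, n_cols = result$n_cols,
    rank = result$rank,
    pivot_columns = result$pivot_columns,
    free_columns = result$free_columns,
    moved_to_dependent = result$moved_to_dependent,
    max_bits = result$max_bits,
    echelon = list(nrow = ech$nrow, ncol = ech$ncol,
                   i = ech$i, j = ech$j, val = ech$val),
    row_ops = result$row_ops
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_elimination_json
#' @export
read_elimination_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "fluxkernel/elimination/v1"))
    fk_stop("fk_parse_error", "unrecognised elimination JSON schema in %s", path)
  ops <- obj$row_ops
  if (is.null(ops) || !length(ops)) {
    ops <- data.frame(kind = character(), target_row = integer(),
                      source_row = integer(), factor = character(),
                      stringsAsFactors = FALSE)
  }
  ops <- as.data.frame(ops, stringsAsFactors = FALSE)
  for (col in c("source_row", "factor"))
    if (is.null(ops[[col]])) ops[[col]] <- NA
  ops <- data.frame(kind = as.character(ops$kind),
                    target_row = as.integer(ops$target_row),
                    source_row = as.integer(ops$source_row),
                    factor = as.character(ops$factor),
                    stringsAsFactors = FALSE)
  structure(
    list(
      echelon = rational_matrix(obj$echelon$nrow, obj$echelon$ncol,
                                obj$echelon$i %||% integer(),
                                obj$echelon$j %||% integer(),
                                obj$echelon$val %||% character()),
      pivot_columns = as.integer(obj$pivot_columns %||% integer()),
      free_columns = as.integer(obj$free_columns %||% integer()),
      rank = as.integer(obj$rank),
      row_ops = ops,
      moved_to_dependent = as.integer(obj$moved_to_dependent %||% integer()),
      max_bits = as.integer(obj$max_bits),
      n_rows = as.integer(obj$n_rows),
      n_cols = as.integer(obj$n_cols)
    ),
    class = "elimination_result"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
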