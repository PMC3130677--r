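#' Exact rational sparse matrices
#'
#' A `rational_matrix` stores a two-dimensional array of exact rational
#' numbers in coordinate (triplet) form. Values are kept as canonical
#' strings `"p/q"` (or `"p"` for integers) with `gcd(|p|, q) = 1` and
#' `q >= 1`; structural zeros are never stored. All arithmetic on these
#' matrices is exact: no rounding occurs anywhere in the package.
#'
#' @param nrow,ncol Matrix dimensions (positive integers).
#' @param i,j Integer vectors of 1-based row/column indices of the nonzero
#'   entries.
#' @param value Entries, parallel to `i` and `j`. Character values may be
#'   `"p/q"` fractions, integers, or decimal literals (`"0.5"`, `"1e-3"`),
#'   all parsed exactly (`"0.1"` becomes `1/10`). Numeric values must be
#'   integral or have a short exact decimal representation.
#' @return An object of class `rational_matrix`.
#' @examples
#' m <- rational_matrix(2, 2, i = c(1, 2), j = c(1, 2), value = c("1/2", "-3"))
#' as.matrix(m)
#' sparsity(m)
#' @export
rational_matrix <- function(nrow, ncol, i = integer(), j = integer(),
                            value = character()) {
  nrow <- as.integer(nrow); ncol <- as.integer(ncol)
  if (length(nrow) != 1L || length(ncol) != 1L || is.na(nrow) || is.na(ncol) ||
      nrow < 0L || ncol < 0L)
    fk_stop("fk_input_error", "matrix dimensions must be single non-negative integers")
  i <- as.integer(i); j <- as.integer(j)
  value <- rat_chr(value)
  if (length(i) != length(j) || length(i) != length(value))
    fk_stop("fk_input_error", "i, j and value must have the same length")
  if (length(i) && (any(i < 1L) || any(i > nrow) || any(j < 1L) || any(j > ncol)))
    fk_stop("fk_input_error", "matrix indices out of bounds")
  value <- cpp_rat_norm(value)
  keep <- value != "0"
  i <- i[keep]; j <- j[keep]; value <- value[keep]
  if (anyDuplicated(cbind(i, j)))
    fk_stop("fk_input_error", "duplicate (row, col) entries")
  ord <- order(i, j)
  structure(
    list(nrow = nrow, ncol = ncol, i = i[ord], j = j[ord], val = value[ord]),
    class = "rational_matrix"
  )
}

# coerce numeric/character input to rational literal strings
rat_chr <- function(x) {
  if (is.character(x)) return(x)
  if (is.numeric(x)) {
    out <- character(length(x))
    whole <- is.finite(x) & x == round(x)
    out[whole] <- sprintf("%.0f", x[whole])
    if (any(!whole)) {
      if (any(!is.finite(x))) fk_stop("fk_input_error", "non-finite matrix entry")
      out[!whole] <- vapply(x[!whole], function(v) format(v, digits = 17), "")
    }
    return(out)
  }
  fk_stop("fk_input_error", "matrix entries must be character or numeric")
}

#' Coerce a dense matrix to a rational matrix
#'
#' @param x A base matrix, either numeric or character (rational literals).
#' @return A [rational_matrix()].
#' @export
as_rational_matrix <- function(x) {
  if (inherits(x, "rational_matrix")) return(x)
  if (!is.matrix(x)) fk_stop("fk_input_error", "expected a matrix")
  v <- rat_chr(as.vector(x))
  v <- cpp_rat_norm(v)
  nz <- which(v != "0")
  rational_matrix(nrow(x), ncol(x),
                  i = ((nz - 1L) %% nrow(x)) + 1L,
                  j = ((nz - 1L) %/% nrow(x)) + 1L,
                  value = v[nz])
}

#' @export
dim.rational_matrix <- function(x) c(x$nrow, x$ncol)

#' @export
print.rational_matrix <- function(x, ...) {
  cat(sprintf("<rational_matrix %d x %d, %d nonzeros, sparsity %.3f>\n",
              x$nrow, x$ncol, length(x$val), sparsity(x)))
  if (x$nrow <= 10L && x$ncol <= 10L) print(as_character_matrix(x), quote = FALSE)
  invisible(x)
}

#' @export
as.matrix.rational_matrix <- function(x, ...) {
  m <- matrix(0, x$nrow, x$ncol)
  if (length(x$val)) m[cbind(x$i, x$j)] <- cpp_rat_to_double(x$val)
  m
}

#' Dense character representation of a rational matrix
#'
#' @param x A [rational_matrix()].
#' @return A character matrix of canonical rational strings, `"0"` for
#'   structural zeros.
#' @export
as_character_matrix <- function(x) {
  m <- matrix("0", x$nrow, x$ncol)
  if (length(x$val)) m[cbind(x$i, x$j)] <- x$val
  m
}

#' Sparsity of a matrix
#'
#' The fraction of entries that are structurally zero,
#' `1 - nnz / (nrow * ncol)`. Genome-scale stoichiometric matrices typically
#' have sparsity above 0.99, which is what makes sparse exact elimination
#' competitive with dense numerics.
#'
#' @param x A [rational_matrix()] or base matrix.
#' @param ... Unused.
#' @return A fraction in `[0, 1]`.
#' @export
sparsity <- function(x, ...) UseMethod("sparsity")

#' @rdname sparsity
#' @export
sparsity.rational_matrix <- function(x, ...) {
  if (x$nrow == 0L || x$ncol == 0L)
    fk_stop("fk_input_error", "sparsity of a zero-sized matrix is undefined")
  1 - length(x$val) / (x$nrow * x$ncol)
}

#' @rdname sparsity
#' @param tol Magnitude below which a numeric entry counts as zero.
#' @export
sparsity.matrix <- function(x, tol = 1e-9, ...) {
  if (nrow(x) == 0L || ncol(x) == 0L)
    fk_stop("fk_input_error", "sparsity of a zero-sized matrix is undefined")
  1 - sum(abs(x) > tol) / (nrow(x) * ncol(x))
}

#' Transpose of a rational matrix
#' @param x A [rational_matrix()].
#' @export
t.rational_matrix <- function(x) {
  rational_matrix(x$ncol, x$nrow, i = x$j, j = x$i, value = x$val)
}

#' Exact product of two rational matrices
#'
#' @param a,b Conformable [rational_matrix()] objects.
#' @return Their exact product as a [rational_matrix()].
#' @export
rmat_mult <- function(a, b) {
  res <- cpp_mat_mult(a$nrow, a$ncol, a$i, a$j, a$val,
                      b$nrow, b$ncol, b$i, b$j, b$val)
  rational_matrix(res$nrow, res$ncol, res$i, res$j, res$val)
}

#' Elementwise negation
#' @param x A [rational_matrix()].
#' @export
rmat_neg <- function(x) {
  v <- x$val
  neg <- startsWith(v, "-")
  v[neg] <- substring(v[neg], 2L)
  v[!neg] <- paste0("-", v[!neg])
  rational_matrix(x$nrow, x$ncol, x$i, x$j, v)
}

#' Subset rows and/or columns of a rational matrix
#'
#' @param x A [rational_matrix()].
#' @param rows,cols Integer index vectors (kept, in the given order);
#'   `NULL` keeps everything.
#' @export
rmat_subset <- function(x, rows = NULL, cols = NULL) {
  if (is.null(rows)) rows <- seq_len(x$nrow)
  if (is.null(cols)) cols <- seq_len(x$ncol)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (length(rows) && (any(rows < 1L) || any(rows > x$nrow)))
    fk_stop("fk_input_error", "row index out of bounds")
  if (length(cols) && (any(cols < 1L) || any(cols > x$ncol)))
    fk_stop("fk_input_error", "column index out of bounds")
  rmap <- rep(NA_integer_, x$nrow); rmap[rows] <- seq_along(rows)
  cmap <- rep(NA_integer_, x$ncol); cmap[cols] <- seq_along(cols)
  keep <- !is.na(rmap[x$i]) & !is.na(cmap[x$j])
  rational_matrix(length(rows), length(cols),
                  i = rmap[x$i[keep]], j = cmap[x$j[keep]], value = x$val[keep])
}

#' Stack rational matrices block-diagonally
#'
#' @param ... [rational_matrix()] objects.
#' @return The block-diagonal [rational_matrix()].
#' @export
rmat_block_diag <- function(...) {
  blocks <- list(...)
  if (length(blocks) == 1L && is.list(blocks[[1]]) &&
      !inherits(blocks[[1]], "rational_matrix"))
    blocks <- blocks[[1]]
  nr <- 0L; nc <- 0L
  ii <- integer(); jj <- integer(); vv <- character()
  for (b in blocks) {
    ii <- c(ii, b$i + nr); jj <- c(jj, b$j + nc); vv <- c(vv, b$val)
    nr <- nr + b$nrow; nc <- nc + b$ncol
  }
  rational_matrix(nr, nc, ii, jj, vv)
}

#' Read a single entry as a rational string
#' @param x A [rational_matrix()].
#' @param i,j Entry position (1-based).
#' @return Canonical rational string, `"0"` if absent.
#' @export
rmat_entry <- function(x, i, j) {
  k <- which(x$i == i & x$j == j)
  if (length(k)) x$val[k] else "0"
}

#' Exact equality of two rational matrices
#' @param a,b [rational_matrix()] objects.
#' @export
rmat_identical <- function(a, b) {
  a$nrow == b$nrow && a$ncol == b$ncol &&
    length(a$val) == length(b$val) &&
    all(a$i == b$i) && all(a$j == b$j) && all(a$val == b$val)
}

#' Rational identity matrix
#' @param n Dimension.
#' @export
rmat_identity <- function(n) {
  rational_matrix(n, n, seq_len(n), seq_len(n), rep("1", n))
}

# largest bit length over numerators and denominators (0 for empty)
rmat_max_bits <- function(x) {
  if (!length(x$val)) return(0L)
  max(cpp_rat_bits(x$val))
}

#' Exact rational scalar arithmetic
#'
#' Vectorised elementwise arithmetic and comparison on rational strings.
#' Inputs may be `"p/q"` fractions, integers, or decimal literals; decimals
#' are converted exactly (`"0.1"` is `1/10`).
#'
#' @param a,b Character vectors of rational literals (recycled).
#' @param op One of `"+", "-", "*", "/"`.
#' @return `rat_arith()`: canonical rational strings. `rat_compare()`:
#'   integer `-1`, `0`, `1` as `a` is less than, equal to, or greater than
#'   `b`. `as_rational()`: canonical rational strings.
#' @examples
#' rat_arith("1/3", "1/6", "+")
#' rat_compare("2/3", "0.6667")
#' as_rational("0.125")
#' @export
rat_arith <- function(a, b, op) cpp_rat_arith(rat_chr(a), rat_chr(b), op)

#' @rdname rat_arith
#' @export
rat_compare <- function(a, b) cpp_rat_cmp(rat_chr(a), rat_chr(b))

#' @rdname rat_arith
#' @param x Vector of rational literals (character) or numerics.
#' @export
as_rational <- function(x) cpp_rat_norm(rat_chr(x))

#' @rdname rat_arith
#' @export
rat_to_double <- function(x) cpp_rat_to_double(rat_chr(x))

#' Write a rational matrix in MatrixMarket coordinate format
#'
#' Uses the standard MatrixMarket coordinate layout with a `rational` field
#' dialect: entries are written as canonical `p/q` strings (plain `p` for
#' integers). Files written this way are read back bit-exactly by
#' [read_rational_mtx()].
#'
#' @param x A [rational_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rational_mtx <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("%%MatrixMarket matrix coordinate rational general", con)
  writeLines(sprintf("%d %d %d", x$nrow, x$ncol, length(x$val)), con)
  if (length(x$val))
    writeLines(sprintf("%d %d %s", x$i, x$j, x$val), con)
  invisible(path)
}

#' @rdname write_rational_mtx
#' @export
read_rational_mtx <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "%")]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) fk_stop("fk_parse_error", "empty MatrixMarket file: %s", path)
  hdr <- scan(text = lines[[1]], what = integer(), quiet = TRUE)
  if (length(hdr) != 3L)
    fk_stop("fk_parse_error", "malformed MatrixMarket size line in %s", path)
  body <- lines[-1]
  if (length(body) != hdr[[3]])
    fk_stop("fk_parse_error", "MatrixMarket entry count mismatch in %s", path)
  if (length(body)) {
    parts <- strsplit(trimws(body), "[[:space:]]+")
    i <- vapply(parts, function(p) as.integer(p[[1]]), 1L)
    j <- vapply(parts, function(p) as.integer(p[[2]]), 1L)
    v <- vapply(parts, function(p) p[[3]], "")
  } else {
    i <- integer(); j <- integer(); v <- character()
  }
  rational_matrix(hdr[[1]], hdr[[2]], i, j, v)
}
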