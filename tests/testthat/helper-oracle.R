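# Pure-R dense rational elimination oracle. Deliberately naive: dense
# character matrices, no sparsity bookkeeping, no pivot scoring. Pivot
# columns are taken in the supplied order (or left to right), the first
# unused row with a nonzero entry wins. Shares only the scalar rational
# arithmetic with the package's sparse engine.
r_dense_rref <- function(m, pivot_col_order = NULL) {
  nr <- nrow(m); nc <- ncol(m)
  order <- if (is.null(pivot_col_order)) seq_len(nc) else pivot_col_order
  used <- rep(FALSE, nr)
  pivots <- integer()
  pivot_rows <- integer()
  for (cc in order) {
    prow <- 0L
    for (r in seq_len(nr)) {
      if (!used[r] && m[r, cc] != "0") { prow <- r; break }
    }
    if (prow == 0L) next
    m[prow, ] <- rat_arith(m[prow, ], m[prow, cc], "/")
    for (r in seq_len(nr)) {
      if (r == prow || m[r, cc] == "0") next
      f <- rat_arith("0", m[r, cc], "-")
      m[r, ] <- rat_arith(m[r, ], rat_arith(f, m[prow, ], "*"), "+")
    }
    used[prow] <- TRUE
    pivots <- c(pivots, cc)
    pivot_rows <- c(pivot_rows, prow)
  }
  ord <- order(pivots)
  rows <- c(pivot_rows[ord], setdiff(seq_len(nr), pivot_rows))
  list(echelon = m[rows, , drop = FALSE], pivot_columns = sort(pivots),
       rank = length(pivots))
}

# dense character matrix of a random small integer matrix
random_int_matrix <- function(nr, nc, density = 0.4, pool = c(-2L, -1L, 1L, 2L)) {
  m <- matrix(0L, nr, nc)
  nz <- which(matrix(runif(nr * nc) < density, nr, nc))
  m[nz] <- pool[sample.int(length(pool), length(nz), replace = TRUE)]
  matrix(as.character(m), nr, nc)
}

# run the package's C++ dense oracle and wrap the result
cpp_oracle <- function(x, pivot_col_order = integer()) {
  r <- fluxkernel:::cpp_dense_rref(x$nrow, x$ncol, x$i, x$j, x$val,
                                   as.integer(pivot_col_order))
  list(echelon = rational_matrix(r$echelon$nrow, r$echelon$ncol,
                                 r$echelon$i, r$echelon$j, r$echelon$val),
       pivot_columns = r$pivot_columns, rank = r$rank)
}

# exact nullspace via the naive oracle: basis with identity at free columns
oracle_nullspace <- function(m_chr) {
  rr <- r_dense_rref(m_chr)
  nc <- ncol(m_chr)
  piv <- rr$pivot_columns
  fre <- setdiff(seq_len(nc), piv)
  R <- matrix("0", nc, length(fre))
  for (q in seq_along(fre)) {
    R[fre[q], q] <- "1"
    if (length(piv)) {
      col <- rr$echelon[seq_along(piv), fre[q]]
      R[piv, q] <- rat_arith("0", col, "-")
    }
  }
  R
}

expect_exact_zero_product <- function(a, b) {
  expect_identical(length(rmat_mult(a, b)$val), 0L)
}
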