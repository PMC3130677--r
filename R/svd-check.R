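#' Numerical SVD kernel for cross-validation
#'
#' Computes the nullspace of the stoichiometric matrix with a dense
#' numerical singular value decomposition and rebuilds it in the same flux
#' coordinate system as the exact Gauss-Jordan kernel, so the two can be
#' compared entry by entry. The SVD on its own does not determine which
#' fluxes are dependent; the partition must come from the exact
#' elimination. With `V_ker` the orthonormal nullspace basis and `V_indep`
#' its rows at the independent flux indices, the comparable kernel is
#' `R_svd = V_ker %*% solve(V_indep)`, whose rows at the independent
#' indices are (numerically) the identity. The condition number of
#' `V_indep` (ratio of its extreme singular values) governs how many
#' digits the numerical kernel loses.
#'
#' @param N The stoichiometric matrix, a [rational_matrix()] or base
#'   numeric matrix.
#' @param partition The `partition` of a `kernel_result` (or the
#'   `kernel_result` itself) from the exact elimination.
#' @param tol Singular values below `tol * max(singular value)` count as
#'   zero; default is the standard rank tolerance
#'   `max(dim(N)) * .Machine$double.eps`.
#' @return An object of class `svd_kernel` with `V_ker` (n x f,
#'   orthonormal columns), `V_indep` (f x f), `R_svd` (n x f), `condition`
#'   and `f`.
#' @export
svd_kernel <- function(N, partition, tol = NULL) {
  if (inherits(partition, "kernel_result")) partition <- partition$partition
  A <- if (inherits(N, "rational_matrix")) as.matrix(N) else N
  indep <- partition$independent
  f <- length(indep)
  if (f < 1L)
    fk_stop("fk_input_error", "trivial kernel (f = 0): nothing to compare")
  n <- ncol(A)
  sv <- svd(A, nu = 0, nv = n)
  smax <- if (length(sv$d)) max(sv$d) else 0
  if (is.null(tol)) tol <- max(dim(A)) * .Machine$double.eps
  rank <- sum(sv$d > tol * smax)
  nullity <- n - rank
  if (nullity != f)
    fk_stop("fk_consistency_error",
            "SVD nullspace dimension %d does not match f = %d (rank tolerance problem?)",
            nullity, f)
  V_ker <- sv$v[, seq.int(rank + 1L, n), drop = FALSE]
  V_indep <- V_ker[indep, , drop = FALSE]
  sv_vi <- svd(V_indep, nu = 0, nv = 0)$d
  if (min(sv_vi) <= .Machine$double.eps * f)
    fk_stop("fk_partition_error",
            "V_indep is numerically singular: the supplied independent set does not span the kernel coordinates")
  structure(
    list(V_ker = V_ker, V_indep = V_indep,
         R_svd = V_ker %*% solve(V_indep),
         condition = max(sv_vi) / min(sv_vi), f = f),
    class = "svd_kernel"
  )
}

#' @export
print.svd_kernel <- function(x, ...) {
  cat(sprintf("<svd_kernel: f = %d, condition(V_indep) = %.3g>\n", x$f, x$condition))
  invisible(x)
}

#' Maximal relative flux error of the numerical kernel
#'
#' The largest entrywise discrepancy between the numerical SVD kernel and
#' the exact Gauss-Jordan kernel, normalised by the largest exact kernel
#' magnitude: `max |r_svd - r_gje| / max |r_gje|`. The exact kernel is the
#' reference, so this measures the error the numerical route introduces;
#' it is 0 exactly when the two kernels are identical, and its order of
#' magnitude approximates the number of inaccurate digits in the
#' numerical dependent fluxes.
#'
#' @param R_gje Exact kernel, a [rational_matrix()] (or numeric matrix).
#' @param R_svd Numerical kernel matrix of the same shape.
#' @return A non-negative number.
#' @export
epsilon_svd <- function(R_gje, R_svd) {
  G <- if (inherits(R_gje, "rational_matrix")) as.matrix(R_gje) else R_gje
  if (!all(dim(G) == dim(R_svd)))
    fk_stop("fk_input_error", "kernel shapes differ: %s vs %s",
            paste(dim(G), collapse = "x"), paste(dim(R_svd), collapse = "x"))
  denom <- max(abs(G))
  if (denom == 0) fk_stop("fk_input_error", "reference kernel is zero")
  max(abs(R_svd - G)) / denom
}

#' Principal angles between two kernel column spaces
#'
#' Orthonormalises both bases and returns the principal angles (radians)
#' between their column spans; all angles near zero means the two bases
#' describe the same steady-state flux space.
#'
#' @param A,B Matrices (or [rational_matrix()]s) with the same number of
#'   rows and columns.
#' @return Numeric vector of principal angles.
#' @export
principal_angles <- function(A, B) {
  A <- if (inherits(A, "rational_matrix")) as.matrix(A) else A
  B <- if (inherits(B, "rational_matrix")) as.matrix(B) else B
  if (nrow(A) != nrow(B))
    fk_stop("fk_input_error", "bases must have the same number of rows")
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  cosv <- sort(pmin(pmax(svd(crossprod(qa, qb), nu = 0, nv = 0)$d, -1), 1),
               decreasing = TRUE)
  # cosine-based values lose accuracy near 0; use the sine-based residual
  # formula for small angles (Bjorck-Golub)
  sinv <- sort(pmin(svd(qb - qa %*% crossprod(qa, qb), nu = 0, nv = 0)$d, 1))
  ifelse(cosv^2 > 0.5, asin(sinv), acos(cosv))
}

#' Cross-validation report
#'
#' Bundles the quantities a researcher checks after a solve: the kernel
#' dimension, the condition number of `V_indep`, the maximal relative flux
#' error of the numerical kernel, and the sparsity of both kernels (the
#' exact kernel exactly; the numerical orthonormal basis with a magnitude
#' threshold).
#'
#' @param kernel The exact `kernel_result`.
#' @param svdk The matching `svd_kernel`.
#' @param path Optional JSON output path.
#' @param zero_tol Magnitude threshold for counting numerical zeros.
#' @return Named list with `f`, `condition`, `epsilon_svd`,
#'   `sparsity_gje`, `sparsity_svd`; written as JSON when `path` is given.
#' @export
svd_report <- function(kernel, svdk, path = NULL, zero_tol = 1e-9) {
  rep <- list(
    schema = "fluxkernel/svd-check/v1",
    f = svdk$f,
    condition = svdk$condition,
    epsilon_svd = epsilon_svd(kernel$R, svdk$R_svd),
    sparsity_gje = sparsity(kernel$R),
    sparsity_svd = sparsity(svdk$V_ker, tol = zero_tol)
  )
  if (!is.null(path)) jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  rep
}
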