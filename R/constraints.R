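#' Constraint systems on the independent fluxes
#'
#' Measured independent fluxes and sign (irreversibility) constraints on
#' dependent fluxes both restrict the steady-state flux space. In the
#' independent-flux coordinate system provided by the exact kernel, a
#' measurement becomes an equality row on the coordinates and a sign
#' constraint on dependent flux d becomes an inequality on the
#' coordinates through d's kernel row (`v_dep = R_dep v_indep >= 0` for an
#' irreversible producing reaction). The assembled system defines a convex
#' polytope, typically with many redundant constraints.
#'
#' @param kernel A `kernel_result` from [build_kernel()].
#' @param flux_ids Character vector naming all fluxes in column order.
#' @param measured Named vector: independent flux id -> measured rational
#'   value (character or numeric). May be empty.
#' @param sign_constraints Named character vector: dependent flux id ->
#'   `"nonnegative"` or `"nonpositive"`. May be empty.
#' @return An object of class `constraint_system` with the coefficient
#'   rows `A` (character matrix over the independent fluxes), right-hand
#'   side `b`, row `sense` (`"eq"`, `"ge"`, `"le"`), row `labels`, the
#'   independent flux ids, and the counts `n_equalities`,
#'   `n_inequalities`.
#' @export
assemble_system <- function(kernel, flux_ids, measured = character(),
                            sign_constraints = character()) {
  if (length(flux_ids) != kernel$R$nrow)
    fk_stop("fk_input_error", "expected %d flux ids, got %d",
            kernel$R$nrow, length(flux_ids))
  indep_idx <- kernel$partition$independent
  dep_idx <- kernel$partition$dependent
  indep_ids <- flux_ids[indep_idx]
  dep_ids <- flux_ids[dep_idx]
  f <- length(indep_idx)
  A <- matrix("0", 0L, f)
  b <- character(); sense <- character(); labels <- character()
  if (length(measured)) {
    bad <- setdiff(names(measured), indep_ids)
    if (length(bad))
      fk_stop("fk_input_error", "measured ids are not independent fluxes: %s",
              paste(bad, collapse = ", "))
    for (id in names(measured)) {
      row <- rep("0", f); row[match(id, indep_ids)] <- "1"
      A <- rbind(A, row); b <- c(b, as_rational(measured[[id]]))
      sense <- c(sense, "eq"); labels <- c(labels, paste0("measured:", id))
    }
  }
  if (length(sign_constraints)) {
    bad <- setdiff(names(sign_constraints), dep_ids)
    if (length(bad))
      fk_stop("fk_input_error",
              "sign-constraint ids are not dependent fluxes: %s",
              paste(bad, collapse = ", "))
    Rchr <- as_character_matrix(kernel$R)
    for (id in names(sign_constraints)) {
      sgn <- sign_constraints[[id]]
      if (!sgn %in% c("nonnegative", "nonpositive"))
        fk_stop("fk_input_error", "sign must be 'nonnegative' or 'nonpositive', got '%s'", sgn)
      row <- Rchr[flux_ids == id, , drop = TRUE]
      A <- rbind(A, row); b <- c(b, "0")
      sense <- c(sense, if (sgn == "nonnegative") "ge" else "le")
      labels <- c(labels, paste0("sign:", id))
    }
  }
  dimnames(A) <- NULL
  structure(
    list(A = A, b = b, sense = sense, labels = labels,
         indep_ids = indep_ids, dep_ids = dep_ids,
         n_equalities = sum(sense == "eq"),
         n_inequalities = sum(sense != "eq"),
         n_relations = length(dep_ids)),
    class = "constraint_system"
  )
}

#' @export
print.constraint_system <- function(x, ...) {
  cat(sprintf("<constraint_system: %d flux relations, %d measured equalities, %d inequalities on %d independent flux(es)>\n",
              x$n_relations, x$n_equalities, x$n_inequalities, length(x$indep_ids)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# dense exact-rational helpers (character matrices of canonical "p/q")

rq_add <- function(A, B) {
  r <- rat_arith(A, B, "+"); dim(r) <- dim(A); r
}

rq_scale <- function(A, s) {
  r <- rat_arith(A, s, "*"); dim(r) <- dim(A); r
}

rq_mult <- function(A, B) {
  ra <- nrow(A); cb <- ncol(B)
  C <- matrix("0", ra, cb)
  for (k in seq_len(ncol(A))) {
    term <- rat_arith(rep(A[, k], times = cb), rep(B[k, ], each = ra), "*")
    C <- rq_add(C, matrix(term, ra, cb))
  }
  C
}

rq_matvec <- function(A, v) as.vector(rq_mult(A, matrix(v, ncol = 1L)))

rq_neg <- function(A) {
  v <- as.vector(A)
  neg <- startsWith(v, "-") & v != "0"
  out <- v
  out[neg] <- substring(v[neg], 2L)
  out[!neg & v != "0"] <- paste0("-", v[!neg & v != "0"])
  dim(out) <- dim(A)
  out
}

rq_from_dense <- function(A) as_rational_matrix(A)

rq_gje <- function(A, preferred = integer(), forbidden = integer()) {
  e <- gauss_jordan_eliminate(rq_from_dense(A), preferred, forbidden)
  list(echelon = as_character_matrix(e$echelon),
       pivot_columns = e$pivot_columns, free_columns = e$free_columns,
       rank = e$rank)
}

# basis of { x : A x = 0 } as a character matrix (ncol(A) x nullity)
rq_nullspace <- function(A) {
  if (nrow(A) == 0L) return(diag_chr(ncol(A)))
  e <- gauss_jordan_eliminate(rq_from_dense(A))
  k <- build_kernel(e, ncol(A))
  as_character_matrix(k$R)
}

diag_chr <- function(n) {
  m <- matrix("0", n, n)
  if (n) diag(m) <- "1"
  m
}

# exact solve of E x = e. Returns the affine solution set x = x0 + B y
# (y the free coordinates), or feasible = FALSE.
affine_solve <- function(E, e) {
  D <- ncol(E)
  if (nrow(E) == 0L)
    return(list(feasible = TRUE, x0 = rep("0", D), B = diag_chr(D),
                free = seq_len(D)))
  aug <- cbind(E, e)
  g <- rq_gje(aug, forbidden = D + 1L)
  if ((D + 1L) %in% g$pivot_columns)
    return(list(feasible = FALSE))
  piv <- g$pivot_columns
  fre <- setdiff(seq_len(D), piv)
  x0 <- rep("0", D)
  x0[piv] <- g$echelon[seq_along(piv), D + 1L]
  B <- matrix("0", D, length(fre))
  if (length(fre)) {
    B[cbind(fre, seq_along(fre))] <- "1"
    if (length(piv)) {
      blk <- g$echelon[seq_along(piv), fre, drop = FALSE]
      B[piv, ] <- rq_neg(blk)
    }
  }
  list(feasible = TRUE, x0 = x0, B = B, free = fre)
}

# canonical scaling for dedup: divide by |first nonzero entry|
canon_dir <- function(v) {
  nz <- which(v != "0")
  if (!length(nz)) return(v)
  lead <- v[nz[[1]]]
  mag <- if (startsWith(lead, "-")) substring(lead, 2L) else lead
  rat_arith(v, mag, "/")
}

# vertices and extreme rays of the pointed polyhedron { z : A z <= c }.
# A must have trivial nullspace (lineality removed beforehand).
vertex_enum_pointed <- function(A, c) {
  k <- ncol(A); m <- nrow(A)
  if (k == 0L) {
    ok <- !length(c) || all(rat_compare(c, "0") >= 0)
    return(list(vertices = if (ok) list(character(0)) else list(), rays = list()))
  }
  vertices <- list(); seen_v <- character()
  if (m >= k) {
    for (S in asplit(combn(m, k), 2L)) {
      sol <- affine_solve(A[S, , drop = FALSE], c[S])
      if (!sol$feasible || length(sol$free)) next
      v <- sol$x0
      lhs <- rq_matvec(A, v)
      if (all(rat_compare(lhs, c) <= 0)) {
        key <- paste(v, collapse = ",")
        if (!key %in% seen_v) { seen_v <- c(seen_v, key); vertices <- c(vertices, list(v)) }
      }
    }
  }
  rays <- list(); seen_r <- character()
  subsets <- if (k == 1L) list(integer(0)) else if (m >= k - 1L)
    asplit(combn(m, k - 1L), 2L) else list()
  for (S in subsets) {
    ns <- rq_nullspace(A[S, , drop = FALSE])
    if (ncol(ns) != 1L) next
    v <- canon_dir(as.vector(ns))
    for (dir in list(v, rq_neg(matrix(v, ncol = 1L))[, 1L])) {
      lhs <- rq_matvec(A, dir)
      if (all(rat_compare(lhs, "0") <= 0)) {
        key <- paste(dir, collapse = ",")
        if (!key %in% seen_r) { seen_r <- c(seen_r, key); rays <- c(rays, list(dir)) }
      }
    }
  }
  list(vertices = vertices, rays = rays)
}

# minimal supporting inequalities (facets) and implicit equalities of
# conv(vertices) + cone(rays) in dimension k. Handles lower-dimensional
# hulls by restricting to the affine hull first.
facet_enum <- function(vertices, rays, k) {
  if (!length(vertices))
    return(list(facets = list(), equalities = list()))
  v0 <- vertices[[1]]
  dirs <- c(lapply(vertices[-1], function(v)
    rat_arith(v, v0, "-")), rays)
  Dm <- if (length(dirs)) do.call(rbind, dirs) else matrix("0", 0L, k)
  a <- if (nrow(Dm)) rq_gje(Dm)$rank else 0L
  equalities <- list()
  if (a < k) {
    W <- rq_nullspace(Dm)   # k x (k - a); columns orthogonal to all dirs
    for (q in seq_len(ncol(W))) {
      w <- W[, q]
      equalities <- c(equalities, list(list(
        a = w, c = sum_rat(rat_arith(w, v0, "*")))))
    }
  }
  if (a == 0L)
    return(list(facets = list(), equalities = equalities))
  if (a < k) {
    # restrict to the affine hull: z = v0 + B t, t = M (z - v0)
    ech <- rq_gje(Dm)$echelon
    B <- t(ech[seq_len(a), , drop = FALSE])      # k x a basis of span(dirs)
    aug <- rq_gje(cbind(B, diag_chr(k)))
    M <- aug$echelon[seq_len(a), a + seq_len(k), drop = FALSE]  # M %*% B = I_a
    tcoord <- function(z) rq_matvec(M, rat_arith(z, v0, "-"))
    tv <- lapply(vertices, tcoord)
    tr <- lapply(rays, function(r) rq_matvec(M, r))
    sub <- facet_enum_fulldim(tv, tr, a)
    facets <- lapply(sub, function(fc) {
      az <- rq_matvec(t(M), fc$a)   # n . M (z - v0) <= c
      list(a = az, c = rat_arith(fc$c, sum_rat(rat_arith(az, v0, "*")), "+"))
    })
    return(list(facets = facets, equalities = equalities))
  }
  list(facets = facet_enum_fulldim(vertices, rays, k), equalities = equalities)
}

sum_rat <- function(v) {
  if (!length(v)) return("0")
  Reduce(function(x, y) rat_arith(x, y, "+"), v)
}

# facets of a full-dimensional pointed polyhedron from its generators
facet_enum_fulldim <- function(vertices, rays, a) {
  gens <- c(lapply(vertices, function(v) c(v, "-1")),
            lapply(rays, function(r) c(r, "0")))
  ng <- length(gens)
  facets <- list(); seen <- character()
  if (ng < a) return(facets)
  for (S in asplit(combn(ng, a), 2L)) {
    Gm <- do.call(rbind, gens[S])
    ns <- rq_nullspace(Gm)      # (a+1)-vector (n, c) with n.v = c, n.r = 0
    if (ncol(ns) != 1L) next
    h <- as.vector(ns)
    n <- h[seq_len(a)]; cc <- h[[a + 1L]]
    if (all(n == "0")) next
    sv <- vapply(vertices, function(v)
      rat_compare(sum_rat(rat_arith(n, v, "*")), cc), 1L)
    sr <- vapply(rays, function(r)
      rat_compare(sum_rat(rat_arith(n, r, "*")), "0"), integer(1))
    s <- c(sv, sr)
    if (all(s <= 0)) {
      # keep as n.x <= c
    } else if (all(s >= 0)) {
      n <- rq_neg(matrix(n, ncol = 1L))[, 1L]
      cc <- rat_arith("-1", cc, "*")
    } else next
    key0 <- canon_dir(c(n, cc))
    key <- paste(key0, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    facets <- c(facets, list(list(a = key0[seq_len(a)], c = key0[[a + 1L]])))
  }
  facets
}

#' Reduce a constraint system to its minimal polytope representation
#'
#' Removes all redundancy from an assembled constraint system by exact
#' geometric computation: measured equalities are eliminated by
#' substitution, invariant (lineality) directions are split off, the
#' vertices and extreme rays of the remaining pointed polyhedron are
#' enumerated, and from those generators the minimal set of facet
#' inequalities is recovered. Everything runs in exact rational
#' arithmetic, so the reduced representation describes exactly the same
#' convex set as the input system. The intermediate V-representation
#' (vertices and rays) is retained — it is the natural input for flux-space
#' scanning applications.
#'
#' @param system A `constraint_system` from [assemble_system()].
#' @return An object of class `polytope` with `feasible`, `H_rep`
#'   (minimal: equality rows then facet rows; matrix `A`, vector `b`,
#'   `sense`), and `V_rep` (`vertices`, `rays`, `lineality`, each a list
#'   of exact rational coordinate vectors over the independent fluxes).
#'   An infeasible system yields `feasible = FALSE` with an empty
#'   V-representation, not an error.
#' @export
reduce_polytope <- function(system) {
  f <- length(system$indep_ids)
  if (f < 1L) fk_stop("fk_input_error", "no independent fluxes to constrain")
  empty <- function() structure(
    list(feasible = FALSE,
         H_rep = list(A = matrix("0", 0L, f), b = character(), sense = character()),
         V_rep = list(vertices = list(), rays = list(), lineality = list()),
         indep_ids = system$indep_ids),
    class = "polytope")
  eq <- system$sense == "eq"
  sol <- affine_solve(system$A[eq, , drop = FALSE], system$b[eq])
  if (!sol$feasible) return(empty())
  d <- length(sol$free)
  # inequalities over the free coordinates y, normalised to a.y <= c
  Ai <- system$A[!eq, , drop = FALSE]
  bi <- system$b[!eq]
  flip <- system$sense[!eq] == "ge"
  if (nrow(Ai)) {
    Ay <- rq_mult(Ai, sol$B)
    cy <- rat_arith(bi, rq_matvec(Ai, sol$x0), "-")
    if (any(flip)) {
      Ay[flip, ] <- rq_neg(Ay[flip, , drop = FALSE])
      cy[flip] <- rat_arith("-1", cy[flip], "*")
    }
    trivial <- apply(Ay, 1L, function(r) all(r == "0"))
    if (any(trivial & rat_compare(cy, "0") < 0)) return(empty())
    Ay <- Ay[!trivial, , drop = FALSE]; cy <- cy[!trivial]
  } else {
    Ay <- matrix("0", 0L, d); cy <- character()
  }
  # lineality of the recession cone: directions no inequality sees
  L <- rq_nullspace(Ay)                      # d x l
  l <- ncol(L)
  if (l > 0L) {
    solL <- affine_solve(t(L), rep("0", l))  # y = B2 z with L^T y = 0
    B2 <- solL$B
    free2 <- solL$free
  } else {
    B2 <- diag_chr(d)
    free2 <- seq_len(d)
  }
  k <- ncol(B2)
  Az <- if (nrow(Ay)) rq_mult(Ay, B2) else matrix("0", 0L, k)
  en <- vertex_enum_pointed(Az, cy)
  if (!length(en$vertices)) return(empty())
  fc <- facet_enum(en$vertices, en$rays, k)
  # lift z -> y -> x
  lift_point <- function(z) rat_arith(sol$x0, rq_matvec(sol$B, rq_matvec(B2, z)), "+")
  lift_dir <- function(z) rq_matvec(sol$B, rq_matvec(B2, z))
  y_fun_to_x <- function(ay) {
    # y are the free coordinates of x, so a y-functional just re-indexes;
    # the offset needs no adjustment because x0 vanishes on the free block
    ax <- rep("0", f); ax[sol$free] <- ay; ax
  }
  # Every facet (and implicit equality) of the polyhedron is represented by
  # one of the original inequality rows; identify it by its active
  # generators. Original rows are orthogonal to the lineality by
  # construction, so they remain valid on the whole polyhedron.
  active_set <- function(a, cc) {
    av <- vapply(en$vertices, function(v)
      rat_compare(sum_rat(rat_arith(a, v, "*")), cc) == 0L, TRUE)
    ar <- vapply(en$rays, function(r)
      rat_compare(sum_rat(rat_arith(a, r, "*")), "0") == 0L, TRUE)
    c(av, ar)
  }
  row_active <- lapply(seq_len(nrow(Az)), function(q) active_set(Az[q, ], cy[[q]]))
  implicit_eq <- which(vapply(row_active, all, TRUE))
  H_A <- matrix("0", 0L, f); H_b <- character(); H_s <- character()
  if (sum(eq)) {
    H_A <- system$A[eq, , drop = FALSE]; H_b <- system$b[eq]
    H_s <- rep("eq", sum(eq))
  }
  for (q in implicit_eq) {
    H_A <- rbind(H_A, y_fun_to_x(Ay[q, ])); H_b <- c(H_b, cy[[q]])
    H_s <- c(H_s, "eq")
  }
  for (f2 in fc$facets) {
    fa <- active_set(f2$a, f2$c)
    q <- NULL
    for (qq in setdiff(seq_len(nrow(Az)), implicit_eq)) {
      if (all(row_active[[qq]][fa]) && !all(row_active[[qq]])) { q <- qq; break }
    }
    if (is.null(q))
      fk_stop("fk_internal_error", "facet without a defining input inequality")
    H_A <- rbind(H_A, y_fun_to_x(Ay[q, ])); H_b <- c(H_b, cy[[q]])
    H_s <- c(H_s, "le")
  }
  dimnames(H_A) <- NULL
  lineality_x <- lapply(seq_len(l), function(q) rq_matvec(sol$B, L[, q]))
  structure(
    list(feasible = TRUE,
         H_rep = list(A = H_A, b = H_b, sense = H_s),
         V_rep = list(vertices = lapply(en$vertices, lift_point),
                      rays = lapply(en$rays, lift_dir),
                      lineality = lineality_x),
         indep_ids = system$indep_ids),
    class = "polytope")
}

#' @export
print.polytope <- function(x, ...) {
  if (!x$feasible) {
    cat("<polytope: infeasible (empty)>\n")
    return(invisible(x))
  }
  cat(sprintf("<polytope in %d independent flux(es): %d vertices, %d rays, %d lineality direction(s); minimal H-rep: %d equalities + %d facets>\n",
              length(x$indep_ids), length(x$V_rep$vertices), length(x$V_rep$rays),
              length(x$V_rep$lineality), sum(x$H_rep$sense == "eq"),
              sum(x$H_rep$sense == "le")))
  invisible(x)
}

#' Per-flux bounds from a reduced polytope
#'
#' Reads each independent flux's exact lower and upper bound off the
#' V-representation: the extremes over the vertices, widened to infinity
#' in any direction an unbounded ray (or lineality direction) opens.
#'
#' @param polytope A feasible `polytope` from [reduce_polytope()].
#' @param flux_ids Optional subset of independent flux ids (default all).
#' @return Data frame with columns `flux`, `lower`, `upper` (exact
#'   rational strings, `"-Inf"`/`"Inf"` where unbounded) and decimal
#'   companions `lower_decimal`, `upper_decimal`.
#' @export
bounds_per_flux <- function(polytope, flux_ids = NULL) {
  if (!polytope$feasible)
    fk_stop("fk_infeasible_error",
            "constraint system is infeasible: the polytope is empty")
  ids <- polytope$indep_ids
  if (is.null(flux_ids)) flux_ids <- ids
  bad <- setdiff(flux_ids, ids)
  if (length(bad))
    fk_stop("fk_input_error", "unknown independent fluxes: %s",
            paste(bad, collapse = ", "))
  V <- do.call(cbind, lapply(polytope$V_rep$vertices, function(v) v))
  res <- lapply(flux_ids, function(id) {
    kq <- match(id, ids)
    coords <- V[kq, ]
    ord <- order(rat_to_double(coords))
    lo <- coords[ord[[1]]]; hi <- coords[ord[[length(ord)]]]
    # exact extremes (double ordering is only a shortlist; confirm exactly)
    for (cd in coords) {
      if (rat_compare(cd, lo) < 0) lo <- cd
      if (rat_compare(cd, hi) > 0) hi <- cd
    }
    for (r in polytope$V_rep$rays) {
      s <- rat_compare(r[[kq]], "0")
      if (s < 0) lo <- "-Inf"
      if (s > 0) hi <- "Inf"
    }
    for (r in polytope$V_rep$lineality) {
      if (r[[kq]] != "0") { lo <- "-Inf"; hi <- "Inf" }
    }
    data.frame(flux = id, lower = lo, upper = hi,
               lower_decimal = if (lo == "-Inf") -Inf else rat_to_double(lo),
               upper_decimal = if (hi == "Inf") Inf else rat_to_double(hi),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write polytope representations and bounds
#'
#' `write_polytope_json()` stores both the minimal H-representation and
#' the V-representation; `write_bounds_tsv()` stores the per-flux bound
#' table.
#'
#' @param polytope A `polytope`.
#' @param bounds A bounds data frame from [bounds_per_flux()].
#' @param path Output file.
#' @export
write_polytope_json <- function(polytope, path) {
  H <- polytope$H_rep
  obj <- list(
    schema = "fluxkernel/polytope/v1",
    feasible = polytope$feasible,
    indep_ids = polytope$indep_ids,
    H_rep = lapply(seq_along(H$b), function(k)
      list(a = H$A[k, ], b = H$b[[k]], sense = H$sense[[k]])),
    V_rep = polytope$V_rep
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_polytope_json
#' @export
write_bounds_tsv <- function(bounds, path) {
  utils::write.table(bounds, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read measured fluxes / sign constraints from TSV
#'
#' `read_measured_tsv()` expects columns `flux_id`, `value`;
#' `read_signs_tsv()` expects `flux_id`, `sign` with sign `nonnegative` or
#' `nonpositive`.
#'
#' @param path TSV file path.
#' @return A named character vector.
#' @export
read_measured_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", stringsAsFactors = FALSE)
  if (!all(c("flux_id", "value") %in% names(df)))
    fk_stop("fk_parse_error", "%s must have columns flux_id, value", path)
  setNames(as_rational(df$value), df$flux_id)
}

#' @rdname read_measured_tsv
#' @export
read_signs_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", stringsAsFactors = FALSE)
  if (!all(c("flux_id", "sign") %in% names(df)))
    fk_stop("fk_parse_error", "%s must have columns flux_id, sign", path)
  setNames(df$sign, df$flux_id)
}
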