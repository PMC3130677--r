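#' Build the steady-state kernel from an elimination result
#'
#' Given the reduced row-echelon form of an m x n stoichiometric matrix N,
#' assembles the n x f kernel matrix R whose columns are flux basis
#' vectors: N %*% R = 0 exactly, the rows of R at the independent flux
#' indices form the f x f identity, and the row for dependent flux d is
#' read off the echelon form (negated coefficients of the independent
#' columns in d's pivot row). The independent fluxes are thus coordinates
#' of the steady-state flux space and each column of R describes how all
#' dependent fluxes respond to one independent flux.
#'
#' @param elimination An `elimination_result` from
#'   [gauss_jordan_eliminate()] applied to the stoichiometric matrix.
#' @param n_fluxes Number of reactions n (columns of the eliminated
#'   matrix).
#' @return An object of class `kernel_result` with `partition` (ordered
#'   `dependent` and `independent` column indices and the column
#'   `permutation` placing dependent columns first), the exact kernel `R`
#'   (a [rational_matrix()]), `source = "gje"` and any
#'   `moved_to_dependent` columns inherited from the elimination.
#' @examples
#' n <- as_rational_matrix(matrix(c(1, -1), 1, 2))
#' k <- build_kernel(gauss_jordan_eliminate(n), 2)
#' as.matrix(k$R)   # chain A -> B: both fluxes equal
#' @export
build_kernel <- function(elimination, n_fluxes) {
  if (!inherits(elimination, "elimination_result"))
    fk_stop("fk_input_error", "expected an elimination_result")
  n_fluxes <- as.integer(n_fluxes)
  if (n_fluxes != elimination$n_cols)
    fk_stop("fk_input_error",
            "n_fluxes (%d) does not match the eliminated matrix (%d columns)",
            n_fluxes, elimination$n_cols)
  dep <- elimination$pivot_columns
  indep <- elimination$free_columns
  f <- length(indep)
  ech <- elimination$echelon
  # dependent rows: -(echelon coefficient of each independent column)
  keep <- ech$i <= elimination$rank & ech$j %in% indep
  ri <- dep[ech$i[keep]]
  rj <- match(ech$j[keep], indep)
  rv <- ech$val[keep]
  neg <- startsWith(rv, "-")
  rv[neg] <- substring(rv[neg], 2L)
  rv[!neg] <- paste0("-", rv[!neg])
  # identity block at the independent rows
  R <- rational_matrix(n_fluxes, f,
                       i = c(ri, indep), j = c(rj, seq_len(f)),
                       value = c(rv, rep("1", f)))
  structure(
    list(
      partition = list(dependent = dep, independent = indep,
                       permutation = c(dep, indep)),
      R = R,
      source = "gje",
      moved_to_dependent = elimination$moved_to_dependent
    ),
    class = "kernel_result"
  )
}

#' @export
print.kernel_result <- function(x, ...) {
  cat(sprintf("<kernel_result (%s): %d fluxes = %d dependent + %d independent, kernel sparsity %.3f>\n",
              x$source, x$R$nrow, length(x$partition$dependent),
              length(x$partition$independent),
              if (x$R$ncol > 0) sparsity(x$R) else NA_real_))
  if (length(x$moved_to_dependent))
    cat("  requested independent fluxes moved to dependent:",
        paste(x$moved_to_dependent, collapse = ", "), "\n")
  invisible(x)
}

#' Steady-state flux relations
#'
#' Expresses each dependent flux as an exact linear combination of the
#' independent fluxes (one relation per pivot row of the echelon form,
#' i.e. per dependent flux). Relations are ordered by dependent flux in
#' original reaction order; terms are ordered by independent flux index.
#'
#' @param kernel A `kernel_result` from [build_kernel()].
#' @param flux_ids Character vector naming all n fluxes in column order.
#' @return An object of class `flux_relations`: a data frame in long form
#'   with columns `dependent`, `independent`, `coefficient` (exact
#'   rational strings, zero coefficients omitted), plus attributes
#'   `constants` (per-dependent additive constants, all `"0"` before
#'   substitution), `dependent_ids`, `independent_ids` and `assigned`.
#' @export
flux_relations <- function(kernel, flux_ids) {
  if (length(flux_ids) != kernel$R$nrow)
    fk_stop("fk_input_error", "expected %d flux ids, got %d",
            kernel$R$nrow, length(flux_ids))
  dep <- kernel$partition$dependent
  indep <- kernel$partition$independent
  R <- kernel$R
  keep <- R$i %in% dep
  rel <- data.frame(
    dependent = flux_ids[R$i[keep]],
    independent = flux_ids[indep[R$j[keep]]],
    coefficient = R$val[keep],
    stringsAsFactors = FALSE
  )
  rel <- rel[order(match(rel$dependent, flux_ids),
                   match(rel$independent, flux_ids)), , drop = FALSE]
  rownames(rel) <- NULL
  structure(rel,
            constants = setNames(rep("0", length(dep)), flux_ids[sort(dep)]),
            dependent_ids = flux_ids[sort(dep)],
            independent_ids = flux_ids[indep],
            assigned = character(),
            class = c("flux_relations", "data.frame"))
}

#' Render flux relations as text
#'
#' Human-readable equations such as `"v_PGI = v_EX_glc - 2*v_ZWF"`, with
#' exact rational coefficients (and their decimal value where that aids
#' reading).
#'
#' @param relations A `flux_relations` object.
#' @return Character vector, one equation per dependent flux.
#' @export
format_relations <- function(relations) {
  constants <- attr(relations, "constants")
  vapply(attr(relations, "dependent_ids"), function(d) {
    rows <- relations[relations$dependent == d, , drop = FALSE]
    terms <- character()
    for (k in seq_len(nrow(rows))) {
      cf <- rows$coefficient[k]
      neg <- startsWith(cf, "-")
      mag <- if (neg) substring(cf, 2L) else cf
      t <- if (mag == "1") rows$independent[k] else paste0(mag, "*", rows$independent[k])
      terms <- c(terms, paste0(if (neg) "- " else if (length(terms)) "+ " else "", t))
    }
    cst <- constants[[d]]
    if (cst != "0" || !length(terms)) {
      terms <- c(terms, paste0(
        if (startsWith(cst, "-")) "- " else if (length(terms)) "+ " else "",
        sub("^-", "", cst)))
    }
    paste(d, "=", paste(terms, collapse = " "))
  }, "", USE.NAMES = FALSE)
}

#' @export
print.flux_relations <- function(x, ...) {
  eqs <- format_relations(x)
  cat(sprintf("<%d flux relation(s) on %d independent flux(es)>\n",
              length(attr(x, "dependent_ids")), length(attr(x, "independent_ids"))))
  cat(head(eqs, 20), sep = "\n")
  if (length(eqs) > 20) cat(sprintf("... (%d more)\n", length(eqs) - 20))
  invisible(x)
}

#' Substitute measured values into flux relations
#'
#' Folds exact measured values for independent fluxes into the relations:
#' assigned terms move into the per-relation constant, a dependent flux
#' becomes fully determined once all of its terms are assigned, and the
#' remaining independent fluxes are reported as still free. All arithmetic
#' is exact.
#'
#' @param relations A `flux_relations` object.
#' @param assignments Named vector (independent flux id -> rational value,
#'   character or numeric).
#' @return A list with `relations` (updated), `fully_determined`
#'   (dependent flux ids with no remaining free terms) and `still_free`
#'   (unassigned independent flux ids).
#' @export
substitute_fluxes <- function(relations, assignments) {
  if (!inherits(relations, "flux_relations"))
    fk_stop("fk_input_error", "expected a flux_relations object")
  if (!length(assignments))
    return(list(relations = relations,
                fully_determined = fully_determined_ids(relations),
                still_free = attr(relations, "independent_ids")))
  vals <- as_rational(assignments)
  names(vals) <- names(assignments)
  indep <- attr(relations, "independent_ids")
  bad <- setdiff(names(vals), indep)
  if (length(bad))
    fk_stop("fk_input_error",
            "not independent fluxes (dependent fluxes are constrained via the constraint system): %s",
            paste(bad, collapse = ", "))
  constants <- attr(relations, "constants")
  hit <- relations$independent %in% names(vals)
  if (any(hit)) {
    contrib <- rat_arith(relations$coefficient[hit],
                         vals[relations$independent[hit]], "*")
    for (k in which(hit)) {
      d <- relations$dependent[k]
      constants[[d]] <- rat_arith(constants[[d]], contrib[[match(k, which(hit))]], "+")
    }
    relations <- relations[!hit, , drop = FALSE]
  }
  attr(relations, "constants") <- constants
  attr(relations, "assigned") <- c(attr(relations, "assigned"),
                                   setNames(unname(vals), names(vals)))
  attr(relations, "still_free") <- NULL
  class(relations) <- c("flux_relations", "data.frame")
  list(
    relations = relations,
    fully_determined = fully_determined_ids(relations),
    still_free = setdiff(indep, names(attr(relations, "assigned")))
  )
}

fully_determined_ids <- function(relations) {
  dep <- attr(relations, "dependent_ids")
  dep[!dep %in% unique(relations$dependent)]
}

#' Write flux relations as TSV
#'
#' Long-form table `(dependent_id, independent_id, coefficient)` with the
#' coefficient both as an exact rational string and as a decimal
#' approximation.
#'
#' @param relations A `flux_relations` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_relations_tsv <- function(relations, path) {
  out <- data.frame(
    dependent_id = relations$dependent,
    independent_id = relations$independent,
    coefficient = relations$coefficient,
    coefficient_decimal = rat_to_double(relations$coefficient),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sub-networks controlled by each independent flux
#'
#' Every independent flux controls the set of dependent fluxes with
#' nonzero entries in its kernel column; those sets form sub-networks of
#' the metabolism, and sub-networks sharing a dependent flux merge into
#' connected components (computed on the bipartite independent/dependent
#' sharing graph). Only the sparse Gauss-Jordan kernel supports this
#' reading; a dense orthonormal SVD basis is refused because its columns
#' mix the whole network.
#'
#' @param kernel A `kernel_result` with `source = "gje"`.
#' @param flux_ids Character vector naming all fluxes in column order.
#' @param restrict_to Optional character vector of independent flux ids to
#'   analyse (default: all).
#' @return An object of class `subnetwork_decomposition`: list with
#'   `per_independent` (named list of dependent flux id sets) and
#'   `components` (list of merged flux id sets, each containing the
#'   independent fluxes and the dependent fluxes they control).
#' @export
identify_subnetworks <- function(kernel, flux_ids, restrict_to = NULL) {
  if (!identical(kernel$source, "gje"))
    fk_stop("fk_input_error",
            "sub-network decomposition requires a GJE kernel; the dense SVD basis is not interpretable this way")
  if (length(flux_ids) != kernel$R$nrow)
    fk_stop("fk_input_error", "expected %d flux ids, got %d",
            kernel$R$nrow, length(flux_ids))
  indep_ids <- flux_ids[kernel$partition$independent]
  if (is.null(restrict_to)) restrict_to <- indep_ids
  bad <- setdiff(restrict_to, indep_ids)
  if (length(bad))
    fk_stop("fk_input_error", "not independent fluxes: %s", paste(bad, collapse = ", "))
  R <- kernel$R
  dep_set <- kernel$partition$dependent
  per <- lapply(setNames(restrict_to, restrict_to), function(id) {
    jcol <- match(id, indep_ids)
    rows <- R$i[R$j == jcol]
    flux_ids[intersect(rows, dep_set)]
  })
  edges <- do.call(rbind, lapply(names(per), function(id) {
    if (!length(per[[id]])) return(NULL)
    cbind(id, per[[id]])
  }))
  if (is.null(edges)) {
    comps <- lapply(names(per), function(id) id)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    isolated <- setdiff(names(per), edges[, 1])
    if (length(isolated)) g <- igraph::add_vertices(g, length(isolated), name = isolated)
    mem <- igraph::components(g)$membership
    comps <- unname(lapply(split(names(mem), mem), identity))
  }
  structure(list(per_independent = per, components = comps),
            class = "subnetwork_decomposition")
}

#' @export
print.subnetwork_decomposition <- function(x, ...) {
  cat(sprintf("<subnetwork_decomposition: %d independent flux(es), %d merged component(s)>\n",
              length(x$per_independent), length(x$components)))
  invisible(x)
}

#' Write a sub-network decomposition as JSON
#' @param decomposition A `subnetwork_decomposition`.
#' @param path Output file.
#' @export
write_subnetworks_json <- function(decomposition, path) {
  jsonlite::write_json(
    list(schema = "fluxkernel/subnetworks/v1",
         per_independent = decomposition$per_independent,
         components = decomposition$components),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
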