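#' Synthetic stoichiometric fixtures
#'
#' Random sparse integer stoichiometric matrices with a known kernel
#' dimension, the block-diagonal doubling construction used to scale
#' networks, and small hand-built pathway networks with hand-derived
#' kernels. These emulate the structural features that make sparse exact
#' elimination effective on real networks — high sparsity and small
#' integer coefficients (mostly 1 and -1) — without claiming biological
#' realism of the topology.
#'
#' @param n_species,n_reactions Matrix dimensions (species x reactions).
#' @param target_rank Exact rank of the generated matrix; the kernel
#'   dimension is `n_reactions - target_rank`.
#' @param coefficient_pool Small integers the extra entries are drawn
#'   from.
#' @param sparsity_target Approximate fraction of zero entries aimed for
#'   when placing extra coefficients.
#' @param seed Integer seed; identical specs give identical matrices.
#' @return `fixture_spec()`: a validated spec object.
#' @export
fixture_spec <- function(n_species, n_reactions, target_rank,
                         coefficient_pool = c(-2L, -1L, 1L, 2L),
                         sparsity_target = 0.9, seed = 1L) {
  if (target_rank > min(n_species, n_reactions))
    fk_stop("fk_input_error",
            "target_rank (%d) exceeds min(n_species, n_reactions) = %d",
            target_rank, min(n_species, n_reactions))
  if (target_rank < 1L)
    fk_stop("fk_input_error", "target_rank must be at least 1")
  if (any(coefficient_pool == 0L))
    fk_stop("fk_input_error", "coefficient_pool must not contain 0")
  if (sparsity_target < 0 || sparsity_target >= 1)
    fk_stop("fk_input_error", "sparsity_target must be in [0, 1)")
  structure(list(n_species = as.integer(n_species),
                 n_reactions = as.integer(n_reactions),
                 target_rank = as.integer(target_rank),
                 coefficient_pool = as.integer(coefficient_pool),
                 sparsity_target = sparsity_target,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# sparse integer factor with an embedded identity block, guaranteeing
# exact rank: extra entries never touch the identity rows/cols
sparse_factor <- function(nr, nc, rank, pool, extra_density, identity_in_rows) {
  ii <- integer(); jj <- integer(); vv <- integer()
  if (identity_in_rows) {
    id_rows <- sort(sample.int(nr, rank))
    ii <- id_rows; jj <- seq_len(rank); vv <- rep(1L, rank)
    other <- setdiff(seq_len(nr), id_rows)
    if (length(other) && nc > 0L) {
      n_extra <- max(length(other), round(extra_density * length(other) * nc))
      ei <- other[sample.int(length(other), n_extra, replace = TRUE)]
      ej <- sample.int(nc, n_extra, replace = TRUE)
      keep <- !duplicated(cbind(ei, ej))
      ii <- c(ii, ei[keep]); jj <- c(jj, ej[keep])
      vv <- c(vv, pool[sample.int(length(pool), sum(keep), replace = TRUE)])
    }
  } else {
    id_cols <- sort(sample.int(nc, rank))
    ii <- seq_len(rank); jj <- id_cols; vv <- rep(1L, rank)
    other <- setdiff(seq_len(nc), id_cols)
    if (length(other) && nr > 0L) {
      n_extra <- max(length(other), round(extra_density * length(other) * nr))
      ei <- sample.int(nr, n_extra, replace = TRUE)
      ej <- other[sample.int(length(other), n_extra, replace = TRUE)]
      keep <- !duplicated(cbind(ei, ej))
      ii <- c(ii, ei[keep]); jj <- c(jj, ej[keep])
      vv <- c(vv, pool[sample.int(length(pool), sum(keep), replace = TRUE)])
    }
  }
  rational_matrix(nr, nc, ii, jj, as.character(vv))
}

#' @rdname fixture_spec
#' @param spec A `fixture_spec`.
#' @return `random_network()`: list with `matrix` (a
#'   [rational_matrix()] of exact rank `target_rank`) and `true_nullity`
#'   (`n_reactions - target_rank`).
#' @export
random_network <- function(spec) {
  if (!inherits(spec, "fixture_spec"))
    fk_stop("fk_input_error", "expected a fixture_spec")
  set.seed(spec$seed)
  r <- spec$target_rank
  density <- max(0.02, 1 - spec$sparsity_target)
  # product of full-column-rank (m x r) and full-row-rank (r x n) sparse
  # factors: rank is exactly r by construction
  A <- sparse_factor(spec$n_species, r, r, spec$coefficient_pool,
                     density, identity_in_rows = TRUE)
  B <- sparse_factor(r, spec$n_reactions, r, spec$coefficient_pool,
                     density, identity_in_rows = FALSE)
  list(matrix = rmat_mult(A, B),
       true_nullity = spec$n_reactions - r)
}

#' Diagonal doubling of a stoichiometric matrix
#'
#' Repeats a stoichiometric matrix block-diagonally `copies` times (two
#' independent, identical networks for `copies = 2`) and then applies a
#' seeded random permutation of the columns, modelling real network
#' models whose column order is arbitrary. The kernel dimension scales by
#' `copies` and the sparsity follows `1 - (1 - s)/copies` exactly.
#'
#' @param matrix A [rational_matrix()].
#' @param copies Number of diagonal copies (at least 2).
#' @param seed Integer seed for the column shuffle.
#' @param shuffle Set `FALSE` to keep the block-diagonal column order.
#' @return The doubled [rational_matrix()].
#' @export
double_network <- function(matrix, copies = 2L, seed = 1L, shuffle = TRUE) {
  copies <- as.integer(copies)
  if (copies < 2L) fk_stop("fk_input_error", "copies must be at least 2")
  big <- rmat_block_diag(rep(list(matrix), copies))
  if (!shuffle) return(big)
  set.seed(as.integer(seed))
  perm <- sample.int(big$ncol)
  rational_matrix(big$nrow, big$ncol, big$i, match(big$j, perm), big$val)
}

#' Hand-built toy pathway networks
#'
#' Three small networks whose kernels are known in closed form, shipped
#' with their hand-derived kernels for oracle tests:
#' a linear chain with boundary transport (one independent flux, all
#' fluxes equal), a branch point (two independent fluxes), and a
#' two-compartment shuttle loop patterned on amino-group carrier cycling
#' between cytosol and mitochondria (one internal cycle flux).
#'
#' @return Named list of [metabolic_network()] objects; each carries a
#'   `kernel_truth` attribute with the expected independent columns and
#'   the dense character kernel.
#' @export
toy_pathways <- function() {
  chain <- metabolic_network(
    species = data.frame(id = c("A", "B", "C"), name = c("A", "B", "C"),
                         compartment = "c", is_external = FALSE,
                         stringsAsFactors = FALSE),
    reactions = data.frame(id = c("EX_A", "v1", "v2", "EX_C"),
                           name = c("EX_A", "v1", "v2", "EX_C"),
                           reversible = FALSE,
                           is_exchange = c(TRUE, FALSE, FALSE, TRUE),
                           stringsAsFactors = FALSE),
    stoich = data.frame(
      reaction = c("EX_A", "v1", "v1", "v2", "v2", "EX_C"),
      species = c("A", "A", "B", "B", "C", "C"),
      side = c("product", "reactant", "product", "reactant", "product", "reactant"),
      coeff = "1", stringsAsFactors = FALSE)
  )
  attr(chain, "kernel_truth") <- list(
    independent = 4L,
    R = matrix(c("1", "1", "1", "1"), 4, 1)
  )
  branch <- metabolic_network(
    species = data.frame(id = c("A", "B", "C"), name = c("A", "B", "C"),
                         compartment = "c", is_external = FALSE,
                         stringsAsFactors = FALSE),
    reactions = data.frame(id = c("EX_A", "vAB", "vAC", "EX_B", "EX_C"),
                           name = c("EX_A", "vAB", "vAC", "EX_B", "EX_C"),
                           reversible = FALSE,
                           is_exchange = c(TRUE, FALSE, FALSE, TRUE, TRUE),
                           stringsAsFactors = FALSE),
    stoich = data.frame(
      reaction = c("EX_A", "vAB", "vAB", "vAC", "vAC", "EX_B", "EX_C"),
      species = c("A", "A", "B", "A", "C", "B", "C"),
      side = c("product", "reactant", "product", "reactant", "product",
               "reactant", "reactant"),
      coeff = "1", stringsAsFactors = FALSE)
  )
  # with fluxes (EX_A, vAB, vAC, EX_B, EX_C) and free coordinates
  # (EX_B, EX_C): EX_A = EX_B + EX_C, vAB = EX_B, vAC = EX_C
  attr(branch, "kernel_truth") <- list(
    independent = c(4L, 5L),
    R = matrix(c("1", "1", "0", "1", "0",
                 "1", "0", "1", "0", "1"), 5, 2)
  )
  shuttle <- metabolic_network(
    species = data.frame(
      id = c("glu_c", "akg_c", "glu_m", "akg_m"),
      name = c("glutamate (cytosol)", "oxoglutarate (cytosol)",
               "glutamate (mitochondria)", "oxoglutarate (mitochondria)"),
      compartment = c("c", "c", "m", "m"), is_external = FALSE,
      stringsAsFactors = FALSE),
    reactions = data.frame(
      id = c("t_glu", "t_akg", "amin_c", "deam_m"),
      name = c("glutamate import", "oxoglutarate export",
               "cytosolic amination", "mitochondrial deamination"),
      reversible = TRUE, is_exchange = FALSE, stringsAsFactors = FALSE),
    stoich = data.frame(
      reaction = c("t_glu", "t_glu", "t_akg", "t_akg",
                   "amin_c", "amin_c", "deam_m", "deam_m"),
      species = c("glu_c", "glu_m", "akg_m", "akg_c",
                  "akg_c", "glu_c", "glu_m", "akg_m"),
      side = c("reactant", "product", "reactant", "product",
               "reactant", "product", "reactant", "product"),
      coeff = "1", stringsAsFactors = FALSE)
  )
  # one internal cycle: all four fluxes run at the same rate
  attr(shuttle, "kernel_truth") <- list(
    independent = 4L,
    R = matrix(c("1", "1", "1", "1"), 4, 1)
  )
  list(chain = chain, branch = branch, shuttle = shuttle)
}

#' Write fixture matrices and their ground truth
#'
#' Materialises a fixture as a MatrixMarket file plus a JSON truth file
#' (spec, true nullity) for use outside R.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory.
#' @return Paths of the files written, invisibly.
#' @export
write_fixture <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- random_network(spec)
  stem <- sprintf("fixture_s%d_m%d_n%d_r%d", spec$seed, spec$n_species,
                  spec$n_reactions, spec$target_rank)
  mtx <- file.path(dir, paste0(stem, ".mtx"))
  js <- file.path(dir, paste0(stem, ".json"))
  write_rational_mtx(fx$matrix, mtx)
  jsonlite::write_json(
    list(schema = "fluxkernel/fixture/v1", spec = unclass(spec),
         true_nullity = fx$true_nullity,
         sparsity = sparsity(fx$matrix)),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(mtx, js))
}
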