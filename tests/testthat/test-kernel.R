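test_that("kernel construction matches hand results and the dense oracle", {
  # single reaction chain: both fluxes equal
  n <- as_rational_matrix(matrix(c("1", "-1"), 1, 2))
  k <- build_kernel(gauss_jordan_eliminate(n), 2)
  expect_identical(as_character_matrix(k$R), matrix(c("1", "1"), 2, 1))
  expect_identical(k$partition$independent, 2L)
  # random matrices: N R = 0 exactly, rows at independent indices are I,
  # and R equals the naive dense-oracle nullspace for the same partition
  set.seed(71)
  for (rep in 1:10) {
    dm <- random_int_matrix(8, 12)
    x <- as_rational_matrix(dm)
    e <- gauss_jordan_eliminate(x)
    k <- build_kernel(e, 12)
    expect_exact_zero_product(x, k$R)
    idblock <- rmat_subset(k$R, rows = k$partition$independent)
    expect_true(rmat_identical(idblock, rmat_identity(k$R$ncol)))
    # oracle nullspace uses leftmost pivots; align partitions by passing
    # the package's pivot order into the naive eliminator
    rr <- r_dense_rref(dm, pivot_col_order = e$pivot_columns)
    fre <- setdiff(seq_len(12), rr$pivot_columns)
    expect_identical(fre, e$free_columns)
    R_or <- matrix("0", 12, length(fre))
    for (q in seq_along(fre)) {
      R_or[fre[q], q] <- "1"
      R_or[rr$pivot_columns, q] <-
        rat_arith("0", rr$echelon[seq_along(rr$pivot_columns), fre[q]], "-")
    }
    expect_identical(as_character_matrix(k$R), R_or)
  }
})

test_that("kernel columns form a basis (rank f)", {
  set.seed(72)
  fx <- random_network(fixture_spec(15, 25, 12, seed = 99))
  k <- build_kernel(gauss_jordan_eliminate(fx$matrix), 25)
  expect_identical(gauss_jordan_eliminate(k$R)$rank, k$R$ncol)
})

test_that("fixed independent sets give shuffle-invariant relations", {
  set.seed(73)
  fx <- random_network(fixture_spec(10, 16, 8, seed = 5))
  ids <- sprintf("v%02d", 1:16)
  e0 <- gauss_jordan_eliminate(fx$matrix)
  indep <- e0$free_columns
  k0 <- build_kernel(gauss_jordan_eliminate(fx$matrix, forbidden_pivot_cols = indep), 16)
  rel0 <- flux_relations(k0, ids)
  for (rep in 1:3) {
    rperm <- sample.int(fx$matrix$nrow)
    cperm <- sample.int(16)
    shuf <- rational_matrix(fx$matrix$nrow, 16,
                            match(fx$matrix$i, rperm), match(fx$matrix$j, cperm),
                            fx$matrix$val)
    kS <- build_kernel(gauss_jordan_eliminate(
      shuf, forbidden_pivot_cols = match(indep, cperm)), 16)
    relS <- flux_relations(kS, ids[cperm])
    o0 <- rel0[order(rel0$dependent, rel0$independent), ]
    oS <- relS[order(relS$dependent, relS$independent), ]
    expect_identical(o0$coefficient, oS$coefficient)
    expect_identical(o0$dependent, oS$dependent)
    expect_identical(o0$independent, oS$independent)
  }
})

test_that("flux relations round-trip the kernel and honour edge cases", {
  toys <- toy_pathways()
  net <- toys$chain
  k <- build_kernel(gauss_jordan_eliminate(net$matrix, forbidden_pivot_cols = 4L), 4)
  rel <- flux_relations(k, net$reactions$id)
  expect_identical(format_relations(rel),
                   c("EX_A = EX_C", "v1 = EX_C", "v2 = EX_C"))
  expect_error(flux_relations(k, c("a", "b")), class = "fk_input_error")
  # square regular matrix: trivial kernel, every flux forced to zero
  sq <- rmat_identity(3)
  ksq <- build_kernel(gauss_jordan_eliminate(sq), 3)
  expect_identical(ksq$R$ncol, 0L)
  relsq <- flux_relations(ksq, c("a", "b", "c"))
  expect_identical(nrow(relsq), 0L)
  expect_identical(format_relations(relsq), c("a = 0", "b = 0", "c = 0"))
})

test_that("substitution folds measurements exactly", {
  toys <- toy_pathways()
  net <- toys$branch
  k <- build_kernel(gauss_jordan_eliminate(net$matrix, forbidden_pivot_cols = c(4L, 5L)), 5)
  rel <- flux_relations(k, net$reactions$id)
  # empty assignment: unchanged
  s0 <- substitute_fluxes(rel, character())
  expect_identical(nrow(s0$relations), nrow(rel))
  expect_identical(s0$still_free, c("EX_B", "EX_C"))
  # partial: vAB pinned, EX_A still carries the free EX_C term
  s1 <- substitute_fluxes(rel, c(EX_B = "1/3"))
  expect_identical(s1$fully_determined, "vAB")
  expect_identical(s1$still_free, "EX_C")
  expect_identical(attr(s1$relations, "constants")[["vAB"]], "1/3")
  # assigning everything determines every dependent flux
  s2 <- substitute_fluxes(rel, c(EX_B = "1/3", EX_C = "2/3"))
  expect_identical(sort(s2$fully_determined), sort(c("EX_A", "vAB", "vAC")))
  expect_identical(attr(s2$relations, "constants")[["EX_A"]], "1")
  expect_length(s2$still_free, 0L)
  # substituting a point and evaluating yields N v = 0 exactly
  v <- setNames(rep("0", 5), net$reactions$id)
  v[names(attr(s2$relations, "constants"))] <- attr(s2$relations, "constants")
  v[c("EX_B", "EX_C")] <- c("1/3", "2/3")
  nv <- rmat_mult(net$matrix, rational_matrix(5, 1, 1:5, rep(1L, 5), unname(v)))
  expect_identical(length(nv$val), 0L)
  # dependent ids are refused with a pointer to the constraint module
  expect_error(substitute_fluxes(rel, c(vAB = "1")), class = "fk_input_error")
})

test_that("sub-network decomposition follows the kernel support", {
  # block-diagonal kernel: two separate components
  toys <- toy_pathways()
  two <- metabolic_network(
    species = rbind(toys$chain$species,
                    within(toys$chain$species, id <- paste0(id, "2"))),
    reactions = rbind(toys$chain$reactions,
                      within(toys$chain$reactions, id <- paste0(id, "2"))),
    stoich = rbind(toys$chain$stoich,
                   within(toys$chain$stoich, {
                     reaction <- paste0(reaction, "2")
                     species <- paste0(species, "2")
                   })))
  k <- build_kernel(gauss_jordan_eliminate(two$matrix,
                                           forbidden_pivot_cols = c(4L, 8L)), 8)
  dec <- identify_subnetworks(k, two$reactions$id)
  expect_length(dec$components, 2L)
  expect_setequal(dec$per_independent[["EX_C"]], c("EX_A", "v1", "v2"))
  expect_setequal(dec$per_independent[["EX_C2"]], c("EX_A2", "v12", "v22"))
  # a column touching every dependent flux merges everything
  chain <- toys$chain
  k1 <- build_kernel(gauss_jordan_eliminate(chain$matrix,
                                            forbidden_pivot_cols = 4L), 4)
  d1 <- identify_subnetworks(k1, chain$reactions$id)
  expect_length(d1$components, 1L)
  expect_setequal(d1$components[[1]], chain$reactions$id)
  # SVD kernels are refused
  fake <- k1; fake$source <- "svd"
  expect_error(identify_subnetworks(fake, chain$reactions$id),
               class = "fk_input_error")
})
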