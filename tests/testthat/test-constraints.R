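# helper: a kernel whose independent block is the identity on chosen
# fluxes, so constraint rows can be written down by hand
toy_kernel <- function() {
  toys <- toy_pathways()
  net <- toys$branch
  k <- build_kernel(gauss_jordan_eliminate(net$matrix,
                                           forbidden_pivot_cols = c(4L, 5L)), 5)
  list(net = net, k = k, ids = net$reactions$id)
}

test_that("system assembly maps measurements and signs to the right rows", {
  tk <- toy_kernel()
  sys <- assemble_system(tk$k, tk$ids,
                         measured = c(EX_B = "2", EX_C = "0.5"),
                         sign_constraints = c(EX_A = "nonnegative",
                                              vAB = "nonpositive"))
  expect_identical(sys$n_equalities, 2L)
  expect_identical(sys$n_inequalities, 2L)
  # the sign row for a dependent flux is exactly its kernel row
  r_eha <- sys$A[sys$labels == "sign:EX_A", ]
  expect_identical(r_eha, as_character_matrix(tk$k$R)[1, ])
  # empty system: whole kernel space feasible
  s0 <- assemble_system(tk$k, tk$ids)
  expect_identical(nrow(s0$A), 0L)
  # wrong partition keys are refused
  expect_error(assemble_system(tk$k, tk$ids, measured = c(vAB = "1")),
               class = "fk_input_error")
  expect_error(assemble_system(tk$k, tk$ids,
                               sign_constraints = c(EX_B = "nonnegative")),
               class = "fk_input_error")
})

# build a constraint system directly for geometric unit tests
raw_system <- function(A, b, sense, ids = paste0("x", seq_len(ncol(A)))) {
  structure(list(A = A, b = b, sense = sense,
                 labels = paste0("row", seq_along(b)),
                 indep_ids = ids, dep_ids = character(),
                 n_equalities = sum(sense == "eq"),
                 n_inequalities = sum(sense != "eq"),
                 n_relations = 0L),
            class = "constraint_system")
}

test_that("redundant 1-D constraints reduce to the minimal pair", {
  sys <- raw_system(matrix(c("1", "1", "1"), 3, 1),
                    c("0", "-1", "1"), c("ge", "ge", "le"))
  p <- reduce_polytope(sys)
  expect_true(p$feasible)
  expect_identical(sum(p$H_rep$sense == "le"), 2L)   # x >= -1 dropped
  verts <- sort(vapply(p$V_rep$vertices, identity, ""))
  expect_identical(verts, c("0", "1"))
  b <- bounds_per_flux(p)
  expect_identical(b$lower, "0")
  expect_identical(b$upper, "1")
})

test_that("equalities are substituted before enumeration", {
  # x + y = 1, x >= 0, y >= 0: the unit segment
  sys <- raw_system(rbind(c("1", "1"), c("1", "0"), c("0", "1")),
                    c("1", "0", "0"), c("eq", "ge", "ge"))
  p <- reduce_polytope(sys)
  verts <- lapply(p$V_rep$vertices, identity)
  keys <- sort(vapply(verts, paste, "", collapse = ","))
  expect_identical(keys, c("0,1", "1,0"))
  expect_length(p$V_rep$rays, 0L)
  b <- bounds_per_flux(p)
  expect_identical(b$lower, c("0", "0"))
  expect_identical(b$upper, c("1", "1"))
})

test_that("the simplex bounds every coordinate by [0, 1]", {
  sys <- raw_system(rbind(c("1", "1", "1"),
                          c("1", "0", "0"), c("0", "1", "0"), c("0", "0", "1")),
                    c("1", "0", "0", "0"), c("eq", "ge", "ge", "ge"))
  p <- reduce_polytope(sys)
  expect_length(p$V_rep$vertices, 3L)
  b <- bounds_per_flux(p)
  expect_identical(b$lower, rep("0", 3))
  expect_identical(b$upper, rep("1", 3))
})

test_that("unbounded directions surface as rays and infinite bounds", {
  sys <- raw_system(matrix("1", 1, 1), "3", "ge")
  p <- reduce_polytope(sys)
  expect_length(p$V_rep$rays, 1L)
  b <- bounds_per_flux(p)
  expect_identical(b$lower, "3")
  expect_identical(b$upper, "Inf")
  # a completely unconstrained coordinate shows up as lineality
  sys2 <- raw_system(rbind(c("1", "0"), c("1", "0")), c("0", "1"),
                     c("ge", "le"))
  p2 <- reduce_polytope(sys2)
  expect_length(p2$V_rep$lineality, 1L)
  b2 <- bounds_per_flux(p2)
  expect_identical(b2$lower, c("0", "-Inf"))
  expect_identical(b2$upper, c("1", "Inf"))
})

test_that("infeasible systems yield an empty polytope, not an error", {
  sys <- raw_system(rbind("1", "1"), c("1", "-1"), c("ge", "le"))
  p <- reduce_polytope(sys)
  expect_false(p$feasible)
  expect_length(p$V_rep$vertices, 0L)
  expect_error(bounds_per_flux(p), class = "fk_infeasible_error")
  # contradictory equalities too
  sys2 <- raw_system(rbind(c("1", "1"), c("1", "1")), c("1", "2"),
                     c("eq", "eq"))
  expect_false(reduce_polytope(sys2)$feasible)
})

test_that("H/V duality round-trips on small systems", {
  set.seed(91)
  for (rep in 1:6) {
    d <- sample(2:3, 1)
    m <- sample((d + 1):(d + 4), 1)
    A <- matrix(as.character(sample(-2:2, d * m, replace = TRUE)), m, d)
    b <- as.character(sample(0:3, m, replace = TRUE))
    sys <- raw_system(A, b, rep("le", m))
    p <- reduce_polytope(sys)
    if (!p$feasible) next
    # feed the reduced H-rep back in: same vertices, rays, facet count
    sys2 <- raw_system(p$H_rep$A, p$H_rep$b, p$H_rep$sense)
    p2 <- reduce_polytope(sys2)
    key <- function(vs) sort(vapply(vs, paste, "", collapse = ","))
    expect_identical(key(p2$V_rep$vertices), key(p$V_rep$vertices))
    expect_identical(key(p2$V_rep$rays), key(p$V_rep$rays))
    expect_identical(sum(p2$H_rep$sense == "le"), sum(p$H_rep$sense == "le"))
    # every original constraint is implied: all generators satisfy it
    for (q in seq_len(m)) {
      for (v in p$V_rep$vertices)
        expect_lte(rat_compare(fluxkernel:::sum_rat(rat_arith(A[q, ], v, "*")),
                               b[[q]]), 0L)
      for (r in p$V_rep$rays)
        expect_lte(rat_compare(fluxkernel:::sum_rat(rat_arith(A[q, ], r, "*")),
                               "0"), 0L)
    }
  }
})

test_that("the worked pathway example reduces to interpretable bounds", {
  tk <- toy_kernel()
  sys <- assemble_system(tk$k, tk$ids,
                         measured = c(EX_B = "2"),
                         sign_constraints = c(vAB = "nonnegative",
                                              vAC = "nonnegative",
                                              EX_A = "nonnegative"))
  p <- reduce_polytope(sys)
  b <- bounds_per_flux(p)
  expect_identical(b$lower[b$flux == "EX_C"], "0")
  expect_identical(b$upper[b$flux == "EX_C"], "Inf")
  expect_identical(b$lower[b$flux == "EX_B"], "2")
  expect_identical(b$upper[b$flux == "EX_B"], "2")
  # capping total uptake EX_A <= 5 bounds the free branch: EX_C in [0, 3]
  sysA <- raw_system(rbind(c("1", "0"), c("0", "1"), c("1", "1")),
                     c("2", "0", "5"), c("eq", "ge", "le"),
                     ids = c("EX_B", "EX_C"))
  bA <- bounds_per_flux(reduce_polytope(sysA))
  expect_identical(bA$upper[bA$flux == "EX_C"], "3")
})
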