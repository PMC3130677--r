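mini_sbml <- system.file("extdata", "yeast_mini_synthetic.xml",
                         package = "fluxkernel")

sbml_snippet <- function(species, reactions) {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="4">\n',
    "<model id=\"m\">\n<listOfSpecies>\n", species,
    "\n</listOfSpecies>\n<listOfReactions>\n", reactions,
    "\n</listOfReactions>\n</model>\n</sbml>\n")
}

write_tmp_sbml <- function(species, reactions) {
  p <- withr::local_tempfile(fileext = ".xml", .local_envir = parent.frame())
  writeLines(sbml_snippet(species, reactions), p)
  p
}

test_that("SBML parsing preserves order, signs and exact coefficients", {
  net <- parse_sbml(mini_sbml)
  expect_identical(nrow(net$species), 22L)
  expect_identical(nrow(net$reactions), 19L)
  expect_identical(sum(net$species$is_external), 6L)
  expect_identical(net$reactions$id[1], "GLK")
  # sign convention: 2A -> B gives column (-2, +1); decimal text is exact
  p <- write_tmp_sbml(
    '<species id="A" compartment="c"/><species id="B" compartment="c"/>',
    paste0('<reaction id="r1" reversible="false"><listOfReactants>',
           '<speciesReference species="A" stoichiometry="2"/></listOfReactants>',
           '<listOfProducts><speciesReference species="B" stoichiometry="0.5"/>',
           '</listOfProducts></reaction>'))
  toy <- parse_sbml(p)
  expect_identical(rmat_entry(toy$matrix, 1, 1), "-2")
  expect_identical(rmat_entry(toy$matrix, 2, 1), "1/2")
  # the worked example network carries an exact 1/2 as well
  expect_identical(rmat_entry(net$matrix,
                              match("asp_c", net$species$id),
                              match("BIO", net$reactions$id)), "-1/2")
})

test_that("malformed SBML is rejected with a pointed message", {
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model><oops>", bad)
  expect_error(parse_sbml(bad), class = "fk_parse_error")
  p <- write_tmp_sbml(
    '<species id="A" compartment="c"/>',
    paste0('<reaction id="r1"><listOfReactants>',
           '<speciesReference species="GHOST"/></listOfReactants></reaction>'))
  expect_error(parse_sbml(p), class = "fk_validation_error")
  expect_error(parse_sbml(p), "GHOST")
})

test_that("preprocessing removes orphans and rewires polymerization species", {
  p <- write_tmp_sbml(
    paste0('<species id="A" compartment="c"/><species id="X" compartment="c"/>',
           '<species id="B" compartment="c"/><species id="orphan" compartment="c"/>'),
    paste0('<reaction id="poly" reversible="false"><listOfReactants>',
           '<speciesReference species="A"/><speciesReference species="X"/>',
           '</listOfReactants><listOfProducts>',
           '<speciesReference species="A"/><speciesReference species="B"/>',
           '</listOfProducts></reaction>'))
  net <- parse_sbml(p)
  pre <- preprocess(net)
  # orphan dropped
  expect_false("orphan" %in% pre$species$id)
  expect_identical(nrow(pre$species), 3L)
  # A dropped from reactants (product side kept), exchange appended
  expect_identical(nrow(pre$reactions), 2L)
  expect_identical(pre$reactions$id[2], "EX_A")
  expect_true(pre$reactions$is_exchange[2])
  expect_identical(rmat_entry(pre$matrix, match("A", pre$species$id), 1), "1")
  expect_identical(rmat_entry(pre$matrix, match("A", pre$species$id), 2), "-1")
  # idempotent
  pre2 <- preprocess(pre)
  expect_identical(pre2$species$id, pre$species$id)
  expect_identical(pre2$reactions$id, pre$reactions$id)
  expect_true(rmat_identical(pre2$matrix, pre$matrix))
})

test_that("degree-based opening adds one exchange per degree-1 species", {
  p <- write_tmp_sbml(
    '<species id="A" compartment="c"/><species id="B" compartment="c"/>',
    paste0('<reaction id="v1" reversible="false"><listOfReactants>',
           '<speciesReference species="A"/></listOfReactants><listOfProducts>',
           '<speciesReference species="B"/></listOfProducts></reaction>'))
  net <- preprocess(parse_sbml(p))
  opened <- open_by_degree(net)
  expect_identical(nrow(opened$reactions), 3L)
  expect_identical(opened$reactions$id, c("v1", "EX_A", "EX_B"))
  expect_identical(rmat_entry(opened$matrix, 1, 2), "-1")
  # a network where every species already participates twice is unchanged
  toys <- toy_pathways()
  same <- open_by_degree(toys$shuttle)
  expect_identical(nrow(same$reactions), nrow(toys$shuttle$reactions))
})

test_that("external-row opening deletes rows, flags emptied reactions", {
  net <- preprocess(parse_sbml(mini_sbml))
  opened <- open_by_externals(net)   # boundaryCondition flags
  expect_identical(nrow(opened$species), 16L)
  expect_identical(nrow(opened$reactions), 19L)
  expect_length(opened$empty_reactions, 0L)
  # empty external set: unchanged
  same <- open_by_externals(net, character())
  expect_identical(nrow(same$species), nrow(net$species))
  # all species external: zero-row matrix, every reaction flagged
  all_ext <- open_by_externals(net, net$species$id)
  expect_identical(nrow(all_ext$species), 0L)
  expect_identical(sort(all_ext$empty_reactions), sort(net$reactions$id))
  expect_error(open_by_externals(net, "no_such_species"),
               class = "fk_input_error")
})

test_that("the two opening rules give the same steady states on chains", {
  # closed chain with explicit external pools:
  # Aext -> A -> B -> Bext ; opening by degree (transport for Aext, Bext)
  # and opening by externals (delete Aext, Bext rows) must allow the same
  # flux values on the shared original reactions
  p <- write_tmp_sbml(
    paste0('<species id="Aext" compartment="e" boundaryCondition="true"/>',
           '<species id="A" compartment="c"/><species id="B" compartment="c"/>',
           '<species id="Bext" compartment="e" boundaryCondition="true"/>'),
    paste0('<reaction id="up" reversible="false"><listOfReactants>',
           '<speciesReference species="Aext"/></listOfReactants><listOfProducts>',
           '<speciesReference species="A"/></listOfProducts></reaction>',
           '<reaction id="conv" reversible="false"><listOfReactants>',
           '<speciesReference species="A"/></listOfReactants><listOfProducts>',
           '<speciesReference species="B"/></listOfProducts></reaction>',
           '<reaction id="out" reversible="false"><listOfReactants>',
           '<speciesReference species="B"/></listOfReactants><listOfProducts>',
           '<speciesReference species="Bext"/></listOfProducts></reaction>'))
  net <- preprocess(parse_sbml(p))
  by_deg <- open_by_degree(net)
  by_ext <- open_by_externals(net)
  shared <- net$reactions$id
  kd <- build_kernel(gauss_jordan_eliminate(by_deg$matrix), nrow(by_deg$reactions))
  ke <- build_kernel(gauss_jordan_eliminate(by_ext$matrix), nrow(by_ext$reactions))
  # project both kernels onto the shared original reactions and compare
  # the spanned subspaces exactly: each must be 1-D with all fluxes equal
  proj_d <- rmat_subset(kd$R, rows = match(shared, by_deg$reactions$id))
  proj_e <- rmat_subset(ke$R, rows = match(shared, by_ext$reactions$id))
  for (proj in list(proj_d, proj_e)) {
    dense <- as_character_matrix(proj)
    nzcols <- which(apply(dense, 2, function(cc) any(cc != "0")))
    expect_length(nzcols, 1L)
    expect_identical(unique(dense[, nzcols]), dense[1, nzcols])
  }
})

test_that("write-then-parse round trip preserves the network exactly", {
  net <- preprocess(parse_sbml(mini_sbml))
  p <- withr::local_tempfile(fileext = ".xml")
  write_sbml(net, p)
  back <- parse_sbml(p)
  expect_identical(back$species$id, net$species$id)
  expect_identical(back$reactions$id, net$reactions$id)
  expect_identical(back$species$is_external, net$species$is_external)
  expect_identical(back$reactions$reversible, net$reactions$reversible)
  expect_true(rmat_identical(back$matrix, net$matrix))
})

test_that("summaries and tables are written", {
  net <- parse_sbml(mini_sbml)
  d <- withr::local_tempdir()
  write_network_summary(net, file.path(d, "summary.json"))
  s <- jsonlite::read_json(file.path(d, "summary.json"))
  expect_identical(s$n_species, 22L)
  expect_identical(s$n_reactions, 19L)
  write_network_tables(net, d)
  sp <- read.delim(file.path(d, "species.tsv"))
  expect_identical(nrow(sp), 22L)
})
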