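#' Metabolic networks: species, reactions and exact stoichiometry
#'
#' A `metabolic_network` couples a species table, a reaction table and the
#' exact stoichiometry. Stoichiometry is held per reaction side (reactant /
#' product) so that preprocessing rules that distinguish the two sides can
#' be applied; the m species x n reactions stoichiometric matrix N (negative
#' entries consume, positive produce) is derived from it and cached.
#'
#' @param species Data frame with columns `id`, `name`, `compartment`,
#'   `is_external`.
#' @param reactions Data frame with columns `id`, `name`, `reversible`,
#'   `is_exchange`.
#' @param stoich Data frame with columns `reaction`, `species`, `side`
#'   (`"reactant"` or `"product"`) and `coeff` (positive rational strings).
#' @return An object of class `metabolic_network`.
#' @export
metabolic_network <- function(species, reactions, stoich) {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  stoich <- as.data.frame(stoich, stringsAsFactors = FALSE)
  if (anyDuplicated(species$id))
    fk_stop("fk_validation_error", "duplicate species ids: %s",
            paste(unique(species$id[duplicated(species$id)]), collapse = ", "))
  if (anyDuplicated(reactions$id))
    fk_stop("fk_validation_error", "duplicate reaction ids: %s",
            paste(unique(reactions$id[duplicated(reactions$id)]), collapse = ", "))
  bad_sp <- setdiff(stoich$species, species$id)
  if (length(bad_sp))
    fk_stop("fk_validation_error", "stoichiometry references undeclared species: %s",
            paste(unique(bad_sp), collapse = ", "))
  bad_rx <- setdiff(stoich$reaction, reactions$id)
  if (length(bad_rx))
    fk_stop("fk_validation_error", "stoichiometry references undeclared reaction: %s",
            paste(unique(bad_rx), collapse = ", "))
  if (nrow(stoich)) {
    stoich$coeff <- as_rational(stoich$coeff)
    if (any(rat_compare(stoich$coeff, "0") <= 0))
      fk_stop("fk_validation_error", "stoichiometric coefficients must be positive")
    if (!all(stoich$side %in% c("reactant", "product")))
      fk_stop("fk_validation_error", "stoichiometry side must be 'reactant' or 'product'")
  }
  net <- structure(
    list(species = species, reactions = reactions, stoich = stoich,
         matrix = NULL, empty_reactions = character()),
    class = "metabolic_network"
  )
  net$matrix <- network_matrix(net)
  net
}

# derive N (m x n) from the per-side stoichiometry: product - reactant
network_matrix <- function(net) {
  m <- nrow(net$species); n <- nrow(net$reactions)
  st <- net$stoich
  if (!nrow(st)) return(rational_matrix(m, n))
  i <- match(st$species, net$species$id)
  j <- match(st$reaction, net$reactions$id)
  v <- ifelse(st$side == "reactant", paste0("-", st$coeff), st$coeff)
  key <- paste(i, j)
  if (anyDuplicated(key)) {
    agg <- vapply(split(v, key), function(vs) Reduce(function(a, b)
      rat_arith(a, b, "+"), vs), "")
    ij <- do.call(rbind, strsplit(names(agg), " "))
    i <- as.integer(ij[, 1]); j <- as.integer(ij[, 2]); v <- unname(agg)
  }
  keep <- as_rational(v) != "0"
  rational_matrix(m, n, i[keep], j[keep], v[keep])
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("<metabolic_network: %d species, %d reactions, %d external, matrix sparsity %.3f>\n",
              nrow(x$species), nrow(x$reactions), sum(x$species$is_external),
              if (nrow(x$species) && nrow(x$reactions)) sparsity(x$matrix) else NA_real_))
  invisible(x)
}

xml_attr_or <- function(node, attr, default) {
  v <- xml2::xml_attr(node, attr)
  ifelse(is.na(v), default, v)
}

#' Parse an SBML metabolic network
#'
#' Reads an SBML (level 2 or 3) document into a [metabolic_network()].
#' All stoichiometric coefficients are converted to exact rationals during
#' parsing: decimal literal text is read as an exact decimal fraction
#' (`"0.5"` becomes `1/2`), never through binary floating point. Reactant
#' coefficients enter the stoichiometric matrix negatively, products
#' positively; document order of species and reactions is preserved.
#' Species carrying the SBML `boundaryCondition` flag are marked external.
#'
#' @param path Path to an SBML file.
#' @return A [metabolic_network()].
#' @export
parse_sbml <- function(path) {
  if (!file.exists(path))
    fk_stop("fk_parse_error", "SBML file not found: %s", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    fk_stop("fk_parse_error", "malformed XML in %s: %s", path, conditionMessage(e)))
  sp_nodes <- xml2::xml_find_all(
    doc, "//*[local-name()='listOfSpecies']/*[local-name()='species']")
  rxn_nodes <- xml2::xml_find_all(
    doc, "//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (!length(sp_nodes))
    fk_stop("fk_parse_error", "no <species> elements found in %s", path)
  if (!length(rxn_nodes))
    fk_stop("fk_parse_error", "no <reaction> elements found in %s", path)
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  if (anyNA(sp_id))
    fk_stop("fk_parse_error", "<species> element without id attribute in %s", path)
  species <- data.frame(
    id = sp_id,
    name = xml_attr_or(sp_nodes, "name", sp_id),
    compartment = xml_attr_or(sp_nodes, "compartment", ""),
    is_external = xml_attr_or(sp_nodes, "boundaryCondition", "false") == "true",
    stringsAsFactors = FALSE
  )
  rx_id <- xml2::xml_attr(rxn_nodes, "id")
  if (anyNA(rx_id))
    fk_stop("fk_parse_error", "<reaction> element without id attribute in %s", path)
  reactions <- data.frame(
    id = rx_id,
    name = xml_attr_or(rxn_nodes, "name", rx_id),
    reversible = xml_attr_or(rxn_nodes, "reversible", "true") == "true",
    is_exchange = FALSE,
    stringsAsFactors = FALSE
  )
  rows <- list()
  for (k in seq_along(rxn_nodes)) {
    for (side in c("reactant", "product")) {
      lst <- if (side == "reactant") "listOfReactants" else "listOfProducts"
      refs <- xml2::xml_find_all(
        rxn_nodes[[k]],
        sprintf("./*[local-name()='%s']/*[local-name()='speciesReference']", lst))
      if (!length(refs)) next
      sp <- xml2::xml_attr(refs, "species")
      if (anyNA(sp))
        fk_stop("fk_parse_error",
                "<speciesReference> without species attribute in reaction '%s'", rx_id[[k]])
      unknown <- setdiff(sp, species$id)
      if (length(unknown))
        fk_stop("fk_validation_error",
                "reaction '%s' references undeclared species: %s",
                rx_id[[k]], paste(unknown, collapse = ", "))
      rows[[length(rows) + 1L]] <- data.frame(
        reaction = rx_id[[k]], species = sp, side = side,
        coeff = as_rational(xml_attr_or(refs, "stoichiometry", "1")),
        stringsAsFactors = FALSE
      )
    }
  }
  stoich <- if (length(rows)) do.call(rbind, rows) else
    data.frame(reaction = character(), species = character(),
               side = character(), coeff = character(), stringsAsFactors = FALSE)
  metabolic_network(species, reactions, stoich)
}

# reactions a species participates in (distinct)
species_degree <- function(net) {
  deg <- setNames(integer(nrow(net$species)), net$species$id)
  if (nrow(net$stoich)) {
    u <- unique(net$stoich[c("species", "reaction")])
    tab <- table(u$species)
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

exchange_reaction_rows <- function(ids) {
  list(
    reactions = data.frame(id = paste0("EX_", ids), name = paste0("EX_", ids),
                           reversible = TRUE, is_exchange = TRUE,
                           stringsAsFactors = FALSE),
    stoich = data.frame(reaction = paste0("EX_", ids), species = ids,
                        side = "reactant", coeff = "1", stringsAsFactors = FALSE)
  )
}

#' Preprocess a parsed network
#'
#' Applies two cleanup rules, in this order, before any opening rule:
#' first, species that participate in no reaction are removed; second, a
#' species that appears as both a reactant and a product of the same
#' reaction (as in polymerization reactions) has its reactant-side
#' coefficient removed, keeping the product side, and one boundary
#' transport reaction `EX_<species>` for that species is appended. The
#' operation is idempotent.
#'
#' @param network A [metabolic_network()].
#' @return The preprocessed [metabolic_network()].
#' @export
preprocess <- function(network) {
  st <- network$stoich
  # orphan species removal
  used <- unique(st$species)
  keep <- network$species$id %in% used
  species <- network$species[keep, , drop = FALSE]
  rownames(species) <- NULL
  # polymerization rule: species on both sides of one reaction
  both_key <- intersect(
    paste(st$reaction[st$side == "reactant"], st$species[st$side == "reactant"]),
    paste(st$reaction[st$side == "product"], st$species[st$side == "product"]))
  poly_species <- character()
  if (length(both_key)) {
    drop <- st$side == "reactant" & paste(st$reaction, st$species) %in% both_key
    poly_species <- unique(st$species[drop])
    st <- st[!drop, , drop = FALSE]
  }
  reactions <- network$reactions
  need_ex <- setdiff(poly_species, sub("^EX_", "", reactions$id[reactions$is_exchange]))
  if (length(need_ex)) {
    need_ex <- need_ex[order(match(need_ex, species$id))]
    ex <- exchange_reaction_rows(need_ex)
    reactions <- rbind(reactions, ex$reactions)
    st <- rbind(st, ex$stoich)
  }
  metabolic_network(species, reactions, st)
}

#' Open a closed network by participation degree
#'
#' For every species that participates in exactly one reaction, appends a
#' boundary transport reaction `EX_<species>` (stoichiometric matrix column
#' with a single `-1` entry for that species). New reactions are appended
#' after all original reactions, in species order; original columns are
#' untouched. This is the opening rule that needs no knowledge of which
#' metabolites are external.
#'
#' @param network A preprocessed [metabolic_network()].
#' @return The opened [metabolic_network()].
#' @export
open_by_degree <- function(network) {
  deg <- species_degree(network)
  ids <- network$species$id[deg[network$species$id] == 1L]
  ids <- setdiff(ids, sub("^EX_", "", network$reactions$id[network$reactions$is_exchange]))
  if (!length(ids)) return(network)
  ex <- exchange_reaction_rows(ids)
  metabolic_network(network$species,
                    rbind(network$reactions, ex$reactions),
                    rbind(network$stoich, ex$stoich))
}

#' Open a closed network by removing external species
#'
#' The alternative opening rule for networks whose external metabolites are
#' known: rows for the external species are deleted from the stoichiometric
#' matrix while the reaction set is unchanged. Reactions whose stoichiometry
#' becomes empty are recorded in the `empty_reactions` field of the result
#' (they are flagged, not silently dropped).
#'
#' @param network A preprocessed [metabolic_network()].
#' @param external_ids Character vector of external species ids. When
#'   `NULL`, species flagged external (SBML `boundaryCondition`) are used.
#'   An explicit list always takes precedence over the flag.
#' @return The opened [metabolic_network()].
#' @export
open_by_externals <- function(network, external_ids = NULL) {
  if (is.null(external_ids))
    external_ids <- network$species$id[network$species$is_external]
  unknown <- setdiff(external_ids, network$species$id)
  if (length(unknown))
    fk_stop("fk_input_error", "unknown external species: %s",
            paste(unknown, collapse = ", "))
  if (!length(external_ids)) return(network)
  species <- network$species[!network$species$id %in% external_ids, , drop = FALSE]
  rownames(species) <- NULL
  st <- network$stoich[!network$stoich$species %in% external_ids, , drop = FALSE]
  out <- metabolic_network(species, network$reactions, st)
  out$empty_reactions <- setdiff(network$reactions$id, unique(st$reaction))
  out
}

#' Write a network back to SBML
#'
#' Emits a minimal SBML level 3 document carrying exactly the information
#' the package uses: compartments, species (with `boundaryCondition` for
#' external ones), and reactions with reactant/product stoichiometry.
#' Coefficients with terminating decimal expansions are written as exact
#' decimals; other rationals are written in the `p/q` dialect that
#' [parse_sbml()] reads back exactly. Write-then-parse preserves ids,
#' ordering and the stoichiometric matrix bit-exactly.
#'
#' @param network A [metabolic_network()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(network, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  coeff_txt <- function(v) {
    d <- cpp_rat_decimal(v)
    ifelse(is.na(d), v, d)
  }
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">')
  w('  <model id="fluxkernel_model">')
  comps <- unique(network$species$compartment)
  comps <- comps[nzchar(comps)]
  if (length(comps)) {
    w('    <listOfCompartments>')
    for (cp in comps) w('      <compartment id="%s" constant="true"/>', esc(cp))
    w('    </listOfCompartments>')
  }
  w('    <listOfSpecies>')
  for (k in seq_len(nrow(network$species))) {
    s <- network$species[k, ]
    w('      <species id="%s" name="%s" compartment="%s" boundaryCondition="%s" hasOnlySubstanceUnits="false" constant="false"/>',
      esc(s$id), esc(s$name), esc(s$compartment),
      if (isTRUE(s$is_external)) "true" else "false")
  }
  w('    </listOfSpecies>')
  w('    <listOfReactions>')
  for (k in seq_len(nrow(network$reactions))) {
    r <- network$reactions[k, ]
    w('      <reaction id="%s" name="%s" reversible="%s" fast="false">',
      esc(r$id), esc(r$name), if (isTRUE(r$reversible)) "true" else "false")
    for (side in c("reactant", "product")) {
      st <- network$stoich[network$stoich$reaction == r$id &
                             network$stoich$side == side, , drop = FALSE]
      if (!nrow(st)) next
      w('        <listOf%ss>', if (side == "reactant") "Reactant" else "Product")
      for (q in seq_len(nrow(st)))
        w('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
          esc(st$species[q]), coeff_txt(st$coeff[q]))
      w('        </listOf%ss>', if (side == "reactant") "Reactant" else "Product")
    }
    w('      </reaction>')
  }
  w('    </listOfReactions>')
  w('  </model>')
  w('</sbml>')
  invisible(path)
}

#' Write network summary and tables
#'
#' `write_network_summary()` writes a JSON overview (counts, compartments,
#' sparsity); `write_network_tables()` writes the species and reaction
#' tables as TSV files into a directory.
#'
#' @param network A [metabolic_network()].
#' @param path Output JSON path (summary) or directory (tables).
#' @return The output path(s), invisibly.
#' @export
write_network_summary <- function(network, path) {
  obj <- list(
    schema = "fluxkernel/network-summary/v1",
    n_species = nrow(network$species),
    n_reactions = nrow(network$reactions),
    n_external = sum(network$species$is_external),
    n_exchange = sum(network$reactions$is_exchange),
    compartments = as.list(table(network$species$compartment)),
    sparsity = sparsity(network$matrix),
    empty_reactions = network$empty_reactions
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network_summary
#' @export
write_network_tables <- function(network, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  sp <- file.path(path, "species.tsv")
  rx <- file.path(path, "reactions.tsv")
  utils::write.table(network$species, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(network$reactions, rx, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(sp, rx))
}
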