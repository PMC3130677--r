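#' Pipeline configuration
#'
#' Validated configuration for an end-to-end run: parse an SBML network,
#' preprocess, open it (by participation degree or by removing external
#' species), solve for the exact kernel with optional researcher-selected
#' independent fluxes, cross-validate against the SVD nullspace, and — when
#' measurements or sign constraints are supplied — reduce them to minimal
#' bounds.
#'
#' @param sbml Path to the SBML network.
#' @param out_dir Output directory for the report bundle.
#' @param opening `"degree"` or `"externals"`.
#' @param externals_file Optional file with one external species id per
#'   line (required when `opening = "externals"` and the SBML carries no
#'   boundary flags).
#' @param independent_file Optional file with one preferred independent
#'   flux id per line.
#' @param measured_file Optional TSV (`flux_id`, `value`) of measured
#'   independent fluxes.
#' @param signs_file Optional TSV (`flux_id`, `sign`) of dependent-flux
#'   sign constraints.
#' @param seed Integer seed recorded in the run log (the solve itself is
#'   deterministic).
#' @return A `run_config` object.
#' @export
run_config <- function(sbml, out_dir, opening = c("degree", "externals"),
                       externals_file = NULL, independent_file = NULL,
                       measured_file = NULL, signs_file = NULL, seed = 1L) {
  opening <- match.arg(opening)
  for (p in c(sbml, externals_file, independent_file, measured_file, signs_file)) {
    if (!is.null(p) && !file.exists(p))
      fk_stop("fk_config_error", "input file not found: %s", p)
  }
  structure(list(sbml = sbml, out_dir = out_dir, opening = opening,
                 externals_file = externals_file,
                 independent_file = independent_file,
                 measured_file = measured_file, signs_file = signs_file,
                 seed = as.integer(seed)),
            class = "run_config")
}

read_id_file <- function(path) {
  ids <- trimws(readLines(path))
  ids[nzchar(ids) & !startsWith(ids, "#")]
}

#' Run the full analysis pipeline
#'
#' Executes parse, preprocess, open, solve, SVD cross-check, and (when
#' constraint inputs are present) constraint reduction, writing a
#' deterministic report bundle: `network_summary.json`, `relations.tsv`,
#' `kernel.mtx`, `subnetworks.json`, `svd_check.json`, and, with
#' constraints, `bounds.tsv` and `polytope.json`. A `run_log.txt` records
#' the package version, seed, pivot rule and any preferred independent
#' fluxes that had to be moved to dependent.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `status` (`0` on success), the output
#'   `files`, and the in-memory results.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config"))
    fk_stop("fk_config_error", "expected a run_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    sprintf("fluxkernel %s", as.character(utils::packageVersion("fluxkernel"))),
    sprintf("seed: %d", config$seed),
    "pivot rule: Markowitz (min (row nnz - 1) * (col nnz - 1), ties by column then row)",
    sprintf("started: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  )
  net <- parse_sbml(config$sbml)
  net <- preprocess(net)
  if (config$opening == "degree") {
    net <- open_by_degree(net)
  } else {
    ext <- if (!is.null(config$externals_file))
      read_id_file(config$externals_file)
    else net$species$id[net$species$is_external]
    if (!length(ext))
      fk_stop("fk_config_error",
              "opening = 'externals' needs an externals file or boundaryCondition flags")
    net <- open_by_externals(net, ext)
  }
  flux_ids <- net$reactions$id
  preferred_indep <- integer()
  if (!is.null(config$independent_file)) {
    ids <- read_id_file(config$independent_file)
    bad <- setdiff(ids, flux_ids)
    if (length(bad))
      fk_stop("fk_config_error", "unknown preferred independent fluxes: %s",
              paste(bad, collapse = ", "))
    preferred_indep <- match(ids, flux_ids)
  }
  elim <- gauss_jordan_eliminate(net$matrix,
                                 forbidden_pivot_cols = preferred_indep)
  kern <- build_kernel(elim, length(flux_ids))
  rel <- flux_relations(kern, flux_ids)
  sub <- identify_subnetworks(kern, flux_ids)
  files <- character()
  emit <- function(path) { files <<- c(files, path); path }
  write_network_summary(net, emit(file.path(config$out_dir, "network_summary.json")))
  write_relations_tsv(rel, emit(file.path(config$out_dir, "relations.tsv")))
  write_rational_mtx(kern$R, emit(file.path(config$out_dir, "kernel.mtx")))
  write_subnetworks_json(sub, emit(file.path(config$out_dir, "subnetworks.json")))
  svd_rep <- NULL
  if (length(kern$partition$independent) >= 1L) {
    svdk <- svd_kernel(net$matrix, kern)
    svd_rep <- svd_report(kern, svdk,
                          emit(file.path(config$out_dir, "svd_check.json")))
  }
  if (length(kern$moved_to_dependent))
    log_lines <- c(log_lines, sprintf(
      "moved preferred independent fluxes to dependent: %s",
      paste(flux_ids[kern$moved_to_dependent], collapse = ", ")))
  bounds <- NULL
  substitution <- NULL
  if (!is.null(config$measured_file) || !is.null(config$signs_file)) {
    measured <- if (!is.null(config$measured_file))
      read_measured_tsv(config$measured_file) else character()
    signs <- if (!is.null(config$signs_file))
      read_signs_tsv(config$signs_file) else character()
    if (length(measured))
      substitution <- substitute_fluxes(rel, measured)
    sys <- assemble_system(kern, flux_ids, measured, signs)
    poly <- reduce_polytope(sys)
    write_polytope_json(poly, emit(file.path(config$out_dir, "polytope.json")))
    if (poly$feasible) {
      bounds <- bounds_per_flux(poly)
      write_bounds_tsv(bounds, emit(file.path(config$out_dir, "bounds.tsv")))
    } else {
      log_lines <- c(log_lines, "constraint system infeasible: empty polytope")
    }
  }
  log_lines <- c(log_lines, sprintf("finished: %s",
                                    format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  writeLines(log_lines, emit(file.path(config$out_dir, "run_log.txt")))
  invisible(list(status = 0L, files = files, network = net, kernel = kern,
                 relations = rel, subnetworks = sub, svd_report = svd_rep,
                 substitution = substitution, bounds = bounds))
}
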