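#' Write a simulation trace to CSV
#'
#' Columnar table with time, membrane potential, all calcium compartments
#' and the four reported fluxes.
#'
#' @param sim a [simulate_cell()] result.
#' @param path output CSV path.
#' @export
write_trace <- function(sim, path) {
  if (sim$failed) stop("cannot write a failed simulation")
  cols <- c("time", "V", "Caj", "Casl", "Cai", "Casr", "Cals",
            "J_SERCA", "J_RyR", "J_ls_up", "J_ls_rel")
  utils::write.csv(sim$trace[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' JSON record sufficient to re-run a simulation bit-compatibly: seed,
#' protocol (including intervention flags), scaling factors, solver
#' settings and package version.
#'
#' @param path output JSON path.
#' @param protocol a [make_protocol()] object.
#' @param seed the RNG seed of the enclosing run.
#' @param scalings per-model [scaling_factors()].
#' @param solver list of solver settings.
#' @export
write_manifest <- function(path, protocol, seed = NA,
                           scalings = scaling_factors(),
                           solver = list(method = "lsoda",
                                         rtol = 1e-6, atol = 1e-9)) {
  man <- list(
    package = "lysoca",
    version = as.character(utils::packageVersion("lysoca")),
    seed = seed,
    protocol = list(name = protocol$name,
                    segments = lapply(protocol$segments, as.list),
                    cao = protocol$cao, naadp = protocol$naadp,
                    iso = protocol$iso,
                    release_blocked = protocol$release_block,
                    uptake_blocked = protocol$uptake_block,
                    ncx_multiplier = protocol$ncx_multiplier),
    scaling_factors = as.list(unclass(scalings)),
    solver = solver
  )
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write / read a run configuration
#'
#' Human-readable YAML round-trip of a protocol-plus-population run
#' configuration.
#'
#' @param config list with entries `protocol` (name), optional variant
#'   flags (`ko`, `uptake_block`, `release_block`, `ncx3`), `n_models`,
#'   `seed`, and optional `lysosome` parameter overrides.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config error: a seed is mandatory")
  if (is.null(cfg$protocol)) stop("config error: no protocol named")
  cfg
}

#' Write the population table
#'
#' CSV with model id, the ten scaling factors, the accepted flag and the
#' rejection reason.
#'
#' @param table the `table` element of [calibrate_population()].
#' @param path output CSV path.
#' @export
write_population_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Write lysosomal parameters to a key-value file
#'
#' @param lyso a [lysosome_params()] object.
#' @param path YAML path.
#' @export
write_lysosome_params <- function(lyso, path) {
  yaml::write_yaml(unclass(lyso), path)
  invisible(path)
}
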