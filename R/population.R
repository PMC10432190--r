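#' Population specification
#'
#' @param n_models number of sampled models.
#' @param seed RNG seed (mandatory; recorded in every manifest).
#' @param lower,upper scaling-factor bounds (default 0.5 to 2).
#' @param ncx_extra_multiplier extra NCX multiplier (3 for the enhanced-NCX
#'   delayed-afterdepolarization study).
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(n_models = 1000, seed, lower = 0.5, upper = 2,
                            ncx_extra_multiplier = 1) {
  if (missing(seed)) stop("a seed is mandatory for population sampling")
  stopifnot(n_models >= 1, lower > 0, upper > lower)
  structure(list(n_models = as.integer(n_models), seed = as.integer(seed),
                 lower = lower, upper = upper,
                 ncx_extra_multiplier = ncx_extra_multiplier),
            class = "population_spec")
}

#' Latin hypercube sample of scaling factors
#'
#' Draws `n_models` sets of the ten dimensionless multipliers (I_CaL,
#' J_RyR, j_clc, j_tpc, j_clc_leak, j_tpc_leak, I_NCX, J_SERCA, I_to,
#' I_Kr) by uniform Latin hypercube sampling on `[lower, upper]`: each
#' factor column is stratified into `n_models` equal-probability bins with
#' exactly one draw per bin.  Reproducible from the seed.
#'
#' @param spec a [population_spec()].
#' @return Matrix `n_models` x 10 with factor names as columns and class
#'   `population_sample`; the spec is attached as attribute.
#' @export
sample_population <- function(spec) {
  nm <- names(scaling_factors())
  set.seed(spec$seed)
  u <- lhs::randomLHS(spec$n_models, 10)
  m <- spec$lower + (spec$upper - spec$lower) * u
  colnames(m) <- nm
  rownames(m) <- sprintf("m%03d", seq_len(spec$n_models))
  structure(m, class = c("population_sample", "matrix", "array"),
            spec = spec)
}

## scaling_factors for row i of a population sample
.model_scalings <- function(pop, i) {
  spec <- attr(pop, "spec")
  scaling_factors(pop[i, ], ncx_multiplier = spec$ncx_extra_multiplier)
}

#' Simulate every model of a population under one protocol
#'
#' @param pop a [sample_population()] matrix.
#' @param protocol a [make_protocol()] object.
#' @param cell,lyso shared baseline parameters.
#' @param models optional subset of model indices.
#' @param ... further arguments to [simulate_cell()].
#' @return Named list of `lysoca_sim` objects (one per model; failed
#'   simulations carry `failed = TRUE`).
#' @export
run_population <- function(pop, protocol, cell = cell_params(),
                           lyso = lysosome_params(),
                           models = seq_len(nrow(pop)), ...) {
  out <- lapply(models, function(i)
    simulate_cell(protocol, cell = cell, lyso = lyso,
                  scalings = .model_scalings(pop, i), ...))
  names(out) <- rownames(pop)[models]
  out
}

#' Calibration filter over the baseline protocols
#'
#' Simulates every model under CTRL, NAADP-AM and ISO in the wild-type
#' configuration and accepts those whose cytosolic calcium shows zero
#' spontaneous release events in all three; solver failures are logged
#' separately and excluded.
#'
#' @param pop a [sample_population()] matrix.
#' @param cell,lyso shared baseline parameters.
#' @param theta event detection threshold (see
#'   [detect_spontaneous_release()]).
#' @param keep_sims logical; retain the CTRL/NAADP-AM/ISO wild-type
#'   simulations of accepted models in the result (needed by downstream
#'   amplitude analyses; saves re-simulation).
#' @param ... further arguments to [simulate_cell()].
#' @return List with `accepted` (model indices), `table` (per-model
#'   data.frame: id, ten factors, accepted flag, rejection reason) and,
#'   when `keep_sims`, per-protocol lists of accepted-model simulations.
#' @export
calibrate_population <- function(pop, cell = cell_params(),
                                 lyso = lysosome_params(), theta = 0.10,
                                 keep_sims = TRUE, ...) {
  protos <- list(CTRL = make_protocol("CTRL"),
                 NAADP_AM = make_protocol("NAADP_AM"),
                 ISO = make_protocol("ISO"))
  n <- nrow(pop)
  reason <- rep(NA_character_, n)
  accepted <- logical(n)
  sims <- list(CTRL = vector("list", n), NAADP_AM = vector("list", n),
               ISO = vector("list", n))
  for (i in seq_len(n)) {
    ok <- TRUE
    for (pn in names(protos)) {
      s <- simulate_cell(protos[[pn]], cell = cell, lyso = lyso,
                         scalings = .model_scalings(pop, i), ...)
      if (s$failed) {
        reason[i] <- paste0("solver_failure:", pn); ok <- FALSE; break
      }
      if (nrow(events_of(s, theta = theta)) > 0) {
        reason[i] <- pn; ok <- FALSE; break
      }
      if (keep_sims) sims[[pn]][[i]] <- s
    }
    accepted[i] <- ok
  }
  tab <- data.frame(id = rownames(pop), pop,
                    accepted = accepted, rejection_reason = reason,
                    row.names = NULL, check.names = FALSE)
  res <- list(accepted = which(accepted), table = tab)
  if (keep_sims)
    res$sims <- lapply(sims, function(l) {
      l <- l[accepted]
      names(l) <- rownames(pop)[accepted]
      l
    })
  res
}

#' Paired wild-type / TPC2-knockout execution
#'
#' Simulates each model twice under one protocol with identical scaling
#' factors, differing only in the lysosomal release block (the TPC2
#' knockout).  Results are keyed by model id for paired classification.
#'
#' @param pop a [sample_population()] matrix.
#' @param protocol a [make_protocol()] object (its own `release_block` is
#'   overridden per arm).
#' @param models model indices to run (typically the accepted subset).
#' @param cell,lyso shared baseline parameters.
#' @param ... further arguments to [simulate_cell()].
#' @return List with elements `WT` and `KO`, each a named list of
#'   simulations.
#' @export
run_paired <- function(pop, protocol, models, cell = cell_params(),
                       lyso = lysosome_params(), ...) {
  wt <- protocol; wt$release_block <- FALSE
  ko <- protocol; ko$release_block <- TRUE
  list(WT = run_population(pop, wt, cell, lyso, models = models, ...),
       KO = run_population(pop, ko, cell, lyso, models = models, ...))
}
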