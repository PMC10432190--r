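## Per-simulation metric extraction: everything downstream analyses need,
## without retaining the dense trace.
.sim_metrics <- function(sim, theta = 0.10, theta_low = 0.02) {
  if (sim$failed)
    return(list(failed = TRUE, amp = NA_real_, events = NA_integer_,
                ambiguous = NA))
  lb <- last_beat(sim)
  ev <- events_of(sim, theta = theta)
  list(failed = FALSE,
       amp = amplitude(lb$Cai),
       amp_serca = amplitude(lb$J_SERCA),
       amp_ryr = amplitude(lb$J_RyR),
       max_casr = max(lb$Casr),
       peak_ryr_po = max(lb$RyR_O),
       events = nrow(ev),
       ambiguous = flag_ambiguous(sim$trace$time, sim$trace$Cai,
                                  sim$stim_times, theta = theta,
                                  theta_low = theta_low))
}

.metrics_population <- function(pop, protocol, models, cell, lyso,
                                theta = 0.10, ...) {
  out <- lapply(models, function(i) {
    s <- simulate_cell(protocol, cell = cell, lyso = lyso,
                       scalings = .model_scalings(pop, i), ...)
    .sim_metrics(s, theta = theta)
  })
  names(out) <- rownames(pop)[models]
  out
}

.metric <- function(ms, field) vapply(ms, function(m) {
  v <- m[[field]]
  if (is.null(v)) NA_real_ else as.numeric(v)
}, numeric(1))

#' Run the full population study
#'
#' End-to-end reproduction of the population experiments: seeded Latin
#' hypercube population, calibration filter over the baseline protocols
#' (CTRL, NAADP-AM, ISO in the wild-type configuration), paired TPC2
#' knockout arms, the hypercalcemia plus beta-adrenergic overload protocol
#' with WT/KO classification, and (optionally) the fast-to-slow pacing
#' overload protocol.  Returns the calibration-surface statistics and
#' incidence figures of the study.
#'
#' @param n_models initial population size before filtering.
#' @param seed RNG seed controlling the Latin hypercube draw.
#' @param cell,lyso shared baseline parameters.
#' @param theta event-detector threshold.
#' @param fastpace logical; also run the 10 Hz fast-pacing arm.
#' @param uptake_block logical; rerun hypercalcemia with lysosomal uptake
#'   blocked on the TPC-specific subset (and release-blocked for the
#'   reverted-fraction figure).
#' @return List with elements `targets` (named headline quantities),
#'   `n_accepted`, `accepted_fraction`, `classification` (hypercalcemia),
#'   `fastpace_classification` (when requested) and the per-model metric
#'   tables.
#' @export
run_study <- function(n_models = 140, seed, cell = cell_params(),
                      lyso = lysosome_params(), theta = 0.10,
                      fastpace = TRUE, uptake_block = TRUE) {
  spec <- population_spec(n_models = n_models, seed = seed)
  pop <- sample_population(spec)
  cal <- calibrate_population(pop, cell = cell, lyso = lyso,
                              theta = theta, keep_sims = TRUE)
  acc <- cal$accepted
  if (!length(acc)) stop("no models accepted at this population size")

  m_wt <- lapply(cal$sims, function(sims) lapply(sims, .sim_metrics,
                                                 theta = theta))
  cal$sims <- NULL
  ko <- lapply(c(CTRL = "CTRL", NAADP_AM = "NAADP_AM", ISO = "ISO"),
               function(nm) .metrics_population(
                 pop, make_protocol(nm, ko = TRUE), acc, cell, lyso,
                 theta = theta))

  aC <- .metric(m_wt$CTRL, "amp"); aN <- .metric(m_wt$NAADP_AM, "amp")
  aI <- .metric(m_wt$ISO, "amp")
  aCk <- .metric(ko$CTRL, "amp"); aNk <- .metric(ko$NAADP_AM, "amp")
  aIk <- .metric(ko$ISO, "amp")
  ## amplitude targets are defined on clean paced transients: a knockout
  ## arm that itself fires at baseline (not screened by the wild-type-only
  ## acceptance filter) has no meaningful transient amplitude and is
  ## excluded from the paired amplitude statistics
  ko_ev <- .metric(ko$CTRL, "events") + .metric(ko$NAADP_AM, "events") +
    .metric(ko$ISO, "events")
  ok <- stats::complete.cases(aC, aN, aI, aCk, aNk, aIk, ko_ev) & ko_ev == 0

  nc3 <- normalized_change(aN[ok], aC[ok])
  nc4 <- normalized_change(aNk[ok], aCk[ok])
  nc5 <- normalized_change(aI[ok], aC[ok])
  nc5k <- normalized_change(aIk[ok], aCk[ok])

  ## hypercalcemia + ISO, paired arms
  hyper <- make_protocol("HYPERCALCEMIA_ISO")
  paired <- run_paired(pop, hyper, models = acc, cell = cell, lyso = lyso)
  cls <- classify_models(paired, theta = theta)

  targets <- list(
    po_at_15nM = tpc2_open_probability(15, lyso),
    po_max = tpc2_open_probability(lyso$PO_mean, lyso),
    naadp_norm_change_wt = nc3$mean,
    naadp_norm_change_ko = nc4$mean,
    iso_rel_change_wt = nc5$mean,
    iso_rel_change_ko = nc5k$mean,
    iso_fold_change = fold_change(aI[ok], aC[ok]),
    naadp_fold_change = fold_change(aN[ok], aC[ok]),
    hyper_wt_incidence_pct = cls$summary$wt_incidence_pct,
    hyper_ko_incidence_pct = cls$summary$ko_incidence_pct,
    n_tpc_specific = cls$summary$n_tpc_specific
  )

  res <- list(targets = targets, population = pop, calibration_table = cal$table,
              n_accepted = length(acc), accepted = acc,
              accepted_fraction = length(acc) / n_models,
              classification = cls,
              amplitudes = data.frame(
                id = rownames(pop)[acc][ok],
                CTRL_WT = aC[ok], NAADP_WT = aN[ok], ISO_WT = aI[ok],
                CTRL_KO = aCk[ok], NAADP_KO = aNk[ok], ISO_KO = aIk[ok]),
              seed = seed, n_models = n_models)

  res$hyper_metrics <- list(
    WT = lapply(paired$WT, .sim_metrics, theta = theta),
    KO = lapply(paired$KO, .sim_metrics, theta = theta))

  res$targets$uptake_block_residual_pct <- NA_real_
  res$targets$fastpace_uptake_block_residual_pct <- NA_real_
  tpc_ids <- cls$table$id[cls$table$label == "TPC_specific"]
  tpc_idx <- match(tpc_ids, rownames(pop))
  if (uptake_block && length(tpc_idx)) {
    ub <- .metrics_population(pop, make_protocol("HYPERCALCEMIA_ISO",
                                                 uptake_block = TRUE),
                              tpc_idx, cell, lyso, theta = theta)
    res$targets$uptake_block_residual_pct <-
      100 * mean(.metric(ub, "events") > 0, na.rm = TRUE)
    ## release-blocked reruns for the reverted-fraction figure and the
    ## directional comparison against the paired wild type
    rb <- lapply(tpc_idx, function(i)
      simulate_cell(make_protocol("HYPERCALCEMIA_ISO", release_block = TRUE),
                    cell = cell, lyso = lyso,
                    scalings = .model_scalings(pop, i)))
    rf <- vapply(rb, function(s)
      if (s$failed) NA_real_ else reverted_fraction(s), numeric(1))
    res$targets$reverted_fraction_median <- stats::median(rf, na.rm = TRUE)
    res$release_block_metrics <- lapply(rb, .sim_metrics, theta = theta)
    names(res$release_block_metrics) <- tpc_ids
  }

  if (fastpace) {
    fp <- run_paired(pop, make_protocol("FASTPACE_ISO"), models = acc,
                     cell = cell, lyso = lyso)
    fcls <- classify_models(fp, theta = theta)
    res$fastpace_classification <- fcls
    res$targets$fastpace_wt_incidence_pct <- fcls$summary$wt_incidence_pct
    res$targets$fastpace_ko_incidence_pct <- fcls$summary$ko_incidence_pct
    ftpc <- fcls$table$id[fcls$table$label == "TPC_specific"]
    fidx <- match(ftpc, rownames(pop))
    if (uptake_block && length(fidx)) {
      fub <- .metrics_population(pop, make_protocol("FASTPACE_ISO",
                                                    uptake_block = TRUE),
                                 fidx, cell, lyso, theta = theta)
      res$targets$fastpace_uptake_block_residual_pct <-
        100 * mean(.metric(fub, "events") > 0, na.rm = TRUE)
    }
  }
  res
}
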