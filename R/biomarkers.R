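#' Amplitude biomarker
#'
#' Absolute difference of maximum and minimum of a trace segment.
#'
#' @param x numeric vector (typically one quantity over the final beat).
#' @return Nonnegative scalar.
#' @export
amplitude <- function(x) {
  if (!length(x) || any(!is.finite(x))) stop("amplitude: invalid trace")
  max(x) - min(x)
}

#' Fold change of population medians
#'
#' Ratio of the medians of two populations of amplitudes.
#'
#' @param a,b numeric vectors of per-model amplitudes (protocol vs
#'   reference).
#' @export
fold_change <- function(a, b) {
  if (!length(a) || !length(b)) stop("fold_change: empty population")
  stats::median(a) / stats::median(b)
}

#' Per-model normalized amplitude change
#'
#' `(amp_protocol - amp_ctrl) / amp_ctrl` per model, summarised as mean and
#' standard error across the population.
#'
#' @param amp_protocol,amp_ctrl paired per-model amplitudes.
#' @return List with `per_model`, `mean`, `se`, `n`.
#' @export
normalized_change <- function(amp_protocol, amp_ctrl) {
  if (length(amp_protocol) != length(amp_ctrl))
    stop("normalized_change: unpaired amplitudes")
  if (any(amp_ctrl <= 0)) stop("normalized_change: zero CTRL amplitude")
  d <- (amp_protocol - amp_ctrl) / amp_ctrl
  list(per_model = d, mean = mean(d),
       se = stats::sd(d) / sqrt(length(d)), n = length(d))
}

#' Calcium-transient biomarkers of the final beat
#'
#' Computes the standard per-model biomarker set on the recorded final
#' beat: amplitudes of cytosolic, lysosomal, SR and junctional calcium and
#' of the SERCA and RyR fluxes, diastolic and systolic cytosolic calcium,
#' time to 50% transient decay and peak RyR open probability.
#'
#' @param sim a [simulate_cell()] result.
#' @return Named list of biomarkers.
#' @export
biomarkers <- function(sim) {
  lb <- last_beat(sim)
  ca <- lb$Cai
  dia <- min(ca); sys <- max(ca)
  ipk <- which.max(ca)
  half <- dia + 0.5 * (sys - dia)
  after <- which(ca[ipk:length(ca)] <= half)
  t50 <- if (length(after)) lb$time[ipk + after[1] - 1] - lb$time[1] else NA_real_
  list(
    amp_Cai = sys - dia,
    amp_Cals = amplitude(lb$Cals),
    amp_Casr = amplitude(lb$Casr),
    amp_Caj = amplitude(lb$Caj),
    amp_JSERCA = amplitude(lb$J_SERCA),
    amp_JRyR = amplitude(lb$J_RyR),
    diastolic_Cai = dia,
    systolic_Cai = sys,
    t50_decay = t50,
    max_Casr = max(lb$Casr),
    peak_RyR_PO = max(lb$RyR_O)
  )
}
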