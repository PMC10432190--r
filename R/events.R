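## Local maxima with topographic prominence.  Returns a data.frame with
## index, value and prominence for every interior local maximum of x.
.find_peaks <- function(x) {
  n <- length(x)
  if (n < 3) return(data.frame(index = integer(), value = numeric(),
                               prominence = numeric()))
  dx <- diff(x)
  ## indices where the series switches from rising to falling (plateau-safe)
  s <- sign(dx)
  s[s == 0] <- NA
  s <- zoo_na_locf(s)
  pk <- which(diff(s) < 0) + 1L
  if (!length(pk)) return(data.frame(index = integer(), value = numeric(),
                                     prominence = numeric()))
  prom <- vapply(pk, function(i) {
    v <- x[i]
    left <- x[seq_len(i - 1)]
    right <- x[seq(i + 1, n)]
    hl <- which(left >= v); hr <- which(right >= v)
    lmin <- if (length(hl)) min(x[seq(max(hl) + 1, i - 1)]) else min(left)
    rmin <- if (length(hr)) min(x[seq(i + 1, i + min(hr) - 1)]) else min(right)
    v - max(lmin, rmin)
  }, numeric(1))
  data.frame(index = pk, value = x[pk], prominence = prom)
}

## last-observation-carried-forward for the sign vector (no zoo dependency)
zoo_na_locf <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(rep(1, length(x)))
  idx <- cumsum(ok)
  idx[idx == 0] <- 1
  x[ok][idx]
}

## Per-beat segmentation of a recorded trace: for each inter-stimulus
## interval, locate the paced-transient peak, its amplitude, and the times
## of decay to 90% and 50% (baseline = that beat's minimum).
.segment_beats <- function(time, x, stim_times) {
  st <- stim_times[stim_times >= time[1] - 1e-9 & stim_times <= time[length(time)]]
  ends <- c(st[-1], time[length(time)] + 1e-9)
  out <- vector("list", length(st))
  for (k in seq_along(st)) {
    sel <- which(time >= st[k] & time < ends[k])
    if (length(sel) < 5) next
    xi <- x[sel]; ti <- time[sel]
    base <- min(xi)
    ## paced peak: maximum within the first 40% of the interval
    head_n <- max(3L, ceiling(0.4 * length(sel)))
    ipk <- which.max(xi[seq_len(head_n)])
    amp <- xi[ipk] - base
    dec90 <- base + 0.1 * amp
    dec50 <- base + 0.5 * amp
    aft <- seq(ipk, length(sel))
    i90 <- aft[which(xi[aft] <= dec90)[1]]
    i50 <- aft[which(xi[aft] <= dec50)[1]]
    out[[k]] <- list(sel = sel, onset = st[k], end = ends[k],
                     amp = amp, peak_i = sel[ipk],
                     t90 = if (!is.na(i90)) ti[i90] else NA_real_,
                     t50 = if (!is.na(i50)) ti[i50] else NA_real_)
  }
  out[!vapply(out, is.null, TRUE)]
}

#' Detect spontaneous calcium release events
#'
#' Scans the diastolic phase of each recorded beat (after the paced
#' transient has decayed to 90%) for cytosolic calcium upstrokes whose
#' prominence is at least `theta` times the last paced-transient
#' amplitude.  Events inside a stimulus-triggered transient are never
#' counted.
#'
#' @param time,ci time (ms) and cytosolic calcium (mM) vectors, sampled at
#'   1 kHz or finer.
#' @param stim_times stimulus onset times covering the trace.
#' @param theta event prominence threshold, as a fraction of the paced
#'   transient amplitude (default 0.10).
#' @return Data frame of events: `time`, `type`, `magnitude`, `beat`,
#'   `diastolic`.
#' @export
detect_spontaneous_release <- function(time, ci, stim_times, theta = 0.10) {
  if (length(time) < 10) stop("trace shorter than one beat")
  segs <- .segment_beats(time, ci, stim_times)
  if (!length(segs)) stop("trace shorter than one beat")
  ref_amp <- segs[[length(segs)]]$amp
  ## guard: if the final beat itself is dominated by spontaneous activity
  ## its "paced" amplitude is still a valid scale reference
  ev <- NULL
  for (k in seq_along(segs)) {
    s <- segs[[k]]
    if (is.na(s$t90)) next   # transient never decayed; no diastolic window
    dia <- s$sel[time[s$sel] > s$t90]
    if (length(dia) < 5) next
    pks <- .find_peaks(ci[dia])
    keep <- pks$prominence >= theta * ref_amp
    if (any(keep)) {
      ev <- rbind(ev, data.frame(
        time = time[dia[pks$index[keep]]],
        type = "spontaneous_Ca_release",
        magnitude = pks$prominence[keep],
        beat = k, diastolic = TRUE))
    }
  }
  if (is.null(ev))
    ev <- data.frame(time = numeric(), type = character(),
                     magnitude = numeric(), beat = integer(),
                     diastolic = logical())
  ev[order(ev$time), , drop = FALSE]
}

#' Flag ambiguous relaxation-phase oscillations
#'
#' A trace is ambiguous when its relaxation phase (between 50% transient
#' decay and the next stimulus) carries ripple whose prominence lies
#' between `theta_low` and `theta` times the paced amplitude, while the
#' trace contains no countable suprathreshold event anywhere: such
#' oscillations cannot be clearly ascribed to spontaneous calcium release
#' and the model is excluded from proarrhythmia statistics.  A trace with
#' a full-blown diastolic release is countable, not ambiguous.
#'
#' @inheritParams detect_spontaneous_release
#' @param theta_low lower ripple threshold (default 0.02).
#' @return Logical.
#' @export
flag_ambiguous <- function(time, ci, stim_times, theta = 0.10,
                           theta_low = 0.02) {
  segs <- .segment_beats(time, ci, stim_times)
  if (!length(segs)) return(FALSE)
  ref_amp <- segs[[length(segs)]]$amp
  ripple <- FALSE
  for (s in segs) {
    if (is.na(s$t50)) next
    rel <- s$sel[time[s$sel] > s$t50]
    if (length(rel) < 5) next
    pks <- .find_peaks(ci[rel])
    if (!nrow(pks)) next
    if (any(pks$prominence >= theta * ref_amp)) return(FALSE)  # countable
    if (any(pks$prominence >= theta_low * ref_amp)) ripple <- TRUE
  }
  ripple
}

#' Detect delayed afterdepolarizations
#'
#' Finds diastolic membrane-potential humps occurring after full
#' repolarisation (V below `v_repol`) and outside stimulus windows, with
#' prominence of at least `theta_v` (mV).
#'
#' @param time,v time (ms) and membrane potential (mV).
#' @param stim_times stimulus onset times.
#' @param theta_v DAD prominence threshold (mV, default 1).
#' @param v_repol repolarisation level defining diastole (mV).
#' @param stim_dur stimulus artefact exclusion window (ms).
#' @return Data frame of events (`time`, `type`, `magnitude` = DAD
#'   amplitude in mV, `beat`, `diastolic`).
#' @export
detect_dads <- function(time, v, stim_times, theta_v = 1, v_repol = -65,
                        stim_dur = 5) {
  st <- stim_times[stim_times >= time[1] - 1e-9 & stim_times <= time[length(time)]]
  ends <- c(st[-1], time[length(time)] + 1e-9)
  ev <- NULL
  for (k in seq_along(st)) {
    sel <- which(time >= st[k] + stim_dur & time < ends[k])
    if (length(sel) < 5) next
    ## diastole starts once V first drops below the repolarisation level
    rp <- which(v[sel] <= v_repol)[1]
    if (is.na(rp)) next
    dia <- sel[seq(rp, length(sel))]
    if (length(dia) < 5) next
    pks <- .find_peaks(v[dia])
    keep <- pks$prominence >= theta_v
    if (any(keep))
      ev <- rbind(ev, data.frame(time = time[dia[pks$index[keep]]],
                                 type = "DAD",
                                 magnitude = pks$prominence[keep],
                                 beat = k, diastolic = TRUE))
  }
  if (is.null(ev))
    ev <- data.frame(time = numeric(), type = character(),
                     magnitude = numeric(), beat = integer(),
                     diastolic = logical())
  ev[order(ev$time), , drop = FALSE]
}

#' Spontaneous-release events of a simulation
#'
#' Convenience wrapper running [detect_spontaneous_release()] on the
#' recorded window of a simulation.
#'
#' @param sim a [simulate_cell()] result.
#' @param theta event prominence threshold.
#' @export
events_of <- function(sim, theta = 0.10) {
  if (sim$failed) stop("simulation failed; no trace")
  detect_spontaneous_release(sim$trace$time, sim$trace$Cai,
                             sim$stim_times, theta = theta)
}

#' Fraction of lysosomal calcium reverted to the junction
#'
#' For each recorded beat, integrates the positive part of the lysosomal
#' uptake flux (lysosome-to-junction reversal through the loading channel)
#' times lysosomal volume, and divides by the total outgoing lysosomal
#' throughput (reversal plus TPC2 release) over that beat.  Reported as
#' the mean across recorded beats of one model; take the median across
#' models for the population figure.
#'
#' @param sim a [simulate_cell()] result (typically under release block).
#' @return Scalar fraction in [0, 1] (NaN when the lysosome is silent).
#' @export
reverted_fraction <- function(sim) {
  tr <- sim$trace
  p <- sim$parms
  vls <- p[["Vls"]]
  ## outgoing lysosomal pathways: CLC reversal (junction-ward), TPC2
  ## release, and the passive diffusion legs to cytosol and junction
  jlsi <- if ("Jlsi" %in% names(p))
    p[["Jlsi"]] * (tr$Cals - tr$Cai) else rep(0, nrow(tr))
  jlsj <- if ("Jlsj" %in% names(p))
    p[["Jlsj"]] * (tr$Cals - tr$Caj) else rep(0, nrow(tr))
  segs <- .segment_beats(tr$time, tr$Cai, sim$stim_times)
  trapz <- function(tt, x) sum(diff(tt) * (x[-1] + x[-length(x)]) / 2)
  fr <- vapply(segs, function(s) {
    tt <- tr$time[s$sel]
    num <- trapz(tt, pmax(tr$J_ls_up[s$sel], 0) * vls)
    den <- num + trapz(tt, pmax(tr$J_ls_rel[s$sel], 0) * vls) +
      trapz(tt, pmax(jlsi[s$sel], 0)) + trapz(tt, pmax(jlsj[s$sel], 0))
    if (den <= 0) NaN else num / den
  }, numeric(1))
  mean(fr, na.rm = TRUE)
}
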