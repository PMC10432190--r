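#' Construct a named pacing/pharmacology protocol
#'
#' Builds the declarative specification of each in-silico experiment:
#' \describe{
#'   \item{CTRL}{1 Hz x 150 beats, extracellular Ca 1.0 mM, NAADP 1 nM, no ISO.}
#'   \item{NAADP_AM}{CTRL with NAADP raised to 15 nM (near-maximal TPC2 opening).}
#'   \item{ISO}{CTRL with 100 nM isoprenaline and NAADP 15 nM.}
#'   \item{HYPERCALCEMIA_ISO}{ISO with extracellular Ca raised 1.0 to 1.8 mM.}
#'   \item{FASTPACE_ISO}{ISO paced 10 Hz x 150 beats, then 1 Hz x 5 beats.}
#'   \item{FASTPACE25_ISO}{as FASTPACE_ISO at 25 Hz.}
#' }
#'
#' @param name protocol name (one of the above).
#' @param ko logical, TPC2 knockout (lysosomal release flux forced to zero;
#'   identical to `release_block`).
#' @param uptake_block logical, lysosomal uptake block (J_ls,up = 0).
#' @param release_block logical, lysosomal release block (J_ls,rel = 0).
#' @param ncx3 logical, threefold-enhanced NCX current study.
#' @param n_beats override for the number of beats of the first segment.
#' @return Object of class `protocol_spec`.
#' @export
make_protocol <- function(name = c("CTRL", "NAADP_AM", "ISO",
                                   "HYPERCALCEMIA_ISO", "FASTPACE_ISO",
                                   "FASTPACE25_ISO"),
                          ko = FALSE, uptake_block = FALSE,
                          release_block = FALSE, ncx3 = FALSE,
                          n_beats = NULL) {
  if (!is.character(name) || !name[1] %in% c("CTRL", "NAADP_AM", "ISO",
                                             "HYPERCALCEMIA_ISO",
                                             "FASTPACE_ISO", "FASTPACE25_ISO"))
    stop("unknown protocol '", name[1], "'; valid protocols: CTRL, NAADP_AM, ",
         "ISO, HYPERCALCEMIA_ISO, FASTPACE_ISO, FASTPACE25_ISO")
  name <- name[1]
  spec <- switch(name,
    CTRL = list(segments = list(c(rate = 1, n_beats = 150)),
                cao = 1.0, naadp = 1, iso = 0),
    NAADP_AM = list(segments = list(c(rate = 1, n_beats = 150)),
                    cao = 1.0, naadp = 15, iso = 0),
    ISO = list(segments = list(c(rate = 1, n_beats = 150)),
               cao = 1.0, naadp = 15, iso = 100),
    HYPERCALCEMIA_ISO = list(segments = list(c(rate = 1, n_beats = 150)),
                             cao = 1.8, naadp = 15, iso = 100),
    FASTPACE_ISO = list(segments = list(c(rate = 10, n_beats = 150),
                                        c(rate = 1, n_beats = 5)),
                        cao = 1.0, naadp = 15, iso = 100),
    FASTPACE25_ISO = list(segments = list(c(rate = 25, n_beats = 150),
                                          c(rate = 1, n_beats = 5)),
                          cao = 1.0, naadp = 15, iso = 100)
  )
  if (!is.null(n_beats)) spec$segments[[1]]["n_beats"] <- n_beats
  spec$name <- name
  spec$release_block <- isTRUE(ko) || isTRUE(release_block)
  spec$uptake_block <- isTRUE(uptake_block)
  spec$ncx_multiplier <- if (isTRUE(ncx3)) 3 else 1
  for (s in spec$segments)
    stopifnot(s[["rate"]] > 0, s[["n_beats"]] >= 1)
  stopifnot(spec$cao > 0)
  structure(spec, class = "protocol_spec")
}

#' Stimulus onset times of a protocol
#'
#' @param spec a [make_protocol()] object.
#' @return Numeric vector of stimulus onset times (ms), one per beat.
#' @export
stimulus_times <- function(spec) {
  t0 <- 0
  out <- numeric(0)
  for (s in spec$segments) {
    period <- 1000 / s[["rate"]]
    out <- c(out, t0 + period * (seq_len(s[["n_beats"]]) - 1))
    t0 <- t0 + period * s[["n_beats"]]
  }
  out
}

#' Stimulus current at a given time
#'
#' Rectangular pacing pulse train defined by the protocol's segments.
#'
#' @param t time (ms), vectorised.
#' @param spec a [make_protocol()] object.
#' @param amp,dur pulse amplitude (pA/pF) and duration (ms).
#' @return List with `current` (pA/pF, negative = depolarising inward) and
#'   `onsets` (the stimulus onset times).
#' @export
stimulus <- function(t, spec, amp = 40, dur = 2) {
  onsets <- stimulus_times(spec)
  cur <- vapply(t, function(ti) {
    k <- findInterval(ti, onsets)
    if (k >= 1 && ti - onsets[k] < dur && ti >= onsets[k]) -amp else 0
  }, numeric(1))
  list(current = cur, onsets = onsets)
}

## total protocol duration (ms)
.protocol_duration <- function(spec) {
  sum(vapply(spec$segments,
             function(s) 1000 / s[["rate"]] * s[["n_beats"]], numeric(1)))
}

## pacing-segment parameters for the solver (two segments supported)
.protocol_pacing <- function(spec) {
  s1 <- spec$segments[[1]]
  p1 <- 1000 / s1[["rate"]]
  if (length(spec$segments) >= 2) {
    s2 <- spec$segments[[2]]
    list(p1 = p1, n1 = s1[["n_beats"]],
         p2 = 1000 / s2[["rate"]], n2 = s2[["n_beats"]])
  } else {
    list(p1 = p1, n1 = s1[["n_beats"]], p2 = p1, n2 = 0)
  }
}

#' @export
print.protocol_spec <- function(x, ...) {
  segs <- paste(vapply(x$segments, function(s)
    sprintf("%g Hz x %d beats", s[["rate"]], s[["n_beats"]]), character(1)),
    collapse = ", ")
  cat("Protocol", x$name, "\n  pacing:", segs,
      "\n  Cao:", x$cao, "mM | NAADP:", x$naadp, "nM | ISO:", x$iso, "nM\n")
  flags <- c(if (x$release_block) "release block (TPC2-KO)",
             if (x$uptake_block) "uptake block",
             if (x$ncx_multiplier != 1) sprintf("NCX x%g", x$ncx_multiplier))
  if (length(flags)) cat("  interventions:", paste(flags, collapse = ", "), "\n")
  invisible(x)
}
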