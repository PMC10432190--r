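#' Lysosomal compartment parameters
#'
#' Constants of the lysosomal calcium pool: maximal CLC uptake and TPC2
#' release rate densities, their passive leaks, the Gaussian NAADP
#' open-probability law, lysosomal volume, passive diffusion rates to the
#' junctional and cytosolic subspaces, the current NAADP concentration and
#' the intervention flags.
#'
#' The open-probability law is pinned so that its global maximum is 0.016
#' and its value at 15 nM NAADP is 0.0134; with the calibrated width
#' `PO_sd = 0.55` (log10 units) this fixes
#' `PO_mean = 10^(log10(15) + PO_sd sqrt(2 log(0.016/0.0134)))`, about
#' 31.9 nM.  Flux magnitudes were calibrated against the population-level
#' calcium-transient responses to NAADP-AM and isoprenaline (see the
#' methods vignette).
#'
#' @param ... named overrides of individual parameters.
#' @return Object of class `lysosome_params` (named list). Units: rate
#'   densities in 1/ms (flux per mM of gradient at open probability 1),
#'   diffusion rates in pL/ms, volume in pL, NAADP in nM.
#' @export
lysosome_params <- function(...) {
  p <- list(
    j_clc = 2.45,          # maximal CLC uptake rate density (1/ms)
    j_tpc = 16,            # maximal TPC2 release rate density (1/ms)
    j_clc_leak = 0.02,     # CLC leak rate (1/ms)
    j_tpc_leak = 0.02,     # TPC2 leak rate (1/ms)
    PO_max = 0.016,
    PO_mean = 10^(log10(15) + 0.55 * sqrt(2 * log(0.016 / 0.0134))),  # nM
    PO_sd = 0.55,          # log10-concentration units
    V_ls = 2.4,            # pL
    J_ls_j = 0.001,        # lysosome <-> junction diffusion (pL/ms)
    J_ls_i = 0.02,         # lysosome <-> cytosol diffusion (pL/ms)
    naadp = 1.0,           # nM (CTRL endogenous level)
    uptake_blocked = FALSE,
    release_blocked = FALSE
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown lysosome parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  stopifnot(p$PO_max > 0, p$PO_max <= 1, p$PO_sd > 0, p$V_ls > 0,
            p$j_clc >= 0, p$j_tpc >= 0, p$j_clc_leak >= 0, p$j_tpc_leak >= 0)
  structure(p, class = "lysosome_params")
}

#' TPC2 open probability
#'
#' Gaussian dependence of the open probability of the lysosomal channels on
#' log NAADP concentration:
#' `PO = PO_max * exp(-(log10(naadp) - log10(PO_mean))^2 / (2 PO_sd^2))`.
#' The same value gates both the CLC uptake and TPC2 release conductances.
#'
#' @param naadp NAADP concentration (nM), strictly positive (vectorised).
#' @param params a [lysosome_params()] object.
#' @return Open probability in (0, PO_max].
#' @export
tpc2_open_probability <- function(naadp, params = lysosome_params()) {
  if (!is.numeric(naadp) || any(!is.finite(naadp)) || any(naadp <= 0))
    stop("naadp must be strictly positive (nM)")
  lg <- log10(naadp / params$PO_mean)
  params$PO_max * exp(-lg^2 / (2 * params$PO_sd^2))
}

#' Lysosomal uptake flux (CLC)
#'
#' `J_ls,up = j_clc * PO * (C_ls - C_j) + j_clc_leak * (C_ls - C_j)`,
#' positive for lysosome-to-junction flow, in lysosome-volume units
#' (mM/ms).  Returns 0 when uptake is blocked.
#'
#' @param C_ls,C_j lysosomal and junctional free calcium (mM).
#' @param PO open probability (use [tpc2_open_probability()]).
#' @param params a [lysosome_params()] object.
#' @export
uptake_flux <- function(C_ls, C_j, PO, params = lysosome_params()) {
  if (isTRUE(params$uptake_blocked)) return(0 * C_ls)
  (params$j_clc * PO + params$j_clc_leak) * (C_ls - C_j)
}

#' Lysosomal release flux (TPC2)
#'
#' `J_ls,rel = j_tpc * PO * (C_ls - C_i) + j_tpc_leak * (C_ls - C_i)`,
#' positive for lysosome-to-cytosol flow, in lysosome-volume units (mM/ms).
#' Returns 0 when release is blocked (the TPC2-knockout intervention).
#'
#' @param C_ls,C_i lysosomal and cytosolic free calcium (mM).
#' @param PO open probability.
#' @param params a [lysosome_params()] object.
#' @export
release_flux <- function(C_ls, C_i, PO, params = lysosome_params()) {
  if (isTRUE(params$release_blocked)) return(0 * C_ls)
  (params$j_tpc * PO + params$j_tpc_leak) * (C_ls - C_i)
}

#' Lysosomal coupling terms of the calcium conservation equations
#'
#' Contributions of the lysosomal compartment to the time derivatives of
#' lysosomal, junctional and cytosolic calcium:
#' \itemize{
#'  \item `dC_ls`: `J_ls_j (C_j - C_ls)/V_ls - J_ls,up + J_ls_i (C_i - C_ls)/V_ls - J_ls,rel`
#'  \item `dC_j`:  `J_ls,up V_ls/V_j + J_ls_j (C_ls - C_j)/V_j`
#'  \item `dC_i`:  `J_ls,rel V_ls/V_i + J_ls_i (C_ls - C_i)/V_i`
#' }
#' The volume weighting makes the exchange mass-conserving by construction.
#'
#' @param state named vector with at least `Cals`, `Caj`, `Cai` (mM).
#' @param params a [lysosome_params()] object.
#' @param V_j,V_i junctional and cytosolic volumes (pL).
#' @return List with `dC_ls`, `dC_j`, `dC_i` (mM/ms) and the two fluxes.
#' @export
lysosome_coupling <- function(state, params = lysosome_params(),
                              V_j = cell_params()$Vjunc,
                              V_i = cell_params()$Vmyo) {
  C_ls <- state[["Cals"]]; C_j <- state[["Caj"]]; C_i <- state[["Cai"]]
  PO <- tpc2_open_probability(params$naadp, params)
  J_up <- uptake_flux(C_ls, C_j, PO, params)
  J_rel <- release_flux(C_ls, C_i, PO, params)
  list(
    dC_ls = params$J_ls_j * (C_j - C_ls) / params$V_ls - J_up +
      params$J_ls_i * (C_i - C_ls) / params$V_ls - J_rel,
    dC_j = J_up * params$V_ls / V_j + params$J_ls_j * (C_ls - C_j) / V_j,
    dC_i = J_rel * params$V_ls / V_i + params$J_ls_i * (C_ls - C_i) / V_i,
    J_ls_up = J_up, J_ls_rel = J_rel, PO = PO
  )
}
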