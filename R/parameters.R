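#' @useDynLib lysoca
#' @importFrom stats approx median sd setNames
#' @importFrom utils write.csv read.csv
"_PACKAGE"

## Canonical solver-parameter order.  Must match the `enum` in src/lysoca.c.
.lysoca_parm_names <- c(
  "Cmem", "Vmyo", "Vsr", "Vsl", "Vjunc", "Vls",
  "Temp", "Cao", "Nao", "Ko", "Ki",
  "PCa", "konfca", "kofffca",
  "gto", "gkr", "gsus", "gk1",
  "IbarNCX", "KmCai", "KmCao", "KmNai", "KmNao", "ksat", "eta", "Kdact",
  "gcab", "ibarnak", "KmNaip", "KmKo", "gnab",
  "Vmax_serca", "Kmf", "Kmr", "hillserca",
  "ks", "koCa", "kom", "kiCa", "kim", "ec50SR", "MaxSR", "MinSR", "kleak",
  "Jjsl", "Jsli",
  "BmaxTnC", "konTnC", "koffTnC",
  "BmaxCaM", "konCaM", "koffCaM",
  "BmaxSRB", "konSRB", "koffSRB",
  "BmaxSLL", "BmaxSLLj", "konsll", "koffsll",
  "BmaxSLH", "BmaxSLHj", "konslh", "koffslh",
  "Bmaxcsqn", "koncsqn", "koffcsqn",
  "jclc", "jtpc", "jclcleak", "jtpcleak",
  "POmax", "POmean", "POsd",
  "Jlsj", "Jlsi", "naadp",
  "uptake_block", "release_block",
  "iso_ltcc", "iso_ryr", "iso_serca_kmf", "iso_kmnai", "iso_cdi",
  "sc_ical", "sc_ryr", "sc_jclc", "sc_jtpc", "sc_jclcleak", "sc_jtpcleak",
  "sc_ncx", "sc_serca", "sc_to", "sc_kr",
  "stim_amp", "stim_dur", "p1", "n1", "p2", "n2"
)

#' Baseline cell parameters
#'
#' Returns the full parameter set of the reduced mouse ventricular myocyte
#' model: geometry, maximal current/flux magnitudes, buffer constants and
#' stimulus settings.  Units are mV, ms, mM and pL throughout; membrane
#' currents are normalised to capacitance (pA/pF).
#'
#' Components follow Shannon-style compartmentalisation (junctional,
#' subsarcolemmal, cytosolic and SR calcium pools plus explicit buffers) with
#' mouse-like repolarisation.  The lysosomal constants are supplied
#' separately by [lysosome_params()] and merged by [solver_parms()].
#'
#' @param ... named overrides of individual parameters.
#' @return An object of class `cell_params` (named list).
#' @export
cell_params <- function(...) {
  p <- list(
    ## geometry (mouse: 100 um x 10.25 um radius cylinder, 33 pL)
    Cmem = 138,            # pF
    Vmyo = 21.45,          # pL (65% cell)
    Vsr = 1.155,           # pL (3.5%)
    Vsl = 0.66,            # pL (2%)
    Vjunc = 0.0178,        # pL (0.0539%)
    ## milieu
    Temp = 310, Cao = 1.0, Nao = 140, Ko = 5.4, Ki = 135,
    ## L-type Ca current (GHK scale; slow Ca-dependent inactivation gate)
    PCa = 5.4e-4, konfca = 1.7, kofffca = 0.0119,
    ## K currents
    gto = 0.50, gkr = 0.05, gsus = 0.15, gk1 = 0.35,
    ## NCX
    IbarNCX = 9, KmCai = 0.00359, KmCao = 1.3, KmNai = 12.29,
    KmNao = 87.5, ksat = 0.27, eta = 0.35, Kdact = 2.56e-4,
    ## NaK pump and backgrounds
    gcab = 1.3e-7, ibarnak = 1.907, KmNaip = 11, KmKo = 1.5, gnab = 5.97e-4,
    ## SERCA
    Vmax_serca = 5.3114e-3, Kmf = 2.46e-4, Kmr = 1.7, hillserca = 1.787,
    ## RyR
    ks = 25, koCa = 10, kom = 0.075, kiCa = 0.8, kim = 0.005,
    ec50SR = 0.44, MaxSR = 15, MinSR = 1, kleak = 5.348e-6,
    ## inter-compartment diffusion (pL/ms)
    Jjsl = 1.65, Jsli = 3.7243,
    ## cytosolic buffers: troponin C (low), calmodulin, SR-membrane sites
    BmaxTnC = 0.07, konTnC = 32.7, koffTnC = 0.0196,
    BmaxCaM = 0.024, konCaM = 34, koffCaM = 0.238,
    BmaxSRB = 0.0171, konSRB = 100, koffSRB = 0.06,
    ## sarcolemmal buffers (myoplasm-referenced capacities; low/high affinity)
    BmaxSLL = 0.0374, BmaxSLLj = 4.6e-4, konsll = 100, koffsll = 1.3,
    BmaxSLH = 0.0134, BmaxSLHj = 1.65e-4, konslh = 100, koffslh = 0.03,
    ## SR buffer (calsequestrin, SR-referenced)
    Bmaxcsqn = 2.6, koncsqn = 100, koffcsqn = 65,
    ## beta-adrenergic slowing of L-type Ca-dependent inactivation
    ## (calibrated so 100 nM ISO doubles per-beat L-type Ca influx)
    iso_cdi = 0.41,
    ## stimulus
    stim_amp = 60, stim_dur = 2
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown cell parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  stopifnot(p$Vmyo > 0, p$Vsr > 0, p$Vsl > 0, p$Vjunc > 0, p$Cao > 0)
  structure(p, class = "cell_params")
}

#' Isoprenaline (beta-adrenergic) parameter scalings
#'
#' Builds the static multiplier set describing maximal protein kinase A
#' phosphorylation of its calcium-handling targets.  At 100 nM isoprenaline:
#' L-type current availability x1.56, RyR open probability x2 (applied to
#' the RyR opening rate), SERCA forward-mode half-saturation x0.45
#' (phospholamban relief of forward-mode affinity), and Na/K pump sodium
#' affinity increased (phospholemman) via Km x0.78.
#'
#' @param iso isoprenaline concentration in nM; the pacing protocols are
#'   binary, so only 0 and 100 are supported.
#' @return An object of class `iso_scalings` with elements `ltcc`, `ryr`,
#'   `serca_kmf`, `nak_kmnai` and `cdi` (the slowing factor on L-type
#'   calcium-dependent inactivation that carries the printed twofold
#'   increase of per-beat calcium influx; the cell-level calibrated value
#'   in `cell_params()$iso_cdi` overrides this default inside
#'   [simulate_cell()]).
#' @export
apply_iso <- function(iso) {
  if (!is.numeric(iso) || length(iso) != 1 || !is.finite(iso))
    stop("iso must be a single finite number (nM)")
  if (iso == 0) {
    s <- list(ltcc = 1, ryr = 1, serca_kmf = 1, nak_kmnai = 1, cdi = 1)
  } else if (iso == 100) {
    s <- list(ltcc = 1.56, ryr = 2, serca_kmf = 0.45, nak_kmnai = 0.78, cdi = 0.30)
  } else {
    stop("unsupported ISO concentration: ", iso,
         " nM (protocols are binary: 0 or 100 nM)")
  }
  structure(s, class = "iso_scalings")
}

#' Default state vector
#'
#' Physiological resting initial conditions for all 24 states: membrane
#' potential, seven gating variables, three RyR state occupancies (the
#' fourth is the complement), five calcium pools, intracellular sodium and
#' eight buffer-bound calcium states.
#'
#' @param Cals initial lysosomal free calcium (mM).
#' @return Named numeric vector of length 24.
#' @export
initial_state <- function(Cals = 0.05) {
  c(V = -78, d = 0, f = 1, fcab = 0.015, xto = 0, yto = 1, xkr = 0,
    RyR_R = 0.99, RyR_O = 0, RyR_I = 0,
    Caj = 1e-4, Casl = 1e-4, Cai = 1e-4, Casr = 0.55, Cals = Cals,
    Nai = 12,
    TnCL = 0.009, CaM = 3e-4, SRB = 2.5e-3,
    SLLj = 8e-3, SLHj = 8e-2, SLLsl = 8e-3, SLHsl = 8e-2,
    Csqn = 1.1)
}

#' Assemble the flat solver parameter vector
#'
#' Merges cell parameters, lysosomal parameters, isoprenaline scalings,
#' per-model population scaling factors and the pacing segments into the
#' flat named vector consumed by the compiled right-hand side (and by the
#' reference R implementation).
#'
#' @param cell a [cell_params()] object.
#' @param lyso a [lysosome_params()] object.
#' @param iso an [apply_iso()] scaling set.
#' @param scalings a [scaling_factors()] vector (10 multipliers).
#' @param pacing list with `p1`, `n1`, `p2`, `n2` (segment periods in ms and
#'   beat counts); see [make_protocol()].
#' @return Named numeric vector ordered as the compiled code expects.
#' @export
solver_parms <- function(cell = cell_params(), lyso = lysosome_params(),
                         iso = apply_iso(0), scalings = scaling_factors(),
                         pacing = list(p1 = 1000, n1 = 150, p2 = 1000, n2 = 0)) {
  v <- c(
    cell$Cmem, cell$Vmyo, cell$Vsr, cell$Vsl, cell$Vjunc, lyso$V_ls,
    cell$Temp, cell$Cao, cell$Nao, cell$Ko, cell$Ki,
    cell$PCa, cell$konfca, cell$kofffca,
    cell$gto, cell$gkr, cell$gsus, cell$gk1,
    cell$IbarNCX, cell$KmCai, cell$KmCao, cell$KmNai, cell$KmNao,
    cell$ksat, cell$eta, cell$Kdact,
    cell$gcab, cell$ibarnak, cell$KmNaip, cell$KmKo, cell$gnab,
    cell$Vmax_serca, cell$Kmf, cell$Kmr, cell$hillserca,
    cell$ks, cell$koCa, cell$kom, cell$kiCa, cell$kim,
    cell$ec50SR, cell$MaxSR, cell$MinSR, cell$kleak,
    cell$Jjsl, cell$Jsli,
    cell$BmaxTnC, cell$konTnC, cell$koffTnC,
    cell$BmaxCaM, cell$konCaM, cell$koffCaM,
    cell$BmaxSRB, cell$konSRB, cell$koffSRB,
    cell$BmaxSLL, cell$BmaxSLLj, cell$konsll, cell$koffsll,
    cell$BmaxSLH, cell$BmaxSLHj, cell$konslh, cell$koffslh,
    cell$Bmaxcsqn, cell$koncsqn, cell$koffcsqn,
    lyso$j_clc, lyso$j_tpc, lyso$j_clc_leak, lyso$j_tpc_leak,
    lyso$PO_max, lyso$PO_mean, lyso$PO_sd,
    lyso$J_ls_j, lyso$J_ls_i, lyso$naadp,
    as.numeric(lyso$uptake_blocked), as.numeric(lyso$release_blocked),
    iso$ltcc, iso$ryr, iso$serca_kmf, iso$nak_kmnai, iso$cdi,
    scalings[["I_CaL"]], scalings[["J_RyR"]], scalings[["j_clc"]],
    scalings[["j_tpc"]], scalings[["j_clc_leak"]], scalings[["j_tpc_leak"]],
    scalings[["I_NCX"]], scalings[["J_SERCA"]], scalings[["I_to"]],
    scalings[["I_Kr"]],
    cell$stim_amp, cell$stim_dur,
    pacing$p1, pacing$n1, pacing$p2, pacing$n2
  )
  stats::setNames(v, .lysoca_parm_names)
}

#' Per-model scaling factor set
#'
#' The ten dimensionless multipliers that define one member of a population
#' of models, in the fixed order: I_CaL, J_RyR, j_clc, j_tpc, j_clc_leak,
#' j_tpc_leak, I_NCX, J_SERCA, I_to, I_Kr.
#'
#' @param x numeric vector of length 10 (default: all 1).
#' @param ncx_multiplier extra multiplier applied to I_NCX on top of the
#'   sampled factor (3 in the enhanced-NCX study).
#' @return Named numeric vector of class `scaling_factors`.
#' @export
scaling_factors <- function(x = rep(1, 10), ncx_multiplier = 1) {
  nm <- c("I_CaL", "J_RyR", "j_clc", "j_tpc", "j_clc_leak", "j_tpc_leak",
          "I_NCX", "J_SERCA", "I_to", "I_Kr")
  if (length(x) != 10) stop("scaling factor set must have 10 entries")
  x <- as.numeric(x)
  x[7] <- x[7] * ncx_multiplier
  structure(stats::setNames(x, nm), class = "scaling_factors")
}
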