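## Reference (pure-R) implementation of the model right-hand side.  This is
## the readable, term-by-term statement of the equations; the compiled code
## in src/lysoca.c is its exact mirror and is what the integrator uses.

.Frdy <- 96485
.Rgas <- 8314

## core equations; p is the flat solver parameter vector (see solver_parms),
## y the 24-state vector.  `lysosome = FALSE` removes the lysosomal
## compartment structurally (all coupling terms absent, dCals = 0), giving
## the unextended baseline model for reduction checks.
.rhs_core <- function(t, y, p, lysosome = TRUE) {
  V <- y[[1]]; d <- y[[2]]; f <- y[[3]]; fcab <- y[[4]]
  xto <- y[[5]]; yto <- y[[6]]; xkr <- y[[7]]
  rR <- y[[8]]; rO <- y[[9]]; rI <- y[[10]]
  Caj <- y[[11]]; Casl <- y[[12]]; Cai <- y[[13]]; Casr <- y[[14]]
  Cals <- y[[15]]; Nai <- y[[16]]
  TnCL <- y[[17]]; CaM <- y[[18]]; SRB <- y[[19]]
  SLLj <- y[[20]]; SLHj <- y[[21]]; SLLsl <- y[[22]]; SLHsl <- y[[23]]
  Csqn <- y[[24]]

  FoRT <- .Frdy / (.Rgas * p[["Temp"]])
  EK <- log(p[["Ko"]] / p[["Ki"]]) / FoRT
  ENa <- log(p[["Nao"]] / Nai) / FoRT

  ## L-type Ca current (GHK driving force, junctional cleft)
  vs <- V + 14.5
  dss <- 1 / (1 + exp(-vs / 6))
  taud <- if (abs(vs) < 1e-4) dss / (0.035 * 6) else
    dss * (1 - exp(-vs / 6)) / (0.035 * vs)
  fss <- min(1, 1 / (1 + exp((V + 35.06) / 3.6)) +
               0.6 / (1 + exp((50 - V) / 20)))
  tauf <- 1 / (0.0197 * exp(-(0.0337 * vs)^2) + 0.02)
  dfcab <- p[["konfca"]] * p[["iso_cdi"]] * Caj * (1 - fcab) - p[["kofffca"]] * fcab
  z <- 2 * V * FoRT
  if (abs(z) < 1e-6) z <- sign(z + (z == 0)) * 1e-6
  ibarca <- p[["PCa"]] * p[["iso_ltcc"]] * p[["sc_ical"]] *
    2 * z * .Frdy * (0.341 * Caj * exp(z) - 0.341 * p[["Cao"]]) / (exp(z) - 1)
  ICaL <- ibarca * d * f * (1 - fcab)

  ## K currents (mouse-like repolarisation)
  Ito <- p[["gto"]] * p[["sc_to"]] * xto * yto * (V - EK)
  xtoss <- 1 / (1 + exp(-(V + 5) / 13)); tauxto <- 1.5
  ytoss <- 1 / (1 + exp((V + 38) / 5))
  tauyto <- 8 + 40 / (1 + exp((V + 35) / 6))
  rkr <- 1 / (1 + exp((V + 74) / 24))
  IKr <- p[["gkr"]] * p[["sc_kr"]] * xkr * rkr * (V - EK)
  xkrss <- 1 / (1 + exp(-(V + 10) / 5)); tauxkr <- 50
  Isus <- p[["gsus"]] * (V - EK) / (1 + exp(-(V + 15) / 8))
  aK1 <- 1.02 / (1 + exp(0.2385 * (V - EK - 59.215)))
  bK1 <- (0.49124 * exp(0.08032 * (V - EK + 5.476)) +
            exp(0.06175 * (V - EK - 594.31))) /
    (1 + exp(-0.5143 * (V - EK + 4.753)))
  IK1 <- p[["gk1"]] * sqrt(p[["Ko"]] / 5.4) * aK1 / (aK1 + bK1) * (V - EK)

  ## Na/Ca exchanger (subsarcolemmal)
  Ka <- 1 / (1 + (p[["Kdact"]] / Casl)^2)
  s1 <- exp(p[["eta"]] * V * FoRT) * Nai^3 * p[["Cao"]]
  s2 <- exp((p[["eta"]] - 1) * V * FoRT) * p[["Nao"]]^3 * Casl
  s3 <- p[["KmCai"]] * p[["Nao"]]^3 * (1 + (Nai / p[["KmNai"]])^3) +
    p[["KmNao"]]^3 * Casl * (1 + Casl / p[["KmCai"]]) +
    p[["KmCao"]] * Nai^3 + Nai^3 * p[["Cao"]] + p[["Nao"]]^3 * Casl
  INCX <- p[["IbarNCX"]] * p[["sc_ncx"]] * Ka * (s1 - s2) /
    (s3 * (1 + p[["ksat"]] * exp((p[["eta"]] - 1) * V * FoRT)))

  ## Na/K pump and background currents
  sigma <- (exp(p[["Nao"]] / 67.3) - 1) / 7
  fnak <- 1 / (1 + 0.1245 * exp(-0.1 * V * FoRT) +
                 0.0365 * sigma * exp(-V * FoRT))
  INaK <- p[["ibarnak"]] * fnak * p[["Ko"]] / (p[["Ko"]] + p[["KmKo"]]) /
    (1 + (p[["KmNaip"]] * p[["iso_kmnai"]] / Nai)^4)
  ICab <- p[["gcab"]] * 2 * z * .Frdy *
    (0.341 * Casl * exp(z) - 0.341 * p[["Cao"]]) / (exp(z) - 1)
  INab <- p[["gnab"]] * (V - ENa)

  ## RyR (luminal-gated 4-state: R, O, I, RI = 1-R-O-I)
  kCaSR <- p[["MaxSR"]] - (p[["MaxSR"]] - p[["MinSR"]]) /
    (1 + (p[["ec50SR"]] / Casr)^2.5)
  koSRCa <- p[["koCa"]] * p[["iso_ryr"]] / kCaSR
  kiSRCa <- p[["kiCa"]] * kCaSR
  RI <- 1 - rR - rO - rI
  drR <- (p[["kim"]] * RI - kiSRCa * Caj * rR) -
    (koSRCa * Caj^2 * rR - p[["kom"]] * rO)
  drO <- (koSRCa * Caj^2 * rR - p[["kom"]] * rO) -
    (kiSRCa * Caj * rO - p[["kim"]] * rI)
  drI <- (kiSRCa * Caj * rO - p[["kim"]] * rI) -
    (p[["kom"]] * rI - koSRCa * Caj^2 * RI)
  JRyR <- p[["ks"]] * p[["sc_ryr"]] * rO * (Casr - Caj)   # SR-volume units
  Jleak <- p[["kleak"]] * (Casr - Caj)                    # cytosolic units

  ## SERCA (forward/reverse Hill)
  Kmf <- p[["Kmf"]] * p[["iso_serca_kmf"]]
  fw <- (Cai / Kmf)^p[["hillserca"]]; rv <- (Casr / p[["Kmr"]])^p[["hillserca"]]
  JSERCA <- p[["Vmax_serca"]] * p[["sc_serca"]] * (fw - rv) / (1 + fw + rv)

  ## lysosome
  if (lysosome) {
    lg <- log10(p[["naadp"]] / p[["POmean"]])
    PO <- p[["POmax"]] * exp(-lg^2 / (2 * p[["POsd"]]^2))
    gup <- p[["jclc"]] * p[["sc_jclc"]] * PO +
      p[["jclcleak"]] * p[["sc_jclcleak"]]
    grel <- p[["jtpc"]] * p[["sc_jtpc"]] * PO +
      p[["jtpcleak"]] * p[["sc_jtpcleak"]]
    Jlsup <- if (p[["uptake_block"]] > 0.5) 0 else gup * (Cals - Caj)
    Jlsrel <- if (p[["release_block"]] > 0.5) 0 else grel * (Cals - Cai)
  } else {
    PO <- 0; Jlsup <- 0; Jlsrel <- 0
  }

  ## buffers: cytosolic (troponin C low, calmodulin, SR-membrane),
  ## membrane (low/high affinity, junctional and subsarcolemmal), csqn
  dTnCL <- p[["konTnC"]] * Cai * (p[["BmaxTnC"]] - TnCL) - p[["koffTnC"]] * TnCL
  dCaM <- p[["konCaM"]] * Cai * (p[["BmaxCaM"]] - CaM) - p[["koffCaM"]] * CaM
  dSRB <- p[["konSRB"]] * Cai * (p[["BmaxSRB"]] - SRB) - p[["koffSRB"]] * SRB
  JCaBi <- dTnCL + dCaM + dSRB
  Vmyo <- p[["Vmyo"]]; Vsr <- p[["Vsr"]]; Vsl <- p[["Vsl"]]
  Vjunc <- p[["Vjunc"]]; Vls <- p[["Vls"]]
  dSLLj <- p[["konsll"]] * Caj * (p[["BmaxSLLj"]] * Vmyo / Vjunc - SLLj) -
    p[["koffsll"]] * SLLj
  dSLHj <- p[["konslh"]] * Caj * (p[["BmaxSLHj"]] * Vmyo / Vjunc - SLHj) -
    p[["koffslh"]] * SLHj
  dSLLsl <- p[["konsll"]] * Casl * (p[["BmaxSLL"]] * Vmyo / Vsl - SLLsl) -
    p[["koffsll"]] * SLLsl
  dSLHsl <- p[["konslh"]] * Casl * (p[["BmaxSLH"]] * Vmyo / Vsl - SLHsl) -
    p[["koffslh"]] * SLHsl
  JCaBj <- dSLLj + dSLHj
  JCaBsl <- dSLLsl + dSLHsl
  JCsqn <- p[["koncsqn"]] * Casr * (p[["Bmaxcsqn"]] - Csqn) -
    p[["koffcsqn"]] * Csqn

  convj <- p[["Cmem"]] / (2 * .Frdy * Vjunc)
  convsl <- p[["Cmem"]] / (2 * .Frdy * Vsl)
  convNa <- p[["Cmem"]] / (.Frdy * Vmyo)
  Istim <- .stim_current(t, p)

  lys_j <- if (lysosome)
    Jlsup * Vls / Vjunc + p[["Jlsj"]] * (Cals - Caj) / Vjunc else 0
  lys_i <- if (lysosome)
    Jlsrel * Vls / Vmyo + p[["Jlsi"]] * (Cals - Cai) / Vmyo else 0
  dCals <- if (lysosome)
    p[["Jlsj"]] * (Caj - Cals) / Vls - Jlsup +
      p[["Jlsi"]] * (Cai - Cals) / Vls - Jlsrel else 0

  ydot <- c(
    V = -(ICaL + Ito + IKr + Isus + IK1 + INCX + INaK + ICab + INab + Istim),
    d = (dss - d) / taud,
    f = (fss - f) / tauf,
    fcab = dfcab,
    xto = (xtoss - xto) / tauxto,
    yto = (ytoss - yto) / tauyto,
    xkr = (xkrss - xkr) / tauxkr,
    RyR_R = drR, RyR_O = drO, RyR_I = drI,
    Caj = p[["Jjsl"]] * (Casl - Caj) / Vjunc - ICaL * convj - JCaBj +
      JRyR * Vsr / Vjunc + Jleak * Vmyo / Vjunc + lys_j,
    Casl = p[["Jjsl"]] * (Caj - Casl) / Vsl +
      p[["Jsli"]] * (Cai - Casl) / Vsl - JCaBsl +
      2 * convsl * INCX - convsl * ICab,
    Cai = p[["Jsli"]] * (Casl - Cai) / Vmyo - JSERCA - JCaBi + lys_i,
    Casr = JSERCA * Vmyo / Vsr - JRyR - Jleak * Vmyo / Vsr - JCsqn,
    Cals = dCals,
    Nai = -convNa * (INab + 3 * INCX + 3 * INaK),
    TnCL = dTnCL, CaM = dCaM, SRB = dSRB,
    SLLj = dSLLj, SLHj = dSLHj, SLLsl = dSLLsl, SLHsl = dSLHsl,
    Csqn = JCsqn
  )
  list(ydot = ydot,
       out = c(J_SERCA = JSERCA, J_RyR = JRyR, J_ls_up = Jlsup,
               J_ls_rel = Jlsrel, PO = PO, I_NCX = INCX, I_stim = Istim))
}

## rectangular stimulus defined by the pacing-segment parameters
.stim_current <- function(t, p) {
  T1 <- p[["n1"]] * p[["p1"]]
  if (t < T1) phase <- t %% p[["p1"]]
  else if (t < T1 + p[["n2"]] * p[["p2"]]) phase <- (t - T1) %% p[["p2"]]
  else return(0)
  if (phase < p[["stim_dur"]]) -p[["stim_amp"]] else 0
}

#' Evaluate the model right-hand side
#'
#' Computes the time derivative of the full state vector (and the reported
#' fluxes) at one instant.  This is the reference R statement of the model
#' equations; the compiled integrator path evaluates the identical
#' expressions in C.
#'
#' @param state named 24-element state vector (see [initial_state()]).
#' @param parms flat solver parameter vector from [solver_parms()].
#' @param t time (ms) within the pacing protocol; governs the stimulus.
#' @param lysosome logical; `FALSE` evaluates the baseline model without a
#'   lysosomal compartment (all lysosomal terms structurally absent).
#' @return List with `derivatives` (named, mM/ms etc.) and `fluxes`
#'   (J_SERCA, J_RyR, J_ls_up, J_ls_rel, PO, I_NCX, I_stim).
#' @export
compute_rhs <- function(state, parms, t = 0, lysosome = TRUE) {
  if (length(state) != 24)
    stop("state must have 24 components")
  bad <- names(state)[!is.finite(state)]
  if (is.null(names(state))) bad <- which(!is.finite(state))
  if (length(bad))
    stop("non-finite state component(s): ", paste(bad, collapse = ", "))
  badp <- names(parms)[!is.finite(parms)]
  if (length(badp))
    stop("non-finite parameter(s): ", paste(badp, collapse = ", "))
  res <- .rhs_core(t, state, parms, lysosome = lysosome)
  list(derivatives = res$ydot, fluxes = res$out)
}
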