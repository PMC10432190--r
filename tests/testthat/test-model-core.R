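test_that("compiled and reference right-hand sides agree to machine precision", {
  p <- solver_parms(lyso = lysosome_params(naadp = 15))
  set.seed(100)
  for (i in 1:100) {
    y <- random_state()
    r <- compute_rhs(y, p, t = runif(1, 0, 900))
    dc <- deSolve::DLLfunc(func = "lysoca_derivs", times = 0.5, y = y,
                           parms = p, dllname = "lysoca",
                           initfunc = "lysoca_initmod", nout = 7)
    ## compare at t = 0.5 (stimulus on) separately below; here stim-free
    r2 <- compute_rhs(y, p, t = 0.5)
    rel <- abs(dc$dy - r2$derivatives) /
      pmax(abs(r2$derivatives), 1e-30)
    expect_lt(max(rel[abs(r2$derivatives) > 1e-14]), 1e-12)
  }
})

test_that("derivatives decompose into independently evaluated flux terms", {
  ## the lysosome-coupled calcium derivatives are re-assembled term by term
  ## from the module-level flux functions and compared to the full RHS
  cp <- cell_params()
  lp <- lysosome_params(naadp = 15)
  p <- solver_parms(cell = cp, lyso = lp)
  set.seed(101)
  for (i in 1:100) {
    y <- random_state()
    full <- compute_rhs(y, p, t = 500)
    po <- tpc2_open_probability(15, lp)
    up <- uptake_flux(y[["Cals"]], y[["Caj"]], po, lp)
    rel <- release_flux(y[["Cals"]], y[["Cai"]], po, lp)
    expect_equal(full$fluxes[["J_ls_up"]], up, tolerance = 1e-12)
    expect_equal(full$fluxes[["J_ls_rel"]], rel, tolerance = 1e-12)
    ## lysosomal calcium balance exactly as printed
    dls <- lp$J_ls_j * (y[["Caj"]] - y[["Cals"]]) / lp$V_ls - up +
      lp$J_ls_i * (y[["Cai"]] - y[["Cals"]]) / lp$V_ls - rel
    expect_equal(full$derivatives[["Cals"]], dls, tolerance = 1e-12)
    ## SERCA flux from its closed form
    fw <- (y[["Cai"]] / cp$Kmf)^cp$hillserca
    rv <- (y[["Casr"]] / cp$Kmr)^cp$hillserca
    expect_equal(full$fluxes[["J_SERCA"]],
                 cp$Vmax_serca * (fw - rv) / (1 + fw + rv),
                 tolerance = 1e-12)
    ## RyR release flux from state occupancy
    expect_equal(full$fluxes[["J_RyR"]],
                 cp$ks * y[["RyR_O"]] * (y[["Casr"]] - y[["Caj"]]),
                 tolerance = 1e-12)
  }
})

test_that("lysosomal exchange cancels under volume weighting in the full RHS", {
  p <- solver_parms(lyso = lysosome_params(naadp = 15))
  set.seed(102)
  for (i in 1:25) {
    y <- random_state()
    d1 <- compute_rhs(y, p, t = 500)$derivatives
    p0 <- p
    p0[c("jclc", "jtpc", "jclcleak", "jtpcleak", "Jlsj", "Jlsi")] <- 0
    d0 <- compute_rhs(y, p0, t = 500)$derivatives
    lys <- d1 - d0   # pure lysosome-exchange contribution
    total <- lys[["Cals"]] * p[["Vls"]] + lys[["Caj"]] * p[["Vjunc"]] +
      lys[["Cai"]] * p[["Vmyo"]]
    scale <- max(abs(lys[["Cals"]] * p[["Vls"]]), 1e-12)
    expect_lt(abs(total) / scale, 1e-10)
  }
})

test_that("equal concentrations silence the lysosomal derivative", {
  p <- solver_parms()
  y <- initial_state()
  y[c("Caj", "Casl", "Cai", "Cals")] <- 2e-4
  ## isolate lysosomal terms: all other processes switched off
  p[c("PCa", "gto", "gkr", "gsus", "gk1", "IbarNCX", "gcab", "ibarnak",
      "gnab", "Vmax_serca", "ks", "kleak", "Jjsl", "Jsli",
      "konTnC", "koffTnC", "konCaM", "koffCaM", "konSRB", "koffSRB",
      "konsll", "koffsll", "konslh", "koffslh", "koncsqn", "koffcsqn")] <- 0
  d <- compute_rhs(y, p, t = 500)$derivatives
  expect_equal(d[["Cals"]], 0, tolerance = 1e-18)
})

test_that("invalid states and parameters are rejected by name", {
  p <- solver_parms()
  y <- initial_state()
  y["Casr"] <- NaN
  expect_error(compute_rhs(y, p), "Casr")
  y2 <- initial_state()
  p2 <- p; p2[["Kmf"]] <- Inf
  expect_error(compute_rhs(y2, p2), "Kmf")
  expect_error(compute_rhs(y2[1:5], p), "24")
})

test_that("isoprenaline scalings match the maximal-phosphorylation magnitudes", {
  s0 <- apply_iso(0)
  expect_equal(s0$ltcc, 1)
  expect_equal(s0$ryr, 1)
  expect_equal(s0$serca_kmf, 1)
  s1 <- apply_iso(100)
  expect_equal(s1$ltcc, 1.56)   # 56% increase in L-type availability
  expect_equal(s1$ryr, 2)       # twofold RyR open probability under PKA
  expect_equal(s1$serca_kmf, 0.45)  # 55% decrease of forward-mode Km
  expect_error(apply_iso(50), "unsupported")
  expect_error(apply_iso(-1), "unsupported")
})
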