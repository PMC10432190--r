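test_that("open-probability law reproduces its calibration pins", {
  lp <- lysosome_params()
  ## value at 15 nM NAADP and the global maximum, to printed precision
  expect_equal(tpc2_open_probability(15, lp), 0.0134, tolerance = 5e-4)
  expect_equal(tpc2_open_probability(lp$PO_mean, lp), lp$PO_max)
  expect_equal(lp$PO_max, 0.016)
  ## maximum over a dense concentration grid is attained at PO_mean
  grid <- 10^seq(-2, 4, by = 1e-3)
  po <- tpc2_open_probability(grid, lp)
  expect_lt(max(po) - lp$PO_max, 1e-9)
  expect_equal(grid[which.max(po)], lp$PO_mean, tolerance = 1e-2)
})

test_that("open probability is log-symmetric and unimodal", {
  lp <- lysosome_params()
  for (k in c(1.3, 2, 7, 40)) {
    expect_equal(tpc2_open_probability(lp$PO_mean * k, lp),
                 tpc2_open_probability(lp$PO_mean / k, lp), tolerance = 1e-12)
  }
  ## monotone decreasing away from the peak on both sides
  up <- tpc2_open_probability(lp$PO_mean * 10^seq(0, 3, by = 0.1), lp)
  dn <- tpc2_open_probability(lp$PO_mean / 10^seq(0, 3, by = 0.1), lp)
  expect_true(all(diff(up) < 0))
  expect_true(all(diff(dn) < 0))
  expect_error(tpc2_open_probability(0), "positive")
  expect_error(tpc2_open_probability(-3), "positive")
})

test_that("uptake and release fluxes follow the two-term law", {
  lp <- lysosome_params(j_clc_leak = 0.001)
  ## zero gradient
  expect_equal(uptake_flux(0.3, 0.3, 0.01, lp), 0)
  expect_equal(release_flux(0.2, 0.2, 0.01, lp), 0)
  ## leak-only term at PO = 0
  expect_equal(uptake_flux(0.5, 0.01, 0, lp), 0.001 * 0.49)
  ## random inputs match an independently assembled expression
  set.seed(11)
  for (i in 1:50) {
    cls <- runif(1, 1e-4, 1); cj <- runif(1, 1e-4, 0.1)
    ci <- runif(1, 1e-5, 0.01); po <- runif(1, 0, 0.016)
    expect_equal(uptake_flux(cls, cj, po, lp),
                 lp$j_clc * po * (cls - cj) + lp$j_clc_leak * (cls - cj))
    expect_equal(release_flux(cls, ci, po, lp),
                 lp$j_tpc * po * (cls - ci) + lp$j_tpc_leak * (cls - ci))
  }
})

test_that("fluxes are odd in their concentration gradient", {
  lp <- lysosome_params()
  set.seed(4)
  for (i in 1:20) {
    a <- runif(1, 1e-4, 0.5); b <- runif(1, 1e-4, 0.5); po <- runif(1, 0, 0.016)
    expect_equal(uptake_flux(a, b, po, lp), -uptake_flux(b, a, po, lp))
    expect_equal(release_flux(a, b, po, lp), -release_flux(b, a, po, lp))
  }
})

test_that("intervention flags force the corresponding flux to zero", {
  lp <- lysosome_params(release_blocked = TRUE)
  expect_equal(release_flux(0.7, 1e-4, 0.016, lp), 0)
  lp2 <- lysosome_params(uptake_blocked = TRUE)
  expect_equal(uptake_flux(0.7, 1e-4, 0.016, lp2), 0)
})

test_that("lysosomal coupling terms conserve mass under volume weighting", {
  cp <- cell_params()
  lp <- lysosome_params(naadp = 15)
  set.seed(2)
  for (i in 1:20) {
    st <- c(Cals = runif(1, 1e-4, 0.5), Caj = runif(1, 1e-4, 0.05),
            Cai = runif(1, 1e-5, 0.01))
    cpl <- lysosome_coupling(st, lp, V_j = cp$Vjunc, V_i = cp$Vmyo)
    total <- cpl$dC_ls * lp$V_ls + cpl$dC_j * cp$Vjunc + cpl$dC_i * cp$Vmyo
    expect_equal(total, 0, tolerance = 1e-15)
  }
  ## all-zero lysosomal parameters give zero contributions
  lp0 <- lysosome_params(j_clc = 0, j_tpc = 0, j_clc_leak = 0,
                         j_tpc_leak = 0, J_ls_j = 0, J_ls_i = 0)
  cpl0 <- lysosome_coupling(c(Cals = 0.2, Caj = 1e-3, Cai = 1e-4), lp0)
  expect_equal(cpl0$dC_ls, 0)
  expect_equal(cpl0$dC_j, 0)
  expect_equal(cpl0$dC_i, 0)
})
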