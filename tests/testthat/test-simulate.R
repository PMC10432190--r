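test_that("an unstimulated cell relaxes to quiescence", {
  pr <- make_protocol("CTRL", n_beats = 5)
  cell <- cell_params(stim_amp = 0)
  sim <- simulate_cell(pr, cell = cell)
  expect_false(sim$failed)
  d <- compute_rhs(sim$final_state, sim$parms, t = 4999)$derivatives
  ## scale-aware derivative norm: concentrations move by < 0.01%/s
  rel <- abs(d) / pmax(abs(sim$final_state), 1e-6)
  expect_lt(max(rel), 1e-7 * 1000)
})

test_that("pacing reaches a steady limit cycle within 150 beats", {
  sim <- simulate_cell(make_protocol("CTRL"))
  expect_false(sim$failed)
  expect_lt(steady_state_delta(sim), 1e-3)
  ## gating variables stay in [0,1], concentrations positive
  tr <- sim$trace
  gates <- tr[, c("d", "f", "fcab", "xto", "yto", "xkr")]
  expect_true(all(gates >= -1e-6 & gates <= 1 + 1e-6))
  expect_true(all(tr[, c("Caj", "Casl", "Cai", "Casr", "Cals")] > 0))
  ## RyR occupancies nonnegative, summing to at most 1 (RI is complement)
  ryr <- tr[, c("RyR_R", "RyR_O", "RyR_I")]
  expect_true(all(ryr > -1e-8))
  expect_true(all(rowSums(ryr) < 1 + 1e-8))
})

test_that("solution matches a reference solve at tighter tolerance", {
  pr <- make_protocol("CTRL", n_beats = 12)
  sim <- simulate_cell(pr)
  ref <- simulate_cell(pr, rtol = 1e-8, atol = 1e-11)
  lb <- last_beat(sim)$Cai
  lr <- last_beat(ref)$Cai
  expect_equal(length(lb), length(lr))
  expect_lt(max(abs(lb - lr) / pmax(abs(lr), 1e-12)), 0.005)
})

test_that("total calcium is conserved when sarcolemmal fluxes are disabled", {
  cell <- cell_params(PCa = 0, IbarNCX = 0, gcab = 0)
  pr <- make_protocol("CTRL", n_beats = 12)   # 12 s paced, no Ca crosses membrane
  sim <- simulate_cell(pr, cell = cell, record_beats = 12)
  expect_false(sim$failed)
  p <- sim$parms
  tr <- sim$trace
  total <- (tr$Caj + tr$SLLj + tr$SLHj) * p[["Vjunc"]] +
    (tr$Casl + tr$SLLsl + tr$SLHsl) * p[["Vsl"]] +
    (tr$Cai + tr$TnCL + tr$CaM + tr$SRB) * p[["Vmyo"]] +
    (tr$Casr + tr$Csqn) * p[["Vsr"]] +
    tr$Cals * p[["Vls"]]
  expect_lt(max(abs(total - total[1])) / total[1], 1e-5)
})

test_that("zeroed lysosome reproduces the baseline model without the compartment", {
  ## C path with all lysosomal rates at zero vs the structurally reduced
  ## R implementation (no lysosomal compartment at all)
  lyso0 <- lysosome_params(j_clc = 0, j_tpc = 0, j_clc_leak = 0,
                           j_tpc_leak = 0, J_ls_j = 0, J_ls_i = 0)
  pr <- make_protocol("CTRL", n_beats = 4)
  with_ls <- simulate_cell(pr, lyso = lyso0, record_beats = 4)
  without <- simulate_cell(pr, lyso = lyso0, record_beats = 4,
                           engine = "R", lysosome = FALSE)
  expect_false(with_ls$failed || without$failed)
  for (q in c("Caj", "Cai", "Casr")) {
    a <- with_ls$trace[[q]]; b <- without$trace[[q]]
    expect_lt(max(abs(a - b) / pmax(abs(b), 1e-12)), 1e-3)
  }
})

test_that("knockout forces the release flux to zero over the whole trace", {
  sim <- simulate_cell(make_protocol("NAADP_AM", ko = TRUE, n_beats = 20))
  expect_true(all(sim$trace$J_ls_rel == 0))
  expect_false(all(sim$trace$J_ls_up == 0))
  ub <- simulate_cell(make_protocol("NAADP_AM", uptake_block = TRUE,
                                    n_beats = 20))
  expect_true(all(ub$trace$J_ls_up == 0))
})

test_that("integration failure is flagged, not fatal", {
  ## absurd parameters provoke solver failure
  cell <- cell_params(konsll = 1e12, Vmax_serca = 1e9)
  sim <- suppressWarnings(simulate_cell(make_protocol("CTRL", n_beats = 3),
                                        cell = cell))
  expect_true(sim$failed)
  expect_true(is.character(sim$failure_reason))
})
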