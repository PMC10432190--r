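test_that("Latin hypercube sampling stratifies every factor", {
  spec <- population_spec(n_models = 4, seed = 5)
  m <- sample_population(spec)
  expect_equal(dim(m), c(4, 10))
  expect_true(all(m >= 0.5 & m <= 2))
  ## exactly one draw per quartile of [0.5, 2] in every column
  qs <- seq(0.5, 2, length.out = 5)
  for (j in 1:10) {
    bins <- cut(m[, j], qs, include.lowest = TRUE)
    expect_equal(as.vector(table(bins)), rep(1L, 4))
  }
})

test_that("sampling is reproducible from the seed", {
  s <- population_spec(n_models = 25, seed = 99)
  expect_identical(sample_population(s), sample_population(s))
  s2 <- population_spec(n_models = 25, seed = 100)
  expect_false(identical(sample_population(s), sample_population(s2)))
  expect_error(population_spec(n_models = 10), "seed")
})

test_that("large samples are uniform by Kolmogorov-Smirnov", {
  m <- sample_population(population_spec(n_models = 1000, seed = 3))
  ## one-sample KS distance against Uniform(0.5, 2), n = 1000 5% critical
  crit <- 1.358 / sqrt(1000)
  for (j in 1:10) {
    d <- suppressWarnings(
      stats::ks.test(m[, j], "punif", 0.5, 2)$statistic)
    expect_lt(as.numeric(d), crit)
  }
})

test_that("the NCX study multiplier applies on top of the sampled factor", {
  sc <- scaling_factors(rep(1.5, 10), ncx_multiplier = 3)
  expect_equal(sc[["I_NCX"]], 4.5)
  expect_equal(sc[["I_CaL"]], 1.5)
  expect_error(scaling_factors(1:5), "10")
})

test_that("calibration accepts quiet models and logs rejections by protocol", {
  ## a 3-model toy population: default scalings (quiet) plus one extreme
  ## proarrhythmic member built by construction
  pop <- sample_population(population_spec(n_models = 3, seed = 8))
  pop[1, ] <- 1                               # reference cell: accepted
  pop[2, ] <- c(2, 2, 1, 2, 1, 1, 0.5, 2, 0.5, 0.5)  # overload-prone
  cal <- calibrate_population(pop, keep_sims = TRUE)
  expect_true(1 %in% cal$accepted)
  expect_true(all(cal$accepted %in% seq_len(3)))
  expect_equal(nrow(cal$table), 3)
  rej <- cal$table[!cal$table$accepted, ]
  if (nrow(rej))
    expect_true(all(rej$rejection_reason %in%
                      c("CTRL", "NAADP_AM", "ISO",
                        paste0("solver_failure:", c("CTRL", "NAADP_AM", "ISO")))))
  ## kept simulations are exactly those of accepted models
  expect_equal(length(cal$sims$CTRL), length(cal$accepted))
})

test_that("paired arms share scalings and differ only in the release block", {
  pop <- sample_population(population_spec(n_models = 2, seed = 21))
  pr <- make_protocol("NAADP_AM", n_beats = 15)
  pair <- run_paired(pop, pr, models = 1:2)
  expect_equal(names(pair$WT), names(pair$KO))
  for (id in names(pair$WT)) {
    wt <- pair$WT[[id]]; ko <- pair$KO[[id]]
    sc <- setdiff(names(wt$parms), "release_block")
    expect_identical(wt$parms[sc], ko$parms[sc])
    expect_equal(ko$parms[["release_block"]], 1)
    expect_equal(wt$parms[["release_block"]], 0)
    expect_true(all(ko$trace$J_ls_rel == 0))
  }
})
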