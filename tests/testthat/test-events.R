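test_that("clean paced transients yield no events", {
  tr <- synth_paced_trace()
  ev <- detect_spontaneous_release(tr$time, tr$ci, tr$stim)
  expect_equal(nrow(ev), 0)
  expect_false(flag_ambiguous(tr$time, tr$ci, tr$stim))
})

test_that("an injected diastolic bump is detected exactly once at its time", {
  tr <- synth_paced_trace()
  tr <- inject_bump(tr, t0 = 2600, height = 0.5 * tr$amp)
  ev <- detect_spontaneous_release(tr$time, tr$ci, tr$stim)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$beat, 3)
  expect_lt(abs(ev$time - 2630), 15)   # peak of the half-cosine bump
  expect_true(ev$diastolic)
  ## the event magnitude reflects the injected prominence
  expect_equal(ev$magnitude, 0.5 * tr$amp, tolerance = 0.05)
})

test_that("multiple injected events are returned chronologically", {
  tr <- synth_paced_trace(n_beats = 6)
  for (t0 in c(1550, 3600, 4700))
    tr <- inject_bump(tr, t0 = t0, height = 0.4 * tr$amp)
  ev <- detect_spontaneous_release(tr$time, tr$ci, tr$stim)
  expect_equal(nrow(ev), 3)
  expect_true(all(diff(ev$time) > 0))
  expect_equal(ev$beat, c(2, 4, 5))
})

test_that("detection is invariant to time translation and amplitude rescaling", {
  tr <- synth_paced_trace()
  tr <- inject_bump(tr, t0 = 2600, height = 0.45 * tr$amp)
  ev0 <- detect_spontaneous_release(tr$time, tr$ci, tr$stim)
  ## shift the clock
  ev1 <- detect_spontaneous_release(tr$time + 5e4, tr$ci, tr$stim + 5e4)
  expect_equal(ev1$time - 5e4, ev0$time)
  ## rescale the whole trace (threshold is relative)
  ev2 <- detect_spontaneous_release(tr$time, 3.7 * tr$ci, tr$stim)
  expect_equal(ev2$time, ev0$time)
  expect_equal(nrow(ev2), nrow(ev0))
})

test_that("sub-threshold relaxation ripple flags ambiguity, real events do not", {
  ## 4% ripple in the relaxation phase: ambiguous
  tr <- synth_paced_trace()
  tr <- inject_bump(tr, t0 = 2450, height = 0.04 * tr$amp, width = 50)
  expect_equal(nrow(detect_spontaneous_release(tr$time, tr$ci, tr$stim)), 0)
  expect_true(flag_ambiguous(tr$time, tr$ci, tr$stim))
  ## a full-blown diastolic release is countable, not ambiguous
  tr2 <- synth_paced_trace()
  tr2 <- inject_bump(tr2, t0 = 2600, height = 0.8 * tr2$amp)
  expect_gt(nrow(detect_spontaneous_release(tr2$time, tr2$ci, tr2$stim)), 0)
  expect_false(flag_ambiguous(tr2$time, tr2$ci, tr2$stim))
})

test_that("short traces are rejected", {
  tr <- synth_paced_trace(n_beats = 1)
  expect_error(detect_spontaneous_release(tr$time[1:5], tr$ci[1:5], tr$stim),
               "shorter")
})

test_that("delayed afterdepolarizations are detected from the voltage trace", {
  tr <- synth_ap_trace()
  expect_equal(nrow(detect_dads(tr$time, tr$v, tr$stim)), 0)
  ## a 5 mV diastolic hump is one DAD with its amplitude reported
  tr2 <- inject_v_bump(tr, t0 = 1600, height = 5)
  dd <- detect_dads(tr2$time, tr2$v, tr2$stim)
  expect_equal(nrow(dd), 1)
  expect_equal(dd$magnitude, 5, tolerance = 0.05)
  expect_equal(dd$beat, 2)
  ## sub-threshold (0.5 mV) humps are ignored at the 1 mV default
  tr3 <- inject_v_bump(tr, t0 = 1600, height = 0.5)
  expect_equal(nrow(detect_dads(tr3$time, tr3$v, tr3$stim)), 0)
})

test_that("reverted fraction follows its flux-integral definition", {
  time <- seq(0, 1999, by = 1)
  stim <- c(0, 1000)
  ci <- rep(1e-4, length(time))
  ## paced transient so beat segmentation works
  for (s in stim) {
    idx <- which(time >= s)
    ci[idx] <- ci[idx] + 4e-4 * exp(-(time[idx] - s) / 60)
  }
  ## strictly positive uptake (all outgoing lysosomal flux junction-ward)
  s1 <- synth_sim(time, ci, J_ls_up = rep(2e-5, length(time)),
                  J_ls_rel = rep(0, length(time)), stim_times = stim)
  expect_equal(reverted_fraction(s1), 1.0)
  ## all outgoing flux through release, uptake strictly loading: near 0
  s2 <- synth_sim(time, ci, J_ls_up = rep(-2e-5, length(time)),
                  J_ls_rel = rep(3e-5, length(time)), stim_times = stim)
  expect_equal(reverted_fraction(s2), 0)
  ## equal split
  s3 <- synth_sim(time, ci, J_ls_up = rep(1e-5, length(time)),
                  J_ls_rel = rep(1e-5, length(time)), stim_times = stim)
  expect_equal(reverted_fraction(s3), 0.5, tolerance = 1e-6)
})
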