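## Synthetic calcium / voltage traces with known ground truth, used by the
## event-detector tests.  All fixtures are generated in code.

## A train of idealised paced transients: instant upstroke at each stimulus,
## exponential decay back to the diastolic level.
synth_paced_trace <- function(n_beats = 5, period = 1000, dt = 1,
                              dia = 1e-4, amp = 4e-4, tau = 60) {
  stim <- period * (seq_len(n_beats) - 1)
  time <- seq(0, n_beats * period - dt, by = dt)
  ci <- rep(dia, length(time))
  for (s in stim) {
    idx <- which(time >= s)
    ci[idx] <- ci[idx] + amp * exp(-(time[idx] - s) / tau)
  }
  list(time = time, ci = ci, stim = stim, amp = amp, dia = dia)
}

## inject a smooth diastolic bump (half-cosine) of given height at t0
inject_bump <- function(tr, t0, height, width = 60) {
  idx <- which(tr$time >= t0 & tr$time <= t0 + width)
  tr$ci[idx] <- tr$ci[idx] +
    height * sin(pi * (tr$time[idx] - t0) / width)^2
  tr
}

## idealised action-potential train for the DAD detector
synth_ap_trace <- function(n_beats = 4, period = 1000, dt = 1,
                           v_rest = -80, v_peak = 25, apd = 40) {
  stim <- period * (seq_len(n_beats) - 1)
  time <- seq(0, n_beats * period - dt, by = dt)
  v <- rep(v_rest, length(time))
  for (s in stim) {
    idx <- which(time >= s & time < s + apd)
    v[idx] <- v_rest + (v_peak - v_rest) * exp(-(time[idx] - s) / (apd / 3))
  }
  list(time = time, v = v, stim = stim)
}

inject_v_bump <- function(tr, t0, height, width = 80) {
  idx <- which(tr$time >= t0 & tr$time <= t0 + width)
  tr$v[idx] <- tr$v[idx] + height * sin(pi * (tr$time[idx] - t0) / width)^2
  tr
}

## minimal simulation-like object for flux-integral helpers
synth_sim <- function(time, Cai, J_ls_up, J_ls_rel, stim_times, Vls = 2.2) {
  structure(list(
    trace = data.frame(time = time, Cai = Cai,
                       J_ls_up = J_ls_up, J_ls_rel = J_ls_rel),
    stim_times = stim_times,
    parms = c(Vls = Vls),
    failed = FALSE
  ), class = "lysoca_sim")
}

## random physiological state for right-hand-side oracle tests
random_state <- function() {
  y <- initial_state()
  y["V"] <- runif(1, -85, 30)
  y["d"] <- runif(1); y["f"] <- runif(1); y["fcab"] <- runif(1, 0, 0.5)
  y["xto"] <- runif(1); y["yto"] <- runif(1); y["xkr"] <- runif(1)
  r <- runif(3, 0, 0.3); y["RyR_R"] <- 1 - sum(r)
  y["RyR_O"] <- r[1]; y["RyR_I"] <- r[2]
  y["Caj"] <- 10^runif(1, -4.2, -1.5)
  y["Casl"] <- 10^runif(1, -4.2, -2.5)
  y["Cai"] <- 10^runif(1, -4.5, -3)
  y["Casr"] <- runif(1, 0.2, 1.1)
  y["Cals"] <- 10^runif(1, -4, -1.5)
  y["Nai"] <- runif(1, 8, 16)
  y["TnCL"] <- runif(1, 0, 0.06)
  y["CaM"] <- runif(1, 0, 0.02)
  y["SRB"] <- runif(1, 0, 0.015)
  y["SLLj"] <- runif(1, 0, 0.4); y["SLHj"] <- runif(1, 0, 0.15)
  y["SLLsl"] <- runif(1, 0, 0.8); y["SLHsl"] <- runif(1, 0, 0.3)
  y["Csqn"] <- runif(1, 0.5, 2.2)
  y
}
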