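---
title: "Modelling lysosomal calcium handling in a mouse ventricular myocyte"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling lysosomal calcium handling in a mouse ventricular myocyte}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(lysoca)
```

## The model

`lysoca` implements an ordinary-differential-equation model of the mouse
ventricular cardiomyocyte action potential and calcium cycle, extended with
a lysosomal calcium compartment, and a population-of-models pipeline for
studying how lysosomal calcium release promotes spontaneous calcium release
(SCR) and delayed afterdepolarizations (DADs) under calcium overload.

The electrophysiology follows the classic Shannon-style compartmental
architecture: a junctional cleft where L-type channels face the ryanodine
receptors (RyRs), a subsarcolemmal rim sensed by the Na/Ca exchanger (NCX),
the bulk cytosol, and the sarcoplasmic reticulum (SR).  Calcium-induced
calcium release is carried by a four-state RyR whose opening and
inactivation rates are modulated by SR luminal calcium; reuptake is a
forward/reverse SERCA pump; explicit buffers (troponin C, calmodulin,
SR-membrane sites, low/high-affinity sarcolemmal sites, calsequestrin) are
integrated as state variables so that total calcium is conserved exactly.
Repolarisation is mouse-like (large transient outward current, a sustained
K⁺ component, inward rectifier), giving brief action potentials and
SR-dominated calcium removal.  This is a reduced-order baseline: it keeps
the compartments, fluxes and gating structure of the published mouse
ventricular models, but it omits the dynamic PKA and CaMKII signalling
networks and the fast sodium current (the stimulus depolarises the membrane
directly).  Consequences of these reductions are discussed under
*Limitations*.

### The lysosomal compartment

The new compartment exchanges calcium through four pathways:

* **CLC uptake** between the junctional cleft and the lysosome:
  `J_ls,up = (j_clc · PO + j_clc,leak) (C_ls − C_j)`, positive for
  lysosome→junction flow.  During the junctional calcium spike of each beat
  `C_j > C_ls` and the lysosome loads; between beats the gradient reverses.
* **TPC2 release** into the cytosol:
  `J_ls,rel = (j_tpc · PO + j_tpc,leak) (C_ls − C_i)`.
* Two small passive diffusion legs (`J_ls,j`, `J_ls,i`) to the junction
  and the cytosol.

A single open probability gates both channels and follows a Gaussian
function of log₁₀ NAADP concentration with its two experimental pins built
in: the maximum is `PO_max = 0.016`, and `PO(15 nM) = 0.0134`.  With the
calibrated width `PO_sd = 0.55` (log₁₀ units) this fixes
`PO_mean ≈ 31.9 nM`; the base of the logarithm is a pure parameterisation
convention absorbed by `PO_sd`.  Endogenous NAADP is 1 nM (CTRL); 15 nM
emulates NAADP-AM or the NAADP rise under isoprenaline.

Functionally the compartment is a *fast transport pathway*: it picks
calcium up where it is momentarily abundant (the junctional spike) and
releases it into the cytosol, bypassing the slower junctional→
subsarcolemmal→cytosolic diffusion chain and, importantly, bypassing the
NCX's territory, so a larger fraction of released calcium is retained and
re-pumped into the SR.  Raising NAADP therefore raises the cytosolic
transient, SERCA throughput, SR load and RyR open probability — the
mechanistic chain that makes lysosomal release proarrhythmic under
overload.  The TPC2 knockout (`release_block`) turns the lysosome into a
dead-end store: it still loads through the CLC during each spike and
returns most of that calcium to the junction (the *reverted* fraction
reported by `reverted_fraction()`).

### Beta-adrenergic stimulation

Isoprenaline (100 nM, binary protocol) is a static scaling set applied at
protocol start, reflecting maximal PKA phosphorylation of the targets the
experiments quantify: L-type availability ×1.56; a twofold increase of
per-beat L-type calcium influx, implemented as slowed calcium-dependent
inactivation (`iso_cdi`, calibrated to ≈0.41 on the CDI on-rate so the
influx doubling is met); RyR opening rate ×2; SERCA forward-mode
half-saturation ×0.45 (phospholamban relief — interpreted as an affinity,
not a maximal-rate, change); and a phospholemman-type increase of Na/K
pump sodium affinity (Km ×0.78).  No dynamic kinase network is modelled.

## Protocols and the population

`make_protocol()` builds the six study protocols declaratively (CTRL,
NAADP-AM, ISO, hypercalcemia 1.0→1.8 mM with ISO, and 10 Hz / 25 Hz
fast-to-slow pacing with ISO), each run for 150 beats at 1 Hz (overload
variants per their own schedules) so the system reaches its limit cycle;
biomarkers are evaluated on the final beat and events on the recorded
final beats (for fast pacing, the five slow beats after the transition).

Cell-to-cell variability is a Latin hypercube over ten maximal
conductances/fluxes (I_CaL, J_RyR, j_clc, j_tpc, both lysosomal leaks,
I_NCX, J_SERCA, I_to, I_Kr), uniform on 0.5–2×.  Models are accepted if
their wild-type configuration shows no spontaneous calcium release under
any baseline protocol (CTRL, NAADP-AM, ISO); at the default calibration
roughly half of a sampled population passes, bracketing the full study's
42%.

## Event detection and classification

Spontaneous release events are diastolic cytosolic-calcium upstrokes
outside the stimulated transient (after 90% decay) with topographic
prominence of at least θ = 10% of the last paced transient amplitude.
Relaxation-phase ripple between θ_low = 2% and θ in a trace with no
countable event anywhere marks the model *ambiguous* and excludes it from
incidence statistics; a trace containing a countable event is never
ambiguous, and ambiguity is judged on the wild-type arm (the paired
knockout arm of a borderline model legitimately carries sub-threshold
ripple).  DADs are diastolic membrane-potential humps of ≥1 mV prominence
after full repolarisation.  All thresholds are exposed as arguments.

Paired classification under an overload protocol labels each model
TPC-specific (events in WT, none in KO), other-proarrhythmic,
nonproarrhythmic, or excluded-ambiguous; `incidence()` and
`classify_models()` report arm-wise incidences and the TPC-specific count.

## Numerical choices

The right-hand side is written twice: a reference R implementation
(`compute_rhs()`) stating every term readably, and a compiled C mirror
used by the integrator; the test suite asserts their equality to 1e-12
relative on random states.  Integration uses lsoda with rtol 1e-6 /
atol 1e-9, restarted at every stimulus edge so discontinuities never sit
inside a solver step; recorded beats are sampled at 1 kHz.  Solver
failures flag the model and exclude it downstream rather than aborting a
batch.  The f-gate steady state is clamped at 1 (the classic fitted curve
slightly exceeds unity at rest).  Initial lysosomal calcium starts at a
moderate guess and is conditioned to its limit cycle with the rest of the
state during the 150 pre-beats.

## Problem sizes

Desk-scale runs use reduced populations: the package defaults are n = 140
(seeded) in both the acceptance test suite and `scripts/acceptance.R`, giving ≳40–60 accepted models — enough that the
population means of the normalized amplitude changes have standard errors
well inside the comparison tolerances, while a single 150-beat simulation
costs well under a second.  The full-scale study (n = 1000) is available
via `population_spec(n_models = 1000, seed)` or `--preset full` in the
command-line interface.

## What the generator emulates, and what it does not

The synthetic-population generator reproduces the *conditions* of the
study — pacing schedules, extracellular calcium, NAADP and ISO levels,
intervention flags, 0.5–2× Latin-hypercube variability — so that passing
tests demonstrate the mechanistic chain (lysosomal shuttle → SERCA → SR
load → RyR open probability → SCR/DADs) and its population statistics at
reduced scale.  It does not emulate: experimental photometry noise or
optical artefacts; beat-to-beat stochastic RyR gating (release is
deterministic whole-cell); spatial calcium waves; or inter-animal
variability beyond the ten scaled parameters.

## Known limitations

* **Fast pacing.** Without a fast sodium current the action potential is
  stimulus-driven and relatively long; at 10 Hz the model shows 2:1
  repolarisation alternans, so calcium accumulation during the fast
  segment is weaker than in the full mouse model and fast-pacing SCR
  incidences are far below the hypercalcemia ones.  The hypercalcemia
  overload pathway, which carries the quantitative targets, is unaffected.
* **Lysosomal lumen.** The aggregate lysosomal pool uses a volume and
  rate constants calibrated to whole-cell responses; luminal
  concentrations are intermediate between junctional and cytosolic
  levels rather than the very high lumenal values of single organelles,
  and pH/H⁺ coupling is out of scope.
* **Median-fold compression.** Accepted populations show a negative
  correlation between control transient amplitude and the relative
  isoprenaline response (small-amplitude members have more headroom below
  the luminal-gated RyR leak ceiling), so the fold change computed from
  population medians sits below the per-model median fold.  The
  mean-based relative changes are unaffected.
* **Static β-adrenergic map.** PKA targets switch instantaneously at
  protocol start; transient kinase dynamics and CaMKII feedback are not
  modelled.
* The knockout's NAADP response is calibrated to the small negative
  printed value (−3.5%), which sits in tension with treating the knockout
  transient as strictly unchanged; the package treats "unchanged" as
  |change| below a few per cent.

## A worked example

```{r example, eval = FALSE}
library(lysoca)

## one wild-type cell under NAADP-AM, steady state at 1 Hz
sim <- simulate_cell(make_protocol("NAADP_AM"))
biomarkers(sim)$amp_Cai

## reduced population study (a few minutes)
study <- run_study(n_models = 90, seed = 1, fastpace = FALSE,
                   uptake_block = FALSE)
study$targets
```
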