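---
title: "Model and methods: a spiking CBGT agent for decision tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: a spiking CBGT agent for decision tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

`cbgt` simulates goal-directed decision making with a spiking
cortico-basal ganglia-thalamic (CBGT) network acting as the agent inside a
configurable task environment. The agent maps a stimulus onto a choice and a
decision time; the environment presents stimuli, schedules rewards, and
delivers optogenetic or stop-signal perturbations. This vignette documents
the model equations, the trial state machine, the plasticity rule, the
synthetic default parameter set, and the numerical choices — i.e., what a
green test establishes and what it does not.

## Network composition

Six regions are modeled: cortex (excitatory `Cx` and inhibitory `CxI`),
striatum (`dSPN`, `iSPN`, fast-spiking interneurons `FSI`), external pallidum
(prototypical `GPeP` and arkypallidal `GPeA`), subthalamic nucleus (`STN`),
internal pallidum (`GPi`), and thalamus (`Th`). For an *n*-choice task every
population except the shared `FSI` and `CxI` is instantiated once per action
channel. Channels interact only through the shared populations and through
common-typed projections. The pallidostriatal (`GPeA` to SPN) pathways are
included only in the stop-signal network build.

Connectivity is declared in a seven-column pathway table (`src`, `dest`,
`receptor`, `type`, `con`, `eff`, `plastic`) and realized as independent
Bernoulli draws per ordered neuron pair (no self-connections) under a
per-pathway RNG stream derived from the build seed, so editing one pathway
never redraws the others. `type = "syn"` restricts a channelized-to-
channelized projection to matching channels; `type = "common"` connects all
channel pairs. When channels are added, the efficacy of every pathway
converging from channelized sources onto a shared (or common-typed) target is
divided by the channel count, keeping the expected summed drive onto shared
nuclei invariant — topology is not redrawn.

The shipped default table uses `con = 1` with correspondingly reduced
efficacies. This is a deliberate choice: at the small default population
sizes, binomial in-degree variance otherwise gives each realized network a
quenched left/right asymmetry large enough to dominate the trial-to-trial
noise, producing per-seed deterministic choices instead of chance-level
behavior. Full connectivity removes the quenched disorder while leaving the
Bernoulli machinery in place for user-supplied pathways (`newpathways`),
which may use any `con`.

## Membrane and synapse model

Neurons are conductance-based leaky integrate-and-fire point neurons
(forward Euler, `dt = 0.1` ms):

$$ C\,\dot V = \frac{C}{\tau_m}(V_{rest} - V) + I_{ext} - I_{syn} - I_{opto} $$

$$ I_{syn} = s_{A}(V - V_E) + s_{N}\,B(V)\,(V - V_E) + s_{G}(V - V_I),
\qquad B(V) = \frac{1}{1 + 0.28\,e^{-0.062 V}} $$

with $B(V)$ the standard 1 mM magnesium block of the NMDA conductance. Each
receptor gate decays exponentially (`Tau_AMPA` 2 ms, `Tau_GABA` 5 ms,
`Tau_NMDA` 100 ms) and is incremented by the pathway efficacy on each
presynaptic spike. A neuron reaching `V_thresh` at the start of a step spikes
in that step, is reset to `V_reset`, and is refractory for `refractory` ms.
The single-neuron f–I curve matches the closed-form LIF rate
$1/(t_{ref} + \tau_m \ln\frac{IR - V_{reset} + V_{rest}}{IR - V_{thresh} + V_{rest}})$
to within 2% at this step size (tested).

**Background drive.** Every neuron receives an external Gaussian-process
drive: per step, an instantaneous per-connection rate is drawn from a normal
distribution with the configured mean (`FreqExt_AMPA`) and unit variance on
the spikes/s scale, truncated at zero, and converted to a conductance
increment via the connection count and efficacy. The mean per-step event
intensity is `rate x n_connections x dt`. The defaults use a low
per-connection rate (0.3 sp/s) over 400 connections: because the unit
variance lives on the per-connection scale, this choice makes the membrane
noise several millivolts — large enough to smooth the population transfer
function and to make decision times genuinely stochastic. This is the main
lever that sets the model's behavioral variability.

## The trial state machine

* **Phase 0 (decision).** All cortical channels receive a ramping external
  frequency, `I_ramp(t) = I_ramp(t-dt) + 0.1 [I_target - I_ramp(t-dt)]`, with
  `I_target = maxstim x stimscale` on the per-connection rate scale. Cortical
  drive excites the striatum; dSPN activity suppresses `GPi`, which
  disinhibits `Th` while `Cx` excites it directly. The decision boundary is
  the first channel whose thalamic population rate, smoothed over a sliding
  5 ms window, exceeds `thalamic_threshold` (default 30 spikes/s). The 5 ms
  window resolves a 30 sp/s crossing at `dt = 0.1` ms without excessive lag;
  simultaneous crossings go to the higher rate, exact ties break uniformly at
  random. If no channel crosses within `choice_timeout` (1000 ms n-choice,
  300 ms stop-signal) the decision is recorded as `"none"`.
* **Phase 1 (consolidation).** On decided trials the selected channel's `Cx`
  is driven at `sustainedfraction` (default 0.7) of the phase-0 ramp maximum
  for the movement time — by default drawn from N(250, 1.5) ms, or fixed via
  `["constant", N]` — capped at the 300 ms phase-1 timeout. Timed-out trials
  receive no sustained drive. Reward is drawn at the end of the phase:
  a Bernoulli success with the scheduled probability delivers a magnitude
  from N(`reward_mu`, `reward_std`), truncated at zero (negative "reward
  sizes" are biologically unintended).
* **Phase 2 (reset).** No external input for `inter_trial_interval`
  (default 600 ms).

Before the first trial the network relaxes for 500 ms from random initial
potentials (uniform between rest and threshold); this resting period is not
part of any recorded trace.

## Reward schedules

The `conflict` tuple gives one reward probability per action. `volatility =
[lambda, mode]` places contingency switches every `lambda` trials exactly, or
at gaps drawn as `max(1, Poisson(lambda))` (a zero-trial gap would be an
unobservable switch). At each change point the tuple is permuted — a swap for
two actions and, as the natural generalization, a cyclic rotation for more.
`lambda` may be `NULL` (no switches) only for single-trial and stop-signal
runs; otherwise `0 < lambda < n_trials` is enforced. Trial indices are
0-based throughout.

## Dopamine and corticostriatal plasticity

Per action the agent keeps a Q-value (initially 0.5) updated by a delta
rule: `RPE = reward - Q[choice]`, `Q[choice] += q_alpha x RPE`. Q-values
never influence choice — selection depends solely on the corticostriatal
weights (tested: runs differing only in Q initialization are identical).

The RPE is released as a phasic dopamine impulse `C_scale x RPE` decaying
with `dpmn_tauDOP` (default 5 ms) on a zero baseline. Over the consolidation
window the plastic cortico-dSPN and cortico-iSPN weights of the **selected
channel only** change by

$$ \Delta w = \alpha_w \cdot e \cdot \int D(t)\,dt, \qquad
   e = k\,\frac{r_{Cx}}{1000}\,\frac{r_{SPN}}{1000} $$

where $e$ is an activity-dependent eligibility (product of the phase-1
pre- and postsynaptic population rates in kHz, scaled by
`dpmn_elig_scale`), and $\alpha_w$ is `dpmn_alphaw` (+39.5 for dSPN, -38.2
for iSPN): positive dopamine strengthens the direct pathway and weakens the
indirect pathway of the chosen action. Weights are clipped to
`[0, dpmn_wmax]` (0.08 / 0.06). The exact impulse/eligibility kinetics are a
documented modeling choice honoring the conventional constraints (parameter names,
sign conventions, selected-channel specificity, phase-1 timing); spike-level
three-factor STDP is out of scope.

Plastic rows in the pathway table carry the corticostriatal *weight* in
their `eff` column; `plastic_gain` maps weight onto the conductance scale of
the static efficacies. A small static NMDA floor (`eff = 1e-4`) runs in
parallel so that a fully depressed channel still decides — slowly — rather
than silencing the network.

## Stimulation

**Optogenetics.** The opsin current is
`I_opto = g_opto (V - V_ChR2)` for `g_opto >= 0` (channelrhodopsin-2,
`V_ChR2 = 0` mV) and `-g_opto (V - V_NpHR)` for `g_opto < 0` (halorhodopsin,
`V_NpHR = -400` mV). This piecewise form is implemented exactly as written; at
rest it is negative for positive conductances, so it couples into the
membrane equation with a minus sign — the documented choice that makes a
positive amplitude excitatory and a negative one inhibitory, with the current
vanishing exactly at each opsin's reversal potential.

**Stop signals.** A stop signal adds `stop_amplitude` to the AMPA background
frequency of its target population (typically `STN`, fast non-selective
pause, and `GPeA`, slower selective pallidostriatal brake) for its window.

Both protocol families share the six parameters amplitude, population,
onset (ms after phase-0 start), duration (ms, or a phase name covering
exactly that realized phase), probability, and channel. A fractional
probability selects `round(p x n_trials)` trials without replacement; a list
selects exactly those trials. Numeric durations live on the trial clock and
may span phase boundaries. Channel `"all"` targets every channel, `"any"`
one uniformly drawn channel per trial. Overlapping protocols sum. Applied
windows are recorded (`optogenetic_input`, `stop_input` in
`record_variables`) as interval tables.

## Default parameter set (synthetic)

The shipped JSON parameter files are a **synthetic, tuned parameter set**, calibrated so that (i) all nuclei fire stably and
distinguishably at baseline (cortex ~5 sp/s, SPNs ~1–2, FSI ~15, GPeP/GPi
tonic ~40–50, STN ~15, Th ~5–10), (ii) decisions complete within a few
hundred ms at the default `maxstim = 0.8`, and (iii) symmetric configurations
choose each action at chance. Background efficacies were fitted by per-
population bisection against those targets; the targets themselves follow
the qualitative firing-rate ordering of the basal ganglia literature. The
thalamus uses 80 neurons so that the 5 ms windowed rate estimate is fine
enough for a 30 sp/s boundary. None of these values claims equality with the
in-vivo literature values, and tests green under this parameter set establish
the *mechanisms* (boundary readout, phase timing, plasticity direction,
stop efficacy), not numeric agreement with any recorded physiological trace.

## Numerical choices and limitations

* Forward Euler at `dt = 0.1` ms; gates decay by exact exponential factors.
  Validated by the 2% f–I agreement.
* All randomness flows through R's RNG; a simulation is fully determined by
  its seed. `run_simulations(..., n_sims = k)` gives simulation *i* the seed
  `seed + i - 1` and seeds it inside the worker, so single-core and
  multi-core (forked) execution are bit-identical and ordering is
  submission order.
* Timed-out trials deliver no reward and trigger no Q or weight update
  (a deliberate, documented choice: an unexecuted action has no outcome to
  assign credit to).
* Phase-1 duration is capped at 300 ms; with the default N(250, 1.5)
  movement time the cap binds with negligible probability.
* The cortical model is deliberately simple (no topography, no layered
  structure); rate-level realism of cortex is out of scope, as is
  multi-compartment morphology, spatial connectivity, and opsin photocycle
  kinetics.
* Firing-rate outputs (`popfreqs`) are binned at 5 ms on a single uniform
  grid across the whole simulation; the decision readout uses its own 5 ms
  *sliding* window at step resolution inside the integrator.
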