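# cbgt

Spiking cortico-basal ganglia-thalamic (CBGT) network agents for simulated
decision-making experiments.

`cbgt` is for computational and systems neuroscientists who want
neurophysiologically grounded predictions about basal ganglia dynamics during
behavior: which action a CBGT circuit selects, how long the selection takes,
and what every nucleus was doing meanwhile. The agent is a conductance-based
integrate-and-fire network — cortex (Cx/CxI), striatum (dSPN/iSPN/FSI),
pallidum (GPeP/GPeA), STN, GPi and thalamus — replicated into one action
channel per available choice (FSI and CxI are shared). The environment runs
trials around it: probabilistic rewards with configurable conflict and
volatility, stop-signal paradigms, and simulated optogenetic stimulation.

## The model in brief

Each neuron integrates
`C dV/dt = C/τ_m (V_rest − V) + I_ext − I_syn − I_opto` with exponentially
decaying AMPA/GABA gates and a magnesium-blocked NMDA gate, plus a
stochastic Gaussian background drive. A trial starts with a ramping cortical
input, `I_ramp(t) = I_ramp(t−dt) + 0.1[I_target − I_ramp(t−dt)]`; cortical
drive propagates through the direct pathway (Cx → dSPN ⊣ GPi ⊣ Th), and the
first channel whose thalamic rate (5 ms sliding window) exceeds the decision
boundary of 30 spikes/s is the choice; its latency is the reaction time
(timeout ⇒ decision `"none"`). A consolidation phase sustains the winning
channel's cortex at 70% of the ramp maximum for the movement time, reward is
delivered, and the reward prediction error `RPE = r − Q[choice]` is released
as phasic dopamine that strengthens Cx→dSPN and weakens Cx→iSPN weights of
the selected channel (`Δw = α_w · eligibility · ∫dopamine`, clipped to
`[0, w_max]`). Stop signals are frequency steps to STN/GPeA AMPA inputs;
optogenetic currents follow `I_opto = g(V − V_ChR2)` for `g ≥ 0` and
`−g(V − V_NpHR)` for `g < 0` with `V_ChR2 = 0`, `V_NpHR = −400` mV.

See the methods vignette (`vignettes/cbgt-methods.Rmd`) for equations,
defaults, and the documented design choices.

## Worked example

A 2-choice probabilistic reversal task: reward probabilities (0.8, 0.2)
swapping every 5 trials, binary rewards, plasticity on.

```r
library(cbgt)

cfg <- list(
  experimentchoice = "n-choice", seed = 42, n_trials = 10,
  channels = c("left", "right"), number_of_choices = 2,
  conflict = c(0.8, 0.2), volatility = list(5, "exact"),
  reward_mu = 1, reward_std = 0,
  corticostriatal_plasticity_present = TRUE,
  record_variables = c("weight"))

res <- run_simulations(cfg, n_sims = 1)
res[[1]]$datatables[, c("trial", "decision", "correctdecision",
                        "reward", "decision_time")]
#>    trial decision correctdecision reward decision_time
#> 1      0     left            left      1         609.8
#> 2      1     left            left      1         181.6
#> 3      2     left            left      1         134.6
#> 4      3    right            left      0         158.5
#> 5      4     left            left      1         236.9
#> 6      5     left           right      0         100.9
#> 7      6     left           right      1          15.2
#> 8      7     left           right      1         158.2
#> 9      8     left           right      0         111.0
#> 10     9     left           right      0          78.4
```

Each row is one trial: the chosen action, the currently optimal action (note
the contingency switch at trial 5), the delivered reward, and the reaction
time in ms. The agent learns `left` during the first block and — as in real
reversal experiments — perseverates after the switch while negative
prediction errors unlearn it; the Q table tracks this
(`res[[1]]$Q_df`: `Q[left]` decays from 0.68 to 0.55 over the last three
trials).

```r
fr <- extract_frames(res)
fr$performance        # % of decided trials per action:  left 90, right 10
fr$total_performance  # % matching the optimal action:   40
fr$rt_dist            # reaction times of decided trials (ms)
```

Firing-rate traces for every nucleus are in `res[[1]]$popfreqs`
(`plot(res[[1]])` for a quick look), recorded corticostriatal weights in
`res[[1]]$recordings$weight`, and `save_results(res, "out/")` /
`load_results("out/")` round-trip everything as CSV + JSON.

## Acceptance script

`scripts/acceptance.R` rebuilds the default full-scale network and
recomputes the package's headline operating-point quantities from scratch:
the choice percentage of the first action under a symmetric two-choice
configuration with plasticity disabled (pooled over seeds until at least 200
decided trials), the minimum smoothed thalamic rate of the winning channel
at its recorded decision time, the phase-0 duration when strong inhibitory
optogenetic input to dSPN in all channels suppresses the decision, and the
maximum phase-0 duration across stop-signal trials with STN and GPeA stop
currents. Run it from the repository root against the installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
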