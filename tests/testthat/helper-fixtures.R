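# shared fixtures: built in code, deterministic under the given seed

# minimal two-population parameter file for connectivity tests
toy_paramfile <- function(sizes = c(Cx = 5, Th = 7), pathways = NULL) {
  pf <- cbgt_paramfile("n-choice")
  pf$popsizes <- as.list(sizes)
  bs <- pf$basestim[["Cx"]]
  pf$basestim <- setNames(rep(list(bs), length(sizes)), names(sizes))
  pf$popspecific <- list()
  if (is.null(pathways))
    pathways <- data.frame(src = "Cx", dest = "Th", receptor = "AMPA",
                           type = "syn", con = 1.0, eff = 0.001,
                           plastic = FALSE)
  pf$pathways <- pathways
  pf
}

tiny_cfg <- function(seed = 1, n_trials = 2, ...) {
  make_fixture_network("tiny", seed = seed, n_trials = n_trials,
                       conflict = c(0.5, 0.5),
                       volatility = if (n_trials == 1) list(NULL, "exact")
                                    else list(n_trials - 1, "exact"),
                       corticostriatal_plasticity_present = FALSE,
                       reward_std = 0, ...)
}

run_tiny <- function(fx, n_sims = 1, cores = 1)
  run_simulations(fx$config, n_sims = n_sims, cores = cores,
                  paramfile = fx$paramfile)

# standard single-neuron cell/receptor parameter sets for dynamics tests
cell_std <- list(C = 0.5, Taum = 20, Vrest = -70, Vthresh = -50,
                 Vreset = -55, refractory = 2, VE = 0, VI = -70)
recep_std <- list(Tau_AMPA = 2, Tau_GABA = 5, Tau_NMDA = 100)

# closed-form leaky integrate-and-fire rate under constant current I:
# 1 / (refractory + Taum * log((I R - Vreset + Vrest)/(I R - Vthresh + Vrest)))
lif_rate_closed_form <- function(I, p = cell_std) {
  IR <- I * p$Taum / p$C
  denom <- p$refractory + p$Taum * log((IR - p$Vreset + p$Vrest) /
                                         (IR - p$Vthresh + p$Vrest))
  1000 / denom  # ms -> spikes/s
}
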