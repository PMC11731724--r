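# Trial execution and the simulation runner.
#
# A trial walks through three phases:
#   phase 0 (decision): a ramping external drive excites all cortical
#     channels; the trial ends in a decision when a smoothed thalamic rate
#     exceeds the decision boundary, or in a timeout at the choice timeout.
#   phase 1 (consolidation): the selected channel's cortex is driven at
#     sustainedfraction x the phase-0 ramp maximum for the movement time;
#     reward is delivered at the end and corticostriatal plasticity applies.
#     On timed-out trials no sustained drive is given and nothing is learned.
#   phase 2 (reset): no external input for the inter-trial interval.

PHASE1_TIMEOUT <- 300  # ms, forcible termination of the consolidation phase

prep_network <- function(net) {
  dt <- net$dt
  cell <- list(C = net$cell$C, Taum = net$cell$Taum, Vrest = net$cell$Vrest,
               Vthresh = net$cell$Vthresh, Vreset = net$cell$Vreset,
               refr_steps = as.integer(round(net$cell$refractory / dt)),
               VE = net$cell$VE, VI = net$cell$VI)
  recep <- list(dec_ampa = exp(-dt / net$recep$Tau_AMPA),
                dec_gaba = exp(-dt / net$recep$Tau_GABA),
                dec_nmda = exp(-dt / net$recep$Tau_NMDA))
  th_groups <- lapply(net$channels, function(ch)
    as.integer(pop_neurons(net, "Th", ch) - 1L))
  cx_idx <- lapply(net$channels, function(ch) pop_neurons(net, "Cx", ch))
  names(cx_idx) <- net$channels
  list(cell = cell, recep = recep, th_groups = th_groups, cx_idx = cx_idx,
       pop_index = as.integer(net$neuron_pop - 1L),
       n_popcols = nrow(net$pops), window_steps = as.integer(round(5 / dt)))
}

# stream per-step population spike counts into fixed-width rate bins; the
# carry buffer keeps steps left over at phase/trial boundaries so the time
# axis stays on one uniform grid across the whole simulation
bin_stream <- function() {
  buf <- NULL
  t_bins <- 0L
  list(
    push = function(counts, dt, bin_ms, sizes, names_, flush = FALSE) {
      buf <<- if (is.null(buf)) counts else rbind(buf, counts)
      per_bin <- max(1L, as.integer(round(bin_ms / dt)))
      nfull <- nrow(buf) %/% per_bin
      take <- nfull * per_bin
      if (flush && nrow(buf) > take) { nfull <- nfull + 1L; take <- nrow(buf) }
      if (nfull == 0L) return(NULL)
      rows <- buf[seq_len(take), , drop = FALSE]
      buf <<- if (take < nrow(buf)) buf[(take + 1L):nrow(buf), , drop = FALSE]
              else NULL
      bin_id <- (seq_len(take) - 1L) %/% per_bin
      nsteps <- tabulate(bin_id + 1L)
      agg <- rowsum(rows, bin_id, reorder = TRUE)
      rates <- sweep(agg, 2, sizes, "/") / (nsteps * dt / 1000)
      df <- as.data.frame(rates)
      names(df) <- names_
      out <- cbind(data.frame(time_ms = (t_bins + seq_len(nfull) - 1L) *
                                bin_ms), df)
      t_bins <<- t_bins + nfull
      out
    })
}

phase1_rate <- function(counts, steps_run, dt, idx_rows, net, base, ch) {
  r <- which(net$pops$base == base & !is.na(net$pops$channel) &
               net$pops$channel == ch)
  sum(counts[seq_len(steps_run), r]) /
    (net$pops$size[r] * steps_run * dt / 1000)
}

# let the network relax from its random initial conditions to baseline
# activity (the pre-trial resting phase); not part of any recorded trace
settle_network <- function(net, prep, W, state, ms = 500) {
  res <- sim_phase_cpp(state, prep$cell, prep$recep, W$AMPA, W$NMDA, W$GABA,
                       net$bg, numeric(net$n), 0.1, numeric(net$n), list(),
                       list(), I_ext = numeric(net$n),
                       th_groups = prep$th_groups, threshold = Inf,
                       window_steps = prep$window_steps,
                       check_decision = FALSE,
                       max_steps = as.integer(round(ms / net$dt)),
                       dt = net$dt, pop_index = prep$pop_index,
                       n_popcols = prep$n_popcols, record_spikes = FALSE)
  res$state
}

#' Run a single trial
#'
#' Executes the phase-0/1/2 state machine for one trial of either task,
#' including stimulation protocols, reward delivery and (for the n-choice
#' task with plasticity enabled) the dopamine-dependent corticostriatal
#' weight update. Mainly used internally by \code{\link{run_simulations}};
#' exposed for inspection and testing.
#'
#' @param net a \code{cbgt_network}.
#' @param trial 0-based trial index.
#' @param schedule a \code{cbgt_schedule} covering the trial.
#' @param cfg a validated \code{cbgt_config}.
#' @param protocols resolved stimulation protocols (internal format).
#' @param state dynamical state (from \code{\link{run_simulations}} internals);
#'   \code{NULL} starts from the network's initial conditions.
#' @param q named Q-value vector.
#' @param prep,W cached network preparations (recomputed when NULL).
#' @param t0_ms absolute simulation time at trial onset.
#' @param popfreq_bin firing-rate bin width for the returned traces, ms.
#' @return list with the trial \code{record}, updated \code{net}, \code{state},
#'   \code{q}, the per-step population spike-count matrix \code{counts},
#'   stimulation \code{stim} rows and the weight table after the trial.
#' @export
run_trial <- function(net, trial, schedule, cfg, protocols = list(),
                      state = NULL, q = NULL, prep = NULL, W = NULL,
                      t0_ms = 0, popfreq_bin = 5) {
  dt <- net$dt
  if (is.null(prep)) prep <- prep_network(net)
  if (is.null(W)) W <- assemble_weights(net)
  if (is.null(state)) state <- init_state(net$n, net$V0)
  if (is.null(q)) q <- setNames(rep(0.5, length(net$channels)), net$channels)

  n <- net$n
  sizes <- net$pops$size
  pnames <- net$pops$name
  zero <- numeric(n)
  stim_meta <- list()
  blocks <- list()
  clock <- t0_ms

  run_phase <- function(phase, max_steps, ramp_target, drive_const,
                        check, phase_start_trial_ms) {
    wins <- protocol_windows(protocols, net, trial, phase,
                             phase_start_trial_ms, max_steps, dt)
    res <- sim_phase_cpp(state, prep$cell, prep$recep,
                         W$AMPA, W$NMDA, W$GABA, net$bg,
                         ramp_target, 0.1, drive_const,
                         wins$freq, wins$opto, I_ext = zero,
                         th_groups = prep$th_groups,
                         threshold = cfg$thalamic_threshold,
                         window_steps = prep$window_steps,
                         check_decision = check,
                         max_steps = as.integer(max_steps), dt = dt,
                         pop_index = prep$pop_index,
                         n_popcols = prep$n_popcols, record_spikes = FALSE)
    # close open stimulation windows at the realized phase end
    if (length(wins$meta)) {
      meta <- do.call(rbind, wins$meta)
      off <- pmin(meta$off_step, res$steps_run + 1L)
      meta$offset_ms <- clock + (off - 1L) * dt
      meta$onset_ms <- meta$onset_ms - phase_start_trial_ms + clock
      meta$off_step <- NULL
      stim_meta[[length(stim_meta) + 1]] <<- meta
    }
    blocks[[length(blocks) + 1]] <<-
      res$popcounts[seq_len(res$steps_run), , drop = FALSE]
    clock <<- clock + res$steps_run * dt
    state <<- res$state
    res
  }

  # ---- phase 0: decision -------------------------------------------------
  state$i_ramp <- numeric(n)
  ramp_target <- numeric(n)
  target_val <- cfg$maxstim * net$stimscale
  for (ch in net$channels) ramp_target[prep$cx_idx[[ch]]] <- target_val
  steps0 <- as.integer(round(cfg$choice_timeout / dt))
  res0 <- run_phase(0, steps0, ramp_target, zero, TRUE, 0)
  decided <- res0$decision > 0
  decision <- if (decided) net$channels[res0$decision] else "none"
  decision_time <- if (decided) res0$decision_step * dt else NA_real_
  phase0_ms <- res0$steps_run * dt
  th_rate_dec <- if (decided) res0$th_rate[res0$decision] else NA_real_
  ramp_peak <- max(res0$state$i_ramp)

  # ---- phase 1: consolidation -------------------------------------------
  mt <- sample_movement_time(cfg$movement_time)
  dur1 <- min(mt, PHASE1_TIMEOUT)
  steps1 <- max(1L, as.integer(round(dur1 / dt)))
  drive1 <- numeric(n)
  sustained_level <- 0
  if (decided) {
    idx <- prep$cx_idx[[decision]]
    sustained_level <- cfg$sustainedfraction * ramp_peak
    drive1[idx] <- cfg$sustainedfraction * res0$state$i_ramp[idx]
  }
  state$i_ramp <- numeric(n)  # ramping input extinguished after the decision
  res1 <- run_phase(1, steps1, zero, drive1, FALSE, phase0_ms)
  phase1_ms <- res1$steps_run * dt

  reward <- 0
  if (decided) reward <- draw_reward(schedule, trial, res0$decision)

  # ---- plasticity --------------------------------------------------------
  w_after <- weights_state(net)
  rpe <- NA_real_
  if (decided && cfg$corticostriatal_plasticity_present &&
      length(net$plastic)) {
    pf <- net$paramfile
    upd <- update_q(q, decision, reward, cfg$Q_support_params$q_alpha)
    q <- upd$q
    rpe <- upd$rpe
    r_cx <- phase1_rate(res1$popcounts, res1$steps_run, dt, NULL, net, "Cx",
                        decision)
    escale <- pf$dpmndefaults$dpmn_elig_scale %||% 1
    elig <- list(
      dSPN = escale * (r_cx / 1000) *
        (phase1_rate(res1$popcounts, res1$steps_run, dt, NULL, net, "dSPN",
                     decision) / 1000),
      iSPN = escale * (r_cx / 1000) *
        (phase1_rate(res1$popcounts, res1$steps_run, dt, NULL, net, "iSPN",
                     decision) / 1000))
    Dint <- dopamine_integral(rpe, cfg$Q_support_params$C_scale,
                              pf$dpmndefaults$dpmn_tauDOP, phase1_ms)
    w_after <- update_weights(w_after, decision, Dint, elig,
                              pf$dSPNdefaults, pf$iSPNdefaults)
    net <- set_weights(net, w_after)
  }

  # ---- phase 2: reset ----------------------------------------------------
  steps2 <- as.integer(round(cfg$inter_trial_interval / dt))
  res2 <- run_phase(2, steps2, zero, zero, FALSE, phase0_ms + phase1_ms)
  phase2_ms <- res2$steps_run * dt

  stim <- if (length(stim_meta)) do.call(rbind, stim_meta) else NULL
  counts <- do.call(rbind, blocks)
  record <- data.frame(
    trial = trial, decision = decision,
    correctdecision = schedule$labels[schedule$optimal[trial + 1L]],
    reward = reward, decision_time = decision_time,
    phase0_ms = phase0_ms, phase1_ms = phase1_ms, phase2_ms = phase2_ms,
    th_rate_at_decision = th_rate_dec, rpe = rpe,
    ramp_peak = ramp_peak, sustained_drive = sustained_level,
    opto_applied = !is.null(stim) && any(stim$kind == "opto"),
    stop_applied = !is.null(stim) && any(stim$kind == "stop"),
    stringsAsFactors = FALSE)

  list(record = record, net = net, state = state, q = q,
       counts = counts, stim = stim, weights = w_after,
       end_ms = clock)
}

run_one_sim <- function(config, seed, popfreq_bin = 5, paramfile = NULL) {
  cfg <- validate_config(config)
  set.seed(seed)
  pf <- override_paramfile(paramfile %||% cbgt_paramfile(cfg$experimentchoice),
                           cfg)
  net <- build_network(pf, cfg$channels, newpathways = cfg$newpathways,
                       seed = seed, task = cfg$experimentchoice)
  schedule <- generate_reward_schedule(cfg$conflict, cfg$volatility,
                                       cfg$n_trials, cfg$reward_mu,
                                       cfg$reward_std, labels = cfg$channels)
  protocols <- resolve_protocols(cfg, cfg$channels, cfg$n_trials)
  prep <- prep_network(net)
  W <- assemble_weights(net)
  state <- init_state(net$n, net$V0)
  state <- settle_network(net, prep, W, state, ms = 500)
  q <- cfg$Q_df

  records <- vector("list", cfg$n_trials)
  qrows <- vector("list", cfg$n_trials)
  wrows <- vector("list", cfg$n_trials)
  freqs <- list()
  binner <- bin_stream()
  stims <- list()
  t0 <- 0
  for (tr in seq_len(cfg$n_trials) - 1L) {
    out <- run_trial(net, tr, schedule, cfg, protocols, state, q, prep, W,
                     t0_ms = t0, popfreq_bin = popfreq_bin)
    if (!identical(weights_state(net), out$weights)) W <- assemble_weights(out$net)
    net <- out$net
    state <- out$state
    q <- out$q
    records[[tr + 1L]] <- out$record
    qrows[[tr + 1L]] <- data.frame(trial = tr, as.list(q), check.names = FALSE)
    wrows[[tr + 1L]] <- if (nrow(out$weights))
      cbind(data.frame(trial = tr, time_ms = out$end_ms), out$weights) else NULL
    block <- binner$push(out$counts, net$dt, popfreq_bin, net$pops$size,
                         net$pops$name, flush = (tr == cfg$n_trials - 1L))
    if (!is.null(block)) freqs[[length(freqs) + 1]] <- block
    if (!is.null(out$stim)) stims[[length(stims) + 1]] <- out$stim
    t0 <- out$end_ms
  }
  stim <- if (length(stims)) do.call(rbind, stims) else
    data.frame(trial = integer(), kind = character(), population = character(),
               channel = character(), amplitude = numeric(), phase = integer(),
               onset_ms = numeric(), offset_ms = numeric())

  recordings <- list()
  if ("weight" %in% cfg$record_variables)
    recordings$weight <- do.call(rbind, wrows)
  if ("optogenetic_input" %in% cfg$record_variables)
    recordings$optogenetic_input <- stim[stim$kind == "opto", , drop = FALSE]
  if ("stop_input" %in% cfg$record_variables)
    recordings$stop_input <- stim[stim$kind == "stop", , drop = FALSE]

  structure(list(
    configuration = cfg, seed = seed,
    datatables = do.call(rbind, records),
    popfreqs = do.call(rbind, freqs),
    Q_df = do.call(rbind, qrows),
    recordings = recordings,
    weights = weights_state(net),
    network = summary(net),
    record_variables = cfg$record_variables,
    task = cfg$experimentchoice), class = "cbgt_bundle")
}

#' Run one or more seeded simulations
#'
#' Runs \code{n_sims} simulations of the same configuration with seeds
#' \code{seed, seed+1, ...}. Each simulation seeds its own RNG stream before
#' building the network, so results are identical whether they are executed
#' sequentially or on a process pool, and the returned order always matches
#' the submission order.
#'
#' @param config configuration list (see \code{\link{validate_config}}).
#' @param n_sims number of parallel simulations (>= 1).
#' @param cores number of worker processes (forked; 1 = sequential).
#' @param popfreq_bin bin width of the returned firing-rate traces, ms.
#' @param paramfile optional \code{cbgt_paramfile} replacing the shipped
#'   default for the task (e.g. a fixture parameter file).
#' @return object of class \code{cbgt_results}: a list of per-seed bundles,
#'   each containing \code{datatables}, \code{popfreqs}, \code{Q_df}, the
#'   recorded variables and the full configuration echo.
#' @export
run_simulations <- function(config, n_sims = 1, cores = 1, popfreq_bin = 5,
                            paramfile = NULL) {
  if (n_sims < 1) config_error("n_sims must be >= 1")
  cfg <- validate_config(config)
  seeds <- cfg$seed + seq_len(n_sims) - 1L
  worker <- function(s) run_one_sim(cfg, s, popfreq_bin, paramfile)
  res <- if (cores > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(seeds, function(s) tryCatch(worker(s), error = identity),
                       mc.cores = cores)
  } else {
    lapply(seeds, function(s) tryCatch(worker(s), error = identity))
  }
  for (i in seq_along(res))
    if (inherits(res[[i]], "error") || inherits(res[[i]], "try-error"))
      stop(sprintf("simulation with seed %d failed: %s", seeds[i],
                   conditionMessage(res[[i]])))
  structure(res, class = "cbgt_results")
}

#' @export
print.cbgt_bundle <- function(x, ...) {
  dt <- x$datatables
  cat("CBGT simulation bundle (", x$task, "), seed ", x$seed, "\n", sep = "")
  cat("  ", nrow(dt), "trials;",
      sum(dt$decision != "none"), "decided;",
      sprintf("mean RT %.0f ms", mean(dt$decision_time, na.rm = TRUE)), "\n")
  invisible(x)
}

#' @export
print.cbgt_results <- function(x, ...) {
  cat("CBGT results:", length(x), "simulation(s)\n")
  for (b in x) print(b)
  invisible(x)
}

#' @export
summary.cbgt_results <- function(object, ...) {
  do.call(rbind, lapply(object, function(b) {
    dt <- b$datatables
    data.frame(seed = b$seed, trials = nrow(dt),
               decided = sum(dt$decision != "none"),
               mean_rt = mean(dt$decision_time, na.rm = TRUE),
               reward_rate = mean(dt$reward))
  }))
}
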