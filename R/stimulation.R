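# Optogenetic and stop-signal stimulation: currents, trial schedules,
# channel targeting, and per-trial window resolution.

#' Opsin current
#'
#' The optogenetic current added to a neuron's external current:
#' \deqn{I_{opto} = g_{opto} (V - V_{ChR2})} for \eqn{g_{opto} \ge 0}
#' (channelrhodopsin-2, excitation) and
#' \deqn{I_{opto} = -g_{opto} (V - V_{NpHR})} for \eqn{g_{opto} < 0}
#' (halorhodopsin, inhibition), with reversal potentials
#' \eqn{V_{ChR2} = 0} mV and \eqn{V_{NpHR} = -400} mV. The current couples
#' into the membrane equation with a minus sign so that a positive conductance
#' depolarizes at rest (excitatory semantics) and a negative one
#' hyperpolarizes.
#'
#' @param g_opto signed opsin conductance.
#' @param V membrane potential in mV.
#' @return the opsin current (vectorized over both arguments).
#' @export
opto_current <- function(g_opto, V) {
  n <- max(length(g_opto), length(V))
  g <- rep_len(g_opto, n); v <- rep_len(V, n)
  ifelse(g >= 0, g * (v - 0), -g * (v - (-400)))
}

#' Stop-signal drive
#'
#' A stop signal up-regulates the baseline input frequency to the AMPA
#' receptors of its target population: \code{f_ext + stop_amplitude} during
#' the protocol's active window.
#'
#' @param f_ext baseline external frequency (spikes/s).
#' @param stop_amplitude frequency increment (spikes/s).
#' @return the incremented frequency.
#' @export
stop_drive <- function(f_ext, stop_amplitude) {
  out <- f_ext + stop_amplitude
  if (any(out < 0))
    config_error("stop drive would make the external frequency negative")
  out
}

#' Trials on which a stimulation protocol applies
#'
#' A fractional probability p selects a random subset of round(p * n_trials)
#' trials without replacement; an explicit list selects exactly those trials.
#' Trial indices are 0-based.
#'
#' @param probability a fraction in [0,1] or a vector/list of 0-based trial
#'   indices.
#' @param n_trials number of trials in the run.
#' @return sorted integer vector of 0-based trial indices.
#' @export
schedule_trials <- function(probability, n_trials) {
  if (length(probability) == 1 && !is.list(probability) &&
      probability >= 0 && probability <= 1) {
    k <- round(probability * n_trials)
    if (k == 0) return(integer(0))
    return(sort(sample.int(n_trials, k) - 1L))
  }
  idx <- as.integer(unlist(probability))
  if (any(idx < 0 | idx >= n_trials))
    config_error("stimulation trial index out of range [0, %d]", n_trials - 1)
  sort(unique(idx))
}

#' Per-trial stimulated channels
#'
#' \code{"all"} targets every channel on each trial, \code{"any"} one
#' uniformly drawn channel per trial, and a channel label targets that channel
#' on every trial.
#'
#' @param channel \code{"all"}, \code{"any"} or a channel label.
#' @param channels the channel label vector.
#' @param n_trials number of trials.
#' @return list of length \code{n_trials}, each element a character vector of
#'   target channel labels.
#' @export
resolve_targets <- function(channel, channels, n_trials) {
  if (identical(channel, "all"))
    return(replicate(n_trials, channels, simplify = FALSE))
  if (identical(channel, "any"))
    return(lapply(seq_len(n_trials),
                  function(i) channels[sample.int(length(channels), 1)]))
  if (!channel %in% channels)
    config_error("unknown stimulation channel '%s'; channels are: %s",
                 channel, paste(channels, collapse = ", "))
  replicate(n_trials, channel, simplify = FALSE)
}

# Build the resolved protocol list from the configuration's opt_signal_* /
# stop_signal_* families. Each protocol i yields a record with its kind,
# target population, amplitude, onset (ms after phase-0 start), duration
# (numeric ms or "phase 0"/"phase 1"/"phase 2"), the realized 0-based trial
# set and the per-trial channel targets.
resolve_protocols <- function(config, channels, n_trials) {
  out <- list()
  for (kind in c("opt", "stop")) {
    present <- config[[paste0(kind, "_signal_present")]]
    if (is.null(present) || !any(unlist(present))) next
    getl <- function(suffix) config[[paste0(kind, "_signal_", suffix)]]
    pops <- getl("population")
    nprot <- length(present)
    for (i in seq_len(nprot)) {
      if (!isTRUE(present[[i]])) next
      dur <- getl("duration")[[i]]
      if (is.character(dur) && !dur %in% c("phase 0", "phase 1", "phase 2"))
        config_error("stimulation duration must be a number of ms or one of 'phase 0', 'phase 1', 'phase 2'")
      out[[length(out) + 1]] <- list(
        kind = if (kind == "opt") "opto" else "stop",
        population = pops[[i]],
        amplitude = as.numeric(getl("amplitude")[[i]]),
        onset = as.numeric(getl("onset")[[i]]),
        duration = dur,
        trials = schedule_trials(getl("probability")[[i]], n_trials),
        targets = resolve_targets(getl("channel")[[i]], channels, n_trials))
    }
  }
  out
}

# Windows for one phase of one trial. Numeric durations live on the trial
# clock (measured from phase-0 onset) and may span phase boundaries;
# phase-named durations cover exactly the realized phase. Returns a list of
# C++-ready windows: idx (0-based neurons), amp, on/off (1-based steps within
# the phase), plus metadata for the recorded stimulation tables.
protocol_windows <- function(protocols, net, trial, phase, phase_start_ms,
                             phase_len_steps, dt) {
  fw <- list(); ow <- list(); meta <- list()
  phase_name <- paste("phase", phase)
  for (p in protocols) {
    if (!trial %in% p$trials) next
    if (is.character(p$duration)) {
      if (p$duration != phase_name) next
      on_step <- if (phase == 0) max(1L, as.integer(ceiling(p$onset / dt)) + 1L)
                 else 1L
      off_step <- phase_len_steps + 1L
    } else {
      ws <- p$onset; we <- p$onset + as.numeric(p$duration)  # trial clock, ms
      rel_on <- (ws - phase_start_ms) / dt
      rel_off <- (we - phase_start_ms) / dt
      on_step <- as.integer(max(1, floor(rel_on) + 1))
      off_step <- as.integer(min(phase_len_steps + 1, floor(rel_off) + 1))
      if (off_step <= on_step) next
      if (rel_on > phase_len_steps) next
    }
    chans <- p$targets[[trial + 1L]]
    idx <- unlist(lapply(chans, function(ch) {
      if (p$population %in% SHARED_POPS) pop_neurons(net, p$population)
      else pop_neurons(net, p$population, ch)
    }))
    idx <- sort(unique(idx)) - 1L  # 0-based for C++
    win <- list(idx = idx, amp = p$amplitude, on = on_step, off = off_step)
    if (p$kind == "opto") ow[[length(ow) + 1]] <- win
    else fw[[length(fw) + 1]] <- win
    meta[[length(meta) + 1]] <- data.frame(
      trial = trial, kind = p$kind, population = p$population,
      channel = paste(chans, collapse = "+"), amplitude = p$amplitude,
      phase = phase, onset_ms = phase_start_ms + (on_step - 1) * dt,
      offset_ms = NA_real_, off_step = off_step, stringsAsFactors = FALSE)
  }
  list(freq = fw, opto = ow, meta = meta)
}
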