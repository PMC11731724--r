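# R surface over the compiled integrate-and-fire core.

# fresh dynamical state for n neurons
init_state <- function(n, V) {
  list(V = V, s_ampa = numeric(n), s_nmda = numeric(n), s_gaba = numeric(n),
       refr = integer(n), i_ramp = numeric(n))
}

expand_cell <- function(params, n, dt) {
  f <- function(x) rep_len(as.numeric(x), n)
  list(C = f(params$C), Taum = f(params$Taum), Vrest = f(params$Vrest),
       Vthresh = f(params$Vthresh), Vreset = f(params$Vreset),
       refr_steps = as.integer(round(rep_len(as.numeric(params$refractory), n) / dt)),
       VE = f(params$VE), VI = f(params$VI))
}

expand_recep <- function(receptors, n, dt) {
  f <- function(x) exp(-dt / rep_len(as.numeric(x), n))
  list(dec_ampa = f(receptors$Tau_AMPA), dec_gaba = f(receptors$Tau_GABA),
       dec_nmda = f(receptors$Tau_NMDA))
}

zero_bg <- function(n) {
  list(rate_ampa = numeric(n), n_ampa = numeric(n), eff_ampa = numeric(n),
       rate_gaba = numeric(n), n_gaba = numeric(n), eff_gaba = numeric(n))
}

#' Advance an isolated population of integrate-and-fire neurons
#'
#' Integrates a single unconnected population for \code{n_steps} forward Euler
#' steps: conductance-based leaky integrate-and-fire with exponential
#' AMPA/GABA gates, magnesium-blocked NMDA, an optional constant injected
#' current, and optional stochastic background drive. Neurons crossing
#' threshold emit a spike, are reset, and stay refractory for the configured
#' duration.
#'
#' @param state list with vectors \code{V}, \code{s_ampa}, \code{s_nmda},
#'   \code{s_gaba}, \code{refr}, \code{i_ramp} (see \code{value}); use
#'   \code{NULL} fields to start from rest.
#' @param params cell parameters: \code{C}, \code{Taum}, \code{Vrest},
#'   \code{Vthresh}, \code{Vreset}, \code{refractory}, \code{VE}, \code{VI}
#'   (scalars or per-neuron vectors).
#' @param receptors \code{Tau_AMPA}, \code{Tau_GABA}, \code{Tau_NMDA} in ms.
#' @param external_current constant injected current (scalar or per neuron).
#' @param dt integration step in ms (> 0).
#' @param n_steps number of steps to advance.
#' @param n number of neurons (defaults to \code{length(state$V)}).
#' @param background optional list(rate, n_connections, efficacy) for an
#'   excitatory background Gaussian drive.
#' @return list with the advanced \code{state} and a data frame \code{spikes}
#'   (columns \code{step}, \code{neuron}).
#' @export
step_population <- function(state, params, receptors, external_current = 0,
                            dt = 0.1, n_steps = 1, n = length(state$V),
                            background = NULL) {
  if (dt <= 0) config_error("dt must be > 0")
  if (is.null(state$V)) config_error("state$V required")
  st <- init_state(n, rep_len(state$V, n))
  for (f in c("s_ampa", "s_nmda", "s_gaba", "i_ramp"))
    if (!is.null(state[[f]])) st[[f]] <- rep_len(as.numeric(state[[f]]), n)
  if (!is.null(state$refr)) st$refr <- rep_len(as.integer(state$refr), n)
  bg <- zero_bg(n)
  if (!is.null(background)) {
    rate <- background$rate %||% background$FreqExt_AMPA
    if (rate < 0) config_error("background rate must be >= 0")
    bg$rate_ampa <- rep_len(rate, n)
    bg$n_ampa <- rep_len(background$n_connections, n)
    bg$eff_ampa <- rep_len(background$efficacy, n)
  }
  zeros <- matrix(0, n, n)
  out <- sim_phase_cpp(st, expand_cell(params, n, dt),
                       expand_recep(receptors, n, dt), zeros, zeros, zeros,
                       bg, ramp_target = numeric(n), ramp_coef = 0.1,
                       drive_const = numeric(n), freq_windows = list(),
                       opto_windows = list(),
                       I_ext = rep_len(external_current, n),
                       th_groups = list(), threshold = Inf, window_steps = 1L,
                       check_decision = FALSE, max_steps = as.integer(n_steps),
                       dt = dt, pop_index = rep(0L, n), n_popcols = 1L,
                       record_spikes = TRUE)
  list(state = out$state, spikes = as.data.frame(out$spikes))
}

#' Background drive events
#'
#' Per-step external event intensity for one neuron under the background
#' Gaussian-process model: the instantaneous rate is drawn from a normal
#' distribution with the specified mean and unit variance (on the spikes/s
#' scale), truncated at zero, and multiplied by the number of connections and
#' the step duration. The mean per-step intensity is therefore
#' rate * n_connections * dt.
#'
#' @param spec list with \code{rate} (or \code{FreqExt_AMPA}) in spikes/s and
#'   \code{n_connections} (>= 1).
#' @param n_steps number of steps to draw.
#' @param dt step in ms.
#' @return numeric vector of per-step event intensities (never negative).
#' @export
background_drive <- function(spec, n_steps = 1, dt = 0.1) {
  rate <- spec$rate %||% spec$FreqExt_AMPA
  if (is.null(rate) || rate < 0) config_error("background rate must be >= 0")
  nc <- spec$n_connections %||% 1
  if (nc < 1) config_error("n_connections must be >= 1")
  if (rate == 0) return(numeric(n_steps))
  pmax(rnorm(n_steps, rate, 1), 0) * nc * dt / 1000
}

#' Population firing-rate trace
#'
#' Bins spike times and converts counts to a population rate in spikes/s:
#' rate = count / (n_neurons * window). The rate trace integrates back to the
#' exact spike count: sum(rate) * window * n_neurons = total spikes.
#'
#' @param spike_times spike times in ms (empty vector allowed).
#' @param n_neurons number of neurons in the population.
#' @param window bin width in ms (> 0).
#' @param t_max trace end time in ms (defaults to the last spike, rounded up
#'   to a full bin).
#' @return data frame with \code{time} (bin start, ms) and \code{rate}
#'   (spikes/s).
#' @export
population_rate <- function(spike_times, n_neurons, window, t_max = NULL) {
  if (window <= 0) config_error("window must be > 0")
  if (is.null(t_max))
    t_max <- if (length(spike_times)) max(spike_times) else window
  nbins <- max(1L, as.integer(ceiling(t_max / window)))
  counts <- if (length(spike_times)) {
    # spikes at a bin's right edge belong to that bin
    idx <- pmin(pmax(ceiling(spike_times / window), 1L), nbins)
    tabulate(idx, nbins = nbins)
  } else integer(nbins)
  data.frame(time = (seq_len(nbins) - 1L) * window,
             rate = counts / (n_neurons * window / 1000))
}
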