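# Task environment: reward schedules, trial phase machinery, decision readout.

#' Generate a reward schedule
#'
#' Builds the per-trial reward-probability table for an n-choice task. The
#' initial probabilities are the \code{conflict} tuple (one entry per action);
#' at every change point the contingencies are permuted (a swap for two
#' actions, a cyclic rotation for more). Change points are placed every
#' \code{lambda} trials exactly, or at gaps drawn from a Poisson distribution
#' with mean \code{lambda} (never less than one trial apart).
#'
#' @param conflict numeric vector of reward probabilities, one per action.
#' @param volatility list \code{list(lambda, mode)} with mode \code{"exact"}
#'   or \code{"poisson"}; \code{lambda = NULL} produces a schedule with no
#'   contingency changes (1-trial and stop-signal runs).
#' @param n_trials number of trials (> 0).
#' @param reward_mu,reward_std mean and standard deviation of the Gaussian
#'   reward magnitude; \code{reward_std = 0} gives binary rewards of size
#'   \code{reward_mu}. Magnitudes are truncated at zero.
#' @param labels optional action labels (defaults to \code{A1..An}).
#' @return object of class \code{cbgt_schedule}: probability matrix
#'   (trial x action), 0-based \code{change_points}, per-trial
#'   \code{optimal} action index, and the reward magnitude parameters.
#' @export
generate_reward_schedule <- function(conflict, volatility, n_trials,
                                     reward_mu = 1, reward_std = 0.1,
                                     labels = NULL) {
  conflict <- as.numeric(conflict)
  n_act <- length(conflict)
  if (any(conflict < 0 | conflict > 1))
    config_error("conflict entries are reward probabilities and must lie in [0,1]")
  if (n_trials < 1) config_error("n_trials must be >= 1")
  if (is.null(labels)) labels <- paste0("A", seq_len(n_act))
  lambda <- if (is.null(volatility)) NULL else volatility[[1]]
  mode <- if (is.null(volatility) || length(volatility) < 2) "exact" else
    volatility[[2]]
  if (!is.null(lambda) && !is.na(lambda)) {
    if (lambda <= 0 || lambda >= n_trials)
      config_error(paste("volatility lambda must satisfy 0 < lambda < n_trials;",
                         "it cannot be 0 or the total number of trials"))
    if (!mode %in% c("exact", "poisson"))
      config_error("volatility mode must be 'exact' or 'poisson'")
    cps <- if (mode == "exact") {
      seq(lambda, n_trials - 1, by = lambda)
    } else {
      cp <- integer(0); t <- 0
      repeat {
        t <- t + max(1, rpois(1, lambda))
        if (t >= n_trials) break
        cp <- c(cp, t)
      }
      cp
    }
  } else cps <- integer(0)

  prob <- matrix(NA_real_, n_trials, n_act, dimnames = list(NULL, labels))
  cur <- conflict
  ncp <- 0
  for (t in seq_len(n_trials) - 1L) {     # trials are 0-based
    if (t %in% cps) cur <- cur[c(seq_len(n_act)[-1], 1)]  # cyclic rotation
    prob[t + 1L, ] <- cur
  }
  optimal <- max.col(prob, ties.method = "first")
  structure(list(prob = prob, change_points = as.integer(cps),
                 optimal = optimal, reward_mu = reward_mu,
                 reward_std = reward_std, labels = labels,
                 conflict = conflict, volatility = list(lambda, mode)),
            class = "cbgt_schedule")
}

# draw the delivered reward for a 0-based trial index and 1-based action
draw_reward <- function(schedule, trial, action) {
  p <- schedule$prob[trial + 1L, action]
  if (runif(1) >= p) return(0)
  if (schedule$reward_std == 0) return(schedule$reward_mu)
  max(0, rnorm(1, schedule$reward_mu, schedule$reward_std))
}

#' Cortical ramp recursion
#'
#' One step of the ramping-stimulus recursion
#' \code{I_ramp <- I_ramp + coef * (I_target - I_ramp)}; the external input
#' frequency of the cortical populations is then the baseline plus
#' \code{I_ramp}. Starting from zero with a constant target, after k steps the
#' ramp equals \code{I_target * (1 - (1 - coef)^k)}.
#'
#' @param I_ramp current ramp value.
#' @param I_target target drive.
#' @param coef per-step relaxation coefficient (0.1).
#' @return the next ramp value.
#' @export
ramp_update <- function(I_ramp, I_target, coef = 0.1) {
  I_ramp + coef * (I_target - I_ramp)
}

#' Decision boundary readout
#'
#' Applies the decision rule to smoothed per-channel thalamic rates: the first
#' channel whose rate exceeds the boundary wins; with several channels above
#' the boundary in the same step the highest rate wins and exact ties are
#' broken uniformly at random. If no channel has crossed by the choice
#' timeout, the trial times out and the decision is "none".
#'
#' @param th_rates per-channel smoothed thalamic rates (spikes/s).
#' @param threshold decision boundary in spikes/s (default 30).
#' @param elapsed time since phase-0 onset in ms.
#' @param max_wait choice timeout in ms (default 1000).
#' @return list with \code{event} ("decision", "timeout" or "continue"),
#'   \code{channel} (index or NA) and \code{time}.
#' @export
check_decision <- function(th_rates, threshold = 30, elapsed, max_wait = 1000) {
  if (any(th_rates < 0)) config_error("rates must be >= 0")
  over <- which(th_rates > threshold)
  if (length(over)) {
    best <- over[th_rates[over] == max(th_rates[over])]
    win <- if (length(best) > 1) best[sample.int(length(best), 1)] else best
    return(list(event = "decision", channel = win, time = elapsed))
  }
  if (elapsed >= max_wait)
    return(list(event = "timeout", channel = NA_integer_, time = elapsed))
  list(event = "continue", channel = NA_integer_, time = elapsed)
}

#' Sample a movement (consolidation-phase) time
#'
#' The default draws from a normal distribution N(250, 1.5) ms;
#' \code{list("constant", N)} fixes the duration at N for every trial;
#' \code{list("mean", N)} draws from N(N, 1.5). Draws are truncated positive.
#'
#' @param spec \code{NULL} for the default, or \code{list("constant", N)} /
#'   \code{list("mean", N)}.
#' @param n number of draws.
#' @return movement times in ms.
#' @export
sample_movement_time <- function(spec = NULL, n = 1) {
  if (is.null(spec)) return(rnorm_pos(n, 250, 1.5))
  kind <- spec[[1]]
  N <- as.numeric(spec[[2]])
  if (is.na(N) || N <= 0) config_error("movement time must be positive")
  switch(kind,
         constant = rep(N, n),
         mean = rnorm_pos(n, N, 1.5),
         config_error("movement_time spec must be NULL, ['constant', N] or ['mean', N]"))
}

rnorm_pos <- function(n, mu, sd) {
  v <- rnorm(n, mu, sd)
  while (any(bad <- v <= 0)) v[bad] <- rnorm(sum(bad), mu, sd)
  v
}
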