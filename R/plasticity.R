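# Dopamine-dependent corticostriatal plasticity and the Q-value bookkeeping.
#
# Q-values track the expected reward of each action via a delta rule; the
# reward prediction error (RPE) drives a phasic dopamine transient which, in
# combination with an activity-dependent eligibility, moves the plastic
# cortico-dSPN weight up and the cortico-iSPN weight down (for positive
# dopamine) on the selected channel only.  Q-values never influence choice;
# selection depends solely on the corticostriatal weights.

#' Q-value update (delta rule)
#'
#' @param q named numeric vector of per-action Q-values.
#' @param choice the chosen action (name or index).
#' @param reward delivered reward magnitude.
#' @param q_alpha learning rate.
#' @return list with the updated \code{q} and the reward prediction error
#'   \code{rpe = reward - q[choice]}.
#' @export
update_q <- function(q, choice, reward, q_alpha = 0.1) {
  if (is.character(choice) && !choice %in% names(q))
    config_error("unknown action '%s'", choice)
  rpe <- reward - q[[choice]]
  q[[choice]] <- q[[choice]] + q_alpha * rpe
  list(q = q, rpe = unname(rpe))
}

#' Phasic dopamine transient
#'
#' The reward prediction error is released as an impulse of phasic dopamine,
#' \code{C_scale * rpe}, at reward-delivery time, decaying exponentially with
#' time constant \code{dpmn_tauDOP}; a negative RPE gives a below-baseline
#' dip. The baseline of the phasic signal is zero.
#'
#' @param rpe reward prediction error.
#' @param C_scale scaling between the dopamine change and the weight change.
#' @param dpmn_tauDOP decay time constant in ms.
#' @param t times (ms) after the impulse at which to evaluate the trace.
#' @return dopamine trace at times \code{t}.
#' @export
dopamine_signal <- function(rpe, C_scale = 30, dpmn_tauDOP = 20, t) {
  if (dpmn_tauDOP <= 0) config_error("dpmn_tauDOP must be > 0")
  C_scale * rpe * exp(-t / dpmn_tauDOP)
}

# time integral of the dopamine transient over a consolidation window of
# length T ms (used by the weight update): C_scale * rpe * tau * (1 - e^-T/tau)
dopamine_integral <- function(rpe, C_scale, dpmn_tauDOP, T_ms) {
  C_scale * rpe * (dpmn_tauDOP / 1000) * (1 - exp(-T_ms / dpmn_tauDOP))
}

#' Corticostriatal weight update
#'
#' Updates the plastic cortico-dSPN and cortico-iSPN weights of the selected
#' channel for one consolidation window. The weight change is
#' \code{dpmn_alphaw * eligibility * dopamine}, where \code{dopamine} is the
#' integrated above-baseline phasic transient and \code{eligibility} is the
#' activity-dependent trace (product of the pre- and postsynaptic phase-1
#' population rates, in kHz). With the conventional sign choices
#' (\code{dpmn_alphaw} positive for dSPN, negative for iSPN) a positive
#' dopamine transient strengthens the direct pathway and weakens the indirect
#' pathway of the selected channel. Weights are clipped to
#' \code{[0, dpmn_wmax]}; unselected channels are untouched.
#'
#' @param w data frame with columns \code{channel}, \code{target}
#'   (\code{"dSPN"}/\code{"iSPN"}) and \code{w}, as returned inside results
#'   bundles.
#' @param channel the selected channel label.
#' @param dopamine integrated phasic dopamine (signed).
#' @param eligibility named list or vector with eligibility per target
#'   population (\code{dSPN}, \code{iSPN}).
#' @param dSPN_params,iSPN_params lists with \code{dpmn_alphaw} and
#'   \code{dpmn_wmax}.
#' @param enabled if \code{FALSE} (plasticity switched off) the weights are
#'   returned unchanged.
#' @return the updated weight table.
#' @export
update_weights <- function(w, channel, dopamine, eligibility,
                           dSPN_params, iSPN_params, enabled = TRUE) {
  if (!enabled) return(w)
  for (i in seq_len(nrow(w))) {
    if (w$channel[i] != channel) next
    pars <- if (w$target[i] == "dSPN") dSPN_params else iSPN_params
    elig <- eligibility[[w$target[i]]]
    dw <- pars$dpmn_alphaw * elig * dopamine
    w$w[i] <- min(max(w$w[i] + dw, 0), pars$dpmn_wmax)
  }
  w
}

# apply a weight table back onto the network's plastic pathway entries
set_weights <- function(net, w) {
  for (j in seq_along(net$plastic)) {
    p <- net$plastic[[j]]
    hit <- which(w$channel == p$channel & w$target == p$dest_base)
    if (length(hit)) net$plastic[[j]]$w <- w$w[hit[1]]
  }
  net
}
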