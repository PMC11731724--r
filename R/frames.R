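# Processed data frames extracted from results bundles.

#' Extract analysis-ready data frames from simulation results
#'
#' For the n-choice task returns \code{firing_rates} (long-format population
#' rate traces), \code{reward_q} (per-trial reward and Q-values),
#' \code{performance} (percentage of each decision choice over decided
#' trials), \code{rt_dist} (decision times of decided trials) and
#' \code{total_performance} (percentage of decided trials whose decision
#' equals the optimal action). For the stop-signal task only
#' \code{firing_rates} and \code{rt_dist} are returned. Runs without any
#' decided trial report \code{NA} performance rather than failing.
#'
#' @param results a \code{cbgt_results} object (or a single bundle).
#' @param task experiment choice; defaults to the bundles' own task.
#' @return named list of data frames (see Description).
#' @export
extract_frames <- function(results, task = NULL) {
  if (inherits(results, "cbgt_bundle")) results <- list(results)
  if (!length(results)) config_error("results must contain at least one bundle")
  task <- task %||% results[[1]]$task

  firing_rates <- do.call(rbind, lapply(results, function(b) {
    pf <- b$popfreqs
    long <- data.frame(
      seed = b$seed,
      time_ms = rep(pf$time_ms, ncol(pf) - 1L),
      population = rep(names(pf)[-1], each = nrow(pf)),
      rate = unlist(pf[-1], use.names = FALSE))
    long
  }))

  dtall <- do.call(rbind, lapply(results, function(b)
    cbind(seed = b$seed, b$datatables)))
  decided <- dtall[dtall$decision != "none", , drop = FALSE]
  rt_dist <- decided$decision_time

  if (task == "stop-signal")
    return(list(firing_rates = firing_rates, rt_dist = rt_dist))

  channels <- results[[1]]$configuration$channels
  if (nrow(decided)) {
    counts <- vapply(channels, function(ch) sum(decided$decision == ch),
                     numeric(1))
    performance <- 100 * counts / nrow(decided)
    total_performance <-
      100 * mean(decided$decision == decided$correctdecision)
  } else {
    performance <- setNames(rep(NA_real_, length(channels)), channels)
    total_performance <- NA_real_
  }

  reward_q <- do.call(rbind, lapply(results, function(b) {
    merge(cbind(seed = b$seed, b$Q_df),
          b$datatables[, c("trial", "reward", "decision")], by = "trial")
  }))

  list(firing_rates = firing_rates, reward_q = reward_q,
       performance = performance, rt_dist = rt_dist,
       total_performance = total_performance)
}
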