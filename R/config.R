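# Configuration assembly and validation.
#
# The configuration is a plain named list using the same keys as the
# simulator's configuration dictionary: experimentchoice, seed,
# inter_trial_interval, thalamic_threshold, movement_time, choice_timeout,
# params, pops, receps, base, dpmns, dSPN_params, iSPN_params, channels,
# number_of_choices, newpathways, Q_support_params, Q_df, n_trials,
# volatility, conflict, reward_mu, reward_std, maxstim,
# corticostriatal_plasticity_present, record_variables, sustainedfraction,
# and the opt_signal_* / stop_signal_* families. A NULL value requests the
# documented default.

CONFIG_KEYS <- c(
  "experimentchoice", "seed", "inter_trial_interval", "thalamic_threshold",
  "movement_time", "choice_timeout", "params", "pops", "receps", "base",
  "dpmns", "dSPN_params", "iSPN_params", "channels", "number_of_choices",
  "newpathways", "Q_support_params", "Q_df", "n_trials", "volatility",
  "conflict", "reward_mu", "reward_std", "maxstim",
  "corticostriatal_plasticity_present", "record_variables",
  "sustainedfraction",
  "opt_signal_present", "opt_signal_probability", "opt_signal_amplitude",
  "opt_signal_onset", "opt_signal_duration", "opt_signal_channel",
  "opt_signal_population",
  "stop_signal_present", "stop_signal_probability", "stop_signal_amplitude",
  "stop_signal_onset", "stop_signal_duration", "stop_signal_channel",
  "stop_signal_population")

#' Validate a configuration and substitute defaults
#'
#' Fills documented defaults for NULL entries (inter-trial interval 600 ms,
#' thalamic threshold 30 spikes/s, choice timeout 1000 ms, movement time
#' N(250, 1.5)), normalizes the channel table, and enforces cross-field
#' consistency: the number of choices must equal the channel count, the width
#' of the conflict tuple and of any initial Q table; volatility must satisfy
#' 0 < lambda < n_trials (lambda = NULL only for single-trial or stop-signal
#' runs); a stop-signal run requires the stop_signal parameter family.
#'
#' @param raw named list of configuration entries.
#' @return validated configuration of class \code{cbgt_config}.
#' @export
validate_config <- function(raw) {
  if (inherits(raw, "cbgt_config")) return(raw)
  if (!is.list(raw)) config_error("configuration must be a named list")
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  if (length(unknown))
    config_error("unknown configuration keys: %s",
                 paste(unknown, collapse = ", "))
  cfg <- raw
  task <- cfg$experimentchoice %||% "n-choice"
  if (!task %in% c("n-choice", "stop-signal"))
    config_error("experimentchoice must be 'n-choice' or 'stop-signal'")
  cfg$experimentchoice <- task

  cfg$seed <- as.integer(cfg$seed %||% 0)
  cfg$inter_trial_interval <- cfg$inter_trial_interval %||% 600
  cfg$thalamic_threshold <- cfg$thalamic_threshold %||% 30
  # the stop-signal task uses a 300 ms decision window by default
  cfg$choice_timeout <- cfg$choice_timeout %||%
    (if (task == "stop-signal") 300 else 1000)
  if (cfg$inter_trial_interval <= 0 || cfg$choice_timeout <= 0)
    config_error("phase durations must be > 0")
  if (!is.null(cfg$movement_time)) sample_movement_time(cfg$movement_time, 0)

  # channels: accept a character vector or a one-column data frame (action)
  ch <- cfg$channels %||% c("left", "right")
  if (is.data.frame(ch)) ch <- as.character(ch[[1]])
  ch <- as.character(ch)
  if (anyDuplicated(ch)) config_error("channel labels must be unique")
  cfg$channels <- ch
  n_ch <- length(ch)
  cfg$number_of_choices <- cfg$number_of_choices %||% n_ch
  if (cfg$number_of_choices != n_ch)
    config_error("number_of_choices (%d) must equal the channel count (%d)",
                 cfg$number_of_choices, n_ch)

  cfg$n_trials <- as.integer(cfg$n_trials %||% 3L)
  if (cfg$n_trials < 1) config_error("n_trials must be >= 1")

  cfg$conflict <- as.numeric(unlist(cfg$conflict %||% rep(0.5, n_ch)))
  if (length(cfg$conflict) != n_ch)
    config_error("conflict has width %d but channels has width %d",
                 length(cfg$conflict), n_ch)
  if (any(cfg$conflict < 0 | cfg$conflict > 1))
    config_error("conflict entries must lie in [0,1]")

  # volatility: [lambda, mode]; lambda NULL only for 1-trial or stop runs
  vol <- cfg$volatility %||%
    (if (task == "stop-signal" || cfg$n_trials == 1) list(NULL, "exact")
     else list(max(1L, cfg$n_trials - 1L), "exact"))
  if (!is.list(vol)) vol <- as.list(vol)
  lambda <- vol[[1]]
  if (is.null(lambda) || (length(lambda) == 1 && is.na(lambda))) {
    if (task == "n-choice" && cfg$n_trials > 1)
      config_error("volatility lambda may be NULL only for single-trial or stop-signal runs")
    vol[1] <- list(NULL)
  } else {
    if (cfg$n_trials == 1)
      config_error("if only 1 trial is simulated, volatility must be [NULL, mode]")
    if (lambda <= 0 || lambda >= cfg$n_trials)
      config_error("volatility lambda cannot be 0 or >= the total number of trials")
  }
  cfg$volatility <- vol

  cfg$reward_mu <- cfg$reward_mu %||% 1
  cfg$reward_std <- cfg$reward_std %||% 0.1
  if (cfg$reward_std < 0) config_error("reward_std must be >= 0")
  cfg$maxstim <- cfg$maxstim %||% 0.8
  cfg$sustainedfraction <- cfg$sustainedfraction %||% 0.7
  if (cfg$sustainedfraction < 0 || cfg$sustainedfraction > 1)
    config_error("sustainedfraction must lie in [0,1]")
  cfg$corticostriatal_plasticity_present <-
    isTRUE(cfg$corticostriatal_plasticity_present %||% (task == "n-choice"))
  cfg$record_variables <- as.character(cfg$record_variables %||% character(0))

  # Q machinery
  qs <- as_override(cfg$Q_support_params)
  cfg$Q_support_params <- list(C_scale = qs$C_scale %||% 30,
                               q_alpha = qs$q_alpha %||% 0.1)
  if (!is.null(cfg$Q_df)) {
    qdf <- as.data.frame(cfg$Q_df)
    if (ncol(qdf) != n_ch)
      config_error("Q_df has width %d but channels has width %d",
                   ncol(qdf), n_ch)
    q0 <- as.numeric(qdf[1, ])
    names(q0) <- if (!is.null(names(qdf)) && !all(grepl("^V[0-9]+$", names(qdf))))
      names(qdf) else ch
    cfg$Q_df <- q0
  } else {
    cfg$Q_df <- setNames(rep(0.5, n_ch), ch)
  }

  # stimulation families: equal lengths within a family, valid entries
  for (kind in c("opt", "stop")) {
    present <- cfg[[paste0(kind, "_signal_present")]]
    if (is.null(present)) next
    fam <- paste0(kind, "_signal_",
                  c("present", "probability", "amplitude", "onset",
                    "duration", "channel", "population"))
    lens <- vapply(fam, function(k) length(cfg[[k]]), integer(1))
    if (length(unique(lens[lens > 0])) > 1 || any(lens == 0))
      config_error("%s_signal_* lists must all have one entry per protocol",
                   kind)
    for (i in seq_along(present)) {
      if (!isTRUE(present[[i]])) next
      on <- as.numeric(cfg[[paste0(kind, "_signal_onset")]][[i]])
      if (is.na(on) || on < 0) config_error("stimulation onset must be >= 0")
      p <- cfg[[paste0(kind, "_signal_probability")]][[i]]
      if (length(p) == 1 && !is.list(p) && (p < 0 || p > 1))
        config_error("stimulation probability must lie in [0,1] or be a trial list")
    }
  }
  if (task == "stop-signal" && is.null(cfg$stop_signal_present))
    config_error("a stop-signal run requires the stop_signal_* parameter family")

  structure(cfg, class = "cbgt_config")
}

#' @export
print.cbgt_config <- function(x, ...) {
  cat("CBGT configuration (", x$experimentchoice, ")\n", sep = "")
  cat("  channels:", paste(x$channels, collapse = ", "),
      "| trials:", x$n_trials, "| seed:", x$seed, "\n")
  cat("  conflict:", paste(x$conflict, collapse = "/"),
      "| volatility:", if (is.null(x$volatility[[1]])) "none" else
        paste(x$volatility[[1]], x$volatility[[2]]), "\n")
  invisible(x)
}
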