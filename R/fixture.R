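# Miniature test networks: full topology, scaled-down population sizes.

#' Miniature network fixture
#'
#' Builds a configuration (and its parameter file) for a scaled-down network
#' with the full topology: every population present, shared FSI/CxI, one copy
#' of the remaining populations per channel. Population sizes are shrunk and
#' internal pathway efficacies are scaled up by the same factor so the
#' expected summed synaptic drive per neuron — and hence the operating point —
#' is preserved. Intended for fast unit tests; deterministic under
#' \code{seed}.
#'
#' @param scale \code{"small"} (about half-size populations) or \code{"tiny"}
#'   (about quarter-size).
#' @param seed integer seed stored in the configuration.
#' @param task \code{"n-choice"} or \code{"stop-signal"}.
#' @param n_channels number of action channels.
#' @param ... further configuration entries passed through (see
#'   \code{\link{validate_config}}).
#' @return list with \code{config} (validated) and \code{paramfile}.
#' @export
make_fixture_network <- function(scale = c("small", "tiny"), seed = 0,
                                 task = "n-choice", n_channels = 2, ...) {
  scale <- match.arg(scale)
  factor <- if (scale == "tiny") 0.25 else 0.5
  pf <- cbgt_paramfile(task)
  old_sizes <- unlist(pf$popsizes)
  pf$popsizes <- lapply(pf$popsizes, function(s) max(4L, as.integer(round(s * factor))))
  # keep expected per-neuron drive: efficacy up by the realized shrink factor;
  # plastic rows keep their weight semantics, so their compensation goes
  # through plastic_gain instead
  for (k in seq_len(nrow(pf$pathways))) {
    src <- pf$pathways$src[k]
    shrink <- unlist(pf$popsizes)[[src]] / old_sizes[[src]]
    if (isTRUE(pf$pathways$plastic[k])) next
    pf$pathways$eff[k] <- pf$pathways$eff[k] / shrink
  }
  shrink_cx <- unlist(pf$popsizes)[["Cx"]] / old_sizes[["Cx"]]
  pf$plastic_gain <- (pf$plastic_gain %||% 1) / shrink_cx
  channels <- if (n_channels == 2) c("left", "right") else
    paste0("ch", seq_len(n_channels))
  extra <- list(...)
  config <- c(list(experimentchoice = task, seed = as.integer(seed),
                   channels = channels, number_of_choices = n_channels),
              extra)
  if (task == "stop-signal" && is.null(extra$stop_signal_present)) {
    config <- c(config, list(
      stop_signal_present = list(FALSE), stop_signal_probability = list(0),
      stop_signal_amplitude = list(0), stop_signal_onset = list(0),
      stop_signal_duration = list(0), stop_signal_channel = list("all"),
      stop_signal_population = list("STN")))
  }
  cfg <- validate_config(config)
  list(config = cfg, paramfile = pf)
}

# run a fixture end-to-end with its scaled parameter file
run_fixture <- function(fx, n_sims = 1, cores = 1, popfreq_bin = 5) {
  run_simulations(fx$config, n_sims = n_sims, cores = cores,
                  popfreq_bin = popfreq_bin, paramfile = fx$paramfile)
}
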