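#' Load a default parameter file
#'
#' Reads the shipped parameter file for one of the two supported tasks. The
#' file mirrors the agent parameter tables of the simulator: \code{celldefaults}
#' (membrane parameters common to all neurons), \code{popspecific} (per
#' population overrides), \code{receptordefaults} (synaptic time constants),
#' \code{basestim} (background Gaussian drive per population),
#' \code{dpmndefaults} (dopamine kinetics), \code{dSPNdefaults} /
#' \code{iSPNdefaults} (corticostriatal plasticity constants per striatal
#' target), plus population sizes and the pathway table.
#'
#' The shipped numerical values are a tuned stand-in chosen so that all nuclei
#' show stable, distinguishable baseline firing and decisions complete within
#' a few hundred milliseconds; they are a synthetic operating point, not
#' measured physiological constants.
#'
#' @param task \code{"n-choice"} or \code{"stop-signal"}. The stop-signal file
#'   additionally contains the pallidostriatal (GPeA) pathways, which are only
#'   part of the stop-signal network build.
#' @param path optional path to a user parameter file in the same JSON schema.
#' @return a list of class \code{cbgt_paramfile}.
#' @export
cbgt_paramfile <- function(task = c("n-choice", "stop-signal"), path = NULL) {
  if (is.null(path)) {
    task <- match.arg(task)
    fname <- if (task == "stop-signal") "params_stopsignal.json" else
      "params_nchoice.json"
    path <- system.file("extdata", fname, package = "cbgt", mustWork = TRUE)
  }
  pf <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  pf$pathways <- as.data.frame(pf$pathways, stringsAsFactors = FALSE)
  validate_paramfile(pf)
  structure(pf, class = "cbgt_paramfile")
}

validate_paramfile <- function(pf) {
  need <- c("celldefaults", "popspecific", "receptordefaults", "basestim",
            "dpmndefaults", "dSPNdefaults", "iSPNdefaults", "popsizes",
            "pathways", "stimscale", "dt")
  miss <- setdiff(need, names(pf))
  if (length(miss))
    config_error("parameter file is missing fields: %s",
                 paste(miss, collapse = ", "))
  cd <- pf$celldefaults
  if (cd$Taum <= 0 || cd$C <= 0) config_error("Taum and C must be > 0")
  if (cd$Vreset >= cd$Vthresh) config_error("V_reset must be below V_thresh")
  if (any(unlist(pf$receptordefaults) <= 0))
    config_error("receptor time constants must be > 0")
  for (p in names(pf$basestim)) {
    b <- pf$basestim[[p]]
    if ((b$FreqExt_AMPA %||% 0) < 0 || (b$FreqExt_GABA %||% 0) < 0)
      config_error("background rates must be >= 0 (population %s)", p)
  }
  invisible(pf)
}

# apply configuration overrides (params/pops/receps/base/dpmns/dSPN_params/
# iSPN_params) onto a paramfile; each override is a one-row data frame or a
# named list, as in the configuration dictionary
override_paramfile <- function(pf, config) {
  pf$celldefaults <- modifyList(pf$celldefaults, as_override(config$params))
  if (!is.null(config$pops)) {
    for (p in names(config$pops)) {
      if (!p %in% names(pf$popsizes))
        config_error("pops override names unknown population '%s'", p)
      cur <- pf$popspecific[[p]] %||% list()
      pf$popspecific[[p]] <- modifyList(cur, lapply(as_override(config$pops[[p]]),
                                                    function(v) v[[1]]))
    }
  }
  pf$receptordefaults <- modifyList(pf$receptordefaults,
                                    as_override(config$receps))
  if (!is.null(config$base)) {
    for (p in names(config$base)) {
      if (!p %in% names(pf$basestim))
        config_error("base override names unknown population '%s'", p)
      pf$basestim[[p]] <- modifyList(pf$basestim[[p]],
                                     lapply(as_override(config$base[[p]]),
                                            function(v) v[[1]]))
    }
  }
  pf$dpmndefaults <- modifyList(pf$dpmndefaults, as_override(config$dpmns))
  pf$dSPNdefaults <- modifyList(pf$dSPNdefaults, as_override(config$dSPN_params))
  pf$iSPNdefaults <- modifyList(pf$iSPNdefaults, as_override(config$iSPN_params))
  pf
}

#' @export
print.cbgt_paramfile <- function(x, ...) {
  cat("CBGT parameter file\n")
  cat("  populations:", paste(names(x$popsizes), unlist(x$popsizes),
                              sep = "=", collapse = " "), "\n")
  cat("  pathways:", nrow(x$pathways), "rows; dt =", x$dt, "ms\n")
  invisible(x)
}
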