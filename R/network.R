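# Network construction: populations, action channels, pathway realization.
#
# The network holds one copy of every population per action channel, except
# the striatal fast-spiking interneurons (FSI) and the cortical inhibitory
# pool (CxI), which are shared across channels.  Connectivity is drawn as
# independent Bernoulli trials per ordered neuron pair (no self-connections),
# with a per-pathway RNG stream derived from the build seed so that editing
# one pathway never redraws the topology of the others.

SHARED_POPS <- c("CxI", "FSI")
PATHWAY_COLS <- c("src", "dest", "receptor", "type", "con", "eff", "plastic")

resolve_pop_name <- function(name, known) {
  # "GPe" resolves to the prototypical population unless GPeA is named
  if (identical(name, "GPe")) name <- "GPeP"
  if (!name %in% known)
    config_error("unknown population '%s'; valid names: %s", name,
                 paste(known, collapse = ", "))
  name
}

normalize_pathways <- function(tbl, known, where = "pathway table") {
  if (is.null(tbl)) return(NULL)
  tbl <- as.data.frame(tbl, stringsAsFactors = FALSE)
  if (ncol(tbl) != length(PATHWAY_COLS) && !all(PATHWAY_COLS %in% names(tbl)))
    config_error("%s must have the seven columns %s", where,
                 paste(PATHWAY_COLS, collapse = ", "))
  if (!all(PATHWAY_COLS %in% names(tbl))) names(tbl) <- PATHWAY_COLS
  tbl <- tbl[PATHWAY_COLS]
  for (i in seq_len(nrow(tbl))) {
    tbl$src[i] <- resolve_pop_name(tbl$src[i], known)
    tbl$dest[i] <- resolve_pop_name(tbl$dest[i], known)
    if (!tbl$receptor[i] %in% c("AMPA", "NMDA", "GABA"))
      config_error("%s row %d: receptor must be AMPA, NMDA or GABA", where, i)
    if (!tbl$type[i] %in% c("syn", "common"))
      config_error("%s row %d: type must be 'syn' or 'common'", where, i)
    if (is.na(tbl$con[i]) || tbl$con[i] < 0 || tbl$con[i] > 1)
      config_error("%s row %d: connection probability must lie in [0,1]",
                   where, i)
  }
  tbl$plastic <- as.logical(tbl$plastic)
  tbl
}

#' Override or extend the pathway table
#'
#' Existing rows are matched on (src, dest, receptor) and overridden in place;
#' unmatched rows are appended, which is how new anatomical connections (for
#' example a cortico-pallidal projection) are added to the build. A list of
#' tables is applied in order.
#'
#' @param pathways the current pathway table (seven columns: src, dest,
#'   receptor, type, con, eff, plastic) or a \code{cbgt_network}.
#' @param table a data frame with the same seven column roles (names optional,
#'   positional order accepted), or a list of such data frames.
#' @return the merged table, or a rebuilt network when \code{pathways} is a
#'   \code{cbgt_network}. In the rebuilt network, pathways whose connection
#'   probability is unchanged keep their realized topology.
#' @export
apply_newpathways <- function(pathways, table) {
  if (inherits(pathways, "cbgt_network")) {
    net <- pathways
    pf <- net$paramfile
    pf$pathways <- apply_newpathways(net$pathways_raw, table)
    return(build_network(pf, net$channels, newpathways = NULL,
                         seed = net$seed, task = net$task))
  }
  if (is.null(table) || (is.data.frame(table) && nrow(table) == 0))
    return(pathways)
  if (is.list(table) && !is.data.frame(table)) {
    for (tb in table) pathways <- apply_newpathways(pathways, tb)
    return(pathways)
  }
  known <- union(c("Cx", "CxI", "dSPN", "iSPN", "FSI", "GPeP", "GPeA", "STN",
                   "GPi", "Th"),
                 unique(c(pathways$src, pathways$dest)))
  table <- normalize_pathways(table, known, where = "newpathways")
  for (i in seq_len(nrow(table))) {
    hit <- which(pathways$src == table$src[i] &
                 pathways$dest == table$dest[i] &
                 pathways$receptor == table$receptor[i])
    if (length(hit)) {
      pathways[hit[1], ] <- table[i, ]
    } else {
      pathways <- rbind(pathways, table[i, ])
    }
  }
  rownames(pathways) <- NULL
  pathways
}

#' Scale shared-input efficacies with the number of channels
#'
#' Replicating the network per action channel multiplies the number of
#' afferents converging on the shared populations (FSI, CxI) and on any
#' common-typed target. To keep the expected summed synaptic drive onto such
#' targets independent of the channel count, the efficacy of every
#' channelized-to-converging pathway is divided by \code{n_channels}.
#'
#' @param pathways seven-column pathway table.
#' @param n_channels number of action channels (>= 1).
#' @param shared names of populations instantiated once regardless of channel
#'   count.
#' @return the table with scaled efficacies.
#' @export
scale_shared_inputs <- function(pathways, n_channels,
                                shared = SHARED_POPS) {
  if (n_channels < 1) config_error("n_channels must be >= 1")
  scale_row <- !(pathways$src %in% shared) &
    (pathways$dest %in% shared |
       (pathways$type == "common" & !(pathways$dest %in% shared)))
  pathways$eff[scale_row] <- pathways$eff[scale_row] / n_channels
  pathways
}

#' Build a CBGT network
#'
#' Instantiates one copy of every population per action channel (FSI and CxI
#' are shared), applies user pathway modifications, rescales shared-input
#' efficacies for the channel count, and realizes the connectivity as
#' independent Bernoulli draws under the given seed.
#'
#' @param paramfile a \code{cbgt_paramfile} (see \code{\link{cbgt_paramfile}}).
#' @param channels character vector of unique action channel labels.
#' @param newpathways optional pathway modification table (or list of tables),
#'   see \code{\link{apply_newpathways}}.
#' @param seed integer seed controlling connectivity and initial conditions.
#' @param task \code{"n-choice"} or \code{"stop-signal"}; kept as metadata.
#' @return an object of class \code{cbgt_network}.
#' @export
build_network <- function(paramfile, channels, newpathways = NULL, seed = 0,
                          task = "n-choice") {
  stopifnot(inherits(paramfile, "cbgt_paramfile") || is.list(paramfile))
  channels <- as.character(channels)
  if (length(channels) < 1) config_error("at least one channel label required")
  if (anyDuplicated(channels)) config_error("channel labels must be unique")
  n_ch <- length(channels)
  known <- names(paramfile$popsizes)

  tbl <- normalize_pathways(paramfile$pathways, known)
  tbl_raw <- apply_newpathways(tbl, newpathways)
  tbl_scaled <- scale_shared_inputs(tbl_raw, n_ch)

  # population instances
  bases <- names(paramfile$popsizes)
  pops <- do.call(rbind, lapply(bases, function(b) {
    if (b %in% SHARED_POPS)
      data.frame(name = b, base = b, channel = NA_character_,
                 size = paramfile$popsizes[[b]], stringsAsFactors = FALSE)
    else
      data.frame(name = paste0(b, "_", channels), base = b, channel = channels,
                 size = paramfile$popsizes[[b]], stringsAsFactors = FALSE)
  }))
  pops$offset <- cumsum(c(0, pops$size[-nrow(pops)]))  # 0-based start
  n <- sum(pops$size)

  neuron_pop <- rep(seq_len(nrow(pops)), pops$size)

  cellfield <- function(field) {
    vapply(seq_len(nrow(pops)), function(i) {
      b <- pops$base[i]
      ov <- paramfile$popspecific[[b]]
      val <- if (!is.null(ov) && !is.null(ov[[field]])) ov[[field]] else
        paramfile$celldefaults[[field]]
      as.numeric(val)
    }, numeric(1))[neuron_pop]
  }
  recfield <- function(field) {
    vapply(seq_len(nrow(pops)), function(i) {
      b <- pops$base[i]
      ov <- paramfile$popspecific[[b]]
      val <- if (!is.null(ov) && !is.null(ov[[field]])) ov[[field]] else
        paramfile$receptordefaults[[field]]
      as.numeric(val)
    }, numeric(1))[neuron_pop]
  }
  bgfield <- function(field) {
    vapply(seq_len(nrow(pops)), function(i) {
      val <- paramfile$basestim[[pops$base[i]]][[field]]
      as.numeric(val %||% 0)
    }, numeric(1))[neuron_pop]
  }

  cell <- list(C = cellfield("C"), Taum = cellfield("Taum"),
               Vrest = cellfield("Vrest"), Vthresh = cellfield("Vthresh"),
               Vreset = cellfield("Vreset"), refractory = cellfield("refractory"),
               VE = cellfield("VE"), VI = cellfield("VI"))
  if (any(cell$Taum <= 0) || any(cell$C <= 0))
    config_error("Taum and C must be > 0")
  recep <- list(Tau_AMPA = recfield("Tau_AMPA"), Tau_GABA = recfield("Tau_GABA"),
                Tau_NMDA = recfield("Tau_NMDA"))
  bg <- list(rate_ampa = bgfield("FreqExt_AMPA"), n_ampa = bgfield("nconn_AMPA"),
             eff_ampa = bgfield("eff_AMPA"), rate_gaba = bgfield("FreqExt_GABA"),
             n_gaba = bgfield("nconn_GABA"), eff_gaba = bgfield("eff_GABA"))
  # mild per-neuron heterogeneity of the background efficacy smooths the
  # population transfer function (homogeneous populations flip as a block)
  jit <- paramfile$bg_jitter %||% 0
  if (jit > 0) {
    u <- with_seed(derive_seed(seed, "bgjit"), runif(n, -1, 1))
    bg$eff_ampa <- bg$eff_ampa * (1 + jit * u)
    bg$eff_gaba <- bg$eff_gaba * (1 + jit * u)
  }

  idx_of <- function(pop_row) {
    pops$offset[pop_row] + seq_len(pops$size[pop_row])
  }

  W <- list(AMPA = matrix(0, n, n), NMDA = matrix(0, n, n),
            GABA = matrix(0, n, n))
  plastic <- list()
  realized <- tbl_scaled
  realized$n_connections <- 0L

  for (k in seq_len(nrow(tbl_scaled))) {
    row <- tbl_scaled[k, ]
    src_rows <- which(pops$base == row$src)
    dest_rows <- which(pops$base == row$dest)
    for (si in src_rows) for (di in dest_rows) {
      src_sh <- is.na(pops$channel[si]); dest_sh <- is.na(pops$channel[di])
      if (!src_sh && !dest_sh && row$type == "syn" &&
          pops$channel[si] != pops$channel[di]) next
      sidx <- idx_of(si); didx <- idx_of(di)
      mask <- with_seed(
        derive_seed(seed, "path", k, pops$name[si], pops$name[di]),
        matrix(runif(length(didx) * length(sidx)) < row$con,
               length(didx), length(sidx)))
      if (si == di) diag(mask) <- FALSE  # no self-connections
      realized$n_connections[k] <- realized$n_connections[k] + sum(mask)
      if (isTRUE(row$plastic)) {
        # plastic rows: eff is the corticostriatal weight (the quantity the
        # plasticity rule updates and clips at dpmn_wmax); plastic_gain maps
        # it onto the conductance scale of the static efficacies
        ch <- if (!dest_sh) pops$channel[di] else pops$channel[si]
        plastic[[length(plastic) + 1]] <- list(
          row = k, channel = ch, dest_base = row$dest, src_base = row$src,
          receptor = row$receptor, rows = didx, cols = sidx,
          adj = mask * 1.0, w = row$eff,
          gain = paramfile$plastic_gain %||% 1)
      } else {
        W[[row$receptor]][didx, sidx] <-
          W[[row$receptor]][didx, sidx] + mask * row$eff
      }
    }
  }

  V0 <- with_seed(derive_seed(seed, "init"),
                  runif(n, cell$Vrest, cell$Vthresh))

  structure(list(
    pops = pops, n = n, channels = channels, seed = seed, task = task,
    cell = cell, recep = recep, bg = bg, W_static = W, plastic = plastic,
    pathways_raw = tbl_raw, pathways = realized, paramfile = paramfile,
    dt = paramfile$dt, stimscale = paramfile$stimscale, V0 = V0,
    neuron_pop = neuron_pop), class = "cbgt_network")
}

# neuron indices (1-based) of a population instance
pop_neurons <- function(net, base, channel = NULL) {
  sel <- net$pops$base == base
  if (!is.null(channel)) sel <- sel & !is.na(net$pops$channel) &
      net$pops$channel == channel
  i <- which(sel)
  if (!length(i)) config_error("no population '%s' (channel %s)", base,
                               channel %||% "any")
  unlist(lapply(i, function(r) net$pops$offset[r] + seq_len(net$pops$size[r])))
}

# full weight matrices: static part plus current plastic weights
assemble_weights <- function(net) {
  W <- net$W_static
  for (p in net$plastic)
    W[[p$receptor]][p$rows, p$cols] <-
      W[[p$receptor]][p$rows, p$cols] + p$adj * (p$w * p$gain)
  W
}

# current plastic weight table (channel x target population)
weights_state <- function(net) {
  if (!length(net$plastic))
    return(data.frame(channel = character(), target = character(),
                      w = numeric()))
  do.call(rbind, lapply(net$plastic, function(p)
    data.frame(channel = p$channel, target = p$dest_base, w = p$w,
               stringsAsFactors = FALSE)))
}

#' @export
print.cbgt_network <- function(x, ...) {
  cat("CBGT network (", x$task, "), ", length(x$channels), " channel(s): ",
      paste(x$channels, collapse = ", "), "\n", sep = "")
  cat("  ", x$n, "neurons in", nrow(x$pops), "population instances\n")
  cat("  ", sum(x$pathways$n_connections), "realized connections across",
      nrow(x$pathways), "pathways\n")
  invisible(x)
}

#' @export
summary.cbgt_network <- function(object, ...) {
  list(populations = object$pops[, c("name", "base", "channel", "size")],
       pathways = object$pathways)
}
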