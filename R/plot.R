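# Minimal plotting: firing-rate traces and the reward/Q trajectory.

#' Plot population firing-rate traces
#'
#' Base-graphics traces of the binned population rates in a bundle, one panel
#' per population base name, channels overlaid.
#'
#' @param x a \code{cbgt_bundle}.
#' @param populations base population names to show (default Cx, dSPN, iSPN,
#'   GPi, Th).
#' @param ... ignored.
#' @return invisibly, \code{x}.
#' @export
plot.cbgt_bundle <- function(x, populations = c("Cx", "dSPN", "iSPN", "GPi",
                                                "Th"), ...) {
  pf <- x$popfreqs
  cols <- names(pf)[-1]
  base_of <- sub("_(.*)$", "", cols)
  populations <- intersect(populations, unique(base_of))
  op <- graphics::par(mfrow = c(length(populations), 1),
                      mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  for (b in populations) {
    sel <- cols[base_of == b]
    graphics::matplot(pf$time_ms, as.matrix(pf[sel]), type = "l", lty = 1,
                      xlab = "", ylab = paste(b, "(sp/s)"))
    graphics::legend("topright", legend = sel, lty = 1,
                     col = seq_along(sel), bty = "n", cex = 0.7)
  }
  invisible(x)
}

#' Plot per-trial reward and Q-values
#'
#' @param results a \code{cbgt_results} object or single bundle.
#' @return invisibly, the reward/Q data frame plotted.
#' @export
plot_reward_q <- function(results) {
  fr <- extract_frames(results)
  rq <- fr$reward_q
  qcols <- setdiff(names(rq), c("seed", "trial", "reward", "decision"))
  graphics::matplot(rq$trial, as.matrix(rq[qcols]), type = "l", lty = 1,
                    xlab = "trial", ylab = "Q value",
                    ylim = range(c(0, 1, unlist(rq[qcols]))))
  graphics::points(rq$trial, rq$reward, pch = 16, cex = 0.6)
  graphics::legend("topright", legend = c(qcols, "reward"), bty = "n",
                   lty = c(rep(1, length(qcols)), NA),
                   pch = c(rep(NA, length(qcols)), 16),
                   col = c(seq_along(qcols), "black"), cex = 0.8)
  invisible(rq)
}
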