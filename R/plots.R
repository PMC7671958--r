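#' Plot stacked membrane-potential traces
#'
#' One panel per compartment (plus drive potentials if requested), the
#' standard layout for inspecting a simulation.
#'
#' @param x A `sim_result`.
#' @param window Length-2 time window in ms (default: last 500 ms).
#' @param drives Include external-potential traces (default `TRUE`).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.sim_result <- function(x, window = NULL,
                            drives = TRUE, ...) {
  if (is.null(window))
    window <- c(max(0, max(x$time) - 500), max(x$time))
  cols <- grep("\\.V$", colnames(x$traces), value = TRUE)
  if (drives)
    cols <- c(cols, grep("\\.Vext$", colnames(x$traces), value = TRUE))
  sel <- x$time >= window[1] & x$time <= window[2]
  old <- graphics::par(mfrow = c(length(cols), 1),
                       mar = c(1.5, 4, 0.5, 1))
  on.exit(graphics::par(old))
  for (cc in cols) {
    graphics::plot(x$time[sel], x$traces[sel, cc], type = "l",
                   xlab = "", ylab = cc, ...)
  }
  invisible(x)
}

#' Plot an interburst-interval map
#'
#' Interval length against the lag of the slow-cell spike, colored by the
#' spike count of the opening burst.
#'
#' @param x An `interburst_map`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.interburst_map <- function(x, ...) {
  cnt <- factor(x$count_open)
  graphics::plot(x$ib_si, x$ib_ib, col = as.integer(cnt), pch = 16,
                 xlab = "burst onset to slow-cell spike (ms)",
                 ylab = "interburst interval (ms)", ...)
  graphics::legend("topleft", legend = paste(levels(cnt), "spikes"),
                   col = seq_along(levels(cnt)), pch = 16, bty = "n")
  invisible(x)
}

#' Plot a firing-probability-versus-phase histogram
#'
#' @param x Data frame from [firingProbabilityVsPhase()].
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plotPhaseProbability <- function(x, ...) {
  graphics::plot(x$phase, x$prob, type = "h", lwd = 3,
                 xlab = "phase of reference input (ms)",
                 ylab = "P(fire | pulse at phase)", ylim = c(0, 1), ...)
  invisible(x)
}
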