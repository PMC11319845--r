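#' Plot replicate adult-count trajectories
#'
#' One panel in the style of the experiment figure: thin black lines for
#' individual replicate populations, a red line for the ensemble mean.
#'
#' @param x A `"replicate_set"`.
#' @param max_lines Number of replicate lines drawn (the mean always uses
#'   all replicates).
#' @param ylim Y limits; defaults to the range of the drawn replicates.
#' @param main Panel title.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.replicate_set <- function(x, max_lines = 100, ylim = NULL,
                               main = NULL, ...) {
  tr <- x$adult_trajectories
  days <- 0:(ncol(tr) - 1L)
  shown <- tr[seq_len(min(nrow(tr), max_lines)), , drop = FALSE]
  if (is.null(ylim)) ylim <- c(0, max(shown, 1))
  if (is.null(main)) main <- paste("Scenario", x$scenario$id)
  graphics::matplot(days, t(shown), type = "l", lty = 1, lwd = 0.4,
                    col = grDevices::adjustcolor("black", alpha.f = 0.25),
                    xlab = "day", ylab = "adult flies", ylim = ylim,
                    main = main, ...)
  graphics::lines(days, colMeans(tr), col = "red", lwd = 2)
  invisible(x)
}

#' Plot all scenario panels of an experiment
#'
#' A grid of trajectory panels (2 x 3 for the full six-scenario experiment)
#' on a shared y scale, each with per-replicate black lines and the red
#' ensemble mean.
#'
#' @param x A `"fly_experiment"`.
#' @param max_lines Replicate lines per panel.
#' @param ... Passed to [plot.replicate_set()].
#' @return `x`, invisibly.
#' @export
plot.fly_experiment <- function(x, max_lines = 100, ...) {
  sets <- x$sets
  n <- length(sets)
  nc <- min(3L, n)
  nr <- ceiling(n / nc)
  ymax <- max(vapply(sets, function(s)
    max(s$adult_trajectories[seq_len(min(nrow(s$adult_trajectories),
                                         max_lines)), ]), 0), 1)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(4, 4, 2.5, 1))
  on.exit(graphics::par(op))
  for (s in sets) plot(s, max_lines = max_lines, ylim = c(0, ymax), ...)
  invisible(x)
}
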