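# Color-coded trajectory plots. Paths are drawn as right-continuous step
# functions (the cadlag convention for the discrete approximation); when a
# state functional is supplied, segments are colored on a perceptually
# ordered red-to-yellow map — red at the low end, yellow at the high end.

#' Plot an ensemble of Feller paths, color-coded by a state functional
#'
#' Time on the horizontal axis, state on the vertical; each path is drawn as
#' a right-continuous step function. With `value_fn` (for example the local
#' stability index \eqn{\alpha(x)} of the stable-like family) every segment
#' is colored by the functional of its left state on a continuous red-to-
#' yellow map: red marks the minimum of the functional over the plotted
#' range, yellow the maximum. A constant functional gives a single-color
#' rendering.
#'
#' @param paths A `feller_paths` object with at least one path.
#' @param value_fn Optional vectorised function of the state.
#' @param file Optional PNG destination; `NULL` draws on the active device.
#' @param main Plot title.
#' @param ... Passed to [graphics::plot()].
#' @return The destination (or `NULL`), invisibly.
#' @export
plot_paths <- function(paths, value_fn = NULL, file = NULL,
                       main = attr(paths, "model"), ...) {
  if (is.null(paths) || nrow(paths) == 0) {
    stop("no paths to plot", call. = FALSE)
  }
  stopifnot(all(c("path_id", "time", "state") %in% names(paths)))
  palette <- grDevices::colorRampPalette(c("red", "orange", "yellow"))(256)
  if (is.null(value_fn)) {
    seg_color <- function(states) rep("grey25", length(states))
  } else {
    all_v <- value_fn(paths$state)
    if (any(!is.finite(all_v))) {
      stop("`value_fn` returned non-finite values on the plotted range",
           call. = FALSE)
    }
    vr <- range(all_v)
    seg_color <- function(states) {
      v <- value_fn(states)
      idx <- if (diff(vr) == 0) rep(1L, length(v))
             else 1L + as.integer(round(
               255 * pmin(pmax(v - vr[1], 0), diff(vr)) / diff(vr)))
      palette[idx]
    }
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 560)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(range(paths$time), range(paths$state), type = "n",
                 xlab = "time", ylab = "state", main = main, ...)
  for (id in unique(paths$path_id)) {
    p <- paths[paths$path_id == id, ]
    k <- nrow(p)
    if (k < 2) next
    col <- seg_color(p$state[-k])
    # horizontal piece of each step (value held right-continuously) ...
    graphics::segments(p$time[-k], p$state[-k], p$time[-1], p$state[-k],
                       col = col, lwd = 1.4)
    # ... and the jump at the step time
    graphics::segments(p$time[-1], p$state[-k], p$time[-1], p$state[-1],
                       col = col, lwd = 0.6, lty = 3)
  }
  invisible(file)
}

#' @export
plot.feller_paths <- function(x, value_fn = NULL, file = NULL, ...) {
  plot_paths(x, value_fn = value_fn, file = file, ...)
}
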