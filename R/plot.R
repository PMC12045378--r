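#' @importFrom graphics image lines matlines matplot points legend
NULL

#' @export
#' @rdname param_sweep
#' @param x an `mlsel_sweep` object.
#' @param which which statistic matrix to draw, `"s"` or `"theta"`.
#' @param ... further arguments passed to [graphics::image()].
plot.mlsel_sweep <- function(x, which = c("s", "theta"), ...) {
  which <- match.arg(which)
  z <- x[[which]]
  pal <- if (which == "s") grDevices::hcl.colors(21, "Blue-Red 2")
         else grDevices::hcl.colors(21, "Viridis")
  image(x$x, x$y, z, col = pal, xlab = x$xname, ylab = x$yname,
        main = if (which == "s") expression(group("<", S, ">"))
               else expression(group("<", Theta, ">")), ...)
  invisible(x)
}

#' @export
#' @rdname trajectory_ensemble
#' @param x an `mlsel_ensemble` object.
#' @param ... further arguments passed to [graphics::matplot()].
plot.mlsel_ensemble <- function(x, ...) {
  if (is.null(x$trajectories)) stop("ensemble was run with record = FALSE")
  wide <- matrix(x$trajectories$Ng, ncol = x$M)
  matplot(wide, type = "l", lty = 1,
          col = grDevices::adjustcolor("grey40", 0.3),
          xlab = "t", ylab = "Ng", ...)
  lines(x$mean$t + 1, x$mean$Ng, lwd = 3)
  invisible(x)
}

#' @export
#' @rdname biofilm_state
#' @param x an `mlsel_biofilm` object.
#' @param ... further arguments passed to [plot()].
plot.mlsel_biofilm <- function(x, ...) {
  d <- ncol(x$positions)
  plot(x$positions[, 1], x$positions[, d],
       col = ifelse(x$social, "forestgreen", "tan4"), pch = 16,
       xlab = "x", ylab = "height", asp = 1, ...)
  invisible(x)
}
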