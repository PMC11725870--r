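#' Plot a cluster size distribution
#'
#' Log-scale density versus cluster size, the standard presentation for
#' monotonically decreasing HOTS distributions; optionally overlays model
#' curves (e.g. from [predict_curve()]).
#'
#' @param x A [size_distribution].
#' @param curves Optional list of [size_distribution]s drawn as lines.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.size_distribution <- function(x, curves = NULL, ...) {
  keep <- x$density > 0
  graphics::plot(x$n[keep], x$density[keep], log = "y", pch = 16,
                 xlab = "cluster size n",
                 ylab = expression(density ~ (mu * m^-2)), ...)
  if (!is.null(curves)) {
    if (inherits(curves, "size_distribution")) curves <- list(curves)
    for (i in seq_along(curves)) {
      cv <- curves[[i]]
      ok <- cv$density > 0
      graphics::lines(cv$n[ok], cv$density[ok], col = i + 1)
    }
  }
  invisible(x)
}

#' Plot a point pattern
#'
#' Label coordinates inside their membrane-region polygon, in nm.
#'
#' @param x A [point_pattern()].
#' @param cex Point size (default 0.3).
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.point_pattern <- function(x, cex = 0.3, ...) {
  reg <- attr(x, "region")
  graphics::plot(rbind(reg, reg[1, ]), type = "l", asp = 1,
                 xlab = "x (nm)", ylab = "y (nm)", ...)
  graphics::points(x$x, x$y, pch = 16, cex = cex)
  invisible(x)
}
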