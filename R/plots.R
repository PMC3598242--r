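# Display helpers mirroring the standard figures of this analysis: the
# per-nucleus MeC/DAPI scatter (codistribution) and the cumulative LIM/LID
# shell-profile curve with its uniform-density diagonal.

#' Plot a codistribution as a scatter-style density image
#'
#' @param h a [joint_histogram()] result.
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @export
plot_codistribution <- function(h, main = "MeC/DAPI codistribution", ...) {
  stopifnot(inherits(h, "codistribution"))
  xm <- seq(h$range$dapi[1], h$range$dapi[2], length.out = h$bins[2])
  ym <- seq(h$range$mec[1], h$range$mec[2], length.out = h$bins[1])
  graphics::image(xm, ym, t(log1p(h$mass)),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "DAPI intensity", ylab = "MeC intensity",
                  main = main, useRaster = TRUE, ...)
}

#' Plot a cumulative shell profile
#'
#' Cumulative site fraction against cumulative volume fraction (periphery
#' inward); the diagonal marks hypothetically uniform site density across the
#' nuclear volume, and the vertical guide at V/V_tot = 0.5 marks the
#' peripheral-half statistic.
#'
#' @param profile a [shell_profile()] result.
#' @param main plot title.
#' @param ... passed to [graphics::plot()].
#' @export
plot_shell_profile <- function(profile, main = "LIM/LID shell profile", ...) {
  stopifnot(inherits(profile, "shell_profile"))
  graphics::plot(profile$curve$v_frac, profile$curve$site_frac, type = "b",
                 pch = 19, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = expression(V / V[tot]),
                 ylab = "cumulative site fraction", main = main, ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  graphics::abline(v = 0.5, lty = 3, col = "grey70")
  if (!isTRUE(profile$no_sites)) {
    graphics::points(0.5, profile$half_fraction, col = "red", pch = 4)
  }
}
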