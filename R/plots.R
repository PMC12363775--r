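#' Plot an MSD curve
#'
#' @param x an `msd_curve` from [msd()].
#' @param fit optional [fit_diffusion()] result to overlay.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.msd_curve <- function(x, fit = NULL, ...) {
  plot(x$lag, x$msd, type = "l", xlab = "lag (ns)",
       ylab = expression(MSD ~ (ring(A)^2)),
       main = paste("MSD,", attr(x, "category")), ...)
  if (!is.null(fit)) {
    graphics::abline(fit$intercept, fit$d * 4, col = 2, lty = 2)
    graphics::legend("topleft", bty = "n", legend = sprintf(
      "D = %.3g Å²/ns (R² = %.3f)", fit$d, fit$r_squared))
  }
  invisible(x)
}

#' Bar comparison of fitted diffusion coefficients
#'
#' @param fits named list of [fit_diffusion()] results (e.g. bulk/complex).
#' @param ... passed to [graphics::barplot()].
#' @return the bar midpoints, invisibly.
#' @export
plot_diffusion_bars <- function(fits, ...) {
  d <- vapply(fits, `[[`, 0, "d")
  se <- vapply(fits, `[[`, 0, "d_se")
  bp <- graphics::barplot(d, ylab = expression(D ~ (ring(A)^2 / ns)),
                          ylim = c(0, max(d + 3 * se)), ...)
  graphics::arrows(bp, d - se, bp, d + se, angle = 90, code = 3,
                   length = 0.05)
  invisible(bp)
}

#' Plot a per-residue interaction profile
#'
#' Score against residue ID with optional marker lines at residues of
#' interest.
#'
#' @param x an [interaction_score()] profile.
#' @param mark residue IDs to mark with vertical lines.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.interaction_profile <- function(x, mark = NULL, ...) {
  agg <- stats::aggregate(list(score = x$score), list(res_id = x$res_id),
                          mean)
  plot(agg$res_id, agg$score, type = "h", lwd = 2, xlab = "residue",
       ylab = "interaction score s", ...)
  if (!is.null(mark)) graphics::abline(v = mark, col = 2, lty = 3)
  invisible(x)
}

#' Overlay TG clusters on the toroid outline
#'
#' XY scatter of TG glycerol centroids coloured by cluster, with the
#' chamber annulus drawn as two circles.
#'
#' @param traj a [trajectory()].
#' @param sel a [build_selection()] result.
#' @param labels a [cluster_tg()] labelling.
#' @param chamber optional `list(center, r_inner, r_outer)`.
#' @param frame frame index.
#' @param ... passed to [plot()].
#' @return invisibly, the plotted coordinates.
#' @export
plot_clusters <- function(traj, sel, labels, chamber = NULL, frame = 1L,
                          ...) {
  gl <- .glycerol_centroids(traj, sel, dims = 2L)
  xy <- matrix(gl[frame, , ], ncol = 2)
  plot(xy, col = labels, pch = 19, asp = 1, xlab = "x (Å)",
       ylab = "y (Å)", ...)
  if (!is.null(chamber)) {
    th <- seq(0, 2 * pi, length.out = 200)
    for (r in c(chamber$r_inner, chamber$r_outer))
      graphics::lines(chamber$center[1] + r * cos(th),
                      chamber$center[2] + r * sin(th), lty = 2)
  }
  invisible(xy)
}
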