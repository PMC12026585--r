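# Basic plotting: time courses and bistochastic-matrix heatmaps.

#' Plot a simulated time course
#'
#' One line per species; the end product typically rises, overshoots and
#' settles while the first (allosteric) species is repressed.
#'
#' @param traj matrix from [simulate_cascade()].
#' @param ... passed to [graphics::matplot()].
#' @return `NULL`, invisibly.
#' @export
plot_trajectory <- function(traj, ...) {
  graphics::matplot(traj[, 1], traj[, -1, drop = FALSE], type = "l", lty = 1,
                    xlab = "time", ylab = "concentration", ...)
  graphics::legend("topright", legend = colnames(traj)[-1],
                   col = seq_len(ncol(traj) - 1L), lty = 1, cex = 0.8)
  invisible(NULL)
}

#' @export
plot.bistochastic_matrix <- function(x, ...) {
  d <- nrow(x$values)
  graphics::image(seq_len(d), seq_len(d), t(x$values[d:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE),
                  xlab = "binding-site class", ylab = "phenotype row",
                  axes = FALSE, ...)
  graphics::axis(1, at = seq_len(d)); graphics::axis(2, at = seq_len(d),
                                                     labels = rev(seq_len(d)))
  invisible(x)
}
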