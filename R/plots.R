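#' Trace overlay plot
#'
#' Ground-truth and predicted hyoid paths between onset and offset,
#' relative to the ground-truth onset location, plus per-axis time series
#' - the standard presentation of swallowing kinematics.
#'
#' @param trace,gt data frames / matrices of centres.
#' @param events list with 0-based `hyoid_onset`, `hyoid_offset`.
#' @param main title.
#' @return invisibly `NULL`; draws on the current device.
#' @export
plot_trace <- function(trace, gt, events, main = "Hyoid trace") {
  p <- as_xy(trace); g <- as_xy(gt)
  idx <- (events$hyoid_onset:events$hyoid_offset) + 1L
  org <- g[events$hyoid_onset + 1L, ]
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  graphics::plot(g[idx, 1] - org[1], g[idx, 2] - org[2], type = "l",
                 col = "blue", xlab = "x - x(onset) [px]",
                 ylab = "y - y(onset) [px]", main = main,
                 ylim = rev(range(c(g[idx, 2], p[idx, 2]) - org[2])))
  graphics::lines(p[idx, 1] - org[1], p[idx, 2] - org[2], col = "orange")
  graphics::legend("topright", c("ground truth", "inference"),
                   col = c("blue", "orange"), lty = 1, bty = "n")
  for (ax in 1:2) {
    graphics::plot(idx - 1, g[idx, ax] - org[ax], type = "l", col = "blue",
                   xlab = "frame", ylab = paste0(c("x", "y")[ax],
                                                 " - onset [px]"),
                   main = paste0(c("x", "y")[ax], "-axis"))
    graphics::lines(idx - 1, p[idx, ax] - org[ax], col = "orange")
  }
  invisible(NULL)
}

#' Precision plot
#'
#' Mean distance-precision curves at a range of centre-error thresholds,
#' one line per tracker.
#'
#' @param curves named list of data frames `threshold_px`, `precision`.
#' @param main title.
#' @return invisibly `NULL`.
#' @export
plot_precision <- function(curves, main = "Precision plot") {
  if (is.data.frame(curves)) curves <- list(tracker = curves)
  cols <- grDevices::hcl.colors(max(3, length(curves)), "Dark 3")
  graphics::plot(NULL, xlim = range(curves[[1]]$threshold_px),
                 ylim = c(0, 1), xlab = "location error threshold [px]",
                 ylab = "precision", main = main)
  for (i in seq_along(curves))
    graphics::lines(curves[[i]]$threshold_px, curves[[i]]$precision,
                    col = cols[i], lwd = 2)
  p10 <- vapply(curves, function(cv)
    cv$precision[which.min(abs(cv$threshold_px - 10))], 0)
  graphics::legend("bottomright",
                   sprintf("%s [%.1f%% @10px]", names(curves), 100 * p10),
                   col = cols[seq_along(curves)], lwd = 2, bty = "n")
  invisible(NULL)
}

#' Per-frame centre-error plot
#'
#' @param delta centre-error series from [center_error()].
#' @param threshold horizontal reference threshold (pixels).
#' @param main title.
#' @return invisibly `NULL`.
#' @export
plot_center_error <- function(delta, threshold = 10, main = "Center error") {
  graphics::plot(seq_along(delta) - 1, delta, type = "l", col = "steelblue",
                 xlab = "frame", ylab = "center error [px]", main = main)
  graphics::abline(h = threshold, col = "red", lty = 2)
  invisible(NULL)
}
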