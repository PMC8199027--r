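#' Pixel / millimetre calibration
#'
#' @param mm_per_px millimetres per pixel (0.325 in the emulated dataset).
#' @param px_per_mm pixels per millimetre; defaults to the printed 3.078
#'   when `mm_per_px` is the default, otherwise the exact reciprocal. The
#'   pair must be mutually reciprocal within 0.1%.
#' @return object of class `unit_calibration`.
#' @export
unit_calibration <- function(mm_per_px = 0.325,
                             px_per_mm = if (mm_per_px == 0.325) 3.078
                                         else 1 / mm_per_px) {
  if (mm_per_px <= 0 || px_per_mm <= 0)
    stop("calibration factors must be positive")
  if (abs(mm_per_px * px_per_mm - 1) > 1e-3)
    stop("mm_per_px and px_per_mm are not reciprocal within 0.1%")
  structure(list(mm_per_px = mm_per_px, px_per_mm = px_per_mm),
            class = "unit_calibration")
}

#' Convert between pixels and millimetres
#'
#' @param value numeric vector.
#' @param calibration a [unit_calibration()].
#' @param direction `"px_to_mm"` or `"mm_to_px"`.
#' @return converted values.
#' @export
convert_px_mm <- function(value, calibration = unit_calibration(),
                          direction = c("px_to_mm", "mm_to_px")) {
  direction <- match.arg(direction)
  if (direction == "px_to_mm") value * calibration$mm_per_px
  else value / calibration$mm_per_px
}

#' Round for millimetre display (2 decimals, half away from zero)
#'
#' Reproduces the printed conversions 10 px -> 3.25 mm and 5 px -> 1.63 mm
#' (1.625 rounds away from zero, unlike banker's rounding).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded values.
#' @export
round_mm <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Per-frame centre error
#'
#' Euclidean distance between predicted and ground-truth centres at every
#' frame.
#'
#' @param trace,gt n x 2 matrices or data frames with `x`, `y` columns of
#'   equal length.
#' @return numeric vector of per-frame distances (pixels).
#' @export
center_error <- function(trace, gt) {
  p <- as_xy(trace); g <- as_xy(gt)
  if (nrow(p) != nrow(g))
    stop("trace and ground truth differ in length (", nrow(p), " vs ",
         nrow(g), ")")
  sqrt((p[, 1] - g[, 1])^2 + (p[, 2] - g[, 2])^2)
}

as_xy <- function(m) {
  if (is.data.frame(m)) m <- cbind(m$x, m$y)
  if (!is.matrix(m) || ncol(m) < 2) stop("expected x/y columns")
  if (any(!is.finite(m[, 1:2]))) stop("non-finite coordinates")
  m[, 1:2, drop = FALSE]
}

#' Precision at a centre-error threshold
#'
#' Fraction of frames whose centre error is within (inclusively) the
#' threshold.
#'
#' @param delta centre-error series from [center_error()].
#' @param threshold distance threshold in pixels (>= 0).
#' @return fraction in `[0, 1]`.
#' @export
precision_at <- function(delta, threshold) {
  if (!length(delta)) stop("empty center-error series")
  if (threshold < 0) stop("threshold must be >= 0")
  mean(delta <= threshold)
}

#' One-pass-evaluation precision curve
#'
#' Precision evaluated at each threshold; the underlying trace comes from
#' a single initialisation with zero re-initialisation (OPE), so the curve
#' is non-decreasing in the threshold.
#'
#' @param delta centre-error series.
#' @param thresholds ascending thresholds in pixels.
#' @return data frame `threshold_px`, `precision`.
#' @export
precision_curve <- function(delta, thresholds = 1:50) {
  if (is.unsorted(thresholds)) stop("thresholds must be sorted ascending")
  data.frame(threshold_px = thresholds,
             precision = vapply(thresholds, function(th)
               precision_at(delta, th), 0))
}

#' Root-mean-square and average centre error
#'
#' @param delta centre-error series.
#' @return scalar in pixels.
#' @export
rmse <- function(delta) {
  if (!length(delta)) stop("empty center-error series")
  sqrt(mean(delta^2))
}

#' @rdname rmse
#' @export
ae <- function(delta) {
  if (!length(delta)) stop("empty center-error series")
  mean(delta)
}

#' Per-axis Pearson correlation between trace and ground truth
#'
#' @param trace,gt n x 2 matrices or data frames (equal length, n >= 2).
#' @param axis `"x"` or `"y"`.
#' @return Pearson coefficient, or `NA` with a warning when either series
#'   has zero variance.
#' @export
pearson_axis <- function(trace, gt, axis = c("x", "y")) {
  axis <- match.arg(axis)
  k <- if (axis == "x") 1L else 2L
  p <- as_xy(trace)[, k]; g <- as_xy(gt)[, k]
  if (length(p) != length(g)) stop("length mismatch")
  if (length(p) < 2L) stop("need at least 2 frames")
  if (stats::sd(p) == 0 || stats::sd(g) == 0) {
    warning("zero variance on the ", axis,
            " axis; Pearson correlation undefined")
    return(NA_real_)
  }
  stats::cor(p, g)
}

#' Range of motion between hyoid onset and offset
#'
#' With the onset position as reference, the per-axis ROM is the maximum
#' absolute displacement over `[onset, offset]`, and the straight-line ROM
#' the maximum Euclidean distance from the onset point (per-axis maxima
#' may occur at different frames).
#'
#' @param track n x 2 matrix or data frame of centres.
#' @param onset,offset 0-based frame indices, `onset < offset`.
#' @return list with `rom_x`, `rom_y`, `rom_line` in pixels.
#' @export
rom <- function(track, onset, offset) {
  if (is.null(onset) || is.null(offset) || is.na(onset) || is.na(offset))
    stop("onset/offset events are missing")
  m <- as_xy(track)
  n <- nrow(m)
  if (onset < 0 || offset > n - 1 || onset >= offset)
    stop("need 0 <= onset < offset <= ", n - 1)
  idx <- (onset:offset) + 1L
  dx <- m[idx, 1] - m[onset + 1L, 1]
  dy <- m[idx, 2] - m[onset + 1L, 2]
  list(rom_x = max(abs(dx)), rom_y = max(abs(dy)),
       rom_line = max(sqrt(dx^2 + dy^2)))
}

#' Relative ROM error in percent
#'
#' `|ROM_gt - ROM_pred| / ROM_gt * 100`.
#'
#' @param rom_gt,rom_pred scalars (same units); `rom_gt > 0`.
#' @return percent, or `NA` with a warning when `rom_gt` is 0.
#' @export
rom_relative_error <- function(rom_gt, rom_pred) {
  if (rom_gt == 0) {
    warning("ground-truth ROM is zero; relative error undefined")
    return(NA_real_)
  }
  abs(rom_gt - rom_pred) / rom_gt * 100
}

#' Full kinematic evaluation of one trace
#'
#' Computes the complete metric suite for one sequence: the centre-error
#' series, the OPE precision curve with the named 5 px and 10 px points,
#' RMSE and average error, per-axis Pearson correlations, and ground-truth
#' vs predicted ROM (per axis and straight line, pixels and millimetres)
#' with relative errors.
#'
#' @param trace predicted centres (data frame `frame,x,y` or n x 2 matrix).
#' @param gt ground-truth points, same length.
#' @param events list with 0-based `hyoid_onset` and `hyoid_offset`
#'   (optional: ROM entries become `NA` when absent).
#' @param calibration a [unit_calibration()].
#' @param thresholds precision-curve thresholds (pixels).
#' @return object of class `hyoid_eval` (a list of all metrics).
#' @export
evaluate_trace <- function(trace, gt, events = NULL,
                           calibration = unit_calibration(),
                           thresholds = 1:50) {
  delta <- center_error(trace, gt)
  curve <- precision_curve(delta, thresholds)
  res <- list(
    n_frames = length(delta),
    ce_series = delta,
    precision_curve = curve,
    precision_at_5 = precision_at(delta, 5),
    precision_at_10 = precision_at(delta, 10),
    rmse = rmse(delta), ae = ae(delta),
    rmse_mm = convert_px_mm(rmse(delta), calibration),
    ae_mm = convert_px_mm(ae(delta), calibration),
    pearson_x = pearson_axis(trace, gt, "x"),
    pearson_y = pearson_axis(trace, gt, "y"))
  if (!is.null(events) && !is.null(events$hyoid_onset) &&
      !is.null(events$hyoid_offset)) {
    rg <- rom(gt, events$hyoid_onset, events$hyoid_offset)
    rp <- rom(trace, events$hyoid_onset, events$hyoid_offset)
    res$rom_gt <- rg
    res$rom_pred <- rp
    res$rom_gt_mm <- lapply(rg, convert_px_mm, calibration = calibration)
    res$rom_pred_mm <- lapply(rp, convert_px_mm, calibration = calibration)
    res$rel_rom_x <- rom_relative_error(rg$rom_x, rp$rom_x)
    res$rel_rom_y <- rom_relative_error(rg$rom_y, rp$rom_y)
    res$rel_rom_line <- rom_relative_error(rg$rom_line, rp$rom_line)
  }
  structure(res, class = "hyoid_eval")
}

#' @export
print.hyoid_eval <- function(x, ...) {
  cat(sprintf("Kinematic evaluation over %d frames\n", x$n_frames))
  cat(sprintf("  precision@10px %.1f%%  @5px %.1f%%\n",
              100 * x$precision_at_10, 100 * x$precision_at_5))
  cat(sprintf("  RMSE %.2f px (%.2f mm)  AE %.2f px (%.2f mm)\n",
              x$rmse, round_mm(x$rmse_mm), x$ae, round_mm(x$ae_mm)))
  cat(sprintf("  Pearson x %.3f  y %.3f\n", x$pearson_x, x$pearson_y))
  if (!is.null(x$rel_rom_line))
    cat(sprintf("  relative ROM error: x %.1f%%  y %.1f%%  line %.1f%%\n",
                x$rel_rom_x, x$rel_rom_y, x$rel_rom_line))
  invisible(x)
}

#' Aggregate per-sequence evaluations
#'
#' Mean and sample (n-1) SD of each scalar metric across sequences, with
#' precision curves averaged pointwise so every sequence carries equal
#' weight (set `pool_frames = TRUE` to pool all frames instead).
#'
#' @param reports list of `hyoid_eval` objects.
#' @param pool_frames pool frames across sequences for the precision curve
#'   instead of averaging per-sequence curves.
#' @return list with `summary` (data frame metric/mean/sd), `curve`
#'   (aggregate precision curve), `n_sequences`.
#' @export
aggregate_reports <- function(reports, pool_frames = FALSE) {
  if (!length(reports)) stop("no reports to aggregate")
  scalars <- c("precision_at_10", "precision_at_5", "rmse", "ae",
               "pearson_x", "pearson_y", "rel_rom_x", "rel_rom_y",
               "rel_rom_line")
  rows <- lapply(scalars, function(m) {
    v <- vapply(reports, function(r)
      if (is.null(r[[m]])) NA_real_ else as.numeric(r[[m]]), 0)
    v <- v[is.finite(v)]
    if (!length(v)) return(data.frame(metric = m, mean = NA_real_,
                                      sd = NA_real_))
    data.frame(metric = m, mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else 0)
  })
  summary <- do.call(rbind, rows)
  ths <- reports[[1]]$precision_curve$threshold_px
  if (pool_frames) {
    all_delta <- unlist(lapply(reports, function(r) r$ce_series))
    curve <- precision_curve(all_delta, ths)
  } else {
    pm <- sapply(reports, function(r) r$precision_curve$precision)
    curve <- data.frame(threshold_px = ths,
                        precision = rowMeans(as.matrix(pm)))
  }
  list(summary = summary, curve = curve, n_sequences = length(reports))
}
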