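#' Patch geometry and score-map hyperparameters for the Siamese tracker
#'
#' @param exemplar_size exemplar patch side in pixels (127).
#' @param search_size search patch side in pixels (255).
#' @param context_factor margin added around the target box before
#'   cropping: with box `w` x `h` the context pad is
#'   `context_factor * (w + h)` per side pair, giving exemplar crop side
#'   `sqrt((w + 2p)(h + 2p))` with `p = context_factor * (w + h) / 2`.
#'   The default 0.5 is the classic Siamese convention.
#' @param n_scales number of scale hypotheses per frame (odd).
#' @param scale_step multiplicative scale step between hypotheses (> 1).
#' @param scale_penalty multiplicative penalty applied to the score maps of
#'   non-central scales.
#' @param scale_damping damping of the scale-state update in `[0, 1]`.
#' @param window_weight cosine-window blending weight in `[0, 1]`.
#' @param upsample_factor integer bicubic upsampling factor of the raw
#'   score map.
#' @return object of class `siamfc_spec`.
#' @export
patch_spec <- function(exemplar_size = 127L, search_size = 255L,
                       context_factor = 0.5, n_scales = 3L,
                       scale_step = 1.025, scale_penalty = 0.9745,
                       scale_damping = 0.59, window_weight = 0.176,
                       upsample_factor = 16L) {
  exemplar_size <- as.integer(exemplar_size)
  search_size <- as.integer(search_size)
  if (exemplar_size >= search_size)
    stop("exemplar_size must be smaller than search_size")
  n_scales <- as.integer(n_scales)
  if (n_scales < 1L || n_scales %% 2L == 0L)
    stop("n_scales must be a positive odd number")
  if (scale_step <= 1) stop("scale_step must exceed 1")
  if (upsample_factor < 1) stop("upsample_factor must be >= 1")
  structure(list(exemplar_size = exemplar_size, search_size = search_size,
                 context_factor = context_factor, n_scales = n_scales,
                 scale_step = scale_step, scale_penalty = scale_penalty,
                 scale_damping = scale_damping,
                 window_weight = window_weight,
                 upsample_factor = as.integer(upsample_factor)),
            class = "siamfc_spec")
}

# context-padded square crop side for a w x h target box
context_crop_side <- function(box_size, context_factor = 0.5) {
  w <- box_size[1]; h <- box_size[2]
  p <- context_factor * (w + h) / 2
  sqrt((w + 2 * p) * (h + 2 * p))
}

#' Cosine (Hann) window
#'
#' @param n side length.
#' @return n x n outer product of Hann tapers, peak at the grid centre.
#' @export
cosine_window <- function(n) {
  if (n == 1L) return(matrix(1, 1, 1))
  h <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  outer(h, h)
}

#' Select the peak response across scale score maps
#'
#' Two stages, the convention of classic Siamese trackers. First the scale
#' is chosen: each map's maximum is multiplied by `scale_penalty` if it
#' does not belong to the central scale, and the scale with the largest
#' penalised maximum wins (ties to the smallest scale index). The winning
#' map is then normalised to a unit-sum distribution (subtract min, divide
#' by sum) and blended with the unit-sum cosine window,
#' `(1 - w) * map + w * window`; the argmax of the blend is the peak
#' (ties to the lexicographically smallest `(row, col)`).
#'
#' @param grids list of equally sized score matrices, one per scale.
#' @param window cosine window matrix of the same size (see
#'   [cosine_window()]); normalised internally.
#' @param window_weight blending weight in `[0, 1]`.
#' @param scale_penalty penalty multiplier for non-central scales.
#' @return list with `peak` (1-based `c(row, col)`), `scale_index`, and the
#'   blended `response` of the winning scale.
#' @export
select_peak <- function(grids, window, window_weight = 0.176,
                        scale_penalty = 0.9745) {
  if (!length(grids)) stop("no score maps supplied")
  central <- (length(grids) + 1L) %/% 2L
  pen <- vapply(seq_along(grids), function(g)
    max(grids[[g]]) * if (g == central) 1 else scale_penalty, 0)
  si <- which.max(pen)             # first maximum: smallest scale index
  a <- grids[[si]]
  a <- a - min(a)
  s <- sum(a)
  if (s > 0) a <- a / s else a[] <- 1 / length(a)
  a <- (1 - window_weight) * a + window_weight * window / sum(window)
  ij <- which(a == max(a), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE][1, ]
  list(peak = c(row = ij[[1]], col = ij[[2]]), scale_index = si,
       response = a)
}

#' Convert a score-map peak to an image-space displacement
#'
#' The peak's offset from the grid centre, divided by the upsampling
#' factor, times the backbone stride, times the search-patch scale
#' (crop side / search size) gives the displacement of the target centre
#' in image pixels.
#'
#' @param peak `c(row, col)` peak position (1-based, upsampled grid).
#' @param grid_center `c(row, col)` of the grid centre (1-based).
#' @param total_stride backbone stride in pixels.
#' @param upsample_factor integer upsampling factor.
#' @param search_scale image pixels per search-patch pixel.
#' @return `c(dx, dy)` displacement in image pixels.
#' @export
displacement_to_image <- function(peak, grid_center, total_stride,
                                  upsample_factor, search_scale) {
  drc <- (peak - grid_center) * total_stride / upsample_factor * search_scale
  c(dx = unname(drc[2]), dy = unname(drc[1]))
}

#' Track one sequence with the Siamese tracker
#'
#' One-pass evaluation protocol: the exemplar embedding is computed once
#' from the initialisation box on frame 0 and never updated; each
#' subsequent frame is searched with a pyramid of scale hypotheses centred
#' on the previous estimate, and the selected peak displaces the centre.
#' Ground truth beyond frame 0 is never consumed.
#'
#' @param frames list of grayscale integer matrices, or an accessor
#'   `function(i)` with attribute `n_frames`.
#' @param init_box list with `center` (`c(x, y)`, 0-based pixels) and
#'   `size` (`c(w, h)` pixels, default 30 x 30).
#' @param backbone a trained [siamfc_backbone()].
#' @param spec a [patch_spec()].
#' @return data frame `frame` (0-based), `x`, `y`: one centre per frame;
#'   frame 0 equals the initialisation centre exactly.
#' @export
track_sequence <- function(frames, init_box, backbone,
                           spec = patch_spec()) {
  stopifnot(inherits(backbone, "siamfc_backbone"),
            inherits(spec, "siamfc_spec"))
  if (is.function(frames)) {
    n <- attr(frames, "n_frames")
    get_frame <- frames
  } else {
    n <- length(frames)
    get_frame <- function(i) frames[[i]]
  }
  if (!n) stop("empty frame list")
  f0 <- get_frame(1)
  h <- nrow(f0); w <- ncol(f0)
  center <- as.numeric(init_box$center)
  box_size <- if (is.null(init_box$size)) c(30, 30)
              else as.numeric(init_box$size)
  if (center[1] < 0 || center[1] > w - 1 || center[2] < 0 ||
      center[2] > h - 1)
    stop("init box centre outside the first frame")

  s_z <- context_crop_side(box_size, spec$context_factor)
  s_x <- s_z * spec$search_size / spec$exemplar_size
  ex_patch <- crop_patch(f0, center, s_z, spec$exemplar_size) / 255
  ex_feat <- embed(ex_patch, backbone)

  score_side <- backbone_out_size(backbone, spec$search_size) - dim(ex_feat)[1] + 1L
  up_side <- (score_side - 1L) * spec$upsample_factor + 1L
  window <- cosine_window(up_side)
  grid_center <- c((up_side + 1) / 2, (up_side + 1) / 2)
  ks <- seq_len(spec$n_scales) - (spec$n_scales + 1L) / 2L
  scale_mults <- spec$scale_step^ks

  xs <- numeric(n); ys <- numeric(n)
  xs[1] <- center[1]; ys[1] <- center[2]
  if (n > 1L) for (t in 2:n) {
    fr <- get_frame(t)
    fill <- mean(fr)
    grids <- vector("list", spec$n_scales)
    sides <- s_x * scale_mults
    for (g in seq_len(spec$n_scales)) {
      patch <- cpp_crop_resize(matrix(as.numeric(fr), h, w), center[1],
                               center[2], sides[g], spec$search_size,
                               fill) / 255
      feat <- backbone_forward(backbone, patch)$out
      raw <- cross_correlate(ex_feat, feat) * backbone$score_scale +
        backbone$score_bias
      grids[[g]] <- upsample_score(raw, spec$upsample_factor)
    }
    pk <- select_peak(grids, window, spec$window_weight, spec$scale_penalty)
    disp <- displacement_to_image(pk$peak, grid_center,
                                  backbone$total_stride,
                                  spec$upsample_factor,
                                  sides[pk$scale_index] / spec$search_size)
    center <- center + disp
    center[1] <- min(max(center[1], 0), w - 1)
    center[2] <- min(max(center[2], 0), h - 1)
    chosen <- scale_mults[pk$scale_index]
    s_x <- s_x * ((1 - spec$scale_damping) + spec$scale_damping * chosen)
    xs[t] <- center[1]; ys[t] <- center[2]
  }
  data.frame(frame = 0:(n - 1), x = xs, y = ys)
}
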